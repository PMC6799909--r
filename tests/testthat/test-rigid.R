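test_that("transform algebra satisfies the group axioms", {
  set.seed(44)
  id <- rigid_transform()
  expect_equal(invert_transform(id)$rotation, diag(3))
  expect_equal(apply_transform(rigid_transform(diag(3), c(1, 2, 3)),
                               c(0, 0, 0)), c(1, 2, 3))
  pts <- matrix(rnorm(300, 0, 40), 100, 3)
  for (i in 1:20) {
    A <- random_rigid(); B <- random_rigid()
    # inverse: T^-1 (T p) = p
    back <- apply_transform(invert_transform(A), apply_transform(A, pts))
    expect_lt(max(abs(back - pts)), 1e-9)
    # composition: (A o B)(p) = A(B(p))
    lhs <- apply_transform(compose_transforms(A, B), pts)
    rhs <- apply_transform(A, apply_transform(B, pts))
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper")
})

test_that("fit_rigid recovers constructed transforms exactly", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  id <- fit_rigid(tet, tet)
  expect_lt(max(abs(id$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(id$translation)), 1e-9)
  expect_equal(attr(id, "rms"), 0)

  R90 <- rotation_about(c(0, 0, 1), 90)
  tgt <- t(R90 %*% t(tet)) + rep(c(5, 0, 0), each = 4)
  tf <- fit_rigid(tet, tgt)
  expect_lt(max(abs(tf$rotation - R90)), 1e-9)
  expect_lt(max(abs(tf$translation - c(5, 0, 0))), 1e-9)
  expect_lt(attr(tf, "rms"), 1e-9)

  expect_error(fit_rigid(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                         rbind(c(0, 0, 0), c(0, 1, 0), c(0, 2, 0))),
               class = "markermorph_degenerate_error")
})

test_that("fit_rigid never returns a reflection", {
  tet <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  mirrored <- tet %*% diag(c(-1, 1, 1))     # improper motion
  tf <- fit_rigid(tet, mirrored)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  expect_gt(attr(tf, "rms"), 1)             # a proper fit cannot be exact
})

test_that("fit_rigid matches a small-angle grid-search oracle", {
  set.seed(55)
  tet <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  step <- 0.5
  grid <- seq(-4, 4, by = step)
  Rx <- lapply(grid, function(a) rotation_about(c(1, 0, 0), a))
  Ry <- lapply(grid, function(a) rotation_about(c(0, 1, 0), a))
  Rz <- lapply(grid, function(a) rotation_about(c(0, 0, 1), a))
  for (rep in 1:3) {
    angles <- runif(3, -3, 3)
    R_true <- rotation_about(c(1, 0, 0), angles[1]) %*%
      rotation_about(c(0, 1, 0), angles[2]) %*%
      rotation_about(c(0, 0, 1), angles[3])
    tgt <- tet %*% t(R_true)
    # exhaustive search over an Euler-angle grid (no translation)
    best <- c(Inf, NA, NA, NA)
    for (ix in seq_along(grid)) for (iy in seq_along(grid))
      for (iz in seq_along(grid)) {
        R <- Rx[[ix]] %*% Ry[[iy]] %*% Rz[[iz]]
        ss <- sum((tet %*% t(R) - tgt)^2)
        if (ss < best[1]) best <- c(ss, grid[ix], grid[iy], grid[iz])
      }
    tf <- fit_rigid(tet, tgt)
    ss_fit <- sum((apply_transform(tf, tet) - tgt)^2)
    expect_lte(ss_fit, best[1] + 1e-12)      # at least as good as the grid
    expect_lt(max(abs(best[2:4] - angles)), step)  # same optimum basin
    expect_lt(max(abs(tf$rotation - R_true)), 1e-9)
  }
})

test_that("scan registration recovers the scapular motion", {
  lm <- fixture_landmarks()
  expect_equal(register_scan(lm, lm)$rotation, diag(3), tolerance = 1e-12)

  set.seed(66)
  g <- random_rigid(20)
  moved <- transform_landmarks(lm, g)
  tf <- register_scan(lm, moved)      # maps follow-up back to reference
  ginv <- invert_transform(g)
  expect_lt(max(abs(tf$rotation - ginv$rotation)), 1e-9)
  expect_lt(max(abs(tf$translation - ginv$translation)), 1e-9)

  renamed <- lm
  rownames(renamed$groups$scapula) <- c("AA", "TS", "XX")
  expect_error(register_scan(lm, renamed),
               class = "markermorph_validation_error")
})

test_that("registration residuals stay modest under 0.5 mm landmark noise", {
  set.seed(77)
  lm <- fixture_landmarks()
  rms <- replicate(100, {
    noisy <- lm
    noisy$groups$scapula <- noisy$groups$scapula +
      matrix(rnorm(9, 0, 0.5), 3, 3)
    attr(register_scan(lm, noisy), "rms")
  })
  expect_lt(mean(rms), 0.9)
  expect_lt(max(rms), 2)
})

test_that("virtual markers are imputed exactly under rigid bone motion", {
  bone <- rbind(H1 = c(14.2, 28.5, 43.8), H2 = c(13.1, 40.0, 46.2),
                H3 = c(15.0, 50.5, 42.5))
  virt <- rbind(V1 = c(20, 25, 50.2), V2 = c(20, 31, 50.8),
                V3 = c(20, 43, 49.6), V4 = c(20, 53, 50.4))
  model <- virtual_marker_model(virt, bone)

  same <- impute_virtual_markers(model, bone)
  expect_lt(max(abs(same - virt)), 1e-9)
  expect_equal(attr(same, "rms"), 0, tolerance = 1e-12)

  R <- rotation_about(c(0, 0, 1), 30)
  g <- rigid_transform(R, c(3, -2, 5))
  moved <- impute_virtual_markers(model, apply_transform(g, bone))
  expect_lt(max(abs(moved - apply_transform(g, virt))), 1e-9)

  collinear <- rbind(H1 = c(0, 0, 0), H2 = c(1, 0, 0), H3 = c(2, 0, 0))
  expect_error(virtual_marker_model(virt, collinear),
               class = "markermorph_degenerate_error")
  expect_error(impute_virtual_markers(model, bone[1:2, ]), "H3")
})

test_that("measurements from imputed markers are rigid-motion invariant", {
  set.seed(88)
  bone <- rbind(H1 = c(14.2, 28.5, 43.8), H2 = c(13.1, 40.0, 46.2),
                H3 = c(15.0, 50.5, 42.5))
  virt <- rbind(V1 = c(20, 25, 50.2), V2 = c(20, 31, 50.8),
                V3 = c(20, 43, 49.6), V4 = c(20, 53, 50.4))
  tend <- rbind(T1 = c(33.2, 25.4, 51.1), T3 = c(32.6, 30.4, 50.1),
                T5 = c(33.5, 43.8, 50.1), T7 = c(32.9, 52.7, 50.0))
  model <- virtual_marker_model(virt, bone)
  ms <- patient_measurement_set()
  base <- measure_scan(rbind(tend, impute_virtual_markers(model, bone)), ms)
  for (i in 1:10) {
    g <- random_rigid(25)
    pos <- rbind(apply_transform(g, tend),
                 impute_virtual_markers(model, apply_transform(g, bone)))
    rec <- measure_scan(pos, ms)
    expect_lt(max(abs(rec$lengths - base$lengths)), 1e-6)
    expect_lt(max(abs(rec$areas - base$areas)), 1e-6)
  }
})
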