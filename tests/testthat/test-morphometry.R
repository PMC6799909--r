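test_that("marker_length is the Euclidean distance", {
  expect_equal(marker_length(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(marker_length(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(9)
  for (i in 1:50) {
    p <- rnorm(3, 0, 30); q <- rnorm(3, 0, 30)
    expect_equal(marker_length(p, q),
                 sqrt(sum((p - q)^2)), tolerance = 1e-12)
    expect_equal(marker_length(p, q), marker_length(q, p))
  }
})

test_that("quad_area matches hand-computed swap averages", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(quad_area(sq), 1)
  expect_equal(quad_area(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                               c(3, 0, 0))), 0)
  # non-planar worked example: triangulation A gives sqrt(2), B gives
  # (sqrt(3) + 1) / 2
  np <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 1), c(0, 1, 0))
  expect_equal(quad_area(np), (sqrt(2) + (sqrt(3) + 1) / 2) / 2,
               tolerance = 1e-12)
})

# shoelace area of a planar polygon, computed in an in-plane 2-D basis
shoelace_oracle <- function(pts, normal) {
  e1 <- pts[2, ] - pts[1, ]
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  uv <- sweep(pts, 2, pts[1, ]) %*% cbind(e1, e2)
  n <- nrow(uv)
  j <- c(2:n, 1)
  abs(sum(uv[, 1] * uv[j, 2] - uv[j, 1] * uv[, 2])) / 2
}

# random convex planar quadrilateral in a random 3-D plane
random_planar_quad <- function() {
  normal <- rnorm(3); normal <- normal / sqrt(sum(normal^2))
  e1 <- rnorm(3); e1 <- e1 - sum(e1 * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  # four points on a random ellipse, in cyclic order: always a convex
  # quadrilateral, for which both triangulations give the polygon area
  th <- sort(runif(4, 0, 2 * pi))
  ab <- runif(2, 2, 20)
  ctr <- rnorm(3, 0, 30)
  pts <- t(vapply(1:4, function(i)
    ctr + ab[1] * cos(th[i]) * e1 + ab[2] * sin(th[i]) * e2, numeric(3)))
  list(pts = pts, normal = normal)
}

test_that("quad_area equals the shoelace oracle on planar convex quads", {
  set.seed(10)
  for (i in 1:1000) {
    q <- random_planar_quad()
    a <- quad_area(q$pts)
    b <- shoelace_oracle(q$pts, q$normal)
    expect_lt(abs(a - b) / b, 1e-9)
  }
})

test_that("quad_area is rigid-invariant and cyclic-shift invariant", {
  set.seed(11)
  for (i in 1:50) {
    pts <- matrix(rnorm(12, 0, 15), 4, 3)
    a <- quad_area(pts)
    g <- random_rigid(40)
    expect_equal(quad_area(apply_transform(g, pts)), a,
                 tolerance = 1e-9)
    expect_equal(quad_area(pts[c(2, 3, 4, 1), ]), a, tolerance = 1e-9)
  }
})

test_that("projected angles match analytic cases", {
  expect_equal(projected_angle(c(0, 1, 1), c(0, 1, 1), c(1, 0, 0)), 0)
  expect_equal(projected_angle(c(0, 0, 1), c(0, 1, 1), c(1, 0, 0)), 45)
  expect_equal(projected_angle(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0)), 90)
  # out-of-plane components are discarded before measuring
  expect_equal(projected_angle(c(5, 0, 1), c(-3, 1, 1), c(1, 0, 0)), 45)
  # signed variant is antisymmetric
  s1 <- projected_angle(c(0, 0, 1), c(0, 1, 1), c(1, 0, 0), signed = TRUE)
  s2 <- projected_angle(c(0, 1, 1), c(0, 0, 1), c(1, 0, 0), signed = TRUE)
  expect_equal(s1, -s2)
  expect_error(projected_angle(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0)),
               class = "markermorph_projection_error")
})

test_that("humeral orientation recovers single-axis rotations", {
  scap <- scapular_frame(fixture_landmarks())
  expect_equal(as.numeric(humeral_orientation(scap, scap)), c(0, 0, 0),
               tolerance = 1e-9)
  rotate_frame <- function(frame, axis, deg) {
    R <- rotation_about(frame[[axis]], deg)
    transform_frame(frame, rigid_transform(R, frame$origin -
                                             as.vector(R %*% frame$origin)))
  }
  for (deg in c(-35, -20, 5, 20, 30)) {
    ab <- humeral_orientation(scap, rotate_frame(scap, "anterior", deg))
    expect_equal(as.numeric(ab), c(0, 0, abs(deg)), tolerance = 1e-9)
    rot <- humeral_orientation(scap, rotate_frame(scap, "superior", deg))
    expect_equal(as.numeric(rot), c(0, abs(deg), 0), tolerance = 1e-9)
    ext <- humeral_orientation(scap, rotate_frame(scap, "lateral", deg))
    expect_equal(as.numeric(ext)[1], abs(deg), tolerance = 1e-9)
  }
})

fixture_positions <- function() {
  spec <- cadaver_phantom_spec()
  m <- spec$markers
  pos <- as.matrix(m[, c("x", "y", "z")])
  rownames(pos) <- m$label
  pos
}

test_that("measure_scan evaluates the full cadaver protocol", {
  pos <- fixture_positions()
  lm <- fixture_landmarks()
  frames <- list(scapula = scapular_frame(lm), humerus = humeral_frame(lm))
  rec <- measure_scan(pos, cadaver_measurement_set(), frames,
                      scan_id = "s1", timepoint_weeks = 0)
  expect_length(rec$lengths, 14)
  expect_length(rec$areas, 6)
  expect_length(rec$angles, 3)
  expect_false(anyNA(rec$lengths))
  expect_equal(unname(rec$lengths["V1T1"]),
               marker_length(pos["V1", ], pos["T1", ]), tolerance = 1e-12)
  expect_equal(unname(rec$areas["V1V2T3T1"]),
               quad_area(pos[c("V1", "V2", "T3", "T1"), ]),
               tolerance = 1e-12)

  # a missing marker voids only the measurements that touch it
  rec2 <- measure_scan(pos[rownames(pos) != "T4", ],
                       cadaver_measurement_set(), frames)
  touched <- c("T3T4", "T2T4", "T4T6")
  expect_true(all(is.na(rec2$lengths[touched])))
  expect_false(anyNA(rec2$lengths[setdiff(names(rec2$lengths), touched)]))
  expect_equal(attr(rec2, "missing"), "T4")
})

make_record <- function(lengths, areas, angles = NULL, id = "s",
                        weeks = NA_real_) {
  structure(list(scan_id = id, timepoint_weeks = weeks, lengths = lengths,
                 areas = areas, angles = angles,
                 length_groups = setNames(rep("len", length(lengths)),
                                          names(lengths)),
                 area_groups = setNames(rep("area", length(areas)),
                                        names(areas))),
            class = "measurement_record")
}

test_that("precision summary averages per-measurement SDs by class", {
  r1 <- make_record(c(a = 10, b = 20), c(q = 100), c(extension = 5,
                                                     external_rotation = 1,
                                                     abduction = 2))
  r2 <- make_record(c(a = 12, b = 21), c(q = 106), c(extension = 7,
                                                     external_rotation = 1,
                                                     abduction = 4))
  ps <- precision_summary(list(r1, r2))
  expect_equal(unname(ps$pooled["lengths"]),
               mean(c(sd(c(10, 12)), sd(c(20, 21)))))
  expect_equal(unname(ps$pooled["areas"]), sd(c(100, 106)))
  expect_equal(unname(ps$pooled["angles"]),
               mean(c(sd(c(5, 7)), 0, sd(c(2, 4)))))

  # identical repeats have identically zero precision
  ps0 <- precision_summary(list(r1, r1, r1))
  expect_true(all(ps0$per_measurement$sd == 0))
  expect_equal(unname(ps0$pooled), c(0, 0, 0))

  expect_error(precision_summary(list(r1)), "2 repeat")
})

test_that("longitudinal summary reports final-minus-baseline changes", {
  r0 <- make_record(c(a = 10, b = 20), c(q = 100), id = "w0", weeks = 0)
  r1 <- make_record(c(a = 12, b = 26), c(q = 130), id = "w12", weeks = 12)
  r2 <- make_record(c(a = 15, b = 29), c(q = 160), id = "w26", weeks = 26)
  ls <- longitudinal_summary(list(r2, r0, r1))   # order by weeks internally
  per <- ls$per_measurement
  expect_equal(per$change[per$measurement == "a"], 5)
  expect_equal(per$change[per$measurement == "b"], 9)
  expect_equal(ls$by_group$mean_change[ls$by_group$class == "lengths"], 7)
  expect_equal(ls$by_group$sd_change[ls$by_group$class == "lengths"],
               sd(c(5, 9)))

  same <- longitudinal_summary(list(r0, r0))
  expect_true(all(same$per_measurement$change == 0))

  bad <- make_record(c(a = 1, zzz = 2), c(q = 3), id = "w26", weeks = 26)
  expect_error(longitudinal_summary(list(r0, bad)),
               class = "markermorph_validation_error")
})

test_that("table-driven statistics mirror the record-based ones", {
  tab <- data.frame(measurement = c("a", "b", "q"),
                    class = c("lengths", "lengths", "areas"),
                    sd = c(0.5, 0.7, 4))
  ps <- precision_from_table(tab)
  expect_equal(unname(ps$pooled["lengths"]), 0.6)
  expect_equal(unname(ps$pooled["areas"]), 4)

  long <- data.frame(
    measurement = rep(c("a", "q"), each = 2),
    class = rep(c("lengths", "areas"), each = 2),
    group = rep(c("len", "area"), each = 2),
    timepoint_weeks = c(0, 26, 0, 26),
    value = c(10, 15, 100, 160))
  ls <- longitudinal_from_table(long)
  expect_equal(ls$per_measurement$change, c(5, 60))

  expect_error(precision_from_table(data.frame(measurement = "a")),
               class = "markermorph_parse_error")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("measurement,class,sd", empty)
  expect_error(precision_from_table(empty),
               class = "markermorph_parse_error")
})
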