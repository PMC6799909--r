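# independent flood-fill oracle: label 26-connected supra-threshold
# voxels by breadth-first search over the raw array
flood_fill_oracle <- function(data, threshold) {
  d <- dim(data)
  seen <- array(FALSE, d)
  comps <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (lin in which(data >= threshold)) {
    start <- arrayInd(lin, d)
    if (seen[start]) next
    queue <- list(as.vector(start))
    seen[start] <- TRUE
    members <- list()
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      members[[length(members) + 1]] <- v
      for (o in seq_len(nrow(offs))) {
        nb <- v + offs[o, ]
        if (any(nb < 1) || any(nb > d)) next
        nbm <- matrix(nb, 1)
        if (!seen[nbm] && data[nbm] >= threshold) {
          seen[nbm] <- TRUE
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
    comps[[length(comps) + 1]] <- do.call(rbind, members) - 1L
  }
  comps
}

canon <- function(comp) {
  comp <- comp[order(comp[, 1], comp[, 2], comp[, 3]), , drop = FALSE]
  dimnames(comp) <- NULL
  comp
}

test_that("segmentation finds 26-connected supra-threshold components", {
  empty <- block_volume(c(6, 6, 6))
  expect_length(segment_markers(empty, threshold = 500), 0)

  one <- block_volume(c(9, 9, 9), blocks = list(
    list(from = c(4, 4, 4), to = c(6, 6, 6), hu = 2000)))
  comps <- segment_markers(one, threshold = 500, min_voxels = 5,
                           max_voxels = 1000)
  expect_length(comps, 1)
  expect_equal(nrow(comps[[1]]), 27)

  # size gate drops components outside [min, max]
  expect_length(segment_markers(one, threshold = 500, min_voxels = 28,
                                max_voxels = 1000), 0)
  expect_length(segment_markers(one, threshold = 500, min_voxels = 1,
                                max_voxels = 26), 0)
})

test_that("segmentation agrees with a brute-force flood-fill oracle", {
  set.seed(101)
  for (rep in 1:5) {
    data <- array(0, c(10, 10, 8))
    data[sample(length(data), 60)] <- 1500    # random sprinkle
    data[2:3, 2:3, 2:3] <- 2000
    data[6:7, 6:7, 5:6] <- 2000               # separated block
    vol <- voxel_volume(data)
    got <- segment_markers(vol, threshold = 1000, min_voxels = 1,
                           max_voxels = 10000)
    want <- flood_fill_oracle(data, 1000)
    expect_equal(length(got), length(want))
    key <- function(cs) sort(vapply(cs, function(c)
      paste(t(canon(c)), collapse = ","), ""))
    expect_identical(key(got), key(want))
  }
})

test_that("two blocks separated by a background plane form two components", {
  vol <- block_volume(c(9, 4, 4), blocks = list(
    list(from = c(1, 1, 1), to = c(3, 3, 3), hu = 2000),
    list(from = c(5, 1, 1), to = c(7, 3, 3), hu = 2000)))
  expect_length(segment_markers(vol, 500, 1, 1000), 2)
  # touching diagonally (26-connectivity) they merge
  vol2 <- block_volume(c(9, 4, 4), blocks = list(
    list(from = c(1, 1, 1), to = c(3, 3, 3), hu = 2000),
    list(from = c(4, 4, 4), to = c(4, 4, 4), hu = 2000)))
  expect_length(segment_markers(vol2, 500, 1, 1000), 1)
})

test_that("centroid fitting matches hand computation", {
  vol <- block_volume(c(6, 6, 6))
  expect_equal(fit_centroid(vol, matrix(c(2, 2, 2), 1)), c(2, 2, 2))
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(fit_centroid(vol, two), c(0.5, 0, 0))

  # intensity weighting: intensities 1,1,2 at x = 0,1,2
  data <- array(0, c(4, 4, 4))
  data[1, 1, 1] <- 1; data[2, 1, 1] <- 1; data[3, 1, 1] <- 2
  ivol <- voxel_volume(data)
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(fit_centroid(ivol, line, "intensity")[1], 1.25)
  expect_equal(fit_centroid(ivol, line, "uniform")[1], 1)

  expect_error(fit_centroid(vol, matrix(numeric(0), 0, 3)), "empty")
})

test_that("centroid is invariant under voxel-order permutation", {
  set.seed(5)
  vol <- voxel_volume(array(runif(512, 500, 2000), c(8, 8, 8)),
                      make_affine(c(0.5, 0.5, 0.6)))
  comp <- unique(matrix(sample(0:7, 90, replace = TRUE), 30, 3))
  for (w in c("uniform", "intensity")) {
    base <- fit_centroid(vol, comp, w)
    for (i in 1:5) {
      perm <- comp[sample(nrow(comp)), ]
      expect_lt(max(abs(fit_centroid(vol, perm, w) - base)), 1e-6)
    }
  }
})

test_that("seed assignment is greedy, capped, and matches exhaustive matching", {
  vol <- block_volume(c(20, 8, 8), blocks = list(
    list(from = c(2, 2, 2), to = c(3, 3, 3), hu = 2000),
    list(from = c(8, 2, 2), to = c(9, 3, 3), hu = 2000),
    list(from = c(14, 2, 2), to = c(15, 3, 3), hu = 2000)))
  comps <- segment_markers(vol, 500, 1, 1000)
  cents <- t(vapply(comps, function(c) fit_centroid(vol, c), numeric(3)))

  seeds <- cents + matrix(c(0.4, -0.3, 0.2, -0.2, 0.3, -0.4, 0.1, 0.2, -0.1),
                          3, 3)
  rownames(seeds) <- c("T1", "T2", "T3")
  obs <- assign_labels(vol, comps, seeds)
  expect_setequal(obs$label, c("T1", "T2", "T3"))

  # exhaustive assignment oracle over all 3! permutations
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  cost <- vapply(perms, function(p)
    sum(vapply(1:3, function(s)
      marker_length(seeds[s, ], cents[p[s], ])^2, numeric(1))), numeric(1))
  best <- perms[[which.min(cost)]]
  got <- vapply(obs$label, function(l)
    which.min(colSums((t(cents) - unlist(obs[obs$label == l, c("x","y","z")]))^2)),
    integer(1))
  expect_equal(unname(got[c("T1", "T2", "T3")]), best)

  # cap: a far seed stays unmatched with a warning
  far <- rbind(T9 = cents[1, ] + c(0, 50, 0))
  expect_warning(res <- assign_labels(vol, comps, far, distance_cap = 5),
                 "T9")
  expect_equal(nrow(res), 0)
  expect_equal(attr(res, "unmatched"), "T9")
})

test_that("two seeds claiming one sole component raise an ambiguity error", {
  vol <- block_volume(c(8, 8, 8), blocks = list(
    list(from = c(4, 4, 4), to = c(5, 5, 5), hu = 2000)))
  comps <- segment_markers(vol, 500, 1, 1000)
  seeds <- rbind(T1 = c(4, 4, 4), T2 = c(5, 5, 5))
  expect_error(assign_labels(vol, comps, seeds),
               class = "markermorph_ambiguity_error")
})

test_that("noiseless phantom spheres localize to sub-half-voxel accuracy", {
  set.seed(21)
  # well-separated grid of sphere centres with random sub-voxel offsets
  centers <- cbind(c(6, 12, 18, 6, 12, 18),
                   c(6, 6, 6, 16, 16, 16),
                   c(6, 10, 14, 6, 10, 14)) + runif(18, -0.5, 0.5)
  markers <- data.frame(label = paste0("T", 1:6), class = "tendon",
                        x = centers[, 1], y = centers[, 2], z = centers[, 3],
                        radius = 1.5, hu = 2000)
  spec <- phantom_spec(dims = c(48L, 44L, 36L), spacing = c(0.5, 0.5, 0.6),
                       markers = markers)
  vol <- render_phantom(spec)$volume
  sm <- as.matrix(markers[, c("x", "y", "z")]); rownames(sm) <- markers$label
  obs <- localize_markers(vol, sm)
  expect_equal(nrow(obs), 6)
  err <- sqrt(rowSums((as.matrix(obs[, c("x", "y", "z")]) -
                         sm[obs$label, ])^2))
  expect_lt(max(err), 0.3)   # half the largest voxel dimension
})

test_that("median centroid error stays below one voxel under 20 HU noise", {
  markers <- data.frame(label = c("T1", "T2"), class = "tendon",
                        x = c(6.2, 13.7), y = c(6.9, 7.4), z = c(5.1, 5.8),
                        radius = 0.75, hu = 2000)
  spec <- phantom_spec(dims = c(40L, 28L, 20L), spacing = c(0.5, 0.5, 0.6),
                       markers = markers, noise_sd = 20)
  sm <- as.matrix(markers[, c("x", "y", "z")]); rownames(sm) <- markers$label
  errs <- numeric(0)
  for (rep in 1:50) {
    vol <- render_phantom(spec, seed = 1000 + rep)$volume
    obs <- localize_markers(vol, sm)
    errs <- c(errs, sqrt(rowSums((as.matrix(obs[, c("x","y","z")]) -
                                    sm[obs$label, ])^2)))
  }
  expect_gt(length(errs), 90)
  expect_lt(median(errs), 0.6)   # largest voxel dimension
})
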