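# shared fixtures: tiny volumes, random rigid motions, landmark triads

make_affine <- function(spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        rotation = diag(3)) {
  rbind(cbind(rotation %*% diag(spacing), origin), c(0, 0, 0, 1))
}

# uniform background volume with optional bright rectangular blocks
block_volume <- function(dims = c(8, 8, 8), spacing = c(1, 1, 1),
                         background = 0, blocks = list()) {
  data <- array(background, dims)
  for (b in blocks) {
    # b: list(from =, to =, hu =) in 1-based index space
    data[b$from[1]:b$to[1], b$from[2]:b$to[2], b$from[3]:b$to[3]] <- b$hu
  }
  voxel_volume(data, make_affine(spacing))
}

random_rotation <- function() {
  rotation_about(rnorm(3), runif(1, -180, 180))
}

random_rigid <- function(scale = 10) {
  rigid_transform(random_rotation(), rnorm(3, 0, scale))
}

# canonical right-shoulder landmark set (LPS world, lateral = -x)
fixture_landmarks <- function() {
  landmark_set(
    scapula = list(AA = c(18, 60, 52), TS = c(70, 55, 48), AI = c(65, 70, 0)),
    humerus = list(HH = c(16, 40, 52), ME = c(40, 45, -250),
                   LE = c(-10, 48, -255)),
    side = "right")
}

# small-footprint shoulder phantom for fast unit tests (same marker
# layout as the defaults, smaller grid)
small_cadaver_spec <- function(...) {
  cadaver_phantom_spec(dims = c(128L, 120L, 96L), ...)
}

small_patient_spec <- function(...) {
  patient_phantom_spec(dims = c(128L, 120L, 96L), ...)
}

expect_frame_valid <- function(frame) {
  axes <- cbind(frame$lateral, frame$anterior, frame$superior)
  expect_lt(max(abs(crossprod(axes) - diag(3))), 1e-9)
  cr <- c(frame$lateral[2] * frame$anterior[3] - frame$lateral[3] * frame$anterior[2],
          frame$lateral[3] * frame$anterior[1] - frame$lateral[1] * frame$anterior[3],
          frame$lateral[1] * frame$anterior[2] - frame$lateral[2] * frame$anterior[1])
  expect_lt(max(abs(cr - frame$superior)), 1e-9)
}

# named position matrix from a phantom marker table
truth_matrix <- function(markers) {
  pos <- as.matrix(markers[, c("x", "y", "z")])
  rownames(pos) <- markers$label
  pos
}
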