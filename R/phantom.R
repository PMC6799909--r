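#' Synthetic CT phantom specification
#'
#' Describes a synthetic CT volume with known ground truth: grid
#' geometry, soft-tissue background, bright bone shapes, spherical
#' markers standing in for radiopaque suture knots, and the bony-landmark
#' ground truth used to build anatomical frames.  Rendering is fully
#' deterministic given the seed.
#'
#' Markers are rendered as spheres: the analysis localizes the roughly
#' isotropic knot blob to its volumetric centroid, and a sphere is the
#' simplest shape with the same centroid contract.  Knot stacks are
#' about 1.5 mm across, hence the default radius of 0.75 mm.
#'
#' @param dims integer 3-vector of voxel counts.
#' @param spacing voxel spacing in mm (default the clinical
#'   reconstruction grid 0.5 x 0.5 x 0.6).
#' @param origin world position (mm) of voxel (0, 0, 0).
#' @param background_hu soft-tissue background intensity (HU).
#' @param markers data frame with columns `label`, `class`
#'   (`tendon`/`bone`/`virtual`), `x`, `y`, `z` (true centre, mm),
#'   `radius` (mm), `hu`.  Virtual markers are pure geometry and are not
#'   rendered.
#' @param bones list of shapes, each
#'   `list(type = "sphere", centre =, radius =, hu =)` or
#'   `list(type = "cylinder", base =, axis =, radius =, length =, hu =)`.
#' @param landmarks a [landmark_set()] giving the ground-truth bony
#'   landmarks (world mm; may lie outside the rendered volume, as the
#'   epicondyles do for a shoulder field of view).
#' @param noise_sd iid Gaussian noise SD (HU), applied after blurring.
#' @param blur_fwhm isotropic Gaussian blur FWHM (mm); 0 disables.
#' @param seed integer seed recorded in the spec and used by
#'   [render_phantom()] unless overridden.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(160L, 160L, 128L),
                         spacing = c(0.5, 0.5, 0.6),
                         origin = c(0, 0, 0),
                         background_hu = 40,
                         markers = NULL,
                         bones = list(),
                         landmarks = NULL,
                         noise_sd = 0, blur_fwhm = 0, seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    mm_validation_error("'dims' must be 3 positive integers")
  if (length(spacing) != 3L || any(spacing <= 0))
    mm_validation_error("'spacing' must be 3 positive lengths")
  affine <- rbind(cbind(diag(spacing), as.numeric(origin)), c(0, 0, 0, 1))
  if (is.null(markers))
    markers <- data.frame(label = character(0), class = character(0),
                          x = numeric(0), y = numeric(0), z = numeric(0),
                          radius = numeric(0), hu = numeric(0))
  need_cols <- c("label", "class", "x", "y", "z", "radius", "hu")
  if (!all(need_cols %in% names(markers)))
    mm_validation_error(sprintf("'markers' needs columns %s",
                                paste(need_cols, collapse = ", ")))
  if (anyDuplicated(markers$label))
    mm_validation_error("marker labels must be unique")
  spec <- structure(list(dims = dims, spacing = as.numeric(spacing),
                         affine = affine, background_hu = background_hu,
                         markers = markers, bones = bones,
                         landmarks = landmarks, noise_sd = noise_sd,
                         blur_fwhm = blur_fwhm, seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  phys <- spec$markers[spec$markers$class != "virtual", , drop = FALSE]
  if (nrow(phys) == 0L) return(invisible(spec))
  lo <- voxel_to_world(list(affine = spec$affine), c(0, 0, 0))
  hi <- voxel_to_world(list(affine = spec$affine), spec$dims - 1)
  inside <- phys$x >= lo[1] & phys$x <= hi[1] &
            phys$y >= lo[2] & phys$y <= hi[2] &
            phys$z >= lo[3] & phys$z <= hi[3]
  if (!all(inside))
    mm_validation_error(sprintf("marker(s) %s lie outside the volume",
                                paste(phys$label[!inside], collapse = ", ")))
  if (nrow(phys) > 1L) {
    ctr <- as.matrix(phys[, c("x", "y", "z")])
    dd <- as.matrix(dist(ctr))
    lim <- outer(phys$radius, phys$radius, "+")
    diag(dd) <- Inf
    if (any(dd < lim))
      mm_validation_error("physical markers overlap (closer than the sum of their radii)")
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm, %d markers (%d rendered), %d bone shapes\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              nrow(x$markers), sum(x$markers$class != "virtual"),
              length(x$bones)))
  invisible(x)
}

# paint a shape into `data` with 3x3x3 supersampled partial-volume
# coverage; inside(points) returns a logical vector
paint_shape <- function(data, affine, hu, background, bbox_world, inside) {
  d <- dim(data)
  inv <- solve(affine[1:3, 1:3])
  vox_lo <- floor(inv %*% (bbox_world[1, ] - affine[1:3, 4])) - 1
  vox_hi <- ceiling(inv %*% (bbox_world[2, ] - affine[1:3, 4])) + 1
  rng <- lapply(1:3, function(a)
    max(0, vox_lo[a]):min(d[a] - 1, vox_hi[a]))
  if (any(lengths(rng) == 0L)) return(data)
  grid <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  sub <- as.matrix(expand.grid(c(-1, 0, 1) / 3, c(-1, 0, 1) / 3,
                               c(-1, 0, 1) / 3))
  frac <- numeric(nrow(grid))
  for (s in seq_len(nrow(sub))) {
    pts <- sweep(grid, 2, -sub[s, ])            # fractional voxel index
    w <- t(affine[1:3, 1:3] %*% t(pts) + affine[1:3, 4])
    frac <- frac + inside(w)
  }
  frac <- frac / nrow(sub)
  sel <- frac > 0
  if (!any(sel)) return(data)
  lin <- grid[sel, , drop = FALSE] + 1L
  data[lin] <- (1 - frac[sel]) * data[lin] + frac[sel] * hu
  data
}

sphere_painter <- function(centre, radius, hu) {
  list(bbox = rbind(centre - radius, centre + radius), hu = hu,
       inside = function(w) rowSums(sweep(w, 2, centre)^2) <= radius^2)
}

cylinder_painter <- function(base, axis, radius, length, hu) {
  a <- unit3(axis)
  lo <- pmin(base, base + a * length) - radius
  hi <- pmax(base, base + a * length) + radius
  list(bbox = rbind(lo, hi), hu = hu,
       inside = function(w) {
         rel <- sweep(w, 2, base)
         t <- rel %*% a
         perp2 <- rowSums(rel^2) - t^2
         t >= 0 & t <= length & perp2 <= radius^2
       })
}

gaussian_blur <- function(data, spacing, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    s_vox <- sigma / spacing[axis]
    r <- max(1L, ceiling(3 * s_vox))
    k <- exp(-((-r:r)^2) / (2 * s_vox^2))
    k <- k / sum(k)
    acc <- array(0, dim(data))
    n <- dim(data)[axis]
    for (t in -r:r) {
      src <- pmin(pmax(seq_len(n) + t, 1L), n)   # replicate edges
      sl <- switch(axis,
                   data[src, , , drop = FALSE],
                   data[, src, , drop = FALSE],
                   data[, , src, drop = FALSE])
      acc <- acc + k[t + r + 1] * sl
    }
    data <- acc
  }
  data
}

#' Render a phantom volume with ground truth
#'
#' Voxels covered by a shape take its HU with partial-volume handling
#' (coverage fraction by 3 x 3 x 3 supersampling of each voxel); a
#' Gaussian blur and then iid Gaussian noise are applied when requested.
#' All randomness is governed by one explicit seed; the same spec and
#' seed give bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return A list: `volume` (a [voxel_volume()]), `truth` (list with
#'   `markers` — the spec marker table, including virtual positions —
#'   and `landmarks`), and `seed`.
#' @export
render_phantom <- function(spec, seed = NULL) {
  seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  data <- array(spec$background_hu, spec$dims)
  painters <- lapply(spec$bones, function(b) {
    switch(b$type,
           sphere = sphere_painter(b$centre, b$radius, b$hu),
           cylinder = cylinder_painter(b$base, b$axis, b$radius, b$length,
                                       b$hu),
           mm_validation_error(sprintf("unknown bone shape '%s'", b$type)))
  })
  phys <- spec$markers[spec$markers$class != "virtual", , drop = FALSE]
  painters <- c(painters, lapply(seq_len(nrow(phys)), function(i)
    sphere_painter(c(phys$x[i], phys$y[i], phys$z[i]), phys$radius[i],
                   phys$hu[i])))
  for (p in painters)
    data <- paint_shape(data, spec$affine, p$hu, spec$background_hu,
                        p$bbox, p$inside)
  if (spec$blur_fwhm > 0)
    data <- gaussian_blur(data, spec$spacing, spec$blur_fwhm)
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    data <- data + array(rnorm(length(data), 0, spec$noise_sd), dim(data))
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  list(volume = voxel_volume(data, spec$affine),
       truth = list(markers = spec$markers, landmarks = spec$landmarks),
       seed = seed)
}

# named matrix of true marker positions, optionally by class
truth_positions <- function(markers, classes = c("tendon", "bone", "virtual")) {
  sel <- markers$class %in% classes
  m <- as.matrix(markers[sel, c("x", "y", "z")])
  rownames(m) <- markers$label[sel]
  m
}

#' Shoulder marker-grid phantom layouts
#'
#' `cadaver_phantom_spec()` emulates the full proof-of-concept layout:
#' eight tendon markers in two mediolateral rows (odd labels lateral,
#' about 13 mm medial of the footprint line; even labels a further
#' 10 mm medial), three humeral bone markers, four virtual markers
#' along the lateral edge of the rotator cuff footprint, a humeral-shaft
#' bone cylinder, and the full scapular/humeral landmark ground truth.
#' `patient_phantom_spec()` keeps only the lateral tendon row
#' (T1, T3, T5, T7), as in the clinical protocol.
#'
#' @inheritParams phantom_spec
#' @param marker_radius,marker_hu,bone_hu rendering parameters.
#' @return A [phantom_spec()].
#' @export
cadaver_phantom_spec <- function(dims = c(160L, 160L, 128L),
                                 spacing = c(0.5, 0.5, 0.6),
                                 noise_sd = 0, blur_fwhm = 0, seed = 1L,
                                 marker_radius = 0.75, marker_hu = 2000,
                                 bone_hu = 1200) {
  shoulder_phantom_spec(all_tendon = TRUE, dims = dims, spacing = spacing,
                        noise_sd = noise_sd, blur_fwhm = blur_fwhm,
                        seed = seed, marker_radius = marker_radius,
                        marker_hu = marker_hu, bone_hu = bone_hu)
}

#' @rdname cadaver_phantom_spec
#' @export
patient_phantom_spec <- function(dims = c(160L, 160L, 128L),
                                 spacing = c(0.5, 0.5, 0.6),
                                 noise_sd = 0, blur_fwhm = 0, seed = 1L,
                                 marker_radius = 0.75, marker_hu = 2000,
                                 bone_hu = 1200) {
  shoulder_phantom_spec(all_tendon = FALSE, dims = dims, spacing = spacing,
                        noise_sd = noise_sd, blur_fwhm = blur_fwhm,
                        seed = seed, marker_radius = marker_radius,
                        marker_hu = marker_hu, bone_hu = bone_hu)
}

shoulder_phantom_spec <- function(all_tendon, dims, spacing, noise_sd,
                                  blur_fwhm, seed, marker_radius, marker_hu,
                                  bone_hu) {
  # right shoulder in LPS: medial = +x, posterior = +y, superior = +z.
  # Footprint line at x = 20; columns run anterior -> posterior with
  # irregular spacing; slight z wiggle keeps the grid non-planar.
  col_y <- c(25, 31, 43, 53)
  foot_z <- c(50.2, 50.8, 49.6, 50.4)
  v <- data.frame(label = paste0("V", 1:4), class = "virtual",
                  x = 20, y = col_y, z = foot_z,
                  radius = 0, hu = 0)
  lat <- data.frame(label = paste0("T", c(1, 3, 5, 7)), class = "tendon",
                    x = c(33.2, 32.6, 33.5, 32.9),
                    y = col_y + c(0.4, -0.6, 0.8, -0.3),
                    z = foot_z + c(0.9, -0.7, 0.5, -0.4),
                    radius = marker_radius, hu = marker_hu)
  med <- data.frame(label = paste0("T", c(2, 4, 6, 8)), class = "tendon",
                    x = lat$x + c(10.3, 9.6, 10.1, 9.8),
                    y = lat$y + c(0.5, -0.4, 0.7, -0.6),
                    z = lat$z + c(-0.6, 0.8, -0.3, 0.5),
                    radius = marker_radius, hu = marker_hu)
  h <- data.frame(label = paste0("H", 1:3), class = "bone",
                  x = c(14.2, 13.1, 15.0),
                  y = c(28.5, 40.0, 50.5),
                  z = c(43.8, 46.2, 42.5),
                  radius = marker_radius, hu = marker_hu)
  markers <- if (all_tendon) rbind(v, lat, med, h) else rbind(v, lat, h)
  bones <- list(list(type = "cylinder", base = c(10, 40, 2),
                     axis = c(0.08, 0.02, 1), radius = 7, length = 34,
                     hu = bone_hu))
  landmarks <- landmark_set(
    scapula = list(AA = c(18, 60, 52), TS = c(70, 55, 48),
                   AI = c(65, 70, 0)),
    humerus = list(HH = c(16, 40, 52), ME = c(40, 45, -250),
                   LE = c(-10, 48, -255)),
    side = "right")
  phantom_spec(dims = dims, spacing = spacing, origin = c(0, 0, 0),
               background_hu = 40, markers = markers, bones = bones,
               landmarks = landmarks, noise_sd = noise_sd,
               blur_fwhm = blur_fwhm, seed = seed)
}

#' Motion scripts for longitudinal phantoms
#'
#' A motion script gives, per timepoint: the cumulative medial
#' retraction of each tendon marker (mm, along the scapular medial
#' direction), a rigid humeral motion (rotation about a scapular axis
#' through the humeral head, degrees), and a whole-scene repositioning
#' (a [rigid_transform()] applied to markers and landmarks alike,
#' emulating patient/specimen placement in the scanner).
#'
#' @param timepoints list of
#'   `list(weeks =, retraction_mm =, humeral_rotation = list(axis =,
#'   degrees =), reposition =)`; `retraction_mm` is a scalar or a named
#'   vector per tendon marker; `humeral_rotation` and `reposition` are
#'   optional.
#' @return An object of class `motion_script`.
#' @export
motion_script <- function(timepoints) {
  wk <- vapply(timepoints, function(t) as.numeric(t$weeks), numeric(1))
  if (is.unsorted(wk, strictly = TRUE))
    mm_validation_error("timepoints must be strictly increasing in weeks")
  structure(list(timepoints = timepoints), class = "motion_script")
}

#' @rdname motion_script
#' @param retraction_mm named (or scalar) cumulative retraction of the
#'   lateral tendon markers at 26 weeks, along the footprint
#'   measurement line; defaults emulate a repaired tendon retracting by
#'   19 mm on average, unevenly across the anterior-posterior span.
#'   The default script also varies arm position: the humerus is
#'   externally rotated at the intermediate visits and repositioned to
#'   neutral for the baseline and final scans, and every visit carries
#'   a whole-scene rigid repositioning.
#' @export
patient_motion_script <- function(retraction_mm = c(T1 = 18, T3 = 23,
                                                    T5 = 18, T7 = 17)) {
  frac <- c(0, 0.28, 0.72, 1)      # of final retraction at 0/3/12/26 wk
  rot <- list(list(axis = "superior", degrees = 0),
              list(axis = "superior", degrees = 12),
              list(axis = "superior", degrees = 18),
              list(axis = "superior", degrees = 0))
  repos <- list(
    rigid_transform(),
    rigid_transform(rotation_about(c(0, 0, 1), 4), c(2, -1.5, 1)),
    rigid_transform(rotation_about(c(0, 1, 0), -3), c(-1, 2, -2)),
    rigid_transform(rotation_about(c(1, 0, 0), 2.5), c(1.5, 1, 2)))
  motion_script(lapply(1:4, function(i)
    list(weeks = c(0, 3, 12, 26)[i],
         retraction_mm = retraction_mm * frac[i],
         retraction_direction = "footprint_line",
         humeral_rotation = rot[[i]],
         reposition = repos[[i]])))
}

#' Rotation matrix about an axis
#'
#' @param axis length-3 axis vector (normalized internally).
#' @param degrees rotation angle.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
rotation_about <- function(axis, degrees) {
  a <- unit3(as.numeric(axis))
  th <- degrees * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# move the spec's markers/landmarks for one scripted timepoint
apply_motion <- function(spec, tp) {
  markers <- spec$markers
  landmarks <- spec$landmarks
  scap <- scapular_frame(landmarks)
  medial <- -scap$lateral
  # tendon retraction (cumulative).  Direction "medial" displaces along
  # the scapular medial axis; "footprint_line" displaces each tendon
  # marker directly away from its nearest virtual (footprint) marker,
  # i.e. along the mediolateral measurement line itself, so a scripted
  # retraction translates one-for-one into the measured length change.
  ret <- tp$retraction_mm %||% 0
  dir_mode <- tp$retraction_direction %||% "medial"
  tendon <- which(markers$class == "tendon")
  virt <- which(markers$class == "virtual")
  if (length(tendon) > 0L && any(ret != 0)) {
    amounts <- if (length(ret) == 1L && is.null(names(ret))) {
      rep(ret, length(tendon))
    } else {
      out <- ret[markers$label[tendon]]
      out[is.na(out)] <- 0
      out
    }
    dirs <- t(vapply(tendon, function(ix) {
      if (dir_mode == "footprint_line" && length(virt) > 0L) {
        p <- as.numeric(markers[ix, c("x", "y", "z")])
        vm <- as.matrix(markers[virt, c("x", "y", "z")])
        vp <- vm[which.min(rowSums(sweep(vm, 2, p)^2)), ]
        unit3(p - vp)
      } else {
        medial
      }
    }, numeric(3)))
    markers[tendon, c("x", "y", "z")] <-
      markers[tendon, c("x", "y", "z")] + amounts * dirs
  }
  # humeral rigid motion about a scapular axis through the head centre
  if (!is.null(tp$humeral_rotation) && tp$humeral_rotation$degrees != 0) {
    ax <- scap[[tp$humeral_rotation$axis]]
    HH <- landmarks$groups$humerus["HH", ]
    R <- rotation_about(ax, tp$humeral_rotation$degrees)
    tf <- rigid_transform(R, HH - as.vector(R %*% HH))
    bone <- which(markers$class == "bone")
    virt <- which(markers$class == "virtual")
    for (ix in c(bone, virt))
      markers[ix, c("x", "y", "z")] <-
        apply_transform(tf, as.numeric(markers[ix, c("x", "y", "z")]))
    landmarks$groups$humerus <- apply_transform(tf, landmarks$groups$humerus)
  }
  # whole-scene repositioning
  if (!is.null(tp$reposition)) {
    phys <- seq_len(nrow(markers))
    markers[phys, c("x", "y", "z")] <-
      apply_transform(tp$reposition, as.matrix(markers[phys, c("x", "y", "z")]))
    landmarks <- transform_landmarks(landmarks, tp$reposition)
  }
  spec$markers <- markers
  spec$landmarks <- landmarks
  spec
}

#' Render a longitudinal phantom study
#'
#' Applies a [motion_script()] to a base [phantom_spec()] and renders
#' one volume per timepoint.  Virtual markers move rigidly with the
#' humerus (their rigid-body relationship to the bone markers is exact
#' by construction), tendon markers retract medially, and each
#' timepoint may be rigidly repositioned as a whole.  Ground-truth
#' measurement records are computed analytically from the true
#' positions and landmark-derived frames.
#'
#' @param spec a [phantom_spec()] (the week-0 scene).
#' @param script a [motion_script()].
#' @param measurements a [measurement_set()] for the ground-truth
#'   records.
#' @param seed base seed; timepoint i uses `seed + i - 1`.
#' @return A list of class `phantom_study`: `scans` (per timepoint:
#'   `scan_id`, `timepoint_weeks`, `volume`, `landmarks`, `seeds` —
#'   true physical-marker positions, standing in for analyst clicks —
#'   and `truth`), `truth_records`, `measurements`, and `spec`.
#' @export
render_longitudinal <- function(spec, script,
                                measurements = patient_measurement_set(),
                                seed = spec$seed) {
  scans <- vector("list", length(script$timepoints))
  truth_records <- vector("list", length(script$timepoints))
  for (i in seq_along(script$timepoints)) {
    tp <- script$timepoints[[i]]
    moved <- apply_motion(spec, tp)
    rend <- render_phantom(moved, seed = seed + i - 1L)
    pos <- truth_positions(moved$markers)
    frames <- list(scapula = scapular_frame(moved$landmarks),
                   humerus = humeral_frame(moved$landmarks))
    truth_records[[i]] <- measure_scan(
      pos, measurements, frames,
      scan_id = sprintf("week%02d", as.integer(tp$weeks)),
      timepoint_weeks = tp$weeks)
    phys <- moved$markers$class != "virtual"
    scans[[i]] <- list(
      scan_id = sprintf("week%02d", as.integer(tp$weeks)),
      timepoint_weeks = tp$weeks,
      volume = rend$volume,
      landmarks = moved$landmarks,
      seeds = truth_positions(moved$markers, c("tendon", "bone")),
      virtual_truth = truth_positions(moved$markers, "virtual"),
      truth = moved$markers)
  }
  structure(list(scans = scans, truth_records = truth_records,
                 measurements = measurements, spec = spec),
            class = "phantom_study")
}

#' Render a repeat-scan (precision protocol) phantom study
#'
#' The same scene is rendered `n_scans` times, each time rigidly
#' repositioned with a small random jitter (translation SD
#' `jitter_translation_mm` per axis, rotation SD `jitter_rotation_deg`
#' about a random axis through the scene centre) and fresh acquisition
#' noise — emulating a specimen being manipulated and re-approximated
#' to neutral between scans.
#'
#' @param spec a [phantom_spec()].
#' @param n_scans number of repeat scans.
#' @param jitter_translation_mm,jitter_rotation_deg repositioning jitter.
#' @param measurements a [measurement_set()].
#' @param seed governs jitter and noise.
#' @return A `phantom_study` (see [render_longitudinal()]) whose scans
#'   all have `timepoint_weeks = 0`.
#' @export
render_repeat_scans <- function(spec, n_scans = 3,
                                jitter_translation_mm = 0.3,
                                jitter_rotation_deg = 1,
                                measurements = cadaver_measurement_set(),
                                seed = spec$seed) {
  centre <- voxel_to_world(list(affine = spec$affine), (spec$dims - 1) / 2)
  scans <- vector("list", n_scans)
  truth_records <- vector("list", n_scans)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  jitters <- lapply(seq_len(n_scans), function(i) {
    if (i == 1) return(rigid_transform())
    ax <- rnorm(3); ang <- rnorm(1, 0, jitter_rotation_deg)
    R <- rotation_about(ax, ang)
    shift <- rnorm(3, 0, jitter_translation_mm)
    # rotate about the scene centre, then translate
    rigid_transform(R, centre - as.vector(R %*% centre) + shift)
  })
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  for (i in seq_len(n_scans)) {
    tp <- list(weeks = 0, retraction_mm = 0, reposition = jitters[[i]])
    moved <- apply_motion(spec, tp)
    rend <- render_phantom(moved, seed = seed + i)
    frames <- list(scapula = scapular_frame(moved$landmarks),
                   humerus = humeral_frame(moved$landmarks))
    truth_records[[i]] <- measure_scan(
      truth_positions(moved$markers), measurements, frames,
      scan_id = sprintf("repeat%d", i), timepoint_weeks = 0)
    scans[[i]] <- list(
      scan_id = sprintf("repeat%d", i), timepoint_weeks = 0,
      volume = rend$volume, landmarks = moved$landmarks,
      seeds = truth_positions(moved$markers, c("tendon", "bone")),
      virtual_truth = truth_positions(moved$markers, "virtual"),
      truth = moved$markers)
  }
  structure(list(scans = scans, truth_records = truth_records,
                 measurements = measurements, spec = spec),
            class = "phantom_study")
}
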