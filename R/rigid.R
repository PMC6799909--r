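#' Rigid (proper) transforms
#'
#' A `rigid_transform` is a proper rotation plus a translation,
#' `p -> R p + t`.  Reflections are rejected: the rotation must be
#' orthonormal with determinant +1.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric vector (mm).
#' @return An object of class `rigid_transform`.
#' @seealso [fit_rigid()], [compose_transforms()], [invert_transform()],
#'   [apply_transform()]
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!identical(dim(rotation), c(3L, 3L)))
    mm_validation_error("'rotation' must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    mm_validation_error("'rotation' is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    mm_validation_error("'rotation' must be proper (det = +1); reflections are not rigid motions")
  translation <- as.numeric(translation)
  if (length(translation) != 3L || any(!is.finite(translation)))
    mm_validation_error("'translation' must be 3 finite numbers")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  if (!is.null(attr(x, "rms")))
    cat(sprintf("  fit RMS %.4g mm over %d points\n",
                attr(x, "rms"), attr(x, "n_points")))
  invisible(x)
}

#' @rdname rigid_transform
#' @param transform,a,b `rigid_transform` objects.
#' @param points length-3 vector or n x 3 matrix of world points (mm).
#' @details `compose_transforms(a, b)` returns the transform applying `b`
#'   first, then `a`; `apply_transform` maps points; `invert_transform`
#'   gives the inverse motion.  `as_matrix()` returns the homogeneous 4x4
#'   form.
#' @export
apply_transform <- function(transform, points) {
  vec_in <- is.null(dim(points))
  pts <- as_point_matrix(points)
  out <- t(transform$rotation %*% t(pts) + transform$translation)
  rownames(out) <- rownames(pts)
  if (vec_in) drop(out) else out
}

#' @rdname rigid_transform
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.vector(rt %*% transform$translation))
}

#' @rdname rigid_transform
#' @export
as_matrix <- function(transform) {
  rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
}

# smallest altitude of the point cloud: distance of points from their
# best-fit line; a collinearity measure in mm
min_spread_mm <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))$d
  # second singular value ~ extent off the principal axis (mm); for a
  # triangle of altitude h this is about 0.8 h
  if (length(sv) < 2) 0 else sv[2]
}

#' Least-squares rigid fit between matched point sets (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sum_i || R s_i + t - q_i ||^2` over matched source/target pairs, by
#' SVD of the cross-covariance with the standard determinant sign
#' correction, so a reflection is never returned even when it would fit
#' better.  Exactly three non-collinear pairs fully determine the
#' rotation and are accepted.
#'
#' @param source,target n x 3 matrices (n >= 3) of matched points (mm).
#'   Row names, if present, must agree.
#' @param collinearity_tol points whose off-axis spread (mm) falls below
#'   this are treated as collinear and rejected.
#' @return A [rigid_transform()] with attributes `rms` (root-mean-square
#'   residual, mm) and `n_points`.
#' @examples
#' src <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1))
#' tf <- fit_rigid(src, src + 2)   # pure translation
#' attr(tf, "rms")
#' @export
fit_rigid <- function(source, target, collinearity_tol = 0.5) {
  src <- as_point_matrix(source, "source")
  tgt <- as_point_matrix(target, "target")
  if (nrow(src) != nrow(tgt))
    mm_validation_error("source and target must have the same number of points")
  if (nrow(src) < 3L)
    mm_validation_error("at least 3 point pairs are required")
  if (!is.null(rownames(src)) && !is.null(rownames(tgt)) &&
      !identical(rownames(src), rownames(tgt)))
    mm_validation_error("source and target point names disagree")
  if (min_spread_mm(src) < collinearity_tol)
    mm_degenerate_error("source points are (near-)collinear; rotation is not determined")
  sc <- colMeans(src); tc <- colMeans(tgt)
  H <- crossprod(sweep(src, 2, sc), sweep(tgt, 2, tc))
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  if (d == 0) d <- 1
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  t <- tc - as.vector(R %*% sc)
  tf <- rigid_transform(R, t)
  res <- apply_transform(tf, src) - tgt
  attr(tf, "rms") <- sqrt(mean(rowSums(res^2)))
  attr(tf, "n_points") <- nrow(src)
  tf
}

#' Register a follow-up scan to a reference scan via the scapula
#'
#' Longitudinal scans are expressed in a common frame by rigidly fitting
#' the follow-up scapular landmarks to the reference scapular landmarks:
#' the scapula serves as the fixed anatomical reference.  The returned
#' transform maps follow-up world coordinates into the reference world
#' frame.
#'
#' @param reference,followup [landmark_set()]s (or plain named lists with
#'   a `scapula` group) for the reference and follow-up scans.
#' @param group landmark group to register on (default `"scapula"`).
#' @return A [rigid_transform()] with `rms` attribute (mm).
#' @export
register_scan <- function(reference, followup, group = "scapula") {
  ref <- landmark_group_matrix(reference, group)
  fol <- landmark_group_matrix(followup, group)
  common <- rownames(ref)
  if (!setequal(common, rownames(fol)))
    mm_validation_error(sprintf(
      "scans disagree on '%s' landmark names (reference: %s; follow-up: %s)",
      group, paste(rownames(ref), collapse = ", "),
      paste(rownames(fol), collapse = ", ")))
  fit_rigid(fol[common, , drop = FALSE], ref[common, , drop = FALSE])
}

#' Virtual marker model and rigid-body imputation
#'
#' Virtual markers are software-placed points with no physical
#' counterpart (e.g. along the lateral edge of the rotator cuff
#' footprint).  They are defined once, in the reference scan, together
#' with the physical bone markers observed in that scan; in any later
#' scan their coordinates are imputed by applying the rigid transform
#' that carries the reference bone markers onto the bone markers observed
#' in that scan.
#'
#' @param virtual named n x 3 matrix of virtual marker positions in the
#'   reference scan (mm).
#' @param bone named m x 3 matrix (m >= 3, non-collinear) of physical
#'   bone marker positions in the reference scan (mm).
#' @return `virtual_marker_model()` returns an object of class
#'   `virtual_marker_model`; `impute_virtual_markers()` returns a named
#'   n x 3 matrix of imputed virtual positions with attributes `rms`
#'   (bone-marker fit residual, mm — the imputation quality) and
#'   `transform`.
#' @export
virtual_marker_model <- function(virtual, bone) {
  virtual <- as_point_matrix(virtual, "virtual")
  bone <- as_point_matrix(bone, "bone")
  if (nrow(bone) < 3L)
    mm_validation_error("at least 3 bone markers are required")
  if (min_spread_mm(bone) < 0.5)
    mm_degenerate_error("reference bone markers are (near-)collinear")
  if (is.null(rownames(bone)))
    rownames(bone) <- paste0("H", seq_len(nrow(bone)))
  if (is.null(rownames(virtual)))
    rownames(virtual) <- paste0("V", seq_len(nrow(virtual)))
  structure(list(virtual = virtual, bone = bone),
            class = "virtual_marker_model")
}

#' @rdname virtual_marker_model
#' @param model a `virtual_marker_model`.
#' @param bone_observed named m x 3 matrix of the same bone markers
#'   observed in the scan to impute into; names are matched to the model
#'   when present.
#' @export
impute_virtual_markers <- function(model, bone_observed) {
  obs <- as_point_matrix(bone_observed, "bone_observed")
  ref <- model$bone
  if (!is.null(rownames(obs))) {
    missing <- setdiff(rownames(ref), rownames(obs))
    if (length(missing) > 0L)
      mm_validation_error(sprintf("bone marker(s) %s not observed",
                                  paste(missing, collapse = ", ")))
    obs <- obs[rownames(ref), , drop = FALSE]
  } else if (nrow(obs) != nrow(ref)) {
    mm_validation_error("unnamed observed bone markers must match the model count")
  }
  tf <- fit_rigid(ref, obs)
  out <- apply_transform(tf, model$virtual)
  attr(out, "rms") <- attr(tf, "rms")
  attr(out, "transform") <- tf
  out
}
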