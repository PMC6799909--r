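#' Landmark sets
#'
#' A `landmark_set` holds named world-mm coordinates of bony landmarks,
#' grouped by bone (`scapula`, `humerus`), plus the body side.  Landmarks
#' are annotated in the world frame of their own scan, independent of
#' voxel storage.
#'
#' Required scapular landmarks: `AA` (angulus acromialis), `TS`
#' (trigonum spinae), `AI` (angulus inferior).  Humeral landmarks: `ME`
#' and `LE` (medial/lateral epicondyle) plus either `HH` (humeral head
#' centre) or at least five head-surface points named `HS1`, `HS2`, ...
#' from which the centre is sphere-fit.
#'
#' @param scapula,humerus named lists (or named n x 3 matrices) of
#'   length-3 world coordinates (mm).
#' @param side `"right"` or `"left"`.
#' @return An object of class `landmark_set`.
#' @examples
#' lm <- landmark_set(
#'   scapula = list(AA = c(18, 60, 52), TS = c(70, 55, 48), AI = c(65, 70, 0)),
#'   humerus = list(HH = c(16, 40, 52), ME = c(40, 45, -250), LE = c(-10, 48, -255)),
#'   side = "right")
#' scapular_frame(lm)
#' @export
landmark_set <- function(scapula = NULL, humerus = NULL,
                         side = c("right", "left")) {
  side <- match.arg(side)
  groups <- list(scapula = scapula, humerus = humerus)
  groups <- groups[!vapply(groups, is.null, logical(1))]
  groups <- lapply(groups, function(g) {
    m <- if (is.matrix(g)) g else do.call(rbind, g)
    m <- as_point_matrix(m, "landmarks")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)) ||
        any(rownames(m) == ""))
      mm_validation_error("landmarks must have unique non-empty names")
    m
  })
  structure(list(groups = groups, side = side), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> side %s\n", x$side))
  for (g in names(x$groups))
    cat(sprintf("  %s: %s\n", g, paste(rownames(x$groups[[g]]), collapse = ", ")))
  invisible(x)
}

landmark_group_matrix <- function(landmarks, group) {
  if (inherits(landmarks, "landmark_set")) {
    m <- landmarks$groups[[group]]
    if (is.null(m))
      mm_validation_error(sprintf("landmark set has no '%s' group", group))
    return(m)
  }
  # plain named list fallback
  if (!is.null(landmarks[[group]]))
    return(as_point_matrix(do.call(rbind, landmarks[[group]]), group))
  mm_validation_error(sprintf("cannot extract '%s' landmarks", group))
}

landmark_side <- function(landmarks, side = NULL) {
  if (!is.null(side)) return(match.arg(side, c("right", "left")))
  if (inherits(landmarks, "landmark_set")) return(landmarks$side)
  "right"
}

#' Apply a rigid transform to every landmark in a set
#'
#' @param landmarks a [landmark_set()].
#' @param transform a [rigid_transform()].
#' @return A transformed `landmark_set`.
#' @export
transform_landmarks <- function(landmarks, transform) {
  out <- landmarks
  out$groups <- lapply(landmarks$groups,
                       function(m) apply_transform(transform, m))
  out
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps * 100)
    mm_degenerate_error("zero-length axis vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Anatomical coordinate frame
#'
#' An origin plus right-handed orthonormal axes named by anatomical
#' direction.  On the right side all three axes point in their positive
#' anatomical direction (anterior, superior, lateral outward); on the
#' left, lateral and anterior remain anatomical and the `superior` axis
#' is the internal inferior direction, preserving the right-handed
#' convention `lateral x anterior = superior`.  Unsigned projected angles
#' are unaffected by this choice.
#'
#' @param origin length-3 world point (mm).
#' @param lateral,anterior,superior unit axis vectors in world
#'   coordinates; must be orthonormal and right-handed
#'   (`lateral x anterior = superior`) within 1e-9.
#' @return An object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin, lateral, anterior, superior) {
  origin <- as.numeric(origin)
  axes <- cbind(lateral = lateral, anterior = anterior, superior = superior)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9)
    mm_validation_error("frame axes must be orthonormal")
  if (max(abs(cross3(axes[, 1], axes[, 2]) - axes[, 3])) > 1e-9)
    mm_validation_error("frame must satisfy lateral x anterior = superior")
  structure(list(origin = origin,
                 lateral = as.numeric(lateral),
                 anterior = as.numeric(anterior),
                 superior = as.numeric(superior)),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("<anatomical_frame>\n")
  cat(sprintf("  origin   (%8.3f, %8.3f, %8.3f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("lateral", "anterior", "superior"))
    cat(sprintf("  %-8s (%8.5f, %8.5f, %8.5f)\n",
                ax, x[[ax]][1], x[[ax]][2], x[[ax]][3]))
  invisible(x)
}

#' Apply a rigid transform to an anatomical frame
#'
#' The origin is transformed as a point, the axes as directions.
#'
#' @param frame an [anatomical_frame()].
#' @param transform a [rigid_transform()].
#' @return The transformed `anatomical_frame`.
#' @export
transform_frame <- function(frame, transform) {
  R <- transform$rotation
  anatomical_frame(apply_transform(transform, frame$origin),
                   as.vector(R %*% frame$lateral),
                   as.vector(R %*% frame$anterior),
                   as.vector(R %*% frame$superior))
}

# triangle-degeneracy guard: area of (a, b, c) in mm^2
triangle_area <- function(a, b, c) sqrt(sum(cross3(b - a, c - a)^2)) / 2

#' Scapular anatomical frame from bony landmarks
#'
#' Construction (fixed orthogonalization order, so results are exactly
#' reproducible): the medial-lateral axis is the unit vector from the
#' trigonum spinae (`TS`) to the angulus acromialis (`AA`), lateral
#' positive; the anterior axis starts from the normal of the
#' (`AA`, `TS`, `AI`) plane, `(AA - TS) x (AI - TS)`, sign flipped for
#' left-side studies so it points anteriorly; superior is
#' `lateral x anterior` and anterior is re-orthogonalized as
#' `superior x lateral`.  Origin at `AA`.
#'
#' @param landmarks a [landmark_set()] (or named list with a `scapula`
#'   group) containing `AA`, `TS`, `AI`.
#' @param side optional override of the landmark set's side flag.
#' @return An [anatomical_frame()].
#' @export
scapular_frame <- function(landmarks, side = NULL) {
  m <- landmark_group_matrix(landmarks, "scapula")
  side <- landmark_side(landmarks, side)
  need <- c("AA", "TS", "AI")
  missing <- setdiff(need, rownames(m))
  if (length(missing) > 0L)
    mm_validation_error(sprintf("missing scapular landmark(s): %s",
                                paste(missing, collapse = ", ")))
  AA <- m["AA", ]; TS <- m["TS", ]; AI <- m["AI", ]
  if (triangle_area(AA, TS, AI) < 1)
    mm_degenerate_error("scapular landmarks are (near-)collinear (triangle area < 1 mm^2)")
  lateral <- unit3(AA - TS)
  anterior0 <- cross3(AA - TS, AI - TS)
  if (side == "left") anterior0 <- -anterior0
  superior <- unit3(cross3(lateral, unit3(anterior0)))
  anterior <- cross3(superior, lateral)
  anatomical_frame(AA, lateral, anterior, superior)
}

# linear least-squares sphere fit: ||p||^2 = 2 c.p + (r^2 - ||c||^2)
sphere_fit <- function(pts) {
  pts <- as_point_matrix(pts, "head surface points")
  if (nrow(pts) < 5L)
    mm_validation_error("sphere fit needs at least 5 surface points")
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  sol <- tryCatch(qr.solve(A, b),
                  error = function(e)
                    mm_degenerate_error("head-surface points do not determine a sphere"))
  centre <- sol[1:3]
  r2 <- sol[4] + sum(centre^2)
  if (r2 <= 0)
    mm_degenerate_error("degenerate sphere fit")
  list(centre = centre, radius = sqrt(r2))
}

#' Humeral anatomical frame from bony landmarks
#'
#' Construction: the superior axis is the unit vector from the elbow
#' midpoint `(ME + LE)/2` toward the humeral head centre `HH` (`HH` may
#' be given directly, or sphere-fit from >= 5 head-surface points `HS*`);
#' the anterior axis is `superior x (LE - ME)` normalized (sign flipped
#' for left-side studies); lateral completes the right-handed triad.  As
#' for [scapular_frame()], on the left side the frame's `superior` axis
#' is the internal inferior direction.  Origin at `HH`.
#'
#' @inheritParams scapular_frame
#' @return An [anatomical_frame()].
#' @export
humeral_frame <- function(landmarks, side = NULL) {
  m <- landmark_group_matrix(landmarks, "humerus")
  side <- landmark_side(landmarks, side)
  missing <- setdiff(c("ME", "LE"), rownames(m))
  if (length(missing) > 0L)
    mm_validation_error(sprintf("missing humeral landmark(s): %s",
                                paste(missing, collapse = ", ")))
  if ("HH" %in% rownames(m)) {
    HH <- m["HH", ]
  } else {
    hs <- m[grepl("^HS", rownames(m)), , drop = FALSE]
    if (nrow(hs) < 5L)
      mm_validation_error("missing humeral landmark(s): HH (or >= 5 HS* head-surface points)")
    HH <- sphere_fit(hs)$centre
  }
  ME <- m["ME", ]; LE <- m["LE", ]
  elbow <- (ME + LE) / 2
  if (triangle_area(HH, ME, LE) < 1)
    mm_degenerate_error("humeral landmarks are (near-)collinear (triangle area < 1 mm^2)")
  sup_anat <- unit3(HH - elbow)
  anterior0 <- cross3(sup_anat, LE - ME)
  if (side == "left") anterior0 <- -anterior0
  anterior <- unit3(anterior0 - sum(anterior0 * sup_anat) * sup_anat)
  superior <- if (side == "left") -sup_anat else sup_anat
  lateral <- cross3(anterior, superior)
  anatomical_frame(HH, lateral, anterior, superior)
}
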