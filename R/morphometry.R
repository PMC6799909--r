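#' Euclidean distance between two markers
#'
#' Inter-marker lengths are straight-line (Euclidean) distances in world
#' millimetres.
#'
#' @param p,q length-3 world points (mm).
#' @return Distance in mm.
#' @export
marker_length <- function(p, q) {
  sqrt(sum((as.numeric(p) - as.numeric(q))^2))
}

tri_area <- function(a, b, c) sqrt(sum(cross3(b - a, c - a)^2)) / 2

#' Swap-averaged quadrilateral area
#'
#' The area enclosed by four markers in perimeter order
#' `p1 -> p2 -> p3 -> p4` is approximated as the sum of two triangle
#' areas (each one half the magnitude of the cross-product of its edge
#' vectors), computed for both diagonal triangulations and averaged:
#' `area = (tri(p1,p2,p3) + tri(p1,p3,p4) + tri(p2,p3,p4) + tri(p2,p4,p1)) / 2`.
#' For planar convex quadrilaterals the two triangulations agree; for
#' non-planar marker quadruples the average is the reported area.
#'
#' @param p1,p2,p3,p4 length-3 world points in perimeter order, or `p1`
#'   alone may be a 4 x 3 matrix.
#' @return Area in mm^2 (0 for degenerate input).
#' @examples
#' quad_area(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0))  # unit square: 1
#' @export
quad_area <- function(p1, p2 = NULL, p3 = NULL, p4 = NULL) {
  if (is.null(p2)) {
    m <- as_point_matrix(p1, "quad")
    if (nrow(m) != 4L) mm_validation_error("need exactly 4 points")
    p1 <- m[1, ]; p2 <- m[2, ]; p3 <- m[3, ]; p4 <- m[4, ]
  }
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  p3 <- as.numeric(p3); p4 <- as.numeric(p4)
  area_a <- tri_area(p1, p2, p3) + tri_area(p1, p3, p4)
  area_b <- tri_area(p2, p3, p4) + tri_area(p2, p4, p1)
  (area_a + area_b) / 2
}

#' Angle between two vectors projected onto a plane
#'
#' Both vectors are projected onto the plane with unit normal `normal`;
#' the unsigned angle between the projections is returned in degrees
#' (range 0..180).  With `signed = TRUE` the sign follows the
#' right-hand rule about `normal` (rotation carrying the projection of
#' `u` onto that of `v`), range (-180, 180].
#'
#' If either projection is shorter than `floor` times the vector norm
#' the projected angle is numerically meaningless (gimbal-like
#' condition) and an ill-conditioned-projection error is raised.
#'
#' @param u,v length-3 vectors.
#' @param normal length-3 plane normal (normalized internally).
#' @param signed return the signed angle?
#' @param floor relative projection-norm floor.
#' @return Angle in degrees.
#' @examples
#' projected_angle(c(0, 0, 1), c(0, 1, 1), c(1, 0, 0))  # 45
#' @export
projected_angle <- function(u, v, normal, signed = FALSE, floor = 1e-6) {
  u <- as.numeric(u); v <- as.numeric(v)
  n <- unit3(as.numeric(normal))
  pu <- u - sum(u * n) * n
  pv <- v - sum(v * n) * n
  if (sqrt(sum(pu^2)) < floor * sqrt(sum(u^2)) ||
      sqrt(sum(pv^2)) < floor * sqrt(sum(v^2)))
    mm_error("projection onto the plane is ill-conditioned (vector nearly parallel to the normal)",
             "markermorph_projection_error")
  ang <- atan2(sum(cross3(pu, pv) * n), sum(pu * pv)) * 180 / pi
  if (signed) ang else abs(ang)
}

#' Humeral orientation angles relative to the scapula
#'
#' Three projected angles describe the orientation of the humerus in the
#' scapular frame, each computed with [projected_angle()]:
#' \describe{
#'   \item{extension}{superior-inferior axes projected onto the sagittal
#'     plane (normal = scapular lateral axis); positive sign labelled
#'     `extension`, negative `flexion`.}
#'   \item{external_rotation}{medial-lateral axes projected onto the
#'     axial plane (normal = scapular superior axis); labels
#'     `external`/`internal`.}
#'   \item{abduction}{superior-inferior axes projected onto the coronal
#'     plane (normal = scapular anterior axis); labels
#'     `abduction`/`adduction`.}
#' }
#' Reported values are unsigned magnitudes (the comparable quantity when
#' directions are given as words); the signed values and direction
#' labels are attached as attributes.
#'
#' @param scapula,humerus [anatomical_frame()]s from the same scan.
#' @return Named numeric vector `c(extension, external_rotation,
#'   abduction)` in degrees, with attributes `signed` and `direction`.
#' @export
humeral_orientation <- function(scapula, humerus) {
  s_ext <- projected_angle(scapula$superior, humerus$superior,
                           scapula$lateral, signed = TRUE)
  s_rot <- projected_angle(scapula$lateral, humerus$lateral,
                           scapula$superior, signed = TRUE)
  s_abd <- projected_angle(scapula$superior, humerus$superior,
                           scapula$anterior, signed = TRUE)
  signed <- c(extension = s_ext, external_rotation = s_rot,
              abduction = s_abd)
  direction <- c(extension = if (s_ext >= 0) "extension" else "flexion",
                 external_rotation = if (s_rot >= 0) "external" else "internal",
                 abduction = if (s_abd >= 0) "abduction" else "adduction")
  out <- abs(signed)
  attr(out, "signed") <- signed
  attr(out, "direction") <- direction
  out
}

#' Measurement definitions
#'
#' A `measurement_set` lists which marker pairs form lengths and which
#' perimeter-ordered marker quadruples form areas, each with an optional
#' group tag (e.g. `"mediolateral"` vs `"anteroposterior"` lengths).
#' Measurement names are the concatenated marker labels, mirroring the
#' conventional table row labels (`"V1T1"`, `"V1V2T3T1"`, ...).
#'
#' `cadaver_measurement_set()` is the full 8-tendon-marker grid protocol
#' (14 lengths, 6 areas); `patient_measurement_set()` is the reduced
#' 4-tendon-marker clinical protocol (7 lengths, 3 areas).  Odd-numbered
#' tendon markers form the lateral row, even-numbered the medial row.
#'
#' @param lengths list of length-2 character vectors of marker labels.
#' @param areas list of length-4 character vectors in perimeter order.
#' @param length_groups,area_groups optional character vectors of group
#'   tags, one per measurement.
#' @return An object of class `measurement_set`.
#' @export
measurement_set <- function(lengths = list(), areas = list(),
                            length_groups = NULL, area_groups = NULL) {
  lengths <- lapply(lengths, as.character)
  areas <- lapply(areas, as.character)
  if (any(vapply(lengths, length, 1L) != 2L))
    mm_validation_error("each length must name exactly 2 markers")
  if (any(vapply(areas, length, 1L) != 4L))
    mm_validation_error("each area must name exactly 4 markers in perimeter order")
  if (is.null(length_groups)) length_groups <- rep("length", length(lengths))
  if (is.null(area_groups)) area_groups <- rep("area", length(areas))
  if (length(length_groups) != length(lengths) ||
      length(area_groups) != length(areas))
    mm_validation_error("group tags must match the number of measurements")
  names(lengths) <- vapply(lengths, paste0, "", collapse = "")
  names(areas) <- vapply(areas, paste0, "", collapse = "")
  if (anyDuplicated(names(lengths)) || anyDuplicated(names(areas)))
    mm_validation_error("duplicate measurement definitions")
  structure(list(lengths = lengths, areas = areas,
                 length_groups = setNames(length_groups, names(lengths)),
                 area_groups = setNames(area_groups, names(areas))),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set> %d lengths, %d areas\n",
              length(x$lengths), length(x$areas)))
  invisible(x)
}

measurement_labels <- function(ms) {
  unique(c(unlist(ms$lengths, use.names = FALSE),
           unlist(ms$areas, use.names = FALSE)))
}

#' @rdname measurement_set
#' @export
cadaver_measurement_set <- function() {
  ml <- list(c("V1","T1"), c("T1","T2"), c("V2","T3"), c("T3","T4"),
             c("V3","T5"), c("T5","T6"), c("V4","T7"), c("T7","T8"))
  ap <- list(c("T1","T3"), c("T3","T5"), c("T5","T7"),
             c("T2","T4"), c("T4","T6"), c("T6","T8"))
  areas <- list(c("V1","V2","T3","T1"), c("T1","T2","T3","T4"),
                c("V2","V3","T5","T3"), c("T3","T5","T6","T4"),
                c("V3","V4","T7","T5"), c("T5","T7","T8","T6"))
  measurement_set(c(ml, ap), areas,
                  length_groups = c(rep("mediolateral", 8),
                                    rep("anteroposterior", 6)),
                  area_groups = rep("area", 6))
}

#' @rdname measurement_set
#' @export
patient_measurement_set <- function() {
  ml <- list(c("V1","T1"), c("V2","T3"), c("V3","T5"), c("V4","T7"))
  ap <- list(c("T1","T3"), c("T3","T5"), c("T5","T7"))
  areas <- list(c("V1","V2","T3","T1"), c("V2","V3","T5","T3"),
                c("V3","V4","T7","T5"))
  measurement_set(c(ml, ap), areas,
                  length_groups = c(rep("mediolateral", 4),
                                    rep("anteroposterior", 3)),
                  area_groups = rep("area", 3))
}

#' Measure one scan
#'
#' Computes every defined length, area, and the three humeral
#' orientation angles from a set of marker world positions.  Markers
#' missing from `positions` make only the measurements that touch them
#' `NA` (recorded in the `missing` attribute); the rest are computed.
#'
#' @param positions named n x 3 matrix of marker world positions (mm) —
#'   localized physical markers plus imputed virtual markers.
#' @param measurements a [measurement_set()].
#' @param frames optional `list(scapula =, humerus =)` of
#'   [anatomical_frame()]s; when supplied the angles are computed.
#' @param scan_id,timepoint_weeks identifiers stored in the record.
#' @return A `measurement_record`: list with `scan_id`,
#'   `timepoint_weeks`, `lengths`, `areas` (named numeric, mm / mm^2),
#'   `angles` (degrees or `NULL`), and group tags.
#' @export
measure_scan <- function(positions, measurements, frames = NULL,
                         scan_id = NA_character_, timepoint_weeks = NA_real_) {
  pos <- as_point_matrix(positions, "positions")
  if (is.null(rownames(pos)))
    mm_validation_error("'positions' must have marker labels as row names")
  missing_marks <- character(0)
  eval_one <- function(labels, fun) {
    absent <- setdiff(labels, rownames(pos))
    if (length(absent) > 0L) {
      missing_marks <<- union(missing_marks, absent)
      return(NA_real_)
    }
    fun(pos[labels, , drop = FALSE])
  }
  lengths <- vapply(measurements$lengths, eval_one, numeric(1),
                    fun = function(m) marker_length(m[1, ], m[2, ]))
  areas <- vapply(measurements$areas, eval_one, numeric(1), fun = quad_area)
  angles <- NULL
  if (!is.null(frames))
    angles <- humeral_orientation(frames$scapula, frames$humerus)
  structure(list(scan_id = scan_id, timepoint_weeks = timepoint_weeks,
                 lengths = lengths, areas = areas, angles = angles,
                 length_groups = measurements$length_groups,
                 area_groups = measurements$area_groups),
            class = "measurement_record",
            missing = missing_marks)
}

#' @export
print.measurement_record <- function(x, ...) {
  cat(sprintf("<measurement_record> scan %s (week %s): %d lengths, %d areas%s\n",
              x$scan_id, format(x$timepoint_weeks),
              length(x$lengths), length(x$areas),
              if (is.null(x$angles)) "" else ", 3 angles"))
  invisible(x)
}

# long data frame view of one record
record_table <- function(record) {
  out <- data.frame(
    measurement = c(names(record$lengths), names(record$areas)),
    class = c(rep("lengths", length(record$lengths)),
              rep("areas", length(record$areas))),
    group = c(unname(record$length_groups), unname(record$area_groups)),
    value = c(unname(record$lengths), unname(record$areas)),
    stringsAsFactors = FALSE)
  if (!is.null(record$angles))
    out <- rbind(out, data.frame(
      measurement = names(record$angles), class = "angles",
      group = "angle", value = as.numeric(record$angles)))
  out$scan_id <- record$scan_id
  out$timepoint_weeks <- record$timepoint_weeks
  out
}

#' @rdname measure_scan
#' @param x a `measurement_record`.
#' @param ... unused.
#' @export
as.data.frame.measurement_record <- function(x, ...) record_table(x)

records_long <- function(records) {
  do.call(rbind, lapply(records, record_table))
}

check_identical_sets <- function(records) {
  ref <- records[[1]]
  for (r in records[-1]) {
    if (!identical(names(r$lengths), names(ref$lengths)) ||
        !identical(names(r$areas), names(ref$areas)) ||
        is.null(r$angles) != is.null(ref$angles))
      mm_validation_error("records do not share an identical measurement set")
  }
}

#' Repeat-scan precision
#'
#' Precision (repeatability) of each measurement over repeat scans of a
#' repositioned specimen is its sample standard deviation (n - 1
#' denominator); the pooled precision of a measurement class (lengths,
#' areas, angles) is the unweighted mean of the per-measurement SDs.
#'
#' @param records list of >= 2 `measurement_record`s with identical
#'   measurement sets.
#' @return A `precision_summary`: list with `per_measurement` (data
#'   frame: measurement, class, group, mean, sd, n) and `pooled` (named
#'   numeric: lengths mm, areas mm^2, angles degrees).
#' @export
precision_summary <- function(records) {
  if (length(records) < 2L)
    mm_validation_error("at least 2 repeat records are required")
  check_identical_sets(records)
  long <- records_long(records)
  per <- do.call(rbind, lapply(
    split(long, list(long$class, long$measurement), drop = TRUE),
    function(d) data.frame(measurement = d$measurement[1], class = d$class[1],
                           group = d$group[1], mean = mean(d$value),
                           sd = sd(d$value), n = nrow(d))))
  # keep the definition order
  ord <- unique(long[, c("measurement", "class")])
  per <- per[match(paste(ord$measurement, ord$class),
                   paste(per$measurement, per$class)), ]
  rownames(per) <- NULL
  structure(list(per_measurement = per,
                 pooled = pooled_precision(per)),
            class = "precision_summary")
}

pooled_precision <- function(per) {
  vapply(split(per$sd, factor(per$class, c("lengths", "areas", "angles"))),
         function(s) if (length(s)) mean(s) else NA_real_, numeric(1))
}

#' @export
print.precision_summary <- function(x, ...) {
  cat("<precision_summary> pooled precision (mean of repeat-scan SDs):\n")
  cat(sprintf("  lengths %s mm | areas %s mm^2 | angles %s deg\n",
              format(round(x$pooled[["lengths"]], 2), nsmall = 2),
              format(round(x$pooled[["areas"]], 2), nsmall = 2),
              format(round(x$pooled[["angles"]], 1), nsmall = 1)))
  invisible(x)
}

#' Longitudinal change statistics
#'
#' Changes are computed per measurement as final minus baseline value
#' over time-ordered records (baseline = earliest timepoint); each
#' class/group is summarized as mean and sample SD of its changes.
#'
#' @param records list of >= 2 `measurement_record`s with identical
#'   measurement sets, ordered (or orderable) by `timepoint_weeks`.
#' @return A `longitudinal_summary`: list with `per_measurement` (data
#'   frame: measurement, class, group, baseline, final, change) and
#'   `by_group` (data frame: class, group, n, mean_change, sd_change).
#' @export
longitudinal_summary <- function(records) {
  if (length(records) < 2L)
    mm_validation_error("at least 2 timepoints are required")
  check_identical_sets(records)
  wk <- vapply(records, function(r) as.numeric(r$timepoint_weeks), numeric(1))
  if (!any(is.na(wk))) records <- records[order(wk)]
  first <- record_table(records[[1]])
  last <- record_table(records[[length(records)]])
  per <- data.frame(measurement = first$measurement, class = first$class,
                    group = first$group, baseline = first$value,
                    final = last$value, change = last$value - first$value,
                    stringsAsFactors = FALSE)
  by_group <- do.call(rbind, lapply(
    split(per, list(per$class, per$group), drop = TRUE),
    function(d) data.frame(class = d$class[1], group = d$group[1],
                           n = nrow(d), mean_change = mean(d$change),
                           sd_change = sd(d$change))))
  rownames(by_group) <- NULL
  structure(list(per_measurement = per, by_group = by_group,
                 baseline_weeks = records[[1]]$timepoint_weeks,
                 final_weeks = records[[length(records)]]$timepoint_weeks),
            class = "longitudinal_summary")
}

#' @export
print.longitudinal_summary <- function(x, ...) {
  cat(sprintf("<longitudinal_summary> week %s -> %s\n",
              format(x$baseline_weeks), format(x$final_weeks)))
  for (i in seq_len(nrow(x$by_group)))
    cat(sprintf("  %-22s (%s, n=%d): change %8.2f +/- %.2f\n",
                x$by_group$group[i], x$by_group$class[i], x$by_group$n[i],
                x$by_group$mean_change[i], x$by_group$sd_change[i]))
  invisible(x)
}
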