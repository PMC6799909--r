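#' Read landmark, marker, and measurement sidecar files
#'
#' Landmark JSON layout:
#' `{"scapula": {"AA": [x,y,z], ...}, "humerus": {...}, "side": "right"}`.
#' Marker JSON layout: a list of
#' `{"label": "T1", "class": "tendon", "seed": [x,y,z]}` records
#' (`seed` is the analyst's approximate world-mm location; for virtual
#' markers it is the exact placement).  All coordinates are world mm.
#'
#' @param path JSON file path.
#' @return `read_landmarks()`: a [landmark_set()];
#'   `read_markers()`: a data frame with columns `label`, `class`,
#'   `x`, `y`, `z`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    mm_validation_error(sprintf("landmark file does not exist: '%s'", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(scapula = j$scapula, humerus = j$humerus,
               side = j$side %||% "right")
}

#' @rdname read_landmarks
#' @export
read_markers <- function(path) {
  if (!file.exists(path))
    mm_validation_error(sprintf("marker file does not exist: '%s'", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  markers_from_config(j, path)
}

markers_from_config <- function(j, where = "config") {
  if (is.data.frame(j)) {
    lab <- j$label; cls <- j$class
    seed <- do.call(rbind, lapply(j$seed, as.numeric))
  } else {
    lab <- vapply(j, function(m) as.character(m$label), "")
    cls <- vapply(j, function(m) as.character(m$class), "")
    seed <- do.call(rbind, lapply(j, function(m) as.numeric(m$seed)))
  }
  if (anyDuplicated(lab))
    mm_validation_error(sprintf("duplicate marker labels in %s", where))
  bad <- !cls %in% c("tendon", "bone", "virtual")
  if (any(bad))
    mm_validation_error(sprintf("unknown marker class(es): %s",
                                paste(unique(cls[bad]), collapse = ", ")))
  data.frame(label = lab, class = cls,
             x = seed[, 1], y = seed[, 2], z = seed[, 3])
}

#' Read a full study bundle
#'
#' The study config is a JSON file with keys:
#' \describe{
#'   \item{scans}{list of `{id, path, landmarks, timepoint_weeks}`;
#'     `landmarks` is a path to a landmark JSON or an inline landmark
#'     object.  An optional per-scan `markers` entry overrides the
#'     study-level seeds (the analyst re-identifies markers in each
#'     scan; after a 2 cm retraction a week-0 seed would be useless).}
#'   \item{markers}{path to a marker JSON, or inline list.}
#'   \item{measurements}{`lengths`: list of ordered label pairs;
#'     `areas`: list of ordered label quadruples (perimeter order);
#'     optional `length_groups`/`area_groups` tags.}
#'   \item{side}{`"right"` or `"left"` (default right).}
#' }
#' All file paths are resolved relative to the config file's directory.
#' Volumes are loaded eagerly; every label referenced by a measurement
#' must be defined by a marker (dangling labels are a validation error).
#'
#' @param path path to the study config JSON.
#' @return A `study_bundle`: list with `scans` (each:
#'   `scan_id`, `timepoint_weeks`, `volume`, `landmarks`, `seeds`),
#'   `markers`, `measurements`, `side`.
#' @export
read_study <- function(path) {
  if (!file.exists(path))
    mm_validation_error(sprintf("study config does not exist: '%s'", path))
  base <- dirname(normalizePath(path))
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  side <- j$side %||% "right"
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)

  markers <- if (is.character(j$markers)) {
    read_markers(resolve(j$markers))
  } else {
    markers_from_config(j$markers, path)
  }

  meas <- j$measurements %||% list()
  ms <- measurement_set(
    lengths = lapply(meas$lengths %||% list(), unlist),
    areas = lapply(meas$areas %||% list(), unlist),
    length_groups = if (!is.null(meas$length_groups)) unlist(meas$length_groups),
    area_groups = if (!is.null(meas$area_groups)) unlist(meas$area_groups))
  dangling <- setdiff(measurement_labels(ms), markers$label)
  if (length(dangling) > 0L)
    mm_validation_error(sprintf(
      "measurement(s) reference undefined marker label(s): %s",
      paste(dangling, collapse = ", ")))

  if (length(j$scans %||% list()) == 0L)
    mm_validation_error("study config defines no scans")
  scans <- lapply(j$scans, function(s) {
    vol_path <- resolve(s$path)
    if (!file.exists(vol_path))
      mm_validation_error(sprintf("scan '%s': volume file missing: '%s'",
                                  s$id %||% "?", vol_path))
    lms <- if (is.character(s$landmarks)) {
      read_landmarks(resolve(s$landmarks))
    } else {
      lm <- lapply(s$landmarks, function(g)
        if (is.list(g)) lapply(g, unlist) else g)
      landmark_set(scapula = lm$scapula, humerus = lm$humerus, side = side)
    }
    scan_markers <- if (!is.null(s$markers)) {
      if (is.character(s$markers)) read_markers(resolve(s$markers))
      else markers_from_config(s$markers, path)
    } else {
      markers
    }
    seeds <- truth_positions(scan_markers, c("tendon", "bone"))
    list(scan_id = as.character(s$id %||% basename(s$path)),
         timepoint_weeks = as.numeric(s$timepoint_weeks %||% NA),
         volume = read_volume(vol_path),
         landmarks = lms,
         seeds = seeds,
         virtual_truth = truth_positions(scan_markers, "virtual"))
  })
  structure(list(scans = scans, markers = markers, measurements = ms,
                 side = side, config_path = normalizePath(path)),
            class = "study_bundle")
}

#' Write a phantom study to disk as a loadable study bundle
#'
#' Writes one NIfTI volume and one landmark JSON per scan, a marker
#' JSON (seeds = true physical positions, exact virtual placements), a
#' measurement definition, a study config referencing them all, and a
#' `ground_truth.json`.  The result can be read back with
#' [read_study()] or run with the command-line tool.
#'
#' @param study a `phantom_study` from [render_longitudinal()] or
#'   [render_repeat_scans()].
#' @param dir output directory (created if needed).
#' @param format volume format, `"nifti"` or `"nrrd"`.
#' @return The config path, invisibly.
#' @export
write_phantom_study <- function(study, dir, format = c("nifti", "nrrd")) {
  format <- match.arg(format)
  ext <- if (format == "nifti") ".nii.gz" else ".nrrd"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scans_cfg <- list()
  for (s in study$scans) {
    vol_file <- paste0(s$scan_id, ext)
    write_volume(s$volume, file.path(dir, vol_file), format)
    lm_file <- paste0(s$scan_id, "_landmarks.json")
    lm <- s$landmarks
    jsonlite::write_json(
      c(lapply(lm$groups, function(g) apply(g, 1, as.numeric, simplify = FALSE)),
        list(side = lm$side)),
      file.path(dir, lm_file), auto_unbox = TRUE, digits = NA)
    truth <- s$truth
    scan_markers <- lapply(seq_len(nrow(truth)), function(i)
      list(label = truth$label[i], class = truth$class[i],
           seed = as.numeric(truth[i, c("x", "y", "z")])))
    scans_cfg[[length(scans_cfg) + 1L]] <- list(
      id = s$scan_id, path = vol_file, landmarks = lm_file,
      timepoint_weeks = s$timepoint_weeks, markers = scan_markers)
  }
  base_truth <- study$scans[[1]]$truth
  markers_cfg <- lapply(seq_len(nrow(base_truth)), function(i)
    list(label = base_truth$label[i], class = base_truth$class[i],
         seed = as.numeric(base_truth[i, c("x", "y", "z")])))
  ms <- study$measurements
  cfg <- list(side = study$scans[[1]]$landmarks$side,
              markers = markers_cfg,
              measurements = list(
                lengths = unname(ms$lengths), areas = unname(ms$areas),
                length_groups = unname(ms$length_groups),
                area_groups = unname(ms$area_groups)),
              scans = scans_cfg)
  cfg_path <- file.path(dir, "study.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(markers = lapply(study$scans, function(s)
           apply(truth_positions(s$truth), 1, as.numeric, simplify = FALSE)),
         records = lapply(study$truth_records, record_table)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(cfg_path)
}
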