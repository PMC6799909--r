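#' Run a full marker-morphometry study
#'
#' Orchestrates the end-to-end analysis: localize markers in every scan,
#' build anatomical frames from the landmarks, impute virtual markers
#' from their rigid-body relationship to the bone markers of the
#' reference (earliest) scan, measure every scan, and summarize.
#'
#' Two modes mirror the two validation protocols:
#' \describe{
#'   \item{precision}{all scans are repeats of one specimen
#'     (repositioned between acquisitions); the summary is the
#'     repeat-scan [precision_summary()].}
#'   \item{longitudinal}{scans are timepoints; follow-up scans are
#'     registered to the reference scan's world frame via the scapular
#'     landmarks ([register_scan()]) and the summary is the
#'     [longitudinal_summary()] of final-minus-baseline changes.}
#' }
#' Inter-marker lengths and areas are rigid-invariant, so registration
#' affects reported coordinates, not measurements; angles are computed
#' from each scan's own landmark-derived frames.
#'
#' @param study a study: a config path for [read_study()], a
#'   `study_bundle`, or a `phantom_study`.
#' @param mode `"precision"` or `"longitudinal"`.
#' @param threshold,min_voxels,max_voxels,distance_cap,weighting
#'   localization parameters, see [localize_markers()].
#' @param out_dir optional directory; when given, writes
#'   `measurements.csv` (long per-scan table), `summary.json`, and
#'   `manifest.json` (parameters, warnings, file checksums).
#' @return A list of class `study_result`: `records` (per-scan
#'   `measurement_record`s), `summary` (`precision_summary` or
#'   `longitudinal_summary`), `observations` (per-scan localized +
#'   imputed marker tables), `transforms` (per-scan registration, mode
#'   longitudinal), `warnings` (per-stage messages).
#' @export
run_study <- function(study, mode = c("precision", "longitudinal"),
                      threshold = 800, min_voxels = 3L, max_voxels = 500L,
                      distance_cap = 10, weighting = c("uniform", "intensity"),
                      out_dir = NULL) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  if (is.character(study)) study <- read_study(study)
  scans <- study$scans
  measurements <- study$measurements
  if (is.null(scans) || is.null(measurements))
    mm_validation_error("'study' must provide scans and a measurement set")
  warnings_log <- list()
  note <- function(stage, msg)
    warnings_log[[length(warnings_log) + 1L]] <<- list(stage = stage,
                                                       message = msg)

  # order longitudinal scans by timepoint; reference = earliest
  if (mode == "longitudinal") {
    wk <- vapply(scans, function(s) as.numeric(s$timepoint_weeks), numeric(1))
    if (any(is.na(wk)))
      mm_validation_error("longitudinal mode requires timepoint_weeks on every scan")
    scans <- scans[order(wk)]
  }

  # stage 1: localization
  observations <- lapply(scans, function(s) {
    withCallingHandlers(
      localize_markers(s$volume, s$seeds, threshold, min_voxels,
                       max_voxels, distance_cap, weighting),
      warning = function(w) {
        note("localize", sprintf("[%s] %s", s$scan_id, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  })

  # stage 2: frames
  frames <- lapply(scans, function(s)
    list(scapula = scapular_frame(s$landmarks),
         humerus = humeral_frame(s$landmarks)))

  # stage 3: registration (longitudinal only; identity for reference)
  transforms <- NULL
  if (mode == "longitudinal") {
    transforms <- lapply(seq_along(scans), function(i) {
      if (i == 1L) return(rigid_transform())
      tf <- register_scan(scans[[1]]$landmarks, scans[[i]]$landmarks)
      if (isTRUE(attr(tf, "rms") > 1))
        note("register", sprintf("[%s] scapular fit RMS %.2f mm",
                                 scans[[i]]$scan_id, attr(tf, "rms")))
      tf
    })
  }

  # stage 4: virtual marker imputation from the reference scan
  v_ref <- scans[[1]]$virtual_truth
  have_virtual <- !is.null(v_ref) && nrow(v_ref) > 0L
  bone_labels <- grep("^H", rownames(scans[[1]]$seeds), value = TRUE)
  model <- NULL
  if (have_virtual) {
    ref_obs <- observation_matrix(observations[[1]])
    hb <- intersect(bone_labels, rownames(ref_obs))
    if (length(hb) < 3L)
      mm_validation_error(sprintf(
        "reference scan localized only %d bone marker(s); 3 are needed for virtual imputation",
        length(hb)))
    model <- virtual_marker_model(v_ref, ref_obs[hb, , drop = FALSE])
  }

  # stage 5: measurement
  records <- vector("list", length(scans))
  positions_out <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    pos <- observation_matrix(observations[[i]])
    imput_rms <- NA_real_
    if (have_virtual) {
      hb <- intersect(rownames(model$bone), rownames(pos))
      imput <- impute_virtual_markers(model, pos[hb, , drop = FALSE])
      imput_rms <- attr(imput, "rms")
      if (imput_rms > 0.5)
        note("impute", sprintf("[%s] bone-marker fit RMS %.2f mm",
                               scans[[i]]$scan_id, imput_rms))
      pos <- rbind(pos, imput)
    }
    if (mode == "longitudinal")
      pos <- apply_transform(transforms[[i]], pos)
    records[[i]] <- withCallingHandlers(
      measure_scan(pos, measurements, frames[[i]],
                   scan_id = scans[[i]]$scan_id,
                   timepoint_weeks = scans[[i]]$timepoint_weeks),
      warning = function(w) {
        note("measure", sprintf("[%s] %s", scans[[i]]$scan_id,
                                conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    miss <- attr(records[[i]], "missing")
    if (length(miss) > 0L)
      note("measure", sprintf("[%s] marker(s) %s missing; dependent measurements are NA",
                              scans[[i]]$scan_id, paste(miss, collapse = ", ")))
    positions_out[[i]] <- pos
  }

  summary <- if (mode == "precision") precision_summary(records) else
    longitudinal_summary(records)

  result <- structure(list(mode = mode, records = records,
                           summary = summary, observations = observations,
                           positions = positions_out,
                           transforms = transforms,
                           warnings = warnings_log,
                           parameters = list(threshold = threshold,
                                             min_voxels = min_voxels,
                                             max_voxels = max_voxels,
                                             distance_cap = distance_cap,
                                             weighting = weighting)),
                      class = "study_result")
  if (!is.null(out_dir)) write_study_result(result, study, out_dir)
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> mode %s, %d scans, %d warnings\n",
              x$mode, length(x$records), length(x$warnings)))
  print(x$summary)
  invisible(x)
}

summary_as_list <- function(summary) {
  if (inherits(summary, "precision_summary")) {
    list(type = "precision", pooled = as.list(summary$pooled),
         per_measurement = summary$per_measurement)
  } else {
    list(type = "longitudinal", by_group = summary$by_group,
         per_measurement = summary$per_measurement)
  }
}

write_study_result <- function(result, study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meas_path <- file.path(out_dir, "measurements.csv")
  write.csv(records_long(result$records), meas_path, row.names = FALSE)
  summ_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_as_list(result$summary), summ_path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(meas_path, summ_path)
  manifest <- list(
    tool = "markermorph",
    version = as.character(packageVersion("markermorph")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    mode = result$mode,
    parameters = result$parameters,
    config_hash = if (!is.null(study$config_path))
      unname(tools::md5sum(study$config_path)) else NULL,
    warnings = result$warnings,
    outputs = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
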