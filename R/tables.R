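#' Statistics on tabulated measurement values
#'
#' The precision and longitudinal-change arithmetic can be applied
#' directly to tabulated per-measurement values (e.g. published
#' measurement tables), bypassing the imaging stages.
#'
#' `precision_from_table()` expects columns `measurement`, `class`
#' (`lengths` / `areas` / `angles`) and `sd` (the per-measurement
#' repeat-scan SD); the pooled precision of each class is the
#' unweighted mean of its SDs.  `longitudinal_from_table()` expects
#' long-format columns `measurement`, `class`, `group`,
#' `timepoint_weeks`, `value` and summarizes final-minus-baseline
#' changes per class/group with mean and sample SD.
#'
#' @param table a data frame (or CSV path) in the layout above.
#' @return `precision_from_table()`: a `precision_summary`;
#'   `longitudinal_from_table()`: a `longitudinal_summary`.
#' @seealso [reference_precision_table()],
#'   [reference_longitudinal_table()] for the bundled example tables.
#' @export
precision_from_table <- function(table) {
  tab <- load_table(table, c("measurement", "class", "sd"))
  per <- data.frame(measurement = tab$measurement, class = tab$class,
                    group = tab$group %||% tab$class,
                    mean = tab$mean %||% NA_real_, sd = as.numeric(tab$sd),
                    n = tab$n %||% NA_integer_)
  structure(list(per_measurement = per, pooled = pooled_precision(per)),
            class = "precision_summary")
}

#' @rdname precision_from_table
#' @export
longitudinal_from_table <- function(table) {
  tab <- load_table(table, c("measurement", "class", "timepoint_weeks",
                             "value"))
  if (is.null(tab$group)) tab$group <- tab$class
  weeks <- sort(unique(tab$timepoint_weeks))
  if (length(weeks) < 2L)
    mm_validation_error("need at least 2 timepoints")
  records <- lapply(weeks, function(w) {
    d <- tab[tab$timepoint_weeks == w, ]
    rec <- split(d, factor(d$class, c("lengths", "areas", "angles")))
    lengths <- setNames(rec$lengths$value, rec$lengths$measurement)
    areas <- setNames(rec$areas$value, rec$areas$measurement)
    angles <- if (nrow(rec$angles)) setNames(rec$angles$value,
                                             rec$angles$measurement)
    structure(list(scan_id = sprintf("week%02d", as.integer(w)),
                   timepoint_weeks = w, lengths = lengths, areas = areas,
                   angles = angles,
                   length_groups = setNames(rec$lengths$group,
                                            rec$lengths$measurement),
                   area_groups = setNames(rec$areas$group,
                                          rec$areas$measurement)),
              class = "measurement_record")
  })
  longitudinal_summary(records)
}

load_table <- function(table, need) {
  if (is.character(table)) {
    if (!file.exists(table))
      mm_error(sprintf("table file does not exist: '%s'", table),
               "markermorph_parse_error")
    table <- tryCatch(read.csv(table, stringsAsFactors = FALSE),
                      error = function(e)
                        mm_error(sprintf("cannot parse '%s': %s", table,
                                         conditionMessage(e)),
                                 "markermorph_parse_error"))
  }
  if (nrow(table) == 0L)
    mm_error("table has no rows", "markermorph_parse_error")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0L)
    mm_error(sprintf("table lacks column(s): %s",
                     paste(missing, collapse = ", ")),
             "markermorph_parse_error")
  bad <- which(!is.finite(as.numeric(table[[need[length(need)]]])))
  if (length(bad) > 0L)
    mm_error(sprintf("non-numeric value in table row %d", bad[1]),
             "markermorph_parse_error")
  table
}

#' Bundled reference measurement tables
#'
#' Two small tables ship with the package as worked examples for the
#' statistics layer, drawn from published validation work with an
#' implanted radiopaque marker grid on the rotator cuff:
#' `reference_precision_table()` gives per-measurement means and
#' repeat-scan SDs from a cadaveric shoulder imaged three times with
#' repositioning (14 lengths, 6 areas, 3 humeral orientation angles);
#' `reference_longitudinal_table()` gives per-timepoint values from one
#' rotator cuff repair patient scanned at 0, 3, 12 and 26 weeks
#' (4 mediolateral lengths, 3 antero-posterior lengths, 3 areas,
#' 3 angles).
#'
#' @return A data frame (see [precision_from_table()] /
#'   [longitudinal_from_table()] for the layouts).
#' @examples
#' precision_from_table(reference_precision_table())
#' @export
reference_precision_table <- function() {
  read.csv(system.file("extdata", "cadaver_repeat_precision.csv",
                       package = "markermorph"), stringsAsFactors = FALSE)
}

#' @rdname reference_precision_table
#' @export
reference_longitudinal_table <- function() {
  read.csv(system.file("extdata", "patient_longitudinal.csv",
                       package = "markermorph"), stringsAsFactors = FALSE)
}
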