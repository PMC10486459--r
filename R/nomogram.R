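# Points-based survival nomogram evaluation: each of the five clinical
# indices maps to a points axis, the summed total points map to the
# five-year survival probability through a monotone piecewise-linear
# curve (the machine-readable form of a graphically published nomogram).

#' Construct and validate a nomogram specification
#'
#' @param points named list: one named numeric vector per index
#'   (`path_stage`, `lvi`, `node_stage`, `neoadjuvant_chemo`,
#'   `adjuvant_radiotherapy`), mapping every category level to points.
#'   Logical indices use levels `"yes"`/`"no"`.
#' @param probability_knots data frame / matrix with columns
#'   `total_points` and `probability`: a monotone non-increasing
#'   piecewise-linear curve with probabilities in `[0, 1]`.
#' @param horizon_years prediction horizon (5 for five-year survival).
#' @return An object of class `nomogram_spec`.
#' @export
nomogram_spec <- function(points, probability_knots, horizon_years = 5L) {
  lv <- clinical_levels()
  for (ix in lv$indices) {
    if (is.null(points[[ix]]))
      stop_bcsurv(paste0("nomogram spec is missing index: ", ix),
                  "bcsurv_schema_error")
  }
  if (length(setdiff(names(points), lv$indices)))
    stop_bcsurv(paste0("unknown nomogram index: ",
                       paste(setdiff(names(points), lv$indices),
                             collapse = ", ")), "bcsurv_schema_error")
  level_sets <- list(path_stage = lv$path_stage, node_stage = lv$node_stage,
                     lvi = c("no", "yes"), neoadjuvant_chemo = c("no", "yes"),
                     adjuvant_radiotherapy = c("no", "yes"))
  for (ix in lv$indices) {
    miss <- setdiff(level_sets[[ix]], names(points[[ix]]))
    if (length(miss))
      stop_bcsurv(paste0("nomogram index ", ix, " is missing level(s): ",
                         paste(miss, collapse = ", ")),
                  "bcsurv_schema_error")
  }
  pk <- as.data.frame(probability_knots)
  if (!all(c("total_points", "probability") %in% names(pk)))
    stop_bcsurv("probability_knots needs total_points and probability",
                "bcsurv_schema_error")
  pk <- pk[order(pk$total_points), ]
  if (any(pk$probability < 0 | pk$probability > 1))
    stop_bcsurv("knot probabilities must lie in [0, 1]",
                "bcsurv_validation_error")
  if (any(diff(pk$probability) > 1e-12))
    stop_bcsurv("probability knots must be non-increasing in total points",
                "bcsurv_validation_error")
  if (nrow(pk) < 2L)
    stop_bcsurv("need at least two probability knots",
                "bcsurv_validation_error")
  structure(list(points = lapply(points, unlist),
                 probability_knots = pk,
                 horizon_years = as.integer(horizon_years)),
            class = "nomogram_spec")
}

#' Load a nomogram specification from JSON
#'
#' The JSON schema mirrors [nomogram_spec()]: an object with `points`
#' (one object per index mapping level to points), `probability_knots`
#' (array of `{total_points, probability}`), and `horizon_years`.
#'
#' @param file path to the JSON file.
#' @return A validated `nomogram_spec`.
#' @export
load_nomogram_spec <- function(file) {
  if (!file.exists(file))
    stop_bcsurv(paste0("nomogram spec not found: ", file),
                "bcsurv_io_error")
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  nomogram_spec(points = j$points,
                probability_knots = j$probability_knots,
                horizon_years = j$horizon_years %||% 5L)
}

#' Write a nomogram specification as JSON
#'
#' @param spec a `nomogram_spec`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_nomogram_spec <- function(spec, file) {
  jsonlite::write_json(list(points = lapply(spec$points, as.list),
                            probability_knots = spec$probability_knots,
                            horizon_years = spec$horizon_years),
                       file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

record_levels <- function(record) {
  c(path_stage = record$path_stage,
    lvi = if (record$lvi) "yes" else "no",
    node_stage = record$node_stage,
    neoadjuvant_chemo = if (record$neoadjuvant_chemo) "yes" else "no",
    adjuvant_radiotherapy = if (record$adjuvant_radiotherapy) "yes"
                            else "no")
}

#' Evaluate the nomogram for one clinical record
#'
#' Looks up the point value of each of the five indices, sums them to
#' the total points, and maps the total to the survival probability by
#' linear interpolation between the knots (clamped at the end knots).
#'
#' @param record a [clinical_record()].
#' @param spec a `nomogram_spec`.
#' @return An object of class `clinical_descriptor`: `points` (named,
#'   length 5), `total_points`, `survival_probability`.
#' @export
evaluate_nomogram <- function(record, spec) {
  stopifnot(inherits(spec, "nomogram_spec"))
  levs <- record_levels(record)
  pts <- vapply(names(levs), function(ix) {
    p <- spec$points[[ix]]
    if (!levs[[ix]] %in% names(p))
      stop_bcsurv(paste0("level '", levs[[ix]], "' of index ", ix,
                         " is absent from the nomogram spec"),
                  "bcsurv_evaluation_error")
    p[[levs[[ix]]]]
  }, 0)
  total <- sum(pts)
  pk <- spec$probability_knots
  prob <- stats::approx(pk$total_points, pk$probability, xout = total,
                        rule = 2, ties = "ordered")$y
  structure(list(patient_id = record$patient_id, points = pts,
                 total_points = total, survival_probability = prob),
            class = "clinical_descriptor")
}

#' Nomogram descriptors for a whole cohort
#'
#' @param records list of [clinical_record()]s.
#' @param spec a `nomogram_spec`.
#' @return Data frame: `patient_id`, the five per-index point columns
#'   (prefixed `pts_`), `total_points`, `survival_probability`.
#' @export
evaluate_nomogram_cohort <- function(records, spec) {
  rows <- lapply(records, function(r) {
    d <- evaluate_nomogram(r, spec)
    df <- data.frame(patient_id = r$patient_id, t(d$points),
                     total_points = d$total_points,
                     survival_probability = d$survival_probability,
                     stringsAsFactors = FALSE)
    names(df)[2:6] <- paste0("pts_", names(d$points))
    df
  })
  do.call(rbind, rows)
}

#' The synthetic nomogram calibration shipped with the package
#'
#' A stand-in specification with the structure of a published
#' post-cystectomy nomogram (five indices, points axes, monotone total
#' points to five-year survival curve) but synthetic point values; for
#' clinical use a spec transcribed from a published nomogram must be
#' supplied instead.
#'
#' @return Path to the bundled `nomogram_synthetic.json`.
#' @export
default_nomogram_path <- function() {
  system.file("extdata", "nomogram_synthetic.json", package = "bcsurv",
              mustWork = TRUE)
}
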