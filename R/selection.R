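# Mutual-information relevance scoring with equal-frequency binning,
# rank/threshold selection, and Pearson redundancy analysis.

# rank-based equal-frequency bins; depends on the data only through
# ranks, so MI is exactly invariant under strictly monotone transforms
equal_frequency_bins <- function(x, k) {
  r <- rank(x, ties.method = "average")
  b <- ceiling(r * k / length(x))
  pmin(pmax(b, 1L), k)
}

#' Plug-in mutual information between a feature and a binary label
#'
#' The feature is discretised into `k = min(10, floor(sqrt(n)))`
#' equal-frequency bins and the mutual information I(F;C) is computed as
#' the entropy difference H(F) - H(F|C) of the plug-in (empirical)
#' distributions, in nats, clamped at zero.
#'
#' @param feature_values numeric vector.
#' @param labels binary (0/1) vector of the same length (>= 8), with
#'   both classes present.
#' @return Non-negative mutual information in nats.
#' @export
estimate_mutual_information <- function(feature_values, labels) {
  n <- length(feature_values)
  if (n != length(labels) || n < 8)
    stop_bcsurv("need equal-length vectors with n >= 8",
                "bcsurv_selection_error")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop_bcsurv("labels contain a single class", "bcsurv_selection_error")
  if (anyNA(feature_values)) return(NA_real_)
  k <- max(2L, min(10L, as.integer(floor(sqrt(n)))))
  b <- equal_frequency_bins(feature_values, k)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h_f <- ent(tabulate(b, k) / n)
  h_fc <- 0
  for (c0 in unique(labels)) {
    sel <- labels == c0
    h_fc <- h_fc + mean(sel) * ent(tabulate(b[sel], k) / sum(sel))
  }
  max(0, h_f - h_fc)
}

#' Select features by mutual information
#'
#' Scores every column of `feature_matrix` against the binary labels,
#' excludes columns containing missing values, and selects either all
#' features with score at or above `threshold`, or, when `threshold` is
#' `NULL`, the top `k_target` features by descending score (the default
#' targets the 12-feature cardinality used by the reference analysis).
#' Ties in score are broken by name.
#'
#' @param feature_matrix numeric matrix or data frame with named columns.
#' @param labels binary vector, one per row.
#' @param threshold non-negative score cut, or `NULL` for a rank cut.
#' @param k_target number of features kept under the rank cut.
#' @return An object of class `mi_selection`: list with `mi_score`
#'   (named, descending), `threshold`, `selected_names` and
#'   `excluded_missing`.
#' @export
select_by_mi <- function(feature_matrix, labels, threshold = NULL,
                         k_target = 12L) {
  fm <- as.data.frame(feature_matrix, check.names = FALSE)
  fm <- fm[, setdiff(names(fm), "patient_id"), drop = FALSE]
  if (is.null(names(fm)) || any(!nzchar(names(fm))))
    stop_bcsurv("feature matrix columns must be named",
                "bcsurv_selection_error")
  has_na <- vapply(fm, anyNA, TRUE)
  excluded <- names(fm)[has_na]
  keep <- names(fm)[!has_na]
  scores <- vapply(keep, function(nm)
    estimate_mutual_information(fm[[nm]], labels), 0)
  ord <- order(-scores, keep)
  scores <- scores[ord]
  if (is.null(threshold)) {
    k <- min(k_target, length(scores))
    threshold <- if (k > 0) unname(scores[k]) else 0
    selected <- names(scores)[seq_len(k)]
  } else {
    if (threshold < 0)
      stop_bcsurv("threshold must be >= 0", "bcsurv_selection_error")
    selected <- names(scores)[scores >= threshold]
  }
  if (!length(selected))
    warning("MI selection is empty at this threshold")
  structure(list(mi_score = scores, threshold = threshold,
                 selected_names = selected, excluded_missing = excluded),
            class = "mi_selection")
}

#' @export
print.mi_selection <- function(x, ...) {
  cat("MI feature selection: ", length(x$selected_names), " selected of ",
      length(x$mi_score), " scored (threshold ",
      format(x$threshold, digits = 4), ", ",
      length(x$excluded_missing), " excluded for missingness)\n", sep = "")
  print(utils::head(round(x$mi_score, 4), 15))
  invisible(x)
}

#' Pearson correlation matrix of the selected features
#'
#' @param feature_matrix numeric matrix/data frame restricted to the
#'   selected features (>= 2 columns, >= 3 rows).
#' @return A symmetric correlation matrix of class `bcs_corr`; constant
#'   columns get correlation 0 against all others and are listed in the
#'   `constant` attribute.
#' @export
pearson_matrix <- function(feature_matrix) {
  fm <- as.matrix(as.data.frame(feature_matrix, check.names = FALSE))
  if (ncol(fm) < 2L || nrow(fm) < 3L)
    stop_bcsurv("need >= 2 features and >= 3 cases",
                "bcsurv_selection_error")
  sds <- apply(fm, 2, stats::sd)
  const <- colnames(fm)[sds == 0]
  r <- suppressWarnings(stats::cor(fm))
  r[is.na(r)] <- 0
  diag(r) <- 1
  structure(r, class = c("bcs_corr", "matrix"), constant = const)
}

#' Write an MI selection report as JSON
#'
#' @param sel an `mi_selection` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(sel, path) {
  jsonlite::write_json(list(threshold = sel$threshold,
                            selected = sel$selected_names,
                            excluded_missing = sel$excluded_missing,
                            mi_score = as.list(sel$mi_score)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
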