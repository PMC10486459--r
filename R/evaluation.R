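# ROC analysis with Hanley-McNeil standard errors, DeLong paired AUC
# comparison, Bonferroni adjustment, least-misclassification cutoff, and
# Kaplan-Meier stratification with a log-rank test.

# Mann-Whitney AUC with half credit for ties (fast internal helper)
auc_mw <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels != 1]
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' ROC curve and AUC with Hanley-McNeil standard error
#'
#' The AUC is the Mann-Whitney statistic (ties credited 0.5); its
#' standard error uses the Hanley-McNeil formula. ROC points are given
#' at every distinct threshold, so trapezoidal integration of the curve
#' reproduces the AUC exactly.
#'
#' @param scores numeric prediction scores (higher = more likely
#'   positive).
#' @param labels binary 0/1 outcomes.
#' @return An object of class `roc_result`: `auc`, `se`, `points`
#'   (data frame `fpr`, `tpr`, `threshold`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels == 1)
  if (length(unique(labels)) < 2L)
    stop_bcsurv("both classes required for ROC analysis",
                "bcsurv_evaluation_error")
  if (length(scores) != length(labels))
    stop_bcsurv("scores and labels differ in length",
                "bcsurv_evaluation_error")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  a <- auc_mw(scores, labels)
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) +
                (n_neg - 1) * (q2 - a^2)) / (n_pos * n_neg))
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), 0)
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                    threshold = c(Inf, thr, -Inf))
  structure(list(auc = a, se = se, points = pts, n_pos = n_pos,
                 n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f +/- %.3f (Hanley-McNeil SE; %d pos, %d neg)\n",
              x$auc, x$se, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "False positive rate", ylab = "True positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

# DeLong placement values (midrank method)
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels != 1]
  m <- length(x); n <- length(y)
  rall <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (rall[seq_len(m)] - rx) / n
  v01 <- 1 - (rall[m + seq_len(n)] - ry) / m
  list(v10 = v10, v01 = v01, auc = sum(rall[seq_len(m)]) / (m * n) -
         (m + 1) / (2 * n))
}

#' Paired comparison of two AUCs (DeLong)
#'
#' Nonparametric paired test of the AUC difference of two models scored
#' on the same patients, using the DeLong covariance of the placement
#' values; two-sided p-value from the normal reference. Comparing a
#' model with itself gives delta 0 and p = 1.
#'
#' @param scores_a,scores_b score vectors of the two models on the same
#'   patients, in the same order.
#' @param labels shared binary 0/1 outcomes.
#' @param label_pair optional text label, e.g. `"D vs CRD"`.
#' @param adjusted_alpha significance level after multiplicity
#'   adjustment (see [bonferroni_adjust()]).
#' @return An object of class `auc_comparison`: `label_pair`,
#'   `auc_a`, `auc_b`, `delta_auc`, `p_value`, `adjusted_alpha`,
#'   `significant`.
#' @export
compare_aucs <- function(scores_a, scores_b, labels,
                         label_pair = "A vs B", adjusted_alpha = 0.05) {
  labels <- as.integer(labels == 1)
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels))
    stop_bcsurv("both models must score the same patients",
                "bcsurv_contract_error")
  if (length(unique(labels)) < 2L)
    stop_bcsurv("both classes required", "bcsurv_evaluation_error")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  p <- if (v <= 0) {
    if (abs(delta) < 1e-12) 1 else 0
  } else {
    2 * stats::pnorm(-abs(delta) / sqrt(v))
  }
  structure(list(label_pair = label_pair, auc_a = pa$auc, auc_b = pb$auc,
                 delta_auc = delta, p_value = p,
                 adjusted_alpha = adjusted_alpha,
                 significant = p < adjusted_alpha),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("%s: AUC %.3f vs %.3f, delta %+0.3f, p = %.3g (alpha = %s)%s\n",
              x$label_pair, x$auc_a, x$auc_b, x$delta_auc, x$p_value,
              format(x$adjusted_alpha), if (x$significant) " *" else ""))
  invisible(x)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha_family family-wise significance level.
#' @param m number of comparisons (>= 1).
#' @return `alpha_family / m`, reported at three decimals (0.05 over 3
#'   comparisons gives 0.017).
#' @export
bonferroni_adjust <- function(alpha_family, m) {
  if (m < 1) stop_bcsurv("m must be >= 1", "bcsurv_contract_error")
  round(alpha_family / m, 3)
}

#' Least-misclassification score cutoff
#'
#' Among the midpoints of consecutive distinct scores, returns the
#' threshold minimising total misclassifications (false positives plus
#' false negatives) of the rule "positive if score > threshold"; ties
#' are resolved to the lowest threshold.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 outcomes.
#' @return The threshold (numeric scalar).
#' @export
cutoff_least_misclassification <- function(scores, labels) {
  labels <- as.integer(labels == 1)
  if (length(unique(labels)) < 2L)
    stop_bcsurv("both classes required", "bcsurv_evaluation_error")
  s <- sort(unique(scores))
  if (length(s) == 1L) return(s)
  cand <- (s[-1] + s[-length(s)]) / 2
  err <- vapply(cand, function(t)
    sum(scores > t & labels == 0) + sum(scores <= t & labels == 1), 0L)
  cand[which.min(err)]  # which.min takes the first (lowest) minimiser
}

#' Kaplan-Meier stratification with a log-rank test
#'
#' Product-limit survival curves per group and the two-sample log-rank
#' chi-square (1 df, two-sided p). With no events anywhere the curves
#' are constant at 1 and the log-rank statistic is undefined; the result
#' is then flagged `degenerate` with `NA` statistic and p-value.
#'
#' @param survival_months follow-up times in months.
#' @param event logical/0-1 death indicator.
#' @param group two-level grouping (e.g. predicted alive/deceased).
#' @param cutoff optional score cutoff recorded in the result.
#' @return An object of class `km_result`: `curves` (per-group step
#'   tables time / n_risk / n_event / survival), `chisq`, `p_value`,
#'   `degenerate`, `cutoff`.
#' @export
km_logrank <- function(survival_months, event, group, cutoff = NA_real_) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop_bcsurv("exactly two non-empty groups required",
                "bcsurv_evaluation_error")
  group <- droplevels(group)
  event <- as.integer(as.logical(event))
  fit <- survival::survfit(survival::Surv(survival_months, event) ~ group)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(levels(group)[1], length(sm$time))
            else sub("^group=", "", as.character(sm$strata))
  curves <- lapply(levels(group), function(g) {
    k <- strata == g
    data.frame(time = sm$time[k], n_risk = sm$n.risk[k],
               n_event = sm$n.event[k], survival = sm$surv[k])
  })
  names(curves) <- levels(group)
  if (sum(event) == 0L) {
    return(structure(list(curves = curves, chisq = NA_real_,
                          p_value = NA_real_, degenerate = TRUE,
                          cutoff = cutoff),
                     class = "km_result"))
  }
  sd <- survival::survdiff(survival::Surv(survival_months, event) ~ group)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  structure(list(curves = curves, chisq = unname(sd$chisq), p_value = p,
                 degenerate = FALSE, cutoff = cutoff),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Kaplan-Meier: no events observed; log-rank undefined\n")
  } else {
    cat(sprintf("Kaplan-Meier log-rank: chisq = %.3f (1 df), p = %.4g\n",
                x$chisq, x$p_value))
  }
  invisible(x)
}

#' @export
plot.km_result <- function(x, col = c("firebrick", "steelblue"), ...) {
  graphics::plot(NA, xlim = c(0, max(unlist(lapply(x$curves,
                                                   function(cv) cv$time)),
                                     1)),
                 ylim = c(0, 1), xlab = "Months", ylab = "Survival", ...)
  for (i in seq_along(x$curves)) {
    cv <- x$curves[[i]]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$survival)),
                    col = col[(i - 1) %% length(col) + 1], do.points = FALSE)
  }
  graphics::legend("bottomleft", legend = names(x$curves),
                   col = col[seq_along(x$curves)], lty = 1, bty = "n")
  invisible(x)
}
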