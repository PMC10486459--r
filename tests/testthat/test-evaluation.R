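test_that("AUC equals pair counting with tie credit and exact boundaries", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, auc_pair_counting(c(0.1, 0.4, 0.35, 0.8),
                                        c(0, 0, 1, 1)))
  perfect <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$se, 0)
  ties <- roc_auc(rep(0.5, 8), rep(c(0, 1), 4))
  expect_equal(ties$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), class = "bcsurv_evaluation_error")
})

test_that("AUC matches the brute-force oracle on random instances", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    r <- roc_auc(s, y)
    expect_equal(r$auc, auc_pair_counting(s, y), tolerance = 1e-12)
    # trapezoidal integration of the ROC points reproduces the AUC
    trap <- with(r$points, sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) /
                                 2))
    expect_equal(trap, r$auc, tolerance = 1e-10)
  }
})

test_that("Hanley-McNeil SE shrinks with sample size and stays positive", {
  set.seed(5)
  small <- roc_auc(rnorm(20) + rep(c(0, 1), 10), rep(c(0, 1), 10))
  big <- roc_auc(rnorm(400) + rep(c(0, 1), 200), rep(c(0, 1), 200))
  expect_gt(small$se, big$se)
  expect_gt(big$se, 0)
})

test_that("paired AUC comparison is symmetric and self-identical", {
  set.seed(31)
  y <- rep(c(0, 1), 30)
  a <- rnorm(60) + y; b <- rnorm(60) + 0.3 * y
  self <- compare_aucs(a, a, y)
  expect_equal(self$delta_auc, 0)
  expect_equal(self$p_value, 1)
  ab <- compare_aucs(a, b, y); ba <- compare_aucs(b, a, y)
  expect_equal(ab$delta_auc, -ba$delta_auc)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(compare_aucs(a[-1], b, y), class = "bcsurv_contract_error")
})

test_that("paired AUC comparison agrees with an independent DeLong implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:10) {
    n <- sample(40:120, 1)
    y <- rep(c(0, 1), length.out = n)
    a <- rnorm(n) + y; b <- rnorm(n) + 0.5 * y
    mine <- compare_aucs(a, b, y)
    ref <- suppressWarnings(pROC::roc.test(
      pROC::roc(y, a, quiet = TRUE, direction = "<"),
      pROC::roc(y, b, quiet = TRUE, direction = "<"),
      method = "delong", paired = TRUE))
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-9)
    expect_equal(mine$delta_auc,
                 unname(ref$estimate[1] - ref$estimate[2]),
                 tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment reproduces the three-comparison level", {
  expect_equal(bonferroni_adjust(0.05, 3), 0.017)
  expect_equal(bonferroni_adjust(0.05, 1), 0.05)
  expect_equal(bonferroni_adjust(0.10, 5), 0.02)
  expect_error(bonferroni_adjust(0.05, 0), class = "bcsurv_contract_error")
})

test_that("the least-misclassification cutoff matches exhaustive search", {
  expect_equal(cutoff_least_misclassification(c(0.1, 0.2, 0.8, 0.9),
                                              c(0, 0, 1, 1)), 0.5)
  # inverted labels move the optimum; the rule minimises on given labels
  inv <- cutoff_least_misclassification(c(0.1, 0.2, 0.8, 0.9),
                                        c(1, 1, 0, 0))
  errs <- function(t, s, y) sum(s > t & y == 0) + sum(s <= t & y == 1)
  # best midpoint rule on inverted labels: one FN at t = 0.15
  expect_equal(errs(inv, c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 3)
  expect_equal(inv, 0.15)
  set.seed(99)
  for (i in 1:10) {
    s <- round(runif(200), 2)
    y <- rbinom(200, 1, plogis(3 * (s - 0.5)))
    if (length(unique(y)) < 2) next
    t_star <- cutoff_least_misclassification(s, y)
    ss <- sort(unique(s))
    cand <- (ss[-1] + ss[-length(ss)]) / 2
    best <- min(vapply(cand, errs, 0, s = s, y = y))
    expect_equal(errs(t_star, s, y), best)
    # ties resolved to the lowest threshold
    expect_equal(t_star, min(cand[vapply(cand, errs, 0, s = s,
                                         y = y) == best]))
  }
})

test_that("log-rank matches the hand-computed 12-subject fixture", {
  d <- read.csv(test_path("fixtures", "logrank_12.csv"))
  km <- km_logrank(d$months, d$event, d$group)
  expect_equal(km$chisq, logrank_oracle(d$months, d$event, d$group),
               tolerance = 1e-8)
  # frozen value from the observed/expected events table:
  # O1 = 4, E1 = 4.63232, V = 1.95707
  expect_equal(km$chisq, 0.2043017031, tolerance = 1e-8)
  expect_equal(km$p_value, 0.6512708128, tolerance = 1e-8)
  expect_false(km$degenerate)
})

test_that("log-rank degenerates gracefully and nulls on identical groups", {
  t0 <- c(5, 12, 20, 33, 41, 47)
  ev <- c(1, 0, 1, 1, 0, 1)
  km <- km_logrank(c(t0, t0), c(ev, ev), rep(c("x", "y"), each = 6))
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$p_value, 1)
  none <- km_logrank(c(t0, t0), rep(0, 12), rep(c("x", "y"), each = 6))
  expect_true(none$degenerate)
  expect_true(is.na(none$p_value))
  expect_true(all(vapply(none$curves, function(cv) all(cv$survival == 1),
                         TRUE)))
  expect_error(km_logrank(t0, ev, rep("x", 6)),
               class = "bcsurv_evaluation_error")
})

test_that("the product-limit estimate equals the empirical survival without censoring", {
  set.seed(3)
  t1 <- sample(1:40, 15, replace = TRUE)
  t2 <- sample(5:50, 12, replace = TRUE)
  km <- km_logrank(c(t1, t2), rep(1, 27), rep(c("g1", "g2"), c(15, 12)))
  for (g in names(km$curves)) {
    cv <- km$curves[[g]]
    tt <- if (g == "g1") t1 else t2
    emp <- vapply(cv$time, function(u) mean(tt > u), 0)
    expect_equal(cv$survival, emp, tolerance = 1e-12)
    expect_true(all(diff(cv$survival) <= 1e-12))
  }
})
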