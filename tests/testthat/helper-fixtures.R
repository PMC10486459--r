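# Fixtures are generated in code: small cohorts, binary disks, and quick
# pipeline configurations sized for unit testing.

tiny_sim <- function(n = 8, seed = 1L, ...) {
  sim_config(n_patients = n, seed = seed, volume_shape = c(14, 40, 40),
             lesion_radius_range_mm = c(5, 9), ...)
}

# rasterised disk mask (2D) of radius r pixels
disk_mask <- function(r, pad = 5L) {
  n <- 2L * r + 2L * pad + 1L
  ctr <- (n + 1) / 2
  outer(seq_len(n) - ctr, seq_len(n) - ctr,
        function(a, b) (a^2 + b^2) <= r^2) * 1L
}

# ellipse mask with semi-axes (ry, rx)
ellipse_mask <- function(ry, rx, pad = 5L) {
  nr <- 2L * ry + 2L * pad + 1L; nc <- 2L * rx + 2L * pad + 1L
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  outer(seq_len(nr) - cy, seq_len(nc) - cx,
        function(a, b) (a / ry)^2 + (b / rx)^2 <= 1) * 1L
}

# textured image over a mask, reproducible
textured_slice <- function(mask, seed = 1L, base = 40, contrast = 50,
                           noise = 8) {
  set.seed(seed)
  img <- matrix(base, nrow(mask), ncol(mask)) + contrast * mask
  img + matrix(stats::rnorm(length(mask), sd = noise), nrow(mask))
}

# small but complete clinical record
quick_record <- function(id, months, event = TRUE, label = NULL,
                         date = "2010-01-01", stage = "pT2", lvi = FALSE,
                         node = "N0") {
  clinical_record(patient_id = id, path_stage = stage, lvi = lvi,
                  node_stage = node, neoadjuvant_chemo = TRUE,
                  adjuvant_radiotherapy = FALSE, survival_months = months,
                  event = event, label_5yr = label, exam_date = date)
}

# fast pipeline configuration for small cohorts
quick_pipeline <- function(dir, n = 30, seed = 5L, combos = c("C", "CRD"),
                           sim_args = list()) {
  sim <- do.call(sim_config, c(list(
    n_patients = n, seed = seed, volume_shape = c(14, 44, 44),
    lesion_radius_range_mm = c(5, 10)), sim_args))
  pipeline_config(
    out_dir = dir, sim = sim, fractions = c(0.5, 0.15, 0.35),
    roi = roi_config(stride = 8L, max_hybrids_per_case = 6L),
    cnn = cnn_config(conv_channels = c(4L, 8L), lc_channels = c(8L, 8L),
                     epochs = 2L, batch_size = 32L),
    bpnn = bpnn_config(max_iterations = 120L),
    combinations = combos, seed = seed)
}

# independent oracle: discrete mutual information by direct summation
# over the joint distribution table, in nats
mi_from_joint <- function(joint) {
  p <- joint / sum(joint)
  pf <- rowSums(p); pc <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (pf[i] * pc[j]))
  }
  unname(s)
}

# independent oracle: AUC by explicit positive/negative pair counting
auc_pair_counting <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# independent oracle: two-group log-rank statistic from the observed and
# expected event tables (direct hypergeometric computation)
logrank_oracle <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  times <- sort(unique(time[event == 1]))
  o1 <- 0; e1 <- 0; v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}
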