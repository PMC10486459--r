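# Texture families of the feature catalog: direction-merged co-occurrence
# (GLCM) and run-length (GLRLM) statistics on the 32-level quantised
# in-mask intensities, and Sobel gradient-magnitude statistics.

N_GRAY <- 32L

# equal-width quantisation of in-mask intensities into N_GRAY levels;
# a constant region maps to level 1 everywhere
quantize_slice <- function(img, mask, n_levels = N_GRAY) {
  v <- img[mask != 0]
  lo <- min(v); hi <- max(v)
  q <- matrix(0L, nrow(img), ncol(img))
  if (hi > lo) {
    lev <- pmin(n_levels, 1L + as.integer(floor((img - lo) / (hi - lo) *
                                                  n_levels)))
    q[mask != 0] <- lev[mask != 0]
  } else {
    q[mask != 0] <- 1L
  }
  q
}

# co-occurrence counts for one (dr, dc) offset, symmetric, in-mask pairs only
glcm_counts <- function(q, dr, dc, n_levels = N_GRAY) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- a > 0L & b > 0L
  if (!any(ok)) return(matrix(0, n_levels, n_levels))
  counts <- tabulate((a[ok] - 1L) * n_levels + b[ok],
                     nbins = n_levels * n_levels)
  m <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  m + t(m)
}

glcm_stats <- function(q, distance, n_levels = N_GRAY) {
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  m <- Reduce(`+`, lapply(offs, function(o)
    glcm_counts(q, o[1] * distance, o[2] * distance, n_levels)))
  tot <- sum(m)
  out <- c(contrast = 0, dissimilarity = 0, homogeneity = 1, energy = 1,
           entropy = 0, correlation = 0, autocorrelation = 1,
           cluster_shade = 0, cluster_prominence = 0, max_probability = 1,
           sum_average = 2, sum_entropy = 0, difference_entropy = 0,
           inverse_variance = 0)
  if (tot == 0) return(out)
  p <- m / tot
  i <- row(p); j <- col(p)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  s_i <- sqrt(sum(p * (i - mu_i)^2)); s_j <- sqrt(sum(p * (j - mu_j)^2))
  pk_sum <- tapply(p, i + j, sum)
  pk_dif <- tapply(p, abs(i - j), sum)
  nz <- p > 0
  corr <- if (s_i > 0 && s_j > 0)
    sum(p * (i - mu_i) * (j - mu_j)) / (s_i * s_j) else 0
  offd <- i != j
  c(contrast = sum(p * (i - j)^2),
    dissimilarity = sum(p * abs(i - j)),
    homogeneity = sum(p / (1 + (i - j)^2)),
    energy = sum(p^2),
    entropy = -sum(p[nz] * log(p[nz])),
    correlation = corr,
    autocorrelation = sum(p * i * j),
    cluster_shade = sum(p * (i + j - mu_i - mu_j)^3),
    cluster_prominence = sum(p * (i + j - mu_i - mu_j)^4),
    max_probability = max(p),
    sum_average = sum(as.numeric(names(pk_sum)) * pk_sum),
    sum_entropy = -sum(pk_sum[pk_sum > 0] * log(pk_sum[pk_sum > 0])),
    difference_entropy = -sum(pk_dif[pk_dif > 0] * log(pk_dif[pk_dif > 0])),
    inverse_variance = sum(p[offd] / (i[offd] - j[offd])^2))
}

# runs of equal quantised level inside the mask, merged over the four
# principal directions, accumulated into a level x run-length matrix
glrlm_matrix <- function(q, n_levels = N_GRAY) {
  nr <- nrow(q); nc <- ncol(q)
  maxlen <- max(nr, nc)
  rlm <- matrix(0, n_levels, maxlen)
  add_line <- function(vals) {
    vals[vals == 0L] <- NA_integer_
    if (all(is.na(vals))) return()
    r <- rle(as.vector(vals))
    keep <- !is.na(r$values)
    if (any(keep)) {
      g <- r$values[keep]; l <- pmin(r$lengths[keep], maxlen)
      for (k in seq_along(g)) rlm[g[k], l[k]] <<- rlm[g[k], l[k]] + 1
    }
  }
  for (r in seq_len(nr)) add_line(q[r, ])          # 0 degrees
  for (cc in seq_len(nc)) add_line(q[, cc])        # 90 degrees
  for (d in seq(-(nr - 1), nc - 1)) {              # 45 degrees
    rr <- seq_len(nr); ccs <- rr + d
    ok <- ccs >= 1 & ccs <= nc
    if (any(ok)) add_line(q[cbind(rev(rr[ok]), rev(ccs[ok]))])
  }
  for (d in seq(2, nr + nc)) {                     # 135 degrees
    rr <- seq_len(nr); ccs <- d - rr
    ok <- ccs >= 1 & ccs <= nc
    if (any(ok)) add_line(q[cbind(rr[ok], ccs[ok])])
  }
  rlm
}

glrlm_stats <- function(q, n_pix) {
  rlm <- glrlm_matrix(q)
  nr_runs <- sum(rlm)
  if (nr_runs == 0)
    return(c(sre = 0, lre = 0, gln = 0, rln = 0, rp = 0, lgre = 0, hgre = 0,
             srlge = 0, srhge = 0, lrlge = 0, lrhge = 0))
  g <- row(rlm); l <- col(rlm)
  Ng <- rowSums(rlm); Nl <- colSums(rlm)
  c(sre = sum(rlm / l^2) / nr_runs,
    lre = sum(rlm * l^2) / nr_runs,
    gln = sum(Ng^2) / nr_runs,
    rln = sum(Nl^2) / nr_runs,
    rp = nr_runs / (4 * n_pix),  # runs are merged over 4 directions
    lgre = sum(rlm / g^2) / nr_runs,
    hgre = sum(rlm * g^2) / nr_runs,
    srlge = sum(rlm / (g^2 * l^2)) / nr_runs,
    srhge = sum(rlm * g^2 / l^2) / nr_runs,
    lrlge = sum(rlm * l^2 / g^2) / nr_runs,
    lrhge = sum(rlm * g^2 * l^2) / nr_runs)
}

# Sobel gradient magnitude with replicated edges
sobel_magnitude <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  sh <- function(dr, dc) pad[dr + seq_len(nr) + 1L, dc + seq_len(nc) + 1L]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

binned_entropy_uniformity <- function(v, n_bins = N_GRAY) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(c(entropy = 0, uniformity = 1))
  b <- pmin(n_bins, 1L + floor((v - lo) / (hi - lo) * n_bins))
  p <- tabulate(b, n_bins) / length(v)
  p <- p[p > 0]
  c(entropy = -sum(p * log(p)), uniformity = sum(p^2))
}

moments_sk <- function(v) {
  m <- mean(v); s2 <- mean((v - m)^2)
  if (s2 <= 0) return(c(skew = 0, kurt = 0))
  c(skew = mean((v - m)^3) / s2^1.5, kurt = mean((v - m)^4) / s2^2)
}

intensity_features <- function(v) {
  qs <- stats::quantile(v, c(0.05, 0.10, 0.25, 0.75, 0.90, 0.95),
                        names = FALSE, type = 7)
  sk <- moments_sk(v)
  eu <- binned_entropy_uniformity(v)
  m <- mean(v); s <- stats::sd(v); if (is.na(s)) s <- 0
  c(int_mean = m, int_median = stats::median(v), int_sd = s,
    int_variance = s^2, int_skewness = sk[["skew"]],
    int_kurtosis = sk[["kurt"]], int_min = min(v), int_max = max(v),
    int_range = max(v) - min(v), int_p5 = qs[1], int_p10 = qs[2],
    int_p25 = qs[3], int_p75 = qs[4], int_p90 = qs[5], int_p95 = qs[6],
    int_iqr = qs[4] - qs[3], int_mad = stats::mad(v),
    int_energy = mean(v^2), int_rms = sqrt(mean(v^2)),
    int_entropy = eu[["entropy"]], int_uniformity = eu[["uniformity"]],
    int_cv = if (abs(m) > 1e-12) s / m else 0)
}

gradient_features <- function(img, mask) {
  gm <- sobel_magnitude(img)
  v <- gm[mask != 0]
  sk <- moments_sk(v)
  eu <- binned_entropy_uniformity(v)
  c(grad_mean = mean(v), grad_median = stats::median(v),
    grad_sd = if (length(v) > 1) stats::sd(v) else 0,
    grad_skewness = sk[["skew"]], grad_kurtosis = sk[["kurt"]],
    grad_energy = mean(v^2),
    grad_entropy = eu[["entropy"]],
    grad_p90 = stats::quantile(v, 0.9, names = FALSE, type = 7),
    grad_uniformity = eu[["uniformity"]])
}
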