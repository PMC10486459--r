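# Reference CNN for hybrid-ROI survival likelihoods.
#
# Architecture (reconstruction, all sizes configurable): two 5x5
# convolution layers (C1, C2), each followed by ReLU, local response
# normalisation across channels, and 3x3/stride-2 max-pooling; two 3x3
# locally connected layers (L3, L4, untied weights); a 10-unit fully
# connected layer (FC10) and a sigmoid output giving the per-ROI
# survival likelihood. Trained by mini-batch SGD with momentum on binary
# cross-entropy; the retained model is the epoch with the best
# validation ROI-level AUC.
#
# Feature maps are arrays (N, H, W, C); convolutions are evaluated as 25
# (or 9) strided-slice matrix products so the heavy lifting stays in BLAS.

#' CNN configuration
#'
#' @param conv_channels channels of C1 and C2 (length 2).
#' @param conv_kernel convolution kernel size (square, odd).
#' @param lc_channels channels of the locally connected L3 and L4.
#' @param fc_units units of the fully connected FC10 layer.
#' @param lrn_n,lrn_k,lrn_alpha,lrn_beta local response normalisation
#'   window and constants.
#' @param pool_size,pool_stride max-pooling geometry.
#' @param learning_rate,momentum,epochs,batch_size SGD hyperparameters.
#' @param seed integer seed for initialisation and batch shuffling.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(conv_channels = c(16L, 32L), conv_kernel = 5L,
                       lc_channels = c(32L, 32L), fc_units = 10L,
                       lrn_n = 5L, lrn_k = 2, lrn_alpha = 1e-4,
                       lrn_beta = 0.75, pool_size = 3L, pool_stride = 2L,
                       learning_rate = 0.01, momentum = 0.9, epochs = 10L,
                       batch_size = 64L, seed = 1L) {
  if (conv_kernel %% 2L != 1L)
    stop_bcsurv("conv_kernel must be odd", "bcsurv_construction_error")
  if (length(conv_channels) != 2L || any(conv_channels < 1))
    stop_bcsurv("conv_channels must be two positive counts",
                "bcsurv_construction_error")
  structure(list(conv_channels = as.integer(conv_channels),
                 conv_kernel = as.integer(conv_kernel),
                 lc_channels = as.integer(lc_channels),
                 fc_units = as.integer(fc_units),
                 lrn_n = as.integer(lrn_n), lrn_k = lrn_k,
                 lrn_alpha = lrn_alpha, lrn_beta = lrn_beta,
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride),
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

pool_out <- function(h, size, stride) (h - size) %/% stride + 1L

# ---- layer primitives ----------------------------------------------------

conv_forward <- function(x, W, b, pad) {
  d <- dim(x); n <- d[1]; h <- d[2]; w <- d[3]; cin <- d[4]
  k <- dim(W)[1]; cout <- dim(W)[4]
  xp <- array(0, c(n, h + 2 * pad, w + 2 * pad, cin))
  xp[, pad + seq_len(h), pad + seq_len(w), ] <- x
  out <- array(rep(b, each = n * h * w), c(n, h, w, cout))
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    xs <- xp[, ki + seq_len(h) - 1L, kj + seq_len(w) - 1L, , drop = FALSE]
    dim(xs) <- c(n * h * w, cin)
    wm <- W[ki, kj, , , drop = FALSE]; dim(wm) <- c(cin, cout)
    out <- out + array(xs %*% wm, c(n, h, w, cout))
  }
  list(out = out, xp = xp)
}

conv_backward <- function(g, cache, W, pad) {
  xp <- cache$xp
  d <- dim(g); n <- d[1]; h <- d[2]; w <- d[3]; cout <- d[4]
  k <- dim(W)[1]; cin <- dim(W)[3]
  gm <- g; dim(gm) <- c(n * h * w, cout)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(xp))
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    xs <- xp[, ki + seq_len(h) - 1L, kj + seq_len(w) - 1L, , drop = FALSE]
    dim(xs) <- c(n * h * w, cin)
    dW[ki, kj, , ] <- crossprod(xs, gm)
    wm <- W[ki, kj, , , drop = FALSE]; dim(wm) <- c(cin, cout)
    dxs <- gm %*% t(wm)
    dim(dxs) <- c(n, h, w, cin)
    dxp[, ki + seq_len(h) - 1L, kj + seq_len(w) - 1L, ] <-
      dxp[, ki + seq_len(h) - 1L, kj + seq_len(w) - 1L, , drop = FALSE] + dxs
  }
  db <- colSums(gm)
  hh <- dim(dxp)[2] - 2 * pad; ww <- dim(dxp)[3] - 2 * pad
  list(dx = dxp[, pad + seq_len(hh), pad + seq_len(ww), , drop = FALSE],
       dW = dW, db = db)
}

lrn_forward <- function(x, n_win, k0, alpha, beta) {
  cc <- dim(x)[4]
  half <- n_win %/% 2L
  ssum <- array(0, dim(x))
  x2 <- x^2
  for (o in -half:half) {
    j <- seq_len(cc) + o
    ok <- j >= 1L & j <= cc
    ssum[, , , which(ok)] <- ssum[, , , which(ok), drop = FALSE] +
      x2[, , , j[ok], drop = FALSE]
  }
  S <- k0 + (alpha / n_win) * ssum
  out <- x * S^(-beta)
  list(out = out, S = S)
}

lrn_backward <- function(g, x, cache, n_win, k0, alpha, beta) {
  S <- cache$S
  cc <- dim(x)[4]
  half <- n_win %/% 2L
  Tm <- g * x * S^(-beta - 1)
  wsum <- array(0, dim(x))
  for (o in -half:half) {
    j <- seq_len(cc) + o
    ok <- j >= 1L & j <= cc
    wsum[, , , which(ok)] <- wsum[, , , which(ok), drop = FALSE] +
      Tm[, , , j[ok], drop = FALSE]
  }
  g * S^(-beta) - 2 * (alpha / n_win) * beta * x * wsum
}

maxpool_forward <- function(x, size, stride) {
  d <- dim(x); n <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  oh <- pool_out(h, size, stride); ow <- pool_out(w, size, stride)
  cur <- array(-Inf, c(n, oh, ow, cc))
  arg <- array(1L, c(n, oh, ow, cc))
  k <- 1L
  for (dr in seq_len(size)) for (dc in seq_len(size)) {
    rows <- seq.int(dr, by = stride, length.out = oh)
    cols <- seq.int(dc, by = stride, length.out = ow)
    xs <- x[, rows, cols, , drop = FALSE]
    upd <- xs > cur
    cur[upd] <- xs[upd]
    arg[upd] <- k
    k <- k + 1L
  }
  list(out = cur, arg = arg, in_dim = d)
}

maxpool_backward <- function(g, cache, size, stride) {
  d <- cache$in_dim
  oh <- dim(g)[2]; ow <- dim(g)[3]
  dx <- array(0, d)
  k <- 1L
  for (dr in seq_len(size)) for (dc in seq_len(size)) {
    rows <- seq.int(dr, by = stride, length.out = oh)
    cols <- seq.int(dc, by = stride, length.out = ow)
    sel <- cache$arg == k
    if (any(sel)) {
      gk <- g * sel
      dx[, rows, cols, ] <- dx[, rows, cols, , drop = FALSE] + gk
    }
    k <- k + 1L
  }
  dx
}

# im2col for 3x3 valid neighbourhoods: (N, P, 9*Cin), P = OH*OW
lc_im2col <- function(x, k) {
  d <- dim(x); n <- d[1]; h <- d[2]; w <- d[3]; cin <- d[4]
  oh <- h - k + 1L; ow <- w - k + 1L
  xc <- array(0, c(n, oh * ow, k * k * cin))
  s <- 1L
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    xs <- x[, ki + seq_len(oh) - 1L, kj + seq_len(ow) - 1L, , drop = FALSE]
    dim(xs) <- c(n, oh * ow, cin)
    xc[, , s - 1L + seq_len(cin)] <- xs
    s <- s + cin
  }
  xc
}

lc_forward <- function(x, W, b, k) {
  d <- dim(x); n <- d[1]
  oh <- d[2] - k + 1L; ow <- d[3] - k + 1L
  p_tot <- oh * ow; cout <- dim(W)[3]
  xc <- lc_im2col(x, k)
  out <- array(0, c(n, p_tot, cout))
  for (p in seq_len(p_tot))
    out[, p, ] <- xc[, p, ] %*% W[p, , ] +
      matrix(b[p, ], n, cout, byrow = TRUE)
  dim(out) <- c(n, oh, ow, cout)
  list(out = out, xc = xc, in_dim = d)
}

lc_backward <- function(g, cache, W, k) {
  d <- cache$in_dim; n <- d[1]; cin <- d[4]
  oh <- d[2] - k + 1L; ow <- d[3] - k + 1L
  p_tot <- oh * ow; cout <- dim(W)[3]
  gm <- g; dim(gm) <- c(n, p_tot, cout)
  dW <- array(0, dim(W)); db <- matrix(0, p_tot, cout)
  dxc <- array(0, dim(cache$xc))
  for (p in seq_len(p_tot)) {
    gp <- matrix(gm[, p, ], n, cout)
    xp <- matrix(cache$xc[, p, ], n, k * k * cin)
    dW[p, , ] <- crossprod(xp, gp)
    db[p, ] <- colSums(gp)
    dxc[, p, ] <- gp %*% t(W[p, , ])
  }
  dx <- array(0, d)
  s <- 1L
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    dxs <- dxc[, , s - 1L + seq_len(cin), drop = FALSE]
    dim(dxs) <- c(n, oh, ow, cin)
    dx[, ki + seq_len(oh) - 1L, kj + seq_len(ow) - 1L, ] <-
      dx[, ki + seq_len(oh) - 1L, kj + seq_len(ow) - 1L, , drop = FALSE] +
      dxs
    s <- s + cin
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- model ---------------------------------------------------------------

cnn_geometry <- function(cfg) {
  h1 <- 32L
  p1 <- pool_out(h1, cfg$pool_size, cfg$pool_stride)
  p2 <- pool_out(p1, cfg$pool_size, cfg$pool_stride)
  l3 <- p2 - 3L + 1L
  l4 <- l3 - 3L + 1L
  if (l4 < 1L)
    stop_bcsurv("configuration collapses the feature map below 1x1",
                "bcsurv_construction_error")
  list(p1 = p1, p2 = p2, l3 = l3, l4 = l4,
       fc_in = l4 * l4 * cfg$lc_channels[2])
}

init_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Build a seeded, untrained hybrid-ROI CNN
#'
#' @param config a [cnn_config()].
#' @return An object of class `roi_cnn` mapping 32x32 patches to
#'   survival likelihoods in `[0, 1]`.
#' @export
build_cnn <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  g <- cnn_geometry(config)
  k <- config$conv_kernel; c1 <- config$conv_channels[1]
  c2 <- config$conv_channels[2]
  l3c <- config$lc_channels[1]; l4c <- config$lc_channels[2]
  set.seed(config$seed)
  rnd <- function(dims, fan_in)
    array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
  params <- list(
    W1 = rnd(c(k, k, 1L, c1), k * k),
    b1 = numeric(c1),
    W2 = rnd(c(k, k, c1, c2), k * k * c1),
    b2 = numeric(c2),
    W3 = rnd(c(g$l3^2, 9L * c2, l3c), 9 * c2),
    b3 = matrix(0, g$l3^2, l3c),
    W4 = rnd(c(g$l4^2, 9L * l3c, l4c), 9 * l3c),
    b4 = matrix(0, g$l4^2, l4c),
    W5 = init_mat(g$fc_in, config$fc_units, g$fc_in),
    b5 = numeric(config$fc_units),
    W6 = init_mat(config$fc_units, 1L, config$fc_units),
    b6 = 0)
  structure(list(config = config, geometry = g, params = params,
                 trained = FALSE, history = NULL),
            class = "roi_cnn")
}

cnn_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$config; pp <- model$params
  pad <- (cfg$conv_kernel - 1L) %/% 2L
  n <- dim(x)[1]
  a0 <- x; dim(a0) <- c(dim(x), 1L)
  c1 <- conv_forward(a0, pp$W1, pp$b1, pad)
  r1 <- pmax(c1$out, 0)
  n1 <- lrn_forward(r1, cfg$lrn_n, cfg$lrn_k, cfg$lrn_alpha, cfg$lrn_beta)
  p1 <- maxpool_forward(n1$out, cfg$pool_size, cfg$pool_stride)
  c2 <- conv_forward(p1$out, pp$W2, pp$b2, pad)
  r2 <- pmax(c2$out, 0)
  n2 <- lrn_forward(r2, cfg$lrn_n, cfg$lrn_k, cfg$lrn_alpha, cfg$lrn_beta)
  p2 <- maxpool_forward(n2$out, cfg$pool_size, cfg$pool_stride)
  l3 <- lc_forward(p2$out, pp$W3, pp$b3, 3L)
  r3 <- pmax(l3$out, 0)
  l4 <- lc_forward(r3, pp$W4, pp$b4, 3L)
  r4 <- pmax(l4$out, 0)
  f <- r4; dim(f) <- c(n, model$geometry$fc_in)
  h5 <- f %*% pp$W5 + matrix(pp$b5, n, cfg$fc_units, byrow = TRUE)
  r5 <- pmax(h5, 0)
  z <- drop(r5 %*% pp$W6) + pp$b6
  prob <- stats::plogis(z)
  if (!keep_cache) return(list(prob = prob))
  list(prob = prob, a0 = a0, c1 = c1, r1 = r1, n1 = n1, p1 = p1,
       c2 = c2, r2 = r2, n2 = n2, p2 = p2, l3 = l3, r3 = r3, l4 = l4,
       r4 = r4, f = f, h5 = h5, r5 = r5, z = z)
}

cnn_backward <- function(model, cache, y) {
  cfg <- model$config; pp <- model$params
  pad <- (cfg$conv_kernel - 1L) %/% 2L
  n <- length(y)
  dz <- (cache$prob - y) / n                  # BCE + sigmoid
  dW6 <- crossprod(cache$r5, matrix(dz, n, 1))
  db6 <- sum(dz)
  dr5 <- matrix(dz, n, 1) %*% t(pp$W6)
  dh5 <- dr5 * (cache$h5 > 0)
  dW5 <- crossprod(cache$f, dh5)
  db5 <- colSums(dh5)
  df <- dh5 %*% t(pp$W5)
  dr4 <- df; dim(dr4) <- dim(cache$r4)
  dl4 <- dr4 * (cache$l4$out > 0)
  b4g <- lc_backward(dl4, cache$l4, pp$W4, 3L)
  dr3 <- b4g$dx * (cache$l3$out > 0)
  b3g <- lc_backward(dr3, cache$l3, pp$W3, 3L)
  dp2 <- b3g$dx
  dn2 <- maxpool_backward(dp2, cache$p2, cfg$pool_size, cfg$pool_stride)
  dr2 <- lrn_backward(dn2, cache$r2, cache$n2, cfg$lrn_n, cfg$lrn_k,
                      cfg$lrn_alpha, cfg$lrn_beta)
  dc2 <- dr2 * (cache$c2$out > 0)
  b2g <- conv_backward(dc2, cache$c2, pp$W2, pad)
  dp1 <- b2g$dx
  dn1 <- maxpool_backward(dp1, cache$p1, cfg$pool_size, cfg$pool_stride)
  dr1 <- lrn_backward(dn1, cache$r1, cache$n1, cfg$lrn_n, cfg$lrn_k,
                      cfg$lrn_alpha, cfg$lrn_beta)
  dc1 <- dr1 * (cache$c1$out > 0)
  b1g <- conv_backward(dc1, cache$c1, pp$W1, pad)
  list(W1 = b1g$dW, b1 = b1g$db, W2 = b2g$dW, b2 = b2g$db,
       W3 = b3g$dW, b3 = b3g$db, W4 = b4g$dW, b4 = b4g$db,
       W5 = dW5, b5 = db5, W6 = dW6, b6 = db6)
}

dataset_xy <- function(data) {
  if (inherits(data, "roi_dataset"))
    return(list(x = data$patches, y = data$manifest$label,
                id = data$manifest$patient_id))
  list(x = data$x, y = data$y, id = data$id %||% seq_len(dim(data$x)[1]))
}

#' Train the hybrid-ROI CNN
#'
#' Mini-batch SGD with momentum on binary cross-entropy. After every
#' epoch the ROI-level AUC on the validation patches is recorded and the
#' parameters of the best epoch are retained (`epochs = 0` returns the
#' seeded initialisation unchanged).
#'
#' @param model a [build_cnn()] model.
#' @param train,val training and validation data: `roi_dataset`s or
#'   lists with elements `x` (n x 32 x 32 array) and `y` (0/1).
#' @param epochs optional override of `config$epochs`.
#' @return The trained `roi_cnn` with a `history` data frame
#'   (epoch, train_loss, val_auc).
#' @export
train_cnn <- function(model, train, val, epochs = NULL) {
  stopifnot(inherits(model, "roi_cnn"))
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  tr <- dataset_xy(train); va <- dataset_xy(val)
  if (length(unique(tr$y)) < 2L)
    stop_bcsurv("training patches contain a single class",
                "bcsurv_training_error")
  if (epochs == 0L) {
    model$history <- data.frame(epoch = integer(), train_loss = numeric(),
                                val_auc = numeric())
    return(model)
  }
  n <- dim(tr$x)[1]
  set.seed(derive_seed(cfg$seed, 7919L))
  vel <- lapply(model$params, function(p) p * 0)
  best <- list(auc = -Inf, params = model$params)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- tr$x[idx, , , drop = FALSE]; yb <- tr$y[idx]
      cache <- cnn_forward(model, xb, keep_cache = TRUE)
      eps <- 1e-12
      losses <- c(losses, -mean(yb * log(cache$prob + eps) +
                                  (1 - yb) * log(1 - cache$prob + eps)))
      grads <- cnn_backward(model, cache, yb)
      for (nm in names(model$params)) {
        vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$learning_rate * grads[[nm]]
        model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
      }
    }
    val_scores <- cnn_forward(model, va$x)$prob
    v_auc <- if (length(unique(va$y)) > 1L) auc_mw(val_scores, va$y) else NA
    hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                             val_auc = v_auc)
    # ties resolved to the latest epoch: equal ranking, lower loss
    if (!is.na(v_auc) && v_auc >= best$auc)
      best <- list(auc = v_auc, params = model$params)
  }
  if (is.finite(best$auc)) model$params <- best$params
  model$trained <- TRUE
  model$history <- do.call(rbind, hist)
  model
}

#' Predict per-ROI survival likelihoods
#'
#' @param object a `roi_cnn`.
#' @param patches n x 32 x 32 array (or a `roi_dataset`).
#' @param ... unused.
#' @return Numeric vector of likelihoods in `[0, 1]`.
#' @export
predict.roi_cnn <- function(object, patches, ...) {
  if (inherits(patches, "roi_dataset")) patches <- patches$patches
  if (length(dim(patches)) == 2L)
    patches <- array(patches, c(1L, dim(patches)))
  n <- dim(patches)[1]
  if (n == 0L) return(numeric())
  # chunk to bound memory on large datasets
  out <- numeric(n)
  for (start in seq(1L, n, by = 256L)) {
    idx <- start:min(start + 255L, n)
    out[idx] <- cnn_forward(object, patches[idx, , , drop = FALSE])$prob
  }
  out
}

#' @export
print.roi_cnn <- function(x, ...) {
  g <- x$geometry
  cat("hybrid-ROI CNN (", if (x$trained) "trained" else "untrained", ")\n",
      "  C1 ", x$config$conv_channels[1], "@", x$config$conv_kernel, "x",
      x$config$conv_kernel, " -> LRN -> pool -> ", g$p1, "x", g$p1, "\n",
      "  C2 ", x$config$conv_channels[2], " -> LRN -> pool -> ", g$p2, "x",
      g$p2, "\n  L3/L4 locally connected 3x3 -> ", g$l4, "x", g$l4, "x",
      x$config$lc_channels[2], "\n  FC", x$config$fc_units,
      " -> sigmoid likelihood\n", sep = "")
  if (!is.null(x$history) && nrow(x$history))
    cat("  best val AUC ", round(max(x$history$val_auc, na.rm = TRUE), 3),
        " over ", nrow(x$history), " epochs\n", sep = "")
  invisible(x)
}

#' Aggregate per-ROI likelihoods into one case likelihood
#'
#' @param model a trained `roi_cnn`.
#' @param patches n x 32 x 32 array of one patient's hybrid ROIs.
#' @param aggregation `"mean"` (default), `"median"` or `"max"`.
#' @param patient_id optional id carried into the result.
#' @return An object of class `case_score`: list with `patient_id`,
#'   `roi_scores` and `case_likelihood`.
#' @export
score_case <- function(model, patches, aggregation = c("mean", "median",
                                                       "max"),
                       patient_id = NA_character_) {
  aggregation <- match.arg(aggregation)
  if (is.null(patches) ||
      (is.array(patches) && length(dim(patches)) == 3L &&
       dim(patches)[1] == 0L))
    stop_bcsurv("no patches to score", "bcsurv_scoring_error")
  scores <- predict.roi_cnn(model, patches)
  if (!length(scores))
    stop_bcsurv("no patches to score", "bcsurv_scoring_error")
  lik <- switch(aggregation, mean = mean(scores),
                median = stats::median(scores), max = max(scores))
  structure(list(patient_id = patient_id, roi_scores = scores,
                 case_likelihood = lik, aggregation = aggregation),
            class = "case_score")
}

#' Per-patient deep likelihoods for a whole ROI dataset
#'
#' @param model a trained `roi_cnn`.
#' @param dataset a `roi_dataset`.
#' @param aggregation passed to [score_case()].
#' @return Data frame `patient_id`, `dl_likelihood`.
#' @export
score_cases <- function(model, dataset, aggregation = "mean") {
  ids <- unique(dataset$manifest$patient_id)
  lik <- vapply(ids, function(id) {
    keep <- dataset$manifest$patient_id == id
    score_case(model, dataset$patches[keep, , , drop = FALSE],
               aggregation, id)$case_likelihood
  }, 0)
  data.frame(patient_id = ids, dl_likelihood = unname(lik),
             stringsAsFactors = FALSE)
}
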