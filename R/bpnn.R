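# Descriptor fusion: a single-hidden-layer back-propagation network (13
# sigmoid nodes by default) combining clinical nomogram points, selected
# radiomics features, and the deep likelihood into one survival score.

#' Assemble per-patient descriptor sets for a model combination
#'
#' Builds the fusion-network input for one of the six descriptor
#' combinations: C (5 clinical point values), R (selected radiomics),
#' D (deep likelihood), and their combinations CR, CD, CRD. Column
#' order is deterministic (C block, then R, then D); input
#' standardisation happens inside [train_bpnn()] using training-split
#' statistics only.
#'
#' @param combination one of `"C"`, `"R"`, `"D"`, `"CR"`, `"CD"`,
#'   `"CRD"`.
#' @param records list of [clinical_record()]s (labels).
#' @param clinical data frame from [evaluate_nomogram_cohort()]
#'   (required for combinations containing C).
#' @param radiomics feature data frame from
#'   [extract_cohort_features()] (for R).
#' @param selected_names radiomics columns to use (for R).
#' @param deep data frame from [score_cases()] (for D).
#' @return Data frame of class `descriptor_set` with `patient_id`,
#'   `label`, and one column per descriptor; attribute `combination`.
#' @export
assemble_descriptors <- function(combination, records, clinical = NULL,
                                 radiomics = NULL, selected_names = NULL,
                                 deep = NULL) {
  combination <- match.arg(combination, c("C", "R", "D", "CR", "CD", "CRD"))
  ids <- vapply(records, `[[`, "", "patient_id")
  labels <- vapply(records, `[[`, 0L, "label_5yr")
  out <- data.frame(patient_id = ids, label = labels,
                    stringsAsFactors = FALSE)
  need <- strsplit(combination, "")[[1]]
  take_block <- function(df, cols, what) {
    if (is.null(df))
      stop_bcsurv(paste0("combination ", combination, " requires the ",
                         what, " block"), "bcsurv_assembly_error")
    miss <- setdiff(ids, df$patient_id)
    if (length(miss))
      stop_bcsurv(paste0(what, " block is missing patient(s): ",
                         paste(miss, collapse = ", ")),
                  "bcsurv_assembly_error")
    df[match(ids, df$patient_id), cols, drop = FALSE]
  }
  if ("C" %in% need) {
    cols <- paste0("pts_", clinical_levels()$indices)
    out <- cbind(out, take_block(clinical, cols, "clinical"))
  }
  if ("R" %in% need) {
    if (is.null(selected_names) || !length(selected_names))
      stop_bcsurv("combination with R requires selected_names",
                  "bcsurv_assembly_error")
    out <- cbind(out, take_block(radiomics, selected_names, "radiomics"))
  }
  if ("D" %in% need)
    out <- cbind(out, take_block(deep, "dl_likelihood", "deep"))
  attr(out, "combination") <- combination
  class(out) <- c("descriptor_set", "data.frame")
  out
}

#' BPNN configuration
#'
#' @param hidden_nodes hidden-layer size (default 13).
#' @param learning_rate full-batch gradient-descent learning rate.
#' @param momentum momentum coefficient.
#' @param max_iterations training iterations cap.
#' @param seed integer seed for weight initialisation.
#' @return An object of class `bpnn_config`.
#' @export
bpnn_config <- function(hidden_nodes = 13L, learning_rate = 0.5,
                        momentum = 0.9, max_iterations = 200L, seed = 1L) {
  if (hidden_nodes < 1L)
    stop_bcsurv("hidden_nodes must be >= 1", "bcsurv_config_error")
  structure(list(hidden_nodes = as.integer(hidden_nodes),
                 learning_rate = learning_rate, momentum = momentum,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "bpnn_config")
}

descriptor_xy <- function(d) {
  cols <- setdiff(names(d), c("patient_id", "label"))
  list(x = as.matrix(as.data.frame(d, check.names = FALSE)[, cols,
                                                           drop = FALSE]),
       y = d$label, cols = cols)
}

#' Train the fusion BPNN
#'
#' Single-hidden-layer network (sigmoid activations, sigmoid scalar
#' output) trained by full-batch gradient back-propagation with
#' momentum on binary cross-entropy. Inputs are standardised with
#' training-split statistics; constant columns are dropped with a
#' warning. After every iteration the validation AUC is recorded and
#' the best-AUC parameters are retained; `max_iterations = 0` returns
#' the seeded initialisation.
#'
#' @param train,val `descriptor_set` data frames.
#' @param config a [bpnn_config()].
#' @return An object of class `bpnn` with elements `weights`,
#'   `scaling`, `columns`, `combination`, `history`.
#' @export
train_bpnn <- function(train, val, config = bpnn_config()) {
  tr <- descriptor_xy(train); va <- descriptor_xy(val)
  if (length(unique(tr$y)) < 2L)
    stop_bcsurv("training labels contain a single class",
                "bcsurv_training_error")
  mu <- colMeans(tr$x); sdv <- apply(tr$x, 2, stats::sd)
  keep <- sdv > 0
  if (any(!keep)) {
    warning("dropping constant descriptor column(s): ",
            paste(tr$cols[!keep], collapse = ", "))
  }
  if (!any(keep))
    stop_bcsurv("all descriptor columns are constant",
                "bcsurv_training_error")
  cols <- tr$cols[keep]
  scale_x <- function(x) sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]),
                               2, sdv[keep], "/")
  xt <- scale_x(tr$x); xv <- scale_x(va$x)
  n_in <- ncol(xt); nh <- config$hidden_nodes; n <- nrow(xt)
  set.seed(config$seed)
  W1 <- matrix(stats::rnorm(n_in * nh, sd = 1 / sqrt(n_in)), n_in, nh)
  b1 <- numeric(nh)
  W2 <- matrix(stats::rnorm(nh, sd = 1 / sqrt(nh)), nh, 1)
  b2 <- 0
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- 0
  fwd <- function(x, W1, b1, W2, b2) {
    h <- stats::plogis(x %*% W1 + matrix(b1, nrow(x), nh, byrow = TRUE))
    list(h = h, p = drop(stats::plogis(h %*% W2 + b2)))
  }
  best <- list(auc = -Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  hist <- vector("list", config$max_iterations)
  for (it in seq_len(config$max_iterations)) {
    f <- fwd(xt, W1, b1, W2, b2)
    dz <- matrix((f$p - tr$y) / n, n, 1)
    gW2 <- crossprod(f$h, dz); gb2 <- sum(dz)
    dh <- (dz %*% t(W2)) * f$h * (1 - f$h)
    gW1 <- crossprod(xt, dh); gb1 <- colSums(dh)
    vW1 <- config$momentum * vW1 - config$learning_rate * gW1
    vb1 <- config$momentum * vb1 - config$learning_rate * gb1
    vW2 <- config$momentum * vW2 - config$learning_rate * gW2
    vb2 <- config$momentum * vb2 - config$learning_rate * gb2
    W1 <- W1 + vW1; b1 <- b1 + vb1; W2 <- W2 + vW2; b2 <- b2 + vb2
    pv <- fwd(xv, W1, b1, W2, b2)$p
    v_auc <- if (length(unique(va$y)) > 1L) auc_mw(pv, va$y) else NA
    eps <- 1e-12
    hist[[it]] <- data.frame(
      iteration = it,
      train_loss = -mean(tr$y * log(f$p + eps) +
                           (1 - tr$y) * log(1 - f$p + eps)),
      val_auc = v_auc)
    # ties resolved to the latest iterate: equal ranking, lower loss
    if (!is.na(v_auc) && v_auc >= best$auc)
      best <- list(auc = v_auc, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  if (!is.finite(best$auc))
    best <- list(auc = NA_real_, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  structure(list(weights = best[c("W1", "b1", "W2", "b2")],
                 scaling = list(mu = mu[keep], sd = sdv[keep]),
                 columns = cols,
                 combination = attr(train, "combination") %||% NA_character_,
                 config = config,
                 history = do.call(rbind, hist)),
            class = "bpnn")
}

#' Predict survival scores from a trained BPNN
#'
#' @param object a `bpnn`.
#' @param newdata `descriptor_set` (or data frame) with the training
#'   column layout.
#' @param ... unused.
#' @return Numeric scores in `[0, 1]`, one per patient.
#' @export
predict.bpnn <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata, check.names = FALSE)
  miss <- setdiff(object$columns, names(nd))
  if (length(miss))
    stop_bcsurv(paste0("descriptor layout mismatch; missing column(s): ",
                       paste(miss, collapse = ", ")),
                "bcsurv_contract_error")
  x <- as.matrix(nd[, object$columns, drop = FALSE])
  x <- sweep(sweep(x, 2, object$scaling$mu), 2, object$scaling$sd, "/")
  w <- object$weights
  h <- stats::plogis(x %*% w$W1 +
                       matrix(w$b1, nrow(x), length(w$b1), byrow = TRUE))
  unname(drop(stats::plogis(h %*% w$W2 + w$b2)))
}

#' @rdname predict.bpnn
#' @param model a `bpnn`.
#' @param descriptors new `descriptor_set`.
#' @export
predict_bpnn <- function(model, descriptors) {
  predict.bpnn(model, descriptors)
}

#' @export
print.bpnn <- function(x, ...) {
  cat("fusion BPNN (", x$combination, "): ", length(x$columns),
      " inputs -> ", x$config$hidden_nodes, " hidden -> 1\n", sep = "")
  if (!is.null(x$history) && nrow(x$history))
    cat("  best val AUC ", round(max(x$history$val_auc, na.rm = TRUE), 3),
        " over ", nrow(x$history), " iterations\n", sep = "")
  invisible(x)
}

#' @export
coef.bpnn <- function(object, ...) {
  object$weights
}
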