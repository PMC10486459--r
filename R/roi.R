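# Hybrid ROIs: 32x16 sliding windows from the central lesion slice of the
# pre- and post-treatment scans, concatenated side by side into 32x32
# patches that encode treatment change for the CNN.

ROI_H <- 32L
ROI_W <- 16L

#' Configuration of hybrid-ROI dataset construction
#'
#' @param stride sliding-window stride in pixels (>= 1).
#' @param max_hybrids_per_case cap on hybrids kept per case (>= 1);
#'   prevents large lesions from dominating the training set.
#' @param intensity_window `(lower, upper)` HU window mapped linearly to
#'   `[0, 1]` (values clamped).
#' @param pairing `"cross_product"` (every pre window with every post
#'   window) or `"random_pairs"` (seeded random matching).
#' @param seed integer seed for capping/pairing subsampling.
#' @return An object of class `roi_config`.
#' @export
roi_config <- function(stride = 4L, max_hybrids_per_case = 64L,
                       intensity_window = c(0, 150),
                       pairing = c("cross_product", "random_pairs"),
                       seed = 1L) {
  pairing <- match.arg(pairing)
  if (stride < 1L) stop_bcsurv("stride must be >= 1", "bcsurv_config_error")
  if (max_hybrids_per_case < 1L)
    stop_bcsurv("max_hybrids_per_case must be >= 1", "bcsurv_config_error")
  if (diff(intensity_window) <= 0)
    stop_bcsurv("intensity window must have upper > lower",
                "bcsurv_config_error")
  structure(list(stride = as.integer(stride),
                 max_hybrids_per_case = as.integer(max_hybrids_per_case),
                 intensity_window = as.numeric(intensity_window),
                 pairing = pairing, seed = as.integer(seed)),
            class = "roi_config")
}

# offsets of fully-contained windows along one axis (0-based)
window_offsets <- function(extent, win, stride) {
  if (extent < win) return(NULL)
  seq.int(0L, extent - win, by = stride)
}

#' Extract 32x16 sub-ROIs from the VOI of one scan
#'
#' Windows tile the central-slice VOI at the given stride in
#' deterministic row-major order (row offsets outer, column offsets
#' inner). A VOI smaller than the window in either direction yields a
#' single centred zero-padded window, flagged with attribute
#' `padded = TRUE`.
#'
#' @param volume 3D array `(z, y, x)`.
#' @param voi_bbox 2x3 0-based half-open box (rows lo/hi, cols z,y,x).
#' @param slice_index 1-based z index of the slice to window.
#' @param stride window stride in pixels.
#' @return List of 32x16 matrices, each with attribute `offset`
#'   (0-based `(row, col)` origin within the slice).
#' @export
extract_subrois <- function(volume, voi_bbox, slice_index, stride = 4L) {
  sl <- volume[slice_index, , ]
  y0 <- voi_bbox[1, 2] + 1L; y1 <- voi_bbox[2, 2]
  x0 <- voi_bbox[1, 3] + 1L; x1 <- voi_bbox[2, 3]
  reg <- sl[y0:y1, x0:x1, drop = FALSE]
  h <- nrow(reg); w <- ncol(reg)
  if (h < ROI_H || w < ROI_W) {
    # centred symmetric zero padding up to the window size
    out <- matrix(0, max(h, ROI_H), max(w, ROI_W))
    r0 <- (nrow(out) - h) %/% 2L; c0 <- (ncol(out) - w) %/% 2L
    out[r0 + seq_len(h), c0 + seq_len(w)] <- reg
    reg <- out
    h <- nrow(reg); w <- ncol(reg)
    ro <- (h - ROI_H) %/% 2L  # single centred window
    co <- (w - ROI_W) %/% 2L
    win <- reg[ro + seq_len(ROI_H), co + seq_len(ROI_W), drop = FALSE]
    attr(win, "offset") <- c(ro + y0 - 1L, co + x0 - 1L)
    attr(win, "padded") <- TRUE
    return(list(win))
  }
  ros <- window_offsets(h, ROI_H, stride)
  cos <- window_offsets(w, ROI_W, stride)
  out <- vector("list", length(ros) * length(cos))
  k <- 1L
  for (r in ros) for (cc in cos) {
    win <- reg[r + seq_len(ROI_H), cc + seq_len(ROI_W), drop = FALSE]
    attr(win, "offset") <- c(r + y0 - 1L, cc + x0 - 1L)
    attr(win, "padded") <- FALSE
    out[[k]] <- win
    k <- k + 1L
  }
  out
}

normalize_window <- function(m, window) {
  out <- (m - window[1]) / (window[2] - window[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Compose a 32x32 hybrid ROI from one pre and one post window
#'
#' Both 32x16 halves are intensity-normalised to `[0, 1]` by the
#' configured window and concatenated horizontally: pre-treatment on the
#' left (columns 1-16), post-treatment on the right (columns 17-32).
#'
#' @param pre_roi,post_roi 32x16 numeric matrices.
#' @param intensity_window `(lower, upper)` normalisation window.
#' @return A 32x32 matrix with attributes `offset_pre` and `offset_post`.
#' @export
compose_hybrid <- function(pre_roi, post_roi, intensity_window = c(0, 150)) {
  if (!all(dim(pre_roi) == c(ROI_H, ROI_W)) ||
      !all(dim(post_roi) == c(ROI_H, ROI_W)))
    stop_bcsurv("hybrid halves must be 32x16", "bcsurv_contract_error")
  patch <- cbind(normalize_window(pre_roi, intensity_window),
                 normalize_window(post_roi, intensity_window))
  attr(patch, "offset_pre") <- attr(pre_roi, "offset")
  attr(patch, "offset_post") <- attr(post_roi, "offset")
  patch
}

#' Build the labelled hybrid-ROI dataset of a cohort
#'
#' For each case, windows are extracted from the central lesion slice of
#' the pre and post scans, paired according to the pairing rule, capped
#' at `max_hybrids_per_case` by seeded uniform subsampling, and labelled
#' with the case's five-year survival label. Cases whose VOI yields no
#' window are skipped with a warning.
#'
#' @param pairs list of [volume_pair()]s.
#' @param masks list of [lesion_mask()]s.
#' @param records list of [clinical_record()]s (labels).
#' @param config a [roi_config()].
#' @return An object of class `roi_dataset`: list with `patches` (3D
#'   array `n x 32 x 32`), and a `manifest` data frame (`patient_id`,
#'   `label`, pre/post offsets, `padded`).
#' @export
build_roi_dataset <- function(pairs, masks, records, config = roi_config()) {
  labels <- stats::setNames(vapply(records, `[[`, 0L, "label_5yr"),
                            vapply(records, `[[`, "", "patient_id"))
  phases <- vapply(masks, `[[`, "", "phase")
  mids <- vapply(masks, `[[`, "", "patient_id")
  all_patches <- list(); man <- list()
  for (p in pairs) {
    id <- p$patient_id
    if (!id %in% names(labels)) next
    wins <- list()
    for (ph in c("pre", "post")) {
      k <- which(mids == id & phases == ph)
      if (!length(k)) { wins <- NULL; break }
      m <- masks[[k[1]]]
      z <- select_central_slice(m)
      vol <- if (ph == "pre") p$pre_volume else p$post_volume
      wins[[ph]] <- extract_subrois(vol, m$voi_bbox, z, config$stride)
    }
    if (is.null(wins) || !length(wins$pre) || !length(wins$post)) {
      warning("case ", id, " yielded no windows; skipped")
      next
    }
    combos <- expand.grid(i = seq_along(wins$pre), j = seq_along(wins$post))
    set.seed(derive_seed(config$seed, string_seed(id)))
    if (config$pairing == "random_pairs") {
      n <- min(length(wins$pre), length(wins$post))
      combos <- data.frame(i = sample(seq_along(wins$pre), n),
                           j = sample(seq_along(wins$post), n))
    }
    if (nrow(combos) > config$max_hybrids_per_case)
      combos <- combos[sort(sample.int(nrow(combos),
                                       config$max_hybrids_per_case)), ,
                       drop = FALSE]
    for (r in seq_len(nrow(combos))) {
      pre_w <- wins$pre[[combos$i[r]]]; post_w <- wins$post[[combos$j[r]]]
      patch <- compose_hybrid(pre_w, post_w, config$intensity_window)
      all_patches[[length(all_patches) + 1L]] <- patch
      man[[length(man) + 1L]] <- data.frame(
        patient_id = id, label = labels[[id]],
        pre_row = attr(pre_w, "offset")[1], pre_col = attr(pre_w, "offset")[2],
        post_row = attr(post_w, "offset")[1],
        post_col = attr(post_w, "offset")[2],
        padded = isTRUE(attr(pre_w, "padded")) ||
          isTRUE(attr(post_w, "padded")),
        stringsAsFactors = FALSE)
    }
  }
  n <- length(all_patches)
  arr <- array(0, dim = c(n, ROI_H, 2L * ROI_W))
  for (i in seq_len(n)) arr[i, , ] <- all_patches[[i]]
  structure(list(patches = arr, manifest = do.call(rbind, man)),
            class = "roi_dataset")
}

#' @export
print.roi_dataset <- function(x, ...) {
  m <- x$manifest
  cat("hybrid-ROI dataset: ", nrow(m), " patches from ",
      length(unique(m$patient_id)), " cases (",
      sum(m$label[!duplicated(m$patient_id)] == 1), " alive cases)\n",
      sep = "")
  invisible(x)
}

# subset a roi_dataset to the given patient ids
subset_roi_dataset <- function(ds, ids) {
  keep <- ds$manifest$patient_id %in% ids
  structure(list(patches = ds$patches[keep, , , drop = FALSE],
                 manifest = ds$manifest[keep, , drop = FALSE]),
            class = "roi_dataset")
}
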