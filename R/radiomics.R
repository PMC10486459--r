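# The 91-name 2D radiomics catalog and per-case feature assembly.
#
# The catalog spans three families: morphology (21 contour/moment
# features), intensity (22 first-order statistics of in-mask HU values),
# and texture (28 direction-merged co-occurrence statistics at distances
# 1 and 2, 11 run-length statistics, 9 Sobel-gradient statistics). Names
# and order are frozen: extraction always returns the same 91 names.

catalog_names <- function() {
  glcm <- c("contrast", "dissimilarity", "homogeneity", "energy", "entropy",
            "correlation", "autocorrelation", "cluster_shade",
            "cluster_prominence", "max_probability", "sum_average",
            "sum_entropy", "difference_entropy", "inverse_variance")
  c(names(shape_features(matrix(c(0, 1, 1, 1, 1, 1, 0, 1, 1), 3, 3),
                         c(1, 1))),
    names(intensity_features(c(1, 2, 3, 4))),
    paste0("glcm_d1_", glcm), paste0("glcm_d2_", glcm),
    paste0("glrlm_", c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                       "srlge", "srhge", "lrlge", "lrhge")),
    names(gradient_features(matrix(seq_len(16), 4, 4),
                            matrix(1L, 4, 4))))
}

.catalog <- new.env(parent = emptyenv())

#' The frozen 91-feature radiomics catalog
#'
#' @return A data frame with columns `name` and `family`
#'   (`morphology`, `intensity`, `texture_glcm`, `texture_glrlm`,
#'   `texture_gradient`), 91 rows, in extraction order.
#' @export
feature_catalog <- function() {
  if (is.null(.catalog$df)) {
    nm <- catalog_names()
    fam <- rep("texture_glcm", length(nm))
    fam[startsWith(nm, "morph_")] <- "morphology"
    fam[startsWith(nm, "int_")] <- "intensity"
    fam[startsWith(nm, "glrlm_")] <- "texture_glrlm"
    fam[startsWith(nm, "grad_")] <- "texture_gradient"
    .catalog$df <- data.frame(name = nm, family = fam,
                              stringsAsFactors = FALSE)
  }
  .catalog$df
}

#' Write the feature catalog as JSON
#'
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_catalog <- function(path) {
  cat_df <- feature_catalog()
  jsonlite::write_json(list(n_features = nrow(cat_df),
                            quantization_levels = N_GRAY,
                            features = cat_df),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Central slice of a lesion mask
#'
#' The representative slice used for 2D feature extraction: the z-index
#' with the largest in-mask area, ties resolved to the lower index.
#'
#' @param mask a [lesion_mask()].
#' @return Integer z-index (1-based).
#' @export
select_central_slice <- function(mask) {
  m <- if (inherits(mask, "lesion_mask")) mask$mask else mask
  if (length(dim(m)) != 3L)
    stop_bcsurv("mask must be a 3D array", "bcsurv_extraction_error")
  areas <- apply(m != 0, 1, sum)
  if (all(areas == 0))
    stop_bcsurv("empty mask: no central slice", "bcsurv_extraction_error")
  which.max(areas)  # which.max returns the first (lowest) maximal index
}

#' Extract the 91 base radiomics features from one masked slice
#'
#' @param image_slice 2D numeric array (rows = y, cols = x).
#' @param mask_slice 2D binary array of the same shape.
#' @param spacing numeric `(dy, dx)` pixel spacing in mm.
#' @return Named numeric vector of length 91 in catalog order.
#' @export
extract_base_features <- function(image_slice, mask_slice,
                                  spacing = c(1, 1)) {
  if (!all(dim(image_slice) == dim(mask_slice)))
    stop_bcsurv("image and mask slices differ in shape",
                "bcsurv_extraction_error")
  if (any(!is.finite(image_slice)))
    stop_bcsurv("image slice contains non-finite values",
                "bcsurv_extraction_error")
  n_pix <- sum(mask_slice != 0)
  if (n_pix < 4L)
    stop_bcsurv("mask has fewer than 4 pixels; texture undefined",
                "bcsurv_extraction_error")
  v <- image_slice[mask_slice != 0]
  q <- quantize_slice(image_slice, mask_slice)
  g1 <- glcm_stats(q, 1L); g2 <- glcm_stats(q, 2L)
  rl <- glrlm_stats(q, n_pix)
  out <- c(shape_features(mask_slice, spacing),
           intensity_features(v),
           stats::setNames(g1, paste0("glcm_d1_", names(g1))),
           stats::setNames(g2, paste0("glcm_d2_", names(g2))),
           stats::setNames(rl, paste0("glrlm_", names(rl))),
           gradient_features(image_slice, mask_slice))
  out[feature_catalog()$name]
}

#' Relative pre-to-post difference features
#'
#' For every base feature f, the difference feature is
#' `(f_pre - f_post) / f_pre`. A zero pre-treatment value makes the
#' ratio undefined; the result is flagged missing (`NA`) rather than
#' infinite, and downstream selection excludes such features.
#'
#' @param f_pre,f_post named numeric vectors over the same names.
#' @return Named numeric vector with names prefixed by nothing; values
#'   `NA` where `f_pre` is zero.
#' @export
compute_difference_features <- function(f_pre, f_post) {
  if (!identical(names(f_pre), names(f_post)))
    stop_bcsurv("pre and post feature name sets differ",
                "bcsurv_contract_error")
  out <- ifelse(abs(f_pre) > 0, (f_pre - f_post) / f_pre, NA_real_)
  names(out) <- names(f_pre)
  out
}

#' Assemble the 273-value feature vector of one case
#'
#' Selects the central slice of the pre and post lesion masks, extracts
#' the 91 base features from each, computes the 91 relative difference
#' features, and returns them concatenated with namespaced names
#' `pre.*`, `post.*`, `diff.*` in frozen catalog order.
#'
#' @param pair a [volume_pair()].
#' @param masks list of [lesion_mask()]s containing the `pre` and `post`
#'   masks of this patient.
#' @return Named numeric vector of length 273.
#' @export
assemble_case_features <- function(pair, masks) {
  phases <- vapply(masks, `[[`, "", "phase")
  ids <- vapply(masks, `[[`, "", "patient_id")
  keep <- ids == pair$patient_id
  get_phase <- function(ph) {
    k <- which(keep & phases == ph)
    if (!length(k))
      stop_bcsurv(paste0("missing ", ph, " mask for patient ",
                         pair$patient_id), "bcsurv_extraction_error")
    masks[[k[1]]]
  }
  one <- function(vol, mask, spacing) {
    z <- select_central_slice(mask)
    extract_base_features(vol[z, , ], mask$mask[z, , ], spacing[2:3])
  }
  f_pre <- one(pair$pre_volume, get_phase("pre"), pair$voxel_spacing_pre)
  f_post <- one(pair$post_volume, get_phase("post"), pair$voxel_spacing_post)
  f_diff <- compute_difference_features(f_pre, f_post)
  c(stats::setNames(f_pre, paste0("pre.", names(f_pre))),
    stats::setNames(f_post, paste0("post.", names(f_post))),
    stats::setNames(f_diff, paste0("diff.", names(f_diff))))
}

#' Extract features for a whole cohort
#'
#' @param pairs list of [volume_pair()]s.
#' @param masks list of [lesion_mask()]s.
#' @return Data frame with `patient_id` plus 273 feature columns.
#' @export
extract_cohort_features <- function(pairs, masks) {
  rows <- lapply(pairs, function(p) assemble_case_features(p, masks))
  out <- as.data.frame(do.call(rbind, rows))
  data.frame(patient_id = vapply(pairs, `[[`, "", "patient_id"), out,
             check.names = FALSE, stringsAsFactors = FALSE)
}
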