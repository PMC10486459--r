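# Levels of the five clinical indices used throughout the package.
# Pathologic stage and node stage are ordinal; the remaining three binary.

#' Category levels of the clinical indices
#'
#' @return Named list with the ordered level sets of `path_stage` and
#'   `node_stage` and the names of the five nomogram indices.
#' @export
clinical_levels <- function() {
  list(
    path_stage = c("pT0", "pTa/pTi/pTis", "pT1", "pT2", "pT3", "pT4"),
    node_stage = c("N0", "N1", "N2", "N3"),
    indices = c("path_stage", "lvi", "node_stage",
                "neoadjuvant_chemo", "adjuvant_radiotherapy")
  )
}

#' Paired pre-/post-treatment image volumes
#'
#' Holds the two CT urography volumes that bracket neoadjuvant
#' chemotherapy for one patient. Arrays use `(z, y, x)` axis order;
#' voxel spacing is `(dz, dy, dx)` in millimetres.
#'
#' @param patient_id character identifier.
#' @param pre_volume,post_volume 3D numeric arrays (intensities, e.g. HU).
#' @param voxel_spacing_pre,voxel_spacing_post numeric length-3 `(dz, dy, dx)`
#'   spacings in mm, all positive.
#' @param exam_date_pre,exam_date_post `Date`s; pre must not be after post.
#' @param contrast_phase one of `"early"`, `"delayed"`, `"non_contrast"`,
#'   `"unknown"`.
#' @return An object of class `volume_pair`.
#' @export
volume_pair <- function(patient_id, pre_volume, post_volume,
                        voxel_spacing_pre, voxel_spacing_post,
                        exam_date_pre, exam_date_post,
                        contrast_phase = "unknown") {
  if (length(dim(pre_volume)) != 3L || length(dim(post_volume)) != 3L)
    stop_bcsurv("pre_volume and post_volume must be rank-3 arrays",
                "bcsurv_type_error")
  if (any(voxel_spacing_pre <= 0) || any(voxel_spacing_post <= 0))
    stop_bcsurv("voxel spacings must be positive", "bcsurv_type_error")
  exam_date_pre <- as.Date(exam_date_pre)
  exam_date_post <- as.Date(exam_date_post)
  if (exam_date_pre > exam_date_post)
    stop_bcsurv("exam_date_pre must be on or before exam_date_post",
                "bcsurv_type_error")
  contrast_phase <- match.arg(contrast_phase,
                              c("early", "delayed", "non_contrast", "unknown"))
  structure(list(patient_id = as.character(patient_id),
                 pre_volume = pre_volume, post_volume = post_volume,
                 voxel_spacing_pre = as.numeric(voxel_spacing_pre),
                 voxel_spacing_post = as.numeric(voxel_spacing_post),
                 exam_date_pre = exam_date_pre,
                 exam_date_post = exam_date_post,
                 contrast_phase = contrast_phase),
            class = "volume_pair")
}

#' Binary lesion mask aligned to one phase of a volume pair
#'
#' @param patient_id character identifier.
#' @param phase `"pre"` or `"post"`.
#' @param mask binary (0/1 or logical) 3D array with the volume's shape.
#' @param voi_bbox optional 2x3 integer matrix, rows `lo` and `hi`
#'   (0-based, half-open, axis order z,y,x). Defaults to the tight
#'   bounding box of the nonzero voxels.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(patient_id, phase, mask, voi_bbox = NULL) {
  phase <- match.arg(phase, c("pre", "post"))
  if (length(dim(mask)) != 3L)
    stop_bcsurv("mask must be a rank-3 array", "bcsurv_type_error")
  mask <- array(as.integer(mask != 0), dim = dim(mask))
  if (sum(mask) == 0L)
    stop_bcsurv("mask has no nonzero voxels", "bcsurv_type_error")
  if (is.null(voi_bbox)) voi_bbox <- mask_bbox(mask)
  voi_bbox <- matrix(as.integer(voi_bbox), nrow = 2L,
                     dimnames = list(c("lo", "hi"), c("z", "y", "x")))
  idx <- which(mask != 0, arr.ind = TRUE) - 1L  # 0-based
  inside <- idx[, 1] >= voi_bbox[1, 1] & idx[, 1] < voi_bbox[2, 1] &
    idx[, 2] >= voi_bbox[1, 2] & idx[, 2] < voi_bbox[2, 2] &
    idx[, 3] >= voi_bbox[1, 3] & idx[, 3] < voi_bbox[2, 3]
  if (!any(inside))
    stop_bcsurv("mask is zero everywhere inside voi_bbox", "bcsurv_type_error")
  structure(list(patient_id = as.character(patient_id), phase = phase,
                 mask = mask, voi_bbox = voi_bbox),
            class = "lesion_mask")
}

# tight 0-based half-open bounding box of nonzero voxels, rows lo/hi
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  rbind(lo = apply(idx, 2, min) - 1L, hi = apply(idx, 2, max))
}

#' Radiologist lesion annotation
#'
#' Captures the manual measurements recorded when a lesion volume of
#' interest is marked: the two orthogonal diameters, the location, and
#' free-form ratings of lesion type, edge character and likelihood of
#' abnormality.
#'
#' @param longest_diameter_mm,perpendicular_diameter_mm positive reals with
#'   `perpendicular <= longest`.
#' @param location `"bladder"`, `"ureter"` or `"other"`.
#' @param lesion_type,edge,likelihood free-form character ratings.
#' @return An object of class `lesion_annotation`.
#' @export
lesion_annotation <- function(longest_diameter_mm, perpendicular_diameter_mm,
                              location = c("bladder", "ureter", "other"),
                              lesion_type = NA_character_, edge = NA_character_,
                              likelihood = NA_character_) {
  location <- match.arg(location)
  if (longest_diameter_mm <= 0 || perpendicular_diameter_mm <= 0)
    stop_bcsurv("diameters must be positive", "bcsurv_type_error")
  if (perpendicular_diameter_mm > longest_diameter_mm)
    stop_bcsurv("perpendicular diameter exceeds longest diameter",
                "bcsurv_type_error")
  structure(list(longest_diameter_mm = longest_diameter_mm,
                 perpendicular_diameter_mm = perpendicular_diameter_mm,
                 location = location, lesion_type = lesion_type,
                 edge = edge, likelihood = likelihood),
            class = "lesion_annotation")
}

#' One patient's clinical record
#'
#' The five nomogram indices plus survival follow-up. `label_5yr` is the
#' binary five-year survival label (1 = survived beyond 60 months). When
#' not supplied it is derived as `survival_months >= 60`; patients
#' censored before 60 months then receive label 0, a documented choice
#' (see the methods vignette).
#'
#' @param patient_id character identifier.
#' @param path_stage one of the six ordinal pathologic stages.
#' @param lvi,neoadjuvant_chemo,adjuvant_radiotherapy logicals.
#' @param node_stage one of `N0..N3`.
#' @param survival_months non-negative follow-up in months.
#' @param event logical, `TRUE` if death was observed.
#' @param label_5yr optional 0/1; validated against follow-up if given.
#' @param exam_date `Date` of the pre-treatment exam (drives the serial
#'   split).
#' @return An object of class `clinical_record`.
#' @export
clinical_record <- function(patient_id, path_stage, lvi, node_stage,
                            neoadjuvant_chemo, adjuvant_radiotherapy,
                            survival_months, event, label_5yr = NULL,
                            exam_date) {
  lv <- clinical_levels()
  path_stage <- match.arg(path_stage, lv$path_stage)
  node_stage <- match.arg(node_stage, lv$node_stage)
  if (survival_months < 0)
    stop_bcsurv("survival_months must be non-negative", "bcsurv_type_error")
  derived <- as.integer(survival_months >= 60)
  if (is.null(label_5yr) || is.na(label_5yr)) {
    label_5yr <- derived
  } else {
    label_5yr <- as.integer(label_5yr)
    if (label_5yr == 1L && survival_months < 60)
      stop_bcsurv("label_5yr = 1 requires follow-up reaching 60 months",
                  "bcsurv_type_error")
    if (label_5yr == 0L && survival_months >= 60 && !event)
      stop_bcsurv("label_5yr = 0 conflicts with censoring after 60 months",
                  "bcsurv_type_error")
  }
  structure(list(patient_id = as.character(patient_id),
                 path_stage = path_stage, lvi = as.logical(lvi),
                 node_stage = node_stage,
                 neoadjuvant_chemo = as.logical(neoadjuvant_chemo),
                 adjuvant_radiotherapy = as.logical(adjuvant_radiotherapy),
                 survival_months = as.numeric(survival_months),
                 event = as.logical(event), label_5yr = label_5yr,
                 exam_date = as.Date(exam_date)),
            class = "clinical_record")
}

#' Convert a list of clinical records to a data frame
#'
#' @param records list of [clinical_record()] objects.
#' @return A data frame with one row per patient.
#' @export
records_to_df <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(patient_id = r$patient_id, path_stage = r$path_stage,
               lvi = r$lvi, node_stage = r$node_stage,
               neoadjuvant_chemo = r$neoadjuvant_chemo,
               adjuvant_radiotherapy = r$adjuvant_radiotherapy,
               survival_months = r$survival_months, event = r$event,
               label_5yr = r$label_5yr,
               exam_date = as.character(r$exam_date),
               stringsAsFactors = FALSE)
  }))
}

required_clinical_columns <- function() {
  c("patient_id", "path_stage", "lvi", "node_stage", "neoadjuvant_chemo",
    "adjuvant_radiotherapy", "survival_months", "event", "exam_date")
}

df_to_records <- function(df) {
  miss <- setdiff(required_clinical_columns(), names(df))
  if (length(miss))
    stop_bcsurv(paste0("clinical table is missing required column(s): ",
                       paste(miss, collapse = ", ")), "bcsurv_schema_error")
  lapply(seq_len(nrow(df)), function(i) {
    clinical_record(
      patient_id = df$patient_id[i], path_stage = df$path_stage[i],
      lvi = as.logical(df$lvi[i]), node_stage = df$node_stage[i],
      neoadjuvant_chemo = as.logical(df$neoadjuvant_chemo[i]),
      adjuvant_radiotherapy = as.logical(df$adjuvant_radiotherapy[i]),
      survival_months = df$survival_months[i], event = as.logical(df$event[i]),
      label_5yr = if ("label_5yr" %in% names(df)) df$label_5yr[i] else NULL,
      exam_date = as.Date(df$exam_date[i]))
  })
}

# ---- NIfTI helpers -------------------------------------------------------
# In-memory arrays are (z, y, x); NIfTI files store (x, y, z) with pixdim
# (dx, dy, dz), so volumes are transposed on the way in and out.

write_volume_nifti <- function(vol, spacing_zyx, path) {
  disk <- aperm(vol, c(3, 2, 1))
  img <- RNifti::asNifti(disk)
  RNifti::pixdim(img) <- rev(spacing_zyx)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- rev(RNifti::pixdim(img)[1:3])
  list(volume = aperm(as.array(img), c(3, 2, 1)), spacing = spacing)
}

#' Write a cohort to the on-disk layout consumed by [load_cohort()]
#'
#' Volumes and masks are written as NIfTI files named
#' `<id>_pre.nii.gz`, `<id>_post.nii.gz`, `<id>_pre_mask.nii.gz`,
#' `<id>_post_mask.nii.gz`; the clinical table as `clinical.csv`.
#'
#' @param dir output directory (created if needed).
#' @param pairs list of [volume_pair()]s.
#' @param masks list of [lesion_mask()]s.
#' @param records list of [clinical_record()]s.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dir, pairs, masks, records) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in pairs) {
    write_volume_nifti(p$pre_volume, p$voxel_spacing_pre,
                       file.path(dir, paste0(p$patient_id, "_pre.nii.gz")))
    write_volume_nifti(p$post_volume, p$voxel_spacing_post,
                       file.path(dir, paste0(p$patient_id, "_post.nii.gz")))
  }
  for (m in masks) {
    write_volume_nifti(m$mask, c(1, 1, 1),
                       file.path(dir, paste0(m$patient_id, "_", m$phase,
                                             "_mask.nii.gz")))
  }
  df <- records_to_df(records)
  meta <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(patient_id = p$patient_id,
               exam_date_pre = as.character(p$exam_date_pre),
               exam_date_post = as.character(p$exam_date_post),
               contrast_phase = p$contrast_phase, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(meta, file.path(dir, "exams.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a cohort from disk
#'
#' Reads the layout written by [write_cohort()] (or by
#' [generate_cohort()] via `write_cohort()`): paired pre/post NIfTI
#' volumes, their binary lesion masks, and the clinical CSV table.
#' Masks are matched to volumes by patient id and phase; mask/volume
#' shape mismatches raise an alignment error, and patients present in
#' only one of the table or the image directory are reported.
#'
#' @param volume_dir directory holding the NIfTI files and `exams.csv`.
#' @param clinical_table path to the clinical CSV.
#' @return A list with elements `pairs`, `masks`, `records` and
#'   `unmatched` (character vector of patient ids lacking images or a
#'   clinical row).
#' @export
load_cohort <- function(volume_dir, clinical_table) {
  if (!dir.exists(volume_dir))
    stop_bcsurv(paste0("volume directory not found: ", volume_dir),
                "bcsurv_io_error")
  if (!file.exists(clinical_table))
    stop_bcsurv(paste0("clinical table not found: ", clinical_table),
                "bcsurv_io_error")
  df <- utils::read.csv(clinical_table, stringsAsFactors = FALSE)
  records <- df_to_records(df)
  meta_path <- file.path(volume_dir, "exams.csv")
  meta <- if (file.exists(meta_path))
    utils::read.csv(meta_path, stringsAsFactors = FALSE) else NULL
  ids <- vapply(records, `[[`, "", "patient_id")
  pairs <- list(); masks <- list(); unmatched <- character()
  for (i in seq_along(ids)) {
    id <- ids[i]
    paths <- file.path(volume_dir, paste0(id, c("_pre.nii.gz",
                                                "_post.nii.gz",
                                                "_pre_mask.nii.gz",
                                                "_post_mask.nii.gz")))
    if (!all(file.exists(paths))) {
      unmatched <- c(unmatched, id)
      next
    }
    pre <- read_volume_nifti(paths[1]); post <- read_volume_nifti(paths[2])
    mrow <- if (!is.null(meta)) meta[meta$patient_id == id, , drop = FALSE]
            else NULL
    d_pre <- if (!is.null(mrow) && nrow(mrow)) mrow$exam_date_pre[1]
             else records[[i]]$exam_date
    d_post <- if (!is.null(mrow) && nrow(mrow)) mrow$exam_date_post[1]
              else records[[i]]$exam_date
    phase <- if (!is.null(mrow) && nrow(mrow)) mrow$contrast_phase[1]
             else "unknown"
    pairs[[id]] <- volume_pair(id, pre$volume, post$volume,
                               pre$spacing, post$spacing, d_pre, d_post, phase)
    for (ph in c("pre", "post")) {
      mk <- read_volume_nifti(file.path(volume_dir,
                                        paste0(id, "_", ph, "_mask.nii.gz")))
      vol <- if (ph == "pre") pre$volume else post$volume
      if (!identical(dim(mk$volume), dim(vol)))
        stop_bcsurv(paste0("mask/volume shape mismatch for patient ", id,
                           " phase ", ph, ": mask ",
                           paste(dim(mk$volume), collapse = "x"),
                           " vs volume ", paste(dim(vol), collapse = "x")),
                    "bcsurv_alignment_error")
      masks[[paste0(id, "_", ph)]] <- lesion_mask(id, ph, mk$volume)
    }
  }
  extra <- setdiff(sub("_pre\\.nii\\.gz$", "",
                       list.files(volume_dir, pattern = "_pre\\.nii\\.gz$")),
                   ids)
  unmatched <- union(unmatched, extra)
  list(pairs = unname(pairs), masks = unname(masks), records = records,
       unmatched = unmatched)
}

#' Chronological (serial) assignment of patients to splits
#'
#' Emulates prospective deployment: patients are ordered by exam date
#' (ties broken by patient id), the earliest block forms the training
#' set, the next block the validation set, and the latest block the test
#' set. Train and validation block sizes are the ceilings of
#' `n * fraction`; the remainder goes to the test set, which reproduces
#' a 92/7/64 split of 163 patients at fractions (0.56, 0.04, 0.40).
#'
#' @param records list of [clinical_record()]s.
#' @param fractions numeric length 3 `(train, validation, test)` summing
#'   to 1.
#' @return A data frame of class `split_assignment` with columns
#'   `patient_id` and `split` (factor train/validation/test).
#' @export
serial_split <- function(records, fractions = c(0.56, 0.04, 0.40)) {
  if (length(records) < 3L)
    stop_bcsurv("need at least 3 records to split", "bcsurv_split_error")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_bcsurv("fractions must sum to 1", "bcsurv_split_error")
  ids <- vapply(records, `[[`, "", "patient_id")
  dates <- as.Date(vapply(records, function(r) as.character(r$exam_date), ""))
  ord <- order(dates, ids)
  n <- length(records)
  n_train <- min(n - 1L, as.integer(ceiling(n * fractions[1])))
  n_val <- min(n - n_train, as.integer(ceiling(n * fractions[2])))
  split <- rep("test", n)
  split[seq_len(n_train)] <- "train"
  if (n_val > 0) split[n_train + seq_len(n_val)] <- "validation"
  out <- data.frame(patient_id = ids[ord],
                    split = factor(split,
                                   levels = c("train", "validation", "test")),
                    stringsAsFactors = FALSE)
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Read/write a split assignment as a two-column CSV
#'
#' @param split a `split_assignment` data frame.
#' @param path CSV path.
#' @return `read_split` returns the `split_assignment`; `write_split`
#'   returns `path` invisibly.
#' @export
write_split <- function(split, path) {
  utils::write.csv(as.data.frame(split), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$split <- factor(df$split, levels = c("train", "validation", "test"))
  class(df) <- c("split_assignment", "data.frame")
  df
}

split_ids <- function(split, which) {
  split$patient_id[split$split == which]
}
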