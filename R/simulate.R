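# Synthetic cohort generator: ellipsoidal lesions with correlated texture
# noise in paired pre/post volumes, clinical indices drawn with
# outcome-dependent log-odds, and survival times consistent with the
# latent five-year outcome. The planted effects are the dials that the
# property tests and the null-calibration checks turn.

#' Configuration of the synthetic cohort generator
#'
#' @param n_patients number of patients (>= 4).
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the config.
#' @param volume_shape integer `(z, y, x)` voxel counts.
#' @param voxel_spacing_mm numeric `(dz, dy, dx)` in mm.
#' @param lesion_radius_range_mm range the mean pre-treatment lesion
#'   radius is drawn from.
#' @param shrinkage_effect difference (survivors minus non-survivors) in
#'   mean fractional pre-to-post lesion volume reduction, in `[0, 1]`.
#' @param texture_effect relative increase of in-lesion texture noise
#'   scale for non-survivors (>= 0).
#' @param clinical_effect log-odds shift of favourable pathologic stage,
#'   node stage and LVI status applied `+effect` to survivors and
#'   `-effect` to non-survivors (>= 0).
#' @param censor_rate probability that a five-year survivor is
#'   administratively censored after the 60-month mark, in `[0, 1]`.
#' @param background_hu,lesion_contrast_hu,base_noise_hu intensity model:
#'   flat background, additive lesion contrast, and the base scale of the
#'   correlated in-lesion noise (all in HU).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 163, seed = 1L,
                       volume_shape = c(28, 72, 72),
                       voxel_spacing_mm = c(2.5, 0.9, 0.9),
                       lesion_radius_range_mm = c(7, 14),
                       shrinkage_effect = 0.3, texture_effect = 0.5,
                       clinical_effect = 0.75, censor_rate = 0.15,
                       background_hu = 20, lesion_contrast_hu = 50,
                       base_noise_hu = 10) {
  if (n_patients < 4) stop_bcsurv("n_patients must be >= 4",
                                  "bcsurv_config_error")
  if (shrinkage_effect < 0 || shrinkage_effect > 1)
    stop_bcsurv("shrinkage_effect must lie in [0, 1]", "bcsurv_config_error")
  if (texture_effect < 0 || clinical_effect < 0)
    stop_bcsurv("texture_effect and clinical_effect must be >= 0",
                "bcsurv_config_error")
  if (censor_rate < 0 || censor_rate > 1)
    stop_bcsurv("censor_rate must lie in [0, 1]", "bcsurv_config_error")
  if (length(volume_shape) != 3L || any(volume_shape < 4))
    stop_bcsurv("volume_shape must be three counts >= 4",
                "bcsurv_config_error")
  if (diff(lesion_radius_range_mm) < 0 || lesion_radius_range_mm[1] <= 0)
    stop_bcsurv("invalid lesion_radius_range_mm", "bcsurv_config_error")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 volume_shape = as.integer(volume_shape),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 lesion_radius_range_mm = as.numeric(lesion_radius_range_mm),
                 shrinkage_effect = shrinkage_effect,
                 texture_effect = texture_effect,
                 clinical_effect = clinical_effect,
                 censor_rate = censor_rate,
                 background_hu = background_hu,
                 lesion_contrast_hu = lesion_contrast_hu,
                 base_noise_hu = base_noise_hu),
            class = "sim_config")
}

# replicate-edge shift of a 3D array along one axis
shift_axis3 <- function(a, axis, k) {
  d <- dim(a)[axis]
  idx <- pmin(pmax(seq_len(d) + k, 1L), d)
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# separable smoothing with a fixed 5-tap Gaussian kernel; gives the noise
# field a short spatial correlation length (texture rather than speckle)
smooth3 <- function(a) {
  w <- stats::dnorm(-2:2, sd = 1.1); w <- w / sum(w)
  for (axis in 1:3) {
    out <- a * w[3]
    for (k in c(-2L, -1L, 1L, 2L))
      out <- out + w[k + 3] * shift_axis3(a, axis, k)
    a <- out
  }
  a
}

#' Render one ellipsoidal lesion into a volume
#'
#' Produces a flat-background volume containing a single ellipsoidal
#' lesion with additive contrast and, inside the lesion only, spatially
#' correlated Gaussian noise rescaled to `noise_scale`.
#'
#' @param shape integer `(z, y, x)` voxel counts.
#' @param center numeric `(z, y, x)` lesion centre in voxel coordinates
#'   (1-based).
#' @param radii_mm numeric `(rz, ry, rx)` semi-axes in mm.
#' @param spacing numeric `(dz, dy, dx)` in mm.
#' @param background,contrast intensities (HU): volume is `background`
#'   outside the lesion and `background + contrast` inside, plus noise.
#' @param noise_scale standard deviation of the correlated in-lesion
#'   noise; 0 gives a noiseless lesion.
#' @return List with `volume` (3D array) and `mask` (binary 3D array).
#' @export
render_lesion <- function(shape, center, radii_mm, spacing,
                          background = 20, contrast = 50, noise_scale = 0) {
  shape <- as.integer(shape)
  radii_vox <- radii_mm / spacing
  if (any(radii_vox < 0.5))
    stop_bcsurv("lesion radii below voxel size would give an empty mask",
                "bcsurv_config_error")
  if (any(center - radii_vox < 1) || any(center + radii_vox > shape))
    stop_bcsurv("ellipsoid does not fit inside the volume",
                "bcsurv_config_error")
  z <- (seq_len(shape[1]) - center[1]) / radii_vox[1]
  y <- (seq_len(shape[2]) - center[2]) / radii_vox[2]
  x <- (seq_len(shape[3]) - center[3]) / radii_vox[3]
  d2 <- outer(outer(z^2, y^2, `+`), x^2, `+`)
  mask <- array(as.integer(d2 <= 1), dim = shape)
  if (sum(mask) == 0L)
    stop_bcsurv("degenerate ellipsoid produced an empty mask",
                "bcsurv_config_error")
  vol <- array(background, dim = shape) + contrast * mask
  if (noise_scale > 0) {
    noise <- smooth3(array(stats::rnorm(prod(shape)), dim = shape))
    s <- stats::sd(noise[mask == 1])
    if (is.finite(s) && s > 0)
      vol <- vol + mask * noise * (noise_scale / s)
  }
  list(volume = vol, mask = mask)
}

# proportional-odds shift toward lower (favourable) categories
shift_ordinal <- function(base_probs, shift) {
  cb <- stats::qlogis(cumsum(base_probs)[-length(base_probs)])
  cs <- stats::plogis(cb + shift)
  diff(c(0, cs, 1))
}

# baseline category frequencies mirroring a real post-cystectomy cohort
clinical_baseline <- function() {
  list(path_stage = c(35, 15, 16, 36, 45, 16) / 163,
       node_stage = c(112, 24, 23, 4) / 163,
       lvi = 61 / 163)
}

#' Generate a fully synthetic cohort with planted survival signal
#'
#' Each patient receives a latent five-year outcome (alive/deceased with
#' equal probability), clinical indices drawn with outcome-dependent
#' log-odds, a pre-treatment ellipsoidal lesion, and a post-treatment
#' lesion whose volume is reduced by an outcome-dependent shrinkage
#' fraction; in-lesion texture noise is stronger for non-survivors when
#' `texture_effect > 0`. Survival times are drawn consistently with the
#' latent outcome and survivors may be administratively censored after
#' the 60-month mark. Exam dates increase with patient index so the
#' serial splitter sees a chronological cohort.
#'
#' @param config a [sim_config()].
#' @return A list with `pairs`, `masks`, `records` and `truth` (a data
#'   frame of the latent per-patient parameters).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  bl <- clinical_baseline()
  shape <- config$volume_shape
  spacing <- config$voxel_spacing_mm
  ids <- sprintf("P%04d", seq_len(n))
  pairs <- vector("list", n); masks <- vector("list", 2L * n)
  records <- vector("list", n)
  truth <- vector("list", n)
  date0 <- as.Date("2006-03-01")
  date_step <- (14 * 365) / max(1, n - 1)   # cohort spans ~14 years
  lv <- clinical_levels()
  for (i in seq_len(n)) {
    alive <- stats::rbinom(1, 1, 0.5)
    s <- if (alive == 1) config$clinical_effect else -config$clinical_effect
    stage <- sample(lv$path_stage, 1, prob = shift_ordinal(bl$path_stage, s))
    node <- sample(lv$node_stage, 1, prob = shift_ordinal(bl$node_stage, s))
    lvi <- stats::runif(1) < stats::plogis(stats::qlogis(bl$lvi) - s)
    # survival time consistent with the latent outcome
    if (alive == 1) {
      t_death <- 60 + stats::rexp(1, rate = 1 / 36)
      censored <- stats::runif(1) < config$censor_rate
      t_cens <- if (censored) stats::runif(1, 61, 130) else Inf
      surv <- min(t_death, t_cens)
      event <- t_death <= t_cens
    } else {
      surv <- 2 + 56 * stats::rbeta(1, 2, 2)
      event <- TRUE
    }
    # lesion geometry: pre radii, outcome-dependent shrinkage for post
    r_mean <- stats::runif(1, config$lesion_radius_range_mm[1],
                           config$lesion_radius_range_mm[2])
    radii_pre <- pmax(2.5, r_mean * stats::runif(3, 0.85, 1.2))
    mu <- min(0.92, 0.2 + if (alive == 1) config$shrinkage_effect else 0)
    shrink <- stats::rbeta(1, mu * 12, (1 - mu) * 12)
    radii_post <- pmax(2.2, radii_pre * (1 - shrink)^(1 / 3))
    noise_scale <- config$base_noise_hu *
      (1 + if (alive == 1) 0 else config$texture_effect)
    center <- shape / 2 + stats::runif(3, -1.5, 1.5)
    # keep the jittered ellipsoid inside the volume (pre radii dominate)
    rv <- radii_pre / spacing
    if (any(shape < 2 * rv + 2.1))
      stop_bcsurv("lesion radii too large for the volume shape",
                  "bcsurv_config_error")
    center <- pmin(pmax(center, 1.05 + rv), shape - 0.05 - rv)
    pre <- render_lesion(shape, center, radii_pre, spacing,
                         config$background_hu, config$lesion_contrast_hu,
                         noise_scale)
    post <- render_lesion(shape, center, radii_post, spacing,
                          config$background_hu, config$lesion_contrast_hu,
                          noise_scale)
    d_pre <- date0 + round((i - 1) * date_step)
    d_post <- d_pre + 90
    pairs[[i]] <- volume_pair(ids[i], pre$volume, post$volume, spacing,
                              spacing, d_pre, d_post, "early")
    masks[[2 * i - 1]] <- lesion_mask(ids[i], "pre", pre$mask)
    masks[[2 * i]] <- lesion_mask(ids[i], "post", post$mask)
    records[[i]] <- clinical_record(
      patient_id = ids[i], path_stage = stage, lvi = lvi, node_stage = node,
      neoadjuvant_chemo = TRUE, adjuvant_radiotherapy = FALSE,
      survival_months = surv, event = event, label_5yr = alive,
      exam_date = d_pre)
    truth[[i]] <- data.frame(patient_id = ids[i], latent_alive = alive,
                             shrinkage = shrink, noise_scale = noise_scale,
                             r_pre_mm = r_mean, stringsAsFactors = FALSE)
  }
  list(pairs = pairs, masks = masks, records = records,
       truth = do.call(rbind, truth))
}

#' Write a generated cohort plus its truth table to disk
#'
#' Writes the NIfTI/CSV layout consumed by [load_cohort()] together with
#' `truth.csv` recording the latent per-patient parameters.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return The cohort list, invisibly.
#' @export
simulate_to_dir <- function(config, dir) {
  cohort <- generate_cohort(config)
  write_cohort(dir, cohort$pairs, cohort$masks, cohort$records)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(cohort)
}
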