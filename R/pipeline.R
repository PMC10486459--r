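# End-to-end orchestration: simulate/load -> serial split -> nomogram ->
# radiomics -> MI selection -> hybrid ROIs -> CNN -> BPNN fusion ->
# evaluation. Stages communicate through on-disk artifacts with
# documented schemas; a manifest records seeds and file hashes so a
# rerun with the same config reproduces the outputs byte for byte.

#' Pipeline configuration
#'
#' @param out_dir run directory for all stage outputs.
#' @param sim a [sim_config()] to generate a synthetic cohort, or `NULL`
#'   to load an existing one.
#' @param volume_dir,clinical_table input cohort location when `sim` is
#'   `NULL`.
#' @param fractions serial-split fractions `(train, validation, test)`.
#' @param selection list with `threshold` (`NULL` for rank cut) and
#'   `k_target`.
#' @param roi a [roi_config()].
#' @param cnn a [cnn_config()].
#' @param bpnn a [bpnn_config()].
#' @param nomogram_path path to a nomogram spec JSON.
#' @param combinations descriptor combinations to fit (subset of C, R,
#'   D, CR, CD, CRD).
#' @param km_combinations combinations stratified by Kaplan-Meier.
#' @param aggregation per-patient aggregation of ROI likelihoods.
#' @param stages optional explicit stage list (subset of `"nomogram"`,
#'   `"radiomics"`, `"cnn"`); by default the stages required by
#'   `combinations` run. A combination whose descriptor stage is absent
#'   from an explicit list is rejected before execution.
#' @param seed master seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            volume_dir = NULL, clinical_table = NULL,
                            fractions = c(0.56, 0.04, 0.40),
                            selection = list(threshold = NULL,
                                             k_target = 12L),
                            roi = roi_config(),
                            cnn = cnn_config(),
                            bpnn = bpnn_config(),
                            nomogram_path = default_nomogram_path(),
                            combinations = c("C", "R", "D", "CRD"),
                            km_combinations = intersect(combinations,
                                                        c("C", "CRD")),
                            aggregation = "mean",
                            stages = NULL,
                            seed = 1L) {
  combinations <- match.arg(combinations,
                            c("C", "R", "D", "CR", "CD", "CRD"),
                            several.ok = TRUE)
  if (is.null(sim) && (is.null(volume_dir) || is.null(clinical_table)))
    stop_bcsurv("either sim or volume_dir + clinical_table must be given",
                "bcsurv_config_error")
  if (!is.null(stages)) {
    req <- c(C = "nomogram", R = "radiomics", D = "cnn")
    for (combo in combinations) {
      blocks <- strsplit(combo, "")[[1]]
      miss <- setdiff(req[blocks], stages)
      if (length(miss))
        stop_bcsurv(paste0("combination ", combo, " requires stage(s) ",
                           paste(miss, collapse = ", "),
                           " absent from the configured stages"),
                    "bcsurv_config_error")
    }
  }
  structure(list(out_dir = out_dir, sim = sim, volume_dir = volume_dir,
                 clinical_table = clinical_table, fractions = fractions,
                 selection = selection, roi = roi, cnn = cnn, bpnn = bpnn,
                 nomogram_path = nomogram_path,
                 combinations = combinations,
                 km_combinations = km_combinations,
                 aggregation = aggregation, stages = stages,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields override the defaults of [pipeline_config()]; the
#' nested `sim`, `roi`, `cnn` and `bpnn` maps override the defaults of
#' the corresponding config constructors.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(ctor, args) do.call(ctor, as.list(args %||% list()))
  pipeline_config(
    out_dir = raw$out_dir %||% stop_bcsurv("config needs out_dir",
                                           "bcsurv_config_error"),
    sim = if (isFALSE(raw$simulate)) NULL else build(sim_config, raw$sim),
    volume_dir = raw$volume_dir, clinical_table = raw$clinical_table,
    fractions = unlist(raw$fractions %||% c(0.56, 0.04, 0.40)),
    selection = raw$selection %||% list(threshold = NULL, k_target = 12L),
    roi = build(roi_config, raw$roi),
    cnn = build(cnn_config, raw$cnn),
    bpnn = build(bpnn_config, raw$bpnn),
    nomogram_path = raw$nomogram_path %||% default_nomogram_path(),
    combinations = raw$combinations %||% c("C", "R", "D", "CRD"),
    km_combinations = raw$km_combinations %||%
      intersect(raw$combinations %||% c("C", "CRD"), c("C", "CRD")),
    aggregation = raw$aggregation %||% "mean",
    seed = raw$seed %||% 1L)
}

needs_block <- function(combinations, block) {
  any(grepl(block, combinations, fixed = TRUE))
}

#' Run the full survival-prediction pipeline
#'
#' Executes every stage needed by the requested descriptor
#' combinations, writes all stage outputs plus a manifest to
#' `config$out_dir`, and returns the collected results. Model scores
#' are fitted on the training split, selected on the validation split,
#' and evaluated on the chronologically later test split; AUC
#' comparisons against CRD use the Bonferroni-adjusted significance
#' level; Kaplan-Meier stratification uses the least-misclassification
#' cutoff determined on the training + validation scores.
#'
#' @param config a [pipeline_config()] (or path to a YAML/JSON config).
#' @return An object of class `bcs_run`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(); files <- character()
  note <- function(stage) stages <<- c(stages, stage)
  emit <- function(path) files <<- c(files, path)

  # -- cohort --------------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- config$sim; sim$seed <- derive_seed(config$seed, 1L)
    cohort <- generate_cohort(sim)
    utils::write.csv(cohort$truth, file.path(config$out_dir, "truth.csv"),
                     row.names = FALSE)
    emit(file.path(config$out_dir, "truth.csv"))
  } else {
    cohort <- load_cohort(config$volume_dir, config$clinical_table)
  }
  records <- cohort$records
  note("cohort")

  # -- serial split --------------------------------------------------------
  split <- serial_split(records, config$fractions)
  write_split(split, file.path(config$out_dir, "split.csv"))
  emit(file.path(config$out_dir, "split.csv"))
  note("split")
  ids_train <- split_ids(split, "train")
  ids_val <- split_ids(split, "validation")
  ids_test <- split_ids(split, "test")
  rec_ids <- vapply(records, `[[`, "", "patient_id")
  labels <- stats::setNames(vapply(records, `[[`, 0L, "label_5yr"), rec_ids)

  # -- clinical nomogram descriptors ---------------------------------------
  clinical <- NULL
  if (needs_block(config$combinations, "C")) {
    spec <- load_nomogram_spec(config$nomogram_path)
    clinical <- evaluate_nomogram_cohort(records, spec)
    utils::write.csv(clinical, file.path(config$out_dir, "nomogram.csv"),
                     row.names = FALSE)
    emit(file.path(config$out_dir, "nomogram.csv"))
    note("nomogram")
  }

  # -- radiomics + MI selection --------------------------------------------
  radiomics <- NULL; sel <- NULL
  if (needs_block(config$combinations, "R")) {
    radiomics <- extract_cohort_features(cohort$pairs, cohort$masks)
    utils::write.csv(radiomics, file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
    emit(file.path(config$out_dir, "features.csv"))
    note("radiomics")
    tr_rows <- radiomics[radiomics$patient_id %in% ids_train, , drop = FALSE]
    sel <- select_by_mi(tr_rows, labels[tr_rows$patient_id],
                        threshold = config$selection$threshold,
                        k_target = config$selection$k_target %||% 12L)
    write_selection_report(sel, file.path(config$out_dir, "selection.json"))
    emit(file.path(config$out_dir, "selection.json"))
    if (length(sel$selected_names) >= 2L) {
      cm <- pearson_matrix(tr_rows[, sel$selected_names, drop = FALSE])
      utils::write.csv(as.data.frame(unclass(cm)),
                       file.path(config$out_dir, "correlation.csv"))
      emit(file.path(config$out_dir, "correlation.csv"))
    }
    note("selection")
  }

  # -- hybrid ROIs + CNN ---------------------------------------------------
  deep <- NULL; cnn_model <- NULL
  if (needs_block(config$combinations, "D")) {
    roi_cfg <- config$roi; roi_cfg$seed <- derive_seed(config$seed, 11L)
    ds <- build_roi_dataset(cohort$pairs, cohort$masks, records, roi_cfg)
    utils::write.csv(ds$manifest,
                     file.path(config$out_dir, "roi_manifest.csv"),
                     row.names = FALSE)
    emit(file.path(config$out_dir, "roi_manifest.csv"))
    note("rois")
    cnn_cfg <- config$cnn; cnn_cfg$seed <- derive_seed(config$seed, 13L)
    cnn_model <- build_cnn(cnn_cfg)
    ds_train <- subset_roi_dataset(ds, ids_train)
    ds_val <- subset_roi_dataset(ds, ids_val)
    cnn_model <- train_cnn(cnn_model, ds_train, ds_val)
    utils::write.csv(cnn_model$history,
                     file.path(config$out_dir, "cnn_history.csv"),
                     row.names = FALSE)
    emit(file.path(config$out_dir, "cnn_history.csv"))
    deep <- score_cases(cnn_model, ds, config$aggregation)
    utils::write.csv(deep, file.path(config$out_dir, "deep_scores.csv"),
                     row.names = FALSE)
    emit(file.path(config$out_dir, "deep_scores.csv"))
    note("cnn")
  }

  # -- fusion + evaluation -------------------------------------------------
  rec_by_split <- function(ids) records[rec_ids %in% ids]
  preds <- list(); rocs <- list(); models <- list()
  for (ci in seq_along(config$combinations)) {
    combo <- config$combinations[ci]
    dsets <- lapply(list(train = ids_train, val = ids_val,
                         test = ids_test, all = rec_ids), function(ids)
      assemble_descriptors(combo, rec_by_split(ids), clinical = clinical,
                           radiomics = radiomics,
                           selected_names = sel$selected_names,
                           deep = deep))
    bp_cfg <- config$bpnn
    bp_cfg$seed <- derive_seed(config$seed, 17L + ci)
    fit <- train_bpnn(dsets$train, dsets$val, bp_cfg)
    models[[combo]] <- fit
    sc <- predict(fit, dsets$all)
    preds[[combo]] <- data.frame(patient_id = dsets$all$patient_id,
                                 combination = combo, score = sc,
                                 label = dsets$all$label,
                                 split = as.character(
                                   split$split[match(dsets$all$patient_id,
                                                     split$patient_id)]),
                                 stringsAsFactors = FALSE)
    test_rows <- preds[[combo]]$split == "test"
    rocs[[combo]] <- roc_auc(preds[[combo]]$score[test_rows],
                             preds[[combo]]$label[test_rows])
  }
  pred_df <- do.call(rbind, preds)
  utils::write.csv(pred_df, file.path(config$out_dir, "predictions.csv"),
                   row.names = FALSE)
  emit(file.path(config$out_dir, "predictions.csv"))
  note("fusion")

  auc_tab <- do.call(rbind, lapply(names(rocs), function(cb)
    data.frame(combination = cb, auc = rocs[[cb]]$auc, se = rocs[[cb]]$se,
               stringsAsFactors = FALSE)))
  comparisons <- list()
  if ("CRD" %in% names(rocs)) {
    others <- intersect(c("C", "R", "D"), names(rocs))
    alpha <- bonferroni_adjust(0.05, max(1L, length(others)))
    test_crd <- preds[["CRD"]][preds[["CRD"]]$split == "test", ]
    for (cb in others) {
      test_cb <- preds[[cb]][preds[[cb]]$split == "test", ]
      comparisons[[paste(cb, "vs CRD")]] <-
        compare_aucs(test_cb$score, test_crd$score, test_cb$label,
                     paste(cb, "vs CRD"), alpha)
    }
  }
  km <- list()
  surv_m <- stats::setNames(vapply(records, `[[`, 0, "survival_months"),
                            rec_ids)
  events <- stats::setNames(vapply(records, function(r)
    as.integer(r$event), 0L), rec_ids)
  for (cb in intersect(config$km_combinations, names(preds))) {
    p <- preds[[cb]]
    dev_rows <- p$split %in% c("train", "validation")
    cut <- cutoff_least_misclassification(p$score[dev_rows],
                                          p$label[dev_rows])
    tst <- p[p$split == "test", ]
    grp <- ifelse(tst$score > cut, "predicted alive", "predicted deceased")
    km[[cb]] <- if (length(unique(grp)) == 2L)
      km_logrank(surv_m[tst$patient_id], events[tst$patient_id], grp,
                 cutoff = cut)
    else structure(list(curves = list(), chisq = NA_real_,
                        p_value = NA_real_, degenerate = TRUE,
                        cutoff = cut), class = "km_result")
  }
  report <- list(
    auc = auc_tab,
    comparisons = lapply(comparisons, function(x)
      x[c("label_pair", "auc_a", "auc_b", "delta_auc", "p_value",
          "adjusted_alpha", "significant")]),
    km = lapply(km, function(x)
      list(chisq = x$chisq, p_value = x$p_value, cutoff = x$cutoff,
           degenerate = x$degenerate)))
  jsonlite::write_json(report, file.path(config$out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit(file.path(config$out_dir, "evaluation.json"))
  note("evaluation")

  manifest <- list(stages = stages, seed = config$seed,
                   combinations = config$combinations,
                   n_patients = length(records),
                   files = lapply(stats::setNames(files, basename(files)),
                                  function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  note("manifest")

  structure(list(config = config, split = split, auc = auc_tab,
                 rocs = rocs, comparisons = comparisons, km = km,
                 predictions = pred_df, models = models,
                 selection = sel, deep = deep, clinical = clinical,
                 manifest = manifest),
            class = "bcs_run")
}

#' @export
print.bcs_run <- function(x, ...) {
  cat("survival-prediction run (", x$manifest$n_patients, " patients, ",
      "seed ", x$config$seed, ")\n", sep = "")
  cat("stages: ", paste(x$manifest$stages, collapse = " -> "), "\n",
      sep = "")
  cat("test-set AUC:\n")
  for (i in seq_len(nrow(x$auc)))
    cat(sprintf("  %-4s %.3f +/- %.3f\n", x$auc$combination[i],
                x$auc$auc[i], x$auc$se[i]))
  for (cmp in x$comparisons) print(cmp)
  for (cb in names(x$km)) {
    cat(cb, ": ", sep = "")
    print(x$km[[cb]])
  }
  invisible(x)
}

#' @export
summary.bcs_run <- function(object, ...) {
  print(object)
  if (!is.null(object$selection)) {
    cat("\nselected radiomics features:\n  ",
        paste(object$selection$selected_names, collapse = "\n  "), "\n",
        sep = "")
  }
  invisible(object)
}
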