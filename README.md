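# bcsurv — survival prediction after radical cystectomy from clinical, radiomics and deep-learning descriptors

`bcsurv` predicts five-year survival of bladder-cancer patients after
radical cystectomy by fusing three descriptor families extracted from
routinely collected data:

* **C — clinical**: the per-index point values of a points-based
  nomogram over five histopathological indices (pathologic stage `pT0…pT4`,
  lymphovascular invasion, node stage `N0–N3`, neoadjuvant chemotherapy,
  adjuvant radiotherapy). Points sum to total points, which map to the
  5-year survival probability through a monotone piecewise-linear curve.
* **R — radiomics**: 91 frozen 2D features (morphology, intensity,
  grey-level co-occurrence / run-length / gradient texture) extracted
  from the central lesion slice of the pre-treatment and post-treatment
  CT-urography scans, plus 91 relative *difference features*
  `f_diff = (f_pre − f_post) / f_pre` — 273 values per case. Relevance
  is scored by plug-in mutual information `I(F;C) = H(F) − H(F|C)`
  (equal-frequency binning, nats) and the top features (12 by default)
  are kept; redundancy is reported as a Pearson correlation matrix.
* **D — deep**: a survival likelihood from a small CNN (two conv + LRN +
  max-pool stages, two locally connected layers, a fully connected layer,
  sigmoid output) trained on 32×32 *hybrid ROIs* — patches whose left
  32×16 half is a sliding window from the pre-treatment scan and right
  half from the post-treatment scan, so each patch encodes treatment
  change. Per-ROI likelihoods are averaged per patient.

A back-propagation neural network (13 hidden nodes) fuses any block
combination (C, R, D, CR, CD, CRD) into one score. Models are trained
on the chronologically earliest patients, tuned on the next block and
evaluated on the latest block (a *serial* split emulating prospective
deployment; 163 patients at fractions 0.56/0.04/0.40 split 92/7/64).
Evaluation uses Mann–Whitney AUC with Hanley–McNeil standard errors,
DeLong-type paired AUC comparisons at the Bonferroni-adjusted level
α = 0.05/3 = 0.017, and Kaplan–Meier stratification of predicted groups
at the least-misclassification cutoff with a log-rank test.

Because the clinical CTU cohorts behind such models are private, the
package includes a fully synthetic cohort generator
(`generate_cohort()`) that plants controllable survival signal in the
clinical indices (outcome-shifted log-odds), lesion morphology
(outcome-dependent pre→post shrinkage) and lesion texture
(outcome-dependent noise scale), with survival times and administrative
censoring consistent with the five-year labels. Every stage of the
pipeline is testable offline.

## Worked example

```r
library(bcsurv)
cfg <- pipeline_config(
  out_dir = file.path(tempdir(), "demo"),
  sim = sim_config(n_patients = 60, seed = 42,
                   volume_shape = c(16, 44, 44),
                   lesion_radius_range_mm = c(5, 10)),
  roi  = roi_config(stride = 8, max_hybrids_per_case = 8),
  cnn  = cnn_config(conv_channels = c(6, 12), lc_channels = c(12, 12),
                    epochs = 4, batch_size = 64),
  bpnn = bpnn_config(max_iterations = 150),
  combinations = c("C", "R", "D", "CRD"),
  seed = 42)
run <- run_pipeline(cfg)
print(run)
```

```
survival-prediction run (60 patients, seed 42)
stages: cohort -> split -> nomogram -> radiomics -> selection -> rois -> cnn -> fusion -> evaluation
test-set AUC:
  C    0.942 +/- 0.061
  R    1.000 +/- 0.000
  D    0.475 +/- 0.128
  CRD  1.000 +/- 0.000
C vs CRD: AUC 0.942 vs 1.000, delta -0.058, p = 0.212 (alpha = 0.017)
R vs CRD: AUC 1.000 vs 1.000, delta +0.000, p = 1 (alpha = 0.017)
D vs CRD: AUC 0.475 vs 1.000, delta -0.525, p = 0.000573 (alpha = 0.017) *
C: Kaplan-Meier log-rank: chisq = 3.090 (1 df), p = 0.07877
CRD: Kaplan-Meier log-rank: chisq = 19.834 (1 df), p = 8.446e-06
```

Reading the output: each line under *test-set AUC* is the
Mann–Whitney AUC ± Hanley–McNeil SE of one descriptor combination on
the chronologically latest (test) patients. On this synthetic cohort
the planted lesion-shrinkage signal is strong, so the radiomics
difference features alone are nearly perfect and the fused CRD model
matches them; the deep model is weak at this tiny training size (a 30-patient
training split yields very few hybrid ROIs). The comparison lines are
DeLong paired tests against CRD at the Bonferroni level 0.017 (`*`
marks significance), and the last lines test whether the predicted
alive/deceased groups have separated Kaplan–Meier curves.

All stage artifacts (split, feature table, selection report, ROI
manifest, CNN history, per-patient predictions, evaluation report,
manifest with file hashes) are written under `out_dir`; rerunning the
same config reproduces them byte for byte.

Individual stages are ordinary functions if you want them à la carte:
`serial_split()`, `evaluate_nomogram()`, `extract_base_features()`,
`select_by_mi()`, `build_roi_dataset()`, `build_cnn()`/`train_cnn()`,
`train_bpnn()`, `roc_auc()`, `compare_aucs()`, `km_logrank()`. A thin
command-line wrapper lives at `inst/cli/bcsurv.R`.

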