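---
title: "Fusing clinical, radiomics and deep-learning descriptors for post-cystectomy survival prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing clinical, radiomics and deep-learning descriptors for post-cystectomy survival prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcsurv)
```

## The problem

Five-year survival after radical cystectomy for muscle-invasive bladder
cancer varies widely, and the established clinical predictors —
post-surgical pathologic stage, lymphovascular invasion (LVI), node
stage, neoadjuvant chemotherapy and adjuvant radiotherapy — are usually
summarised through a points-based nomogram. Patients who receive
neoadjuvant chemotherapy are imaged by CT urography (CTU) before and
after treatment, so the scan pair also carries treatment-response
information that the clinical indices do not. `bcsurv` implements a
hybrid predictor that fuses three descriptor families for each patient:

* **C (clinical)** — the five per-index point values of a nomogram;
* **R (radiomics)** — 2D features of the central lesion slice of the
  pre- and post-treatment scans, plus relative pre-to-post *difference
  features* `(f_pre - f_post) / f_pre`;
* **D (deep)** — a survival likelihood from a small CNN trained on
  32×32 *hybrid ROIs* whose left half is a 32×16 window from the
  pre-treatment scan and right half the corresponding window from the
  post-treatment scan.

A back-propagation neural network (BPNN) with 13 hidden nodes fuses any
subset of the blocks (C, R, D, CR, CD, CRD) into one score, which is
evaluated by ROC analysis and by Kaplan–Meier stratification of the
predicted groups. Because the clinical imaging data such a model is
built from cannot be redistributed, the package ships a synthetic
cohort generator with controllable, planted survival signal; every
stage is testable end to end without any data download.

## Cohort handling and the serial split

Patients are assigned to training, validation and test sets
*chronologically* (`serial_split()`): sorted by exam date (ties broken
by patient id), the earliest block trains the models, the next block
tunes them, and the latest block evaluates them — emulating deployment
on future patients. Block sizes are the ceilings of `n × fraction` for
train and validation, with the remainder becoming the test set; at the
default fractions (0.56, 0.04, 0.40) a 163-patient cohort splits
92/7/64. Plain rounding would give 91/7/65; the ceiling rule is the
deterministic convention this package fixes.

The binary five-year label is taken from the clinical table when
present. When absent it is derived as `survival_months >= 60`; a
patient censored before 60 months therefore receives label 0. This is
a documented package choice — such patients are genuinely ambiguous,
and a curated table should label or exclude them explicitly.

## The nomogram evaluator

A published nomogram is a graphical object: each index maps to a points
axis, total points map to a survival probability. `nomogram_spec()`
represents it as per-level point values plus a monotone non-increasing
piecewise-linear curve of (total points → probability) knots, which is
the faithful machine-readable form of a graphically printed curve.
Evaluation is a pure function: look up five point values, sum, and
linearly interpolate (clamping beyond the end knots). The bundled
`nomogram_synthetic.json` has the correct structure — the six
pathologic stages `pT0 … pT4`, LVI yes/no, `N0–N3`, chemotherapy and
radiotherapy yes/no — but *synthetic* point values; for clinical use,
supply a spec transcribed from the published source. The fusion network
consumes the five per-index point values (not the single total), so it
can reweight the indices.

## The radiomics catalog

No enumeration of the historical 91-feature set is available, so the
package defines and freezes its own 91-name catalog spanning the same
three families, and treats the count and family structure as the
reproducible contract:

* **morphology (21)** — area, perimeter, equivalent diameter,
  circularity, compactness, eccentricity, axis lengths, extent,
  solidity, convexity, convex area, Feret diameters (max/min/mean/ratio
  from a 1° caliper sweep of the convex hull), roundness, and the first
  three Hu moment invariants. Contour quantities use Moore boundary
  tracing with corrected chain-code lengths (0.948 for axial and 1.340
  for diagonal unit steps), which keeps the circularity of rasterised
  circles within 2% of 1 from radius ~10 px.
* **intensity (22)** — first-order statistics of the in-mask values:
  mean, median, sd, variance, skewness, kurtosis, min/max/range, five
  percentiles, IQR, MAD, energy, RMS, histogram entropy and uniformity,
  and the coefficient of variation.
* **texture (48)** — grey-level co-occurrence statistics (14 of them at
  distances 1 and 2, merged over the four principal directions),
  run-length statistics (11, also direction-merged), and Sobel
  gradient-magnitude statistics (9). Texture is computed on the in-mask
  intensities quantised to 32 equal-width levels over the in-mask
  range, which makes all texture features exactly invariant to global
  intensity shifts and keeps the computation deterministic.

Features are extracted from the **central slice** of the lesion,
defined as the slice of maximal in-mask area (ties to the lower index):
for an irregular lesion this is the representative slice a reader would
pick, and it is stable under small segmentation changes. Per case the
91 base features of the pre scan, the post scan, and their relative
differences are concatenated into 273 named values. A zero
pre-treatment value makes the relative difference undefined; it is
flagged missing (`NA`), never ±infinity, and feature selection excludes
such columns.

## Mutual-information feature selection

Relevance of each feature F for the binary outcome C is scored by the
plug-in mutual information I(F;C) = H(F) − H(F|C) in nats. The
estimator discretises F into k = min(10, ⌊√n⌋) *equal-frequency* bins
computed from ranks, so the score is exactly invariant under strictly
monotone transforms of the feature — a property equal-width binning
does not have — and is clamped at zero. With an explicit threshold,
all features scoring at or above it are kept; by default a rank cut
keeps the top 12 (ties broken by name), the selection cardinality used
by the reference analysis. Selection is fitted on the training split
only and applied unchanged elsewhere, preventing information leakage
into the test years. Redundancy among the selected features is reported
as a Pearson correlation matrix (constant columns flagged, correlation
defined as 0).

## Hybrid ROIs and the CNN

From the central-slice VOI of each scan, 32×16 windows are slid at a
configurable stride (default 4 px); a VOI smaller than the window
yields a single centred zero-padded window, flagged in the manifest.
Each pre-window/post-window pair is concatenated — pre left, post
right — into a 32×32 patch after both halves are normalised to [0, 1]
by a fixed intensity window (default 0–150 HU), keeping the two phases
on a comparable scale. The pre/post pairing is the cross product,
capped per case (default 64) by seeded uniform subsampling so large
lesions cannot dominate the training set; every patch inherits its
case's five-year label.

The CNN is a reconstruction of a classical small-image architecture:
two 5×5 convolution layers (16 and 32 channels), each followed by ReLU,
local response normalisation across channels (n = 5, k = 2, α = 1e-4,
β = 0.75) and 3×3/stride-2 max-pooling; two 3×3 locally connected
layers (untied weights, 32 channels); a 10-unit fully connected layer;
and a sigmoid output. Exact channel counts, the locally connected
channel widths, and the reading of "FC10" as a 10-unit dense layer
before the scalar output are documented reconstructions — all are
configurable. Training is mini-batch SGD with momentum on binary
cross-entropy, fully seeded and single-threaded; after each epoch the
ROI-level validation AUC is recorded and the parameters of the best
epoch are retained, with ties resolved to the latest epoch (equal
ranking, lower loss). The forward/backward passes are implemented as
strided-slice matrix products; the backward pass is verified against
numerical gradients in the test suite. Per-ROI likelihoods of one
patient are aggregated into the case likelihood by the mean (median
and max are available).

## Fusion and evaluation

`assemble_descriptors()` builds the per-patient input for a chosen
combination in fixed block order (C: 5 point values, R: the selected
radiomics, D: 1 likelihood — 18 columns for CRD with 12 selected
features). The BPNN is a single hidden layer of 13 sigmoid nodes with a
sigmoid output, trained by full-batch gradient back-propagation with
momentum; inputs are standardised with statistics of the training split
only, and constant columns (e.g. chemotherapy in a cohort where every
patient received it) are dropped with a warning. The iteration with the
best validation AUC is kept, again with ties to the latest iterate; the
iteration cap (default 200) brackets the ~40 iterations such fusion
networks typically need.

Evaluation uses the Mann–Whitney AUC with 0.5 tie credit, the
Hanley–McNeil standard error, and ROC points at every distinct
threshold so trapezoidal integration reproduces the AUC exactly. Paired
model comparisons use a DeLong-type covariance of the placement values
with a two-sided normal p-value (comparing a model with itself returns
p = 1 by convention); with three comparisons against CRD the
significance level is Bonferroni-adjusted to 0.05/3 = 0.017. For
Kaplan–Meier stratification, the score cutoff is the
least-misclassification threshold — the midpoint between consecutive
distinct scores minimising FP + FN on the training + validation
scores, ties to the lowest threshold — and the predicted groups'
product-limit curves are compared by the two-sample log-rank test
(via the survival package; the test suite checks it against a
hand-computed observed/expected events table). A cohort with no events
yields flat curves and a flagged degenerate result rather than an
error. The statistic choices (Hanley–McNeil SE, DeLong comparison) are
standard reconstructions and are labelled as such in reports.

## The synthetic cohort generator

`generate_cohort()` plants a controllable survival signal in all three
descriptor channels. Each patient receives a latent five-year outcome
(alive with probability 0.5, close to the 79/163 alive fraction of the
motivating cohort). Conditional on the outcome:

* **clinical** — pathologic stage and node stage are drawn from
  proportional-odds-shifted versions of realistic baseline frequencies
  (and LVI from a shifted Bernoulli), survivors shifted `+clinical_effect`
  and non-survivors `-clinical_effect` on the log-odds scale toward
  favourable categories. Chemotherapy is constantly yes and
  radiotherapy constantly no, mirroring the cohort the framework was
  designed around. The default `clinical_effect = 0.75` makes the
  generating model's exact Bayes AUC ≈ 0.82 (computable by enumerating
  the 48 index combinations), matching the performance scale a good
  clinical nomogram reaches;
* **imaging morphology** — the post-treatment lesion volume is the
  pre-treatment volume times `1 - shrinkage`, with shrinkage drawn from
  a Beta distribution whose mean is 0.2 for non-survivors and
  `0.2 + shrinkage_effect` for survivors (default effect 0.3, i.e.
  responders shrink half their lesion on average);
* **imaging texture** — spatially correlated in-lesion noise (white
  noise smoothed by a separable 5-tap Gaussian) has scale
  `base × (1 + texture_effect)` for non-survivors (default effect 0.5).

Lesions are ellipsoids with mildly anisotropic semi-axes drawn from
7–14 mm at CTU-like voxel spacing (2.5 × 0.9 × 0.9 mm), jittered in
position and clamped inside the volume. Survival times are drawn
consistently with the latent outcome — deaths before 60 months for
non-survivors, exponential residual life after 60 months for
survivors — and a fraction `censor_rate` (default 0.15) of survivors
is administratively censored uniformly between months 61 and 130, so
the Kaplan–Meier machinery sees real censoring without ever
contradicting the five-year label. Exam dates increase with patient
index over ~14 years, so the serial splitter sees a chronological
cohort.

What the generator deliberately does **not** emulate: CT physics and
reconstruction artifacts, contrast phases, bladder anatomy and
neighbouring organs, irregular lesion shapes, segmentation error, and
multi-lesion disease (one lesion per patient by design). Passing tests
therefore show that the pipeline recovers signal that is present in
the planted form — morphological change, texture change, correlated
clinical indices — and is honestly calibrated when no signal exists;
they do not certify performance on real CTU data, and the headline
AUCs of any real study are not reproduction targets here.

## Numerical conventions

* Arrays are `(z, y, x)`; boxes are 0-based and half-open; NIfTI files
  are transposed to the conventional `(x, y, z)` on disk.
* All stochastic stages derive sub-seeds from one master seed
  (`derive_seed()`, kept below 2^31), so a pipeline rerun is
  byte-identical, including CSV/JSON artifacts and their manifest
  hashes.
* Ties: central slice → lower index; MI ranking → feature name;
  best-validation model → latest iterate; cutoff → lowest threshold;
  serial-split dates → patient id.
* Degenerate inputs: masks under 4 pixels refuse texture extraction;
  constant images give zero entropy/contrast by construction; single
  class in labels is an error everywhere it would make a quantity
  undefined; no events at all flags the KM result degenerate.

## Problem sizes used by the test suite

The simulation-backed checks run reduced problem sizes chosen as a
package decision to keep the suite quick while leaving the statistics
meaningful: 14×44×44-voxel volumes with 5–10 mm lesions, a slimmed CNN
(6/12 convolution channels, 2–4 epochs, per-case ROI cap 6–8, stride
8), and fusion capped at 120–150 iterations. Null calibration uses 20
seeds × 100 patients (fused test AUC compared against the exact
Mann–Whitney null band); signal recovery uses 10 seeds × 200 patients
at the generator's default effect sizes; the paired-AUC type-I check
uses 1000 null replicates of 120 patients. The acceptance script runs
one 163-patient cohort with the 56/4/40 chronological split and all
six descriptor combinations.

## Limitations

The radiomics catalog is a principled stand-in, not a reproduction of
any historical feature list; absolute feature values will differ from
other radiomics software even where names coincide (perimeter and
hence circularity conventions differ between packages, for example).
The CNN is a faithful small-scale reconstruction trained on CPU;
it is not intended to reach the performance of a tuned deep-learning
stack on real data. The bundled nomogram calibration is synthetic, and
the difference-feature convention leaves features undefined wherever
the pre-treatment value is exactly zero. Finally, the chronological
split means a single run has no variance estimate over cohort
composition; the property tests average over seeds instead.
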