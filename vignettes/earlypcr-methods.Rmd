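---
title: "earlypcr: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{earlypcr: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`earlypcr` predicts pathological complete response (pCR) to neoadjuvant
chemotherapy from dynamic contrast-enhanced breast MRI at two timepoints:
pre-treatment (T1) and early-treatment (T2, after the first chemotherapy
cycle). This vignette is the package's own account of the method: what is
modelled, which knobs matter, what the synthetic data does and does not
emulate, and where the design was genuinely open.

## The imaging model

A patient-timepoint is a `dce_series`: one pre-contrast and two
post-contrast volumes (nominally ~2.5 and ~7.5 minutes after injection)
sharing a shape, plus the in-plane pixel spacing. Two semi-quantitative
enhancement maps drive segmentation:

$$\mathrm{PE} = \frac{\text{post}_1 - \text{pre}}{\text{pre}}, \qquad
  \mathrm{SER} = \frac{\text{post}_1 - \text{pre}}{\text{post}_2 - \text{pre}}.$$

Voxels with a non-positive denominator are flagged invalid and never
thresholded. `segment_tumor()` keeps voxels inside a seed region with
`PE > pe_threshold` and SER inside `ser_range`, then restricts to the
largest 6-connected component. The thresholds are *configuration*, not
science: clinical enhancement-threshold protocols are scanner- and
protocol-specific, so the defaults (`pe_threshold = 0.7`,
`ser_range = [0.9, Inf)`) are documented as arbitrary desk-scale defaults
that segment the shipped phantoms cleanly (Dice ≈ 1).

The ROI is a square of side equal to the clinical largest diameter (LD),
converted to pixels with the in-plane spacing (`round(ld_mm / spacing)`,
half-up, floored at 8 px), centred on the rounded mask centroid in the
slice with the largest tumor area (ties go to the lowest slice index).
The window is half-open, `[c - floor(l/2), c - floor(l/2) + l)`; parts
outside the image are zero-padded. The crop is taken from the *first*
post-contrast volume only and bilinearly resized to 227 × 227. The resize
is corner-aligned, so constant crops stay constant and ramp extremes are
preserved to machine precision — properties the tests rely on. All of
these tie-breaks (centroid rounding, half-open window, zero padding,
bilinear interpolation) are deliberate choices where several conventions
would be defensible; they are fixed here and recorded in each patch's
provenance.

## Feature extraction: the pool2 contract

Downstream stages consume *low-level* convolutional features: the output
of the second pooling stage of an AlexNet-shaped network — a
13 × 13 × 256 block per 227 × 227 × 3 input, flattened to 43,264 values
per timepoint, 86,528 when T1 and T2 are concatenated (T1 block first).
Low-level features capture local structure (edges, dots, curves) and,
being taken after max-pooling, are locally translation-tolerant.

Anything satisfying that contract can serve as the backend
(`make_extractor()` accepts a function; `validate_extractor()` probes
shape and determinism at construction). The shipped `"filterbank"`
backend uses seeded Gaussian random convolutions with the exact AlexNet
geometry (227 → conv 11×11/stride 4 → 55 → pool 3×3/2 → 27 → conv 5×5
pad 2 → 27 → pool 3×3/2 → 13; 96 then 256 channels), bias-free and ReLU
rectified. Random convolutions are not trained edge detectors, but they
preserve what the selection machinery needs: locality, determinism and a
fixed feature identity. Everything downstream of the contract is
backend-agnostic.

Inputs are normalized per patch: min–max to [0, 1] (a constant patch maps
to zero) and the grayscale plane replicated to three channels. The
flattening order is fixed and documented:
`index = (row*13 + col)*256 + channel`, zero-based, so feature ids `f0`
… `f43263` (T1) and `f43264` … `f86527` (T2). `locate_feature()` inverts
this map, identifying the activation-map cell a selected feature lives
in — the basis for localizing selected features on the ROI. Feature ids
are zero-based because the block boundary (43,264) and the flatten
arithmetic are only clean in that form.

## Stability feature selection

With ~86k features and ~100 patients, a single filter pass is unstable:
which features pass p < 0.001 depends heavily on which patients are in
the sample. The package's selection layers three set operations over a
resampled Wilcoxon–Mann–Whitney filter (`selection_config()` defaults):

* **Filter.** Two-sided rank-sum p-value per feature; strict cut-off
  `p < alpha` with `alpha = 0.001`. Midranks for ties; exact distribution
  when the combined n ≤ 25 and the column is tie-free, otherwise the
  normal approximation with tie and continuity correction (matching
  `wilcox.test`). No multiplicity correction — the raw cut-off *is* the
  filter, and the stability layers below are what controls false
  selections.
* **Iteration = union.** Each of `n_subsets = 10` random subsets of
  `subset_fraction = 90%` of the training patients (drawn without
  replacement, unstratified; a draw that loses a class is redrawn and
  logged) is filtered, and the per-subset selections are pooled by
  union: the iteration's candidates.
* **Across iterations = intersection.** `n_iterations = 20` iteration
  sets are intersected per held-out patient: a feature survives only if
  *every* iteration proposed it — the "stable" features.
* **Across patients = intersection (OSF).** Leave-one-patient-out over
  the fine-tuning cohort gives one stable set per held-out patient;
  their intersection is the Optimal Subset of Features.

The union/intersection reading of "pooled within an iteration,
intersected across iterations" is the one coherent formalization of the
layered procedure; it makes the nesting OSF ⊆ per-patient set ⊆ each
iteration set an invariant, which the tests verify by replaying draws.
An empty OSF is a *legal outcome* reported with guidance (raise `alpha`,
or the class effect is too weak), not an exception — on null cohorts it
is the correct answer.

Seeding: one master seed; each (patient, iteration, subset, attempt)
draw derives its own substream seed by a modular mix of the keys, so
results are bit-reproducible and invariant to evaluation order, and the
draw log allows exact replay. Two computational observations keep the
procedure fast without changing its output: a feature eliminated from
the running intersection can never re-enter, so later iterations only
test surviving columns; and once the intersection is empty the remaining
iterations are skipped.

At small sample sizes the exact rank-sum distribution bounds the
attainable p-value (3 vs 3 cannot beat p = 0.1), so `alpha = 0.001` is
unreachable below roughly 7 + 7; the toy configurations in the tests
raise `alpha` accordingly.

## Classification and evaluation

The SVM kernel and regularization were genuinely open design choices;
the package defaults to linear with unit cost because in a p ≫ n regime
a linear maximum-margin classifier with per-column z-scoring (parameters
fit on the training fold only) is the standard conservative choice. Both
are configurable (`kernel`, `cost`). Decision scores are oriented so larger
means more pCR-like (the libsvm sign is checked against training-fold
class means and flipped if needed).

Evaluation reports the AUC via the Mann–Whitney identity (concordant-
pair fraction, half credit for ties) and places the operating threshold
by Youden's index, enumerating every distinct score as a candidate under
the rule "positive when score ≥ threshold". Ties in J break toward
higher specificity; the returned cut-off is the midpoint to the next
lower score, so separable scores get the gap midpoint. Accuracy,
sensitivity and specificity are reported as percentages to one decimal.

Fine-tuning metrics come from pooled LOO scores with a single Youden
threshold; the independent test fits one model on all training patients
and thresholds on the test ROC by default (`threshold_from = "train"`
reuses the training threshold; both thresholds are always recorded).
Every report carries the caveat that the OSF was derived using all
fine-tuning patients, so fine-tuning LOO metrics are optimistically
biased — the independent test is the unbiased surface.

Clinical covariates (ER, PgR, HER2, molecular subtype) are screened by
Mann–Whitney (age) and Pearson χ² without continuity correction
(categorical) at p < 0.05, dropping missing values per variable; the
associated ones are encoded (0/1 for receptors, a single 3-level code
for subtype — the model grid counts subtype as one feature) and appended
to the image features, with missing values imputed to the training-fold
mode. Subtype-stratified metrics reuse the global threshold and exclude
(and count) patients with missing subtype.

## The synthetic-data module

The generators define the study conditions for every test:

* `gen_feature_cohort()` — Gaussian feature matrices with a mean shift of
  `effect_size × noise_sd` planted in known columns of the pCR class.
  Defaults mirror the fine-tuning cohort scale: 30 pCR vs 78 non-pCR,
  1,000 features, 10 informative at effect 3. Gaussian mean-shift is the
  simplest model with controllable rank-sum power; per-patient
  counter-based substreams make patient k invariant to cohort size.
* `gen_dce_patient()` — ellipsoid tumors (default radii 5×10×10 voxels in
  a 24×64×64 volume at 1 mm) with multiplicative post-contrast gains
  (pCR 1.9/1.6, non-pCR 2.6/2.2 at the two acquisitions) and additive
  Gaussian texture (2% of the base intensity). Both classes clear the
  default PE threshold so segmentation is well-posed; the class contrast
  survives per-patch min–max normalization because the
  background-to-tumor ratio differs. LD is the largest in-plane pairwise
  mask extent × spacing.
* `gen_clinical_table()` — age and race class-independent;
  receptor-status probabilities interpolate between identical
  distributions (`assoc_strength = 0`) and a planted effect
  (`assoc_strength = 1`), with subtype derived from ER/PgR/HER2 so its
  association flows from theirs.
* In the image pipeline, responders additionally shrink in-plane by
  factor 0.75 and relax their gains 15% toward 1 at T2 — a coarse
  early-response model that gives the T2 exam genuine incremental signal.

What the phantoms do **not** emulate: MR physics (coil profiles, bias
fields, motion), pharmacokinetic curve shapes, lesion morphology beyond
ellipsoids, inter-site variation, and realistic class overlap — the
phantom classes are deliberately well separated. Passing tests therefore
demonstrate that the pipeline's mechanics (geometry, contracts, set
algebra, calibration, information flow) are correct, not that the
clinical discrimination levels would be reached on real data.

The model grid of the study design distinguishes single-timepoint feature
sets (OSF at T1 alone, OSF at T2 alone) from the combined OSF at T1–T2.
Because feature ids encode their timepoint block, the single-timepoint
variants are column subsets: run `loo_dynamic_select()` on
`features[, locate_feature(colnames(features))$timepoint == "T1"]` (or
T2) to reproduce them. The shipped pipeline runs the combined variant,
which is the design's headline model, plus the clinical-only and
clinical-augmented variants.

## Problem sizes and numerical choices

The shipped configurations are desk-scale by design: the end-to-end run
simulates 108 + 26 patients and feeds 1,000 evenly spaced pool2 features
(500 per timepoint, `n_select_features`) into selection — a spatially
uniform subsample that keeps the selection tractable while exercising the
full 86,528-feature extraction contract. Calibration suites use 20
replicate null cohorts at the 108-patient scale and 5 replicate planted
cohorts; the clinical Monte-Carlo uses 50 tables of 400 patients, where
the planted effects are strongly powered. Degenerate inputs are handled
explicitly: constant feature columns get p = 1; zero-variance columns
pass through scaling untouched; one-class strata report NA for the
undefined metric; empty masks, empty seed regions, impossible thresholds
and empty OSFs raise actionable errors (or a warning, for the OSF, where
emptiness is informative).

## Known limitations

* The filter-bank backend shares only the geometry, not the learned
  weights, of a pretrained network; absolute feature values (and hence
  which features land in the OSF) differ from any pretrained backend.
* Subset draws are unstratified; with very imbalanced small cohorts the
  class-loss redraw rate grows (it is logged).
* The per-patient stable sets of null cohorts are not always empty —
  heavily overlapping 90% subsamples keep a marginally significant noise
  feature selected across iterations — but the cross-patient
  intersection (OSF) reliably empties; that is the calibration that
  matters and the one the tests pin down.
* 3-D ROIs, multi-slice fusion, motion/bias correction and wrapper or
  embedded selection methods are out of scope.
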