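---
title: "Methods: canonical MRS processing, quality control and nosological mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canonical MRS processing, quality control and nosological mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what a green test establishes. It is the
package's own account of its methods; every number quoted here is computed
by the test suite or the examples, not asserted from elsewhere.

## 1. The canonical spectral representation

All classification happens on a fixed grid: 512 real points covering
[−2.7, 7.1] ppm, `ppm(i) = 7.1 − i·(9.8/511)` for zero-based `i`, index 0
at 7.1 ppm (high-field-left display convention; the mapping is the
unambiguous closed form consistent with the stated endpoints and count).
The processing chain per voxel is

1. **HLSVD water removal** (time domain). A rectangular Hankel matrix is
   built from the first `min(512, n)` FID samples (about 383 × 130; the
   rectangular shape makes the SVD roughly 20× cheaper than the square
   256 × 257 variant while using the same samples). The truncated left
   singular subspace (model order 25 by default) yields signal poles by
   shift invariance; complex amplitudes follow by least squares. Fitted
   components with frequency inside [4.31, 5.11] ppm — at most 10, largest
   amplitude first — are subtracted. Only damped poles (|z| ≤ 1) are
   removed, so extrapolation beyond the fitted window cannot diverge. On a
   two-component toy (water at 4.70, NAA at 2.01 ppm) the residual water
   band is < 5% of its original amplitude and NAA changes < 5% (acceptance
   criterion 2; in practice the residual is well under 1%).
2. **FFT** with optional exponential apodization (default 0 Hz — the
   reference processing mentions apodization without a constant, so none is
   applied) and 4× zero-filling, which interpolates the spectrum finely
   enough that peak positions survive resampling to within one canonical
   grid step.
3. **Resampling**: linear interpolation of the real part onto the canonical
   grid; inputs that do not cover [−2.7, 7.1] ppm are an error, never
   extrapolated. Only the real part is classified; no first-order phase
   correction is attempted (flip handling supplies the only zero-order
   correction).
4. **Flip correction**: a spectrum is inverted when |min| > |max| over the
   [0, 4.2] ppm sub-range. The statistic is threshold-free and involutive
   (correcting a corrected spectrum changes nothing); a 180° inversion is
   the only phase error modeled.
5. **Alignment**: the most prominent peak within ±0.15 ppm of 2.01 ppm
   (NAA) is moved onto the bin nearest 2.01 by an integer-bin shift (capped
   at ±8 points, vacated bins zero-filled); if no peak exceeds 3× the noise
   SD (noise region [−2.7, −1.0] ppm), the search falls back to 3.21 (Cho)
   and then 3.03 ppm (Cr), in that priority order. Window, threshold and
   cap are package choices; the priority order is the reference one.
6. **Water-band zeroing**: bins with 4.2 ≤ ppm ≤ 5.1 are set to exactly 0
   (idempotent), so remnant water cannot distort normalization.
7. **UL2 normalization** to unit Euclidean length (a zero spectrum is an
   error), then **extraction** of 0 ≤ ppm ≤ 4.2 — zero-based indices
   152..370, 219 points — and renormalization within that range.

SV training spectra and MV grid spectra pass through the identical chain,
which is the point: the two acquisitions become point-for-point comparable.

## 2. Quality control

Exclusion order: ventricle voxels (from the mask) first, then SNR, then
cNMF screening.

The SNR estimate is `(max − median)` of the [0.5, 4.1] ppm band divided by
the SD of the [−2.7, −1.0] ppm noise region; spectra below 10 are
discarded (10.0 itself is kept). The formula is a package choice — the
reference workflow names no estimator. One consequence matters: the raw
statistic is orientation-sensitive, yet in the reference workflow flipped
spectra demonstrably *passed* the SNR filter and were caught later by the
cNMF screen. `qc_screen()` therefore measures SNR on the flip-normalized
orientation (quality is independent of a sign flip) and leaves flip
detection to the artifact screen.

Convex NMF factorizes the non-negative-shifted feature matrix as
`X ≈ G Wᵀ X` with sources constrained to convex combinations of observed
spectra, so every source looks like a (mixture of) real spectra. Fitting
uses the standard multiplicative updates with a k-means-based
initialization (seeded); the reconstruction objective is non-increasing —
asserted on every fit with a 1e−8 relative numerical tolerance — and
iteration stops at a relative change below `tol = 1e−7` or 300 iterations.
Each spectrum's own minimum is subtracted for non-negativity (recorded);
`k` defaults to 5 with the operator expected to inspect 2–5, matching the
reference workflow. Winning-source ties break to the lowest index.

Sources are labelled artifactual automatically when their median-centered
[0, 4.2] ppm pattern is predominantly negative (the flipped shape) or when
class templates are supplied and the source correlates below 0.3 with all
of them; a manual override is first-class, so an expert-labelled workflow
can be replayed exactly. A spectrum is discarded when its largest mixing
weight falls on a flagged source.

## 3. Feature selection and classification

Redundancy dropping: for any candidate pair with Pearson correlation
strictly above 0.80, the higher-ppm member is discarded, iterating until no
pair exceeds the threshold (constant features are kept — their correlation
is undefined). For SFFS the rule is applied to the candidate pool before
selection; for the ranking methods, to the selected top-k.

SFFS wraps LDA in stratified 5-fold cross-validation scored by balanced
accuracy (fold count and criterion are package choices; the reference
states only that cross-validation was used). Forward steps add the
best-scoring feature; after each addition, conditional backward removals
are accepted only when they beat the best criterion recorded for the
smaller size. Fold assignment is fixed by the seed, making selection
deterministic. On a seeded 8-feature problem the k = 3 selection attains
the exhaustive-search optimum (acceptance criterion 4).

The baselines are chi-square on min-shifted features, one-way ANOVA F,
one-vs-rest L1 logistic regression (glmnet; features ranked by largest
absolute coefficient at the first lambda activating at least k features),
and Boruta (shadow-feature random forest, one-sided binomial confirmation
at α = 0.05; defaults 100 iterations × 500 trees, scaled down in tests).

LDA uses class means, a pooled within-class covariance with ridge
`1e−6 × mean(diag(Σ))`, and empirical priors (uniform on request);
posteriors are the usual Gaussian discriminants. The random forest (CART,
Gini, per-split feature subsampling) and squared-hinge linear SVM are
implemented in-package — no RF/SVM package is available in the target
environment — and only promise the common scoring interface, determinism
included. Evaluation: BER and per-class one-vs-rest AUC (Mann–Whitney,
ties 0.5) over stratified bootstrap refits (default 1000; stratification
preserves class counts, so no replicate can lose a class; training metrics
are in-bag, a choice the reference leaves open). Features are selected
once, before bootstrapping — the reference is silent on per-replicate
re-selection, and fixing the set isolates classifier variance. The best
configuration minimizes the mean per-class |1 − AUC_test/AUC_train|, then
maximizes mean AUC_test, then minimizes mean BER_test.

## 4. The synthetic world

The generator replaces two proprietary clinical databases, so its defaults
are the package's statement of what a plausible world looks like:

* **Lineshape**: pure Lorentzian (exponentially damped complex sinusoids),
  matching the HLSVD model class and keeping the water-removal oracle
  exact. No Gaussian/Voigt component, no J-coupling, no multiplets.
* **Class templates** (relative amplitudes, configurable): normal has NAA
  (2.01 ppm) strictly tallest; glioblastoma and metastasis have necrotic
  patterns with lipids (0.90/1.28 ppm) above NAA; meningioma has high
  choline, alanine, and near-absent NAA/creatine; low-grade glioma keeps
  substantial NAA with elevated choline and the 2.3–2.4 ppm region. The
  qualitative patterns are the published ones; the numbers are package
  defaults, not claimed values.
* **Between-subject variability**: each resonance amplitude is jittered
  with CV 0.25. The value was revised once during development (from a
  first-draft 0.15) because a 0.15 world is perfectly separable — training
  BER identically zero, which no real MRS dataset shows; 20–30% is the
  range typically reported for metabolite-level variability, and 0.25
  produces the realistic regime of near-zero training error with nonzero
  test error.
* **Acquisition**: 1024 complex points at 2404 Hz bandwidth; transmitter
  63.87 MHz (1.5 T) for SV training data and 127.74 MHz (3 T) for MV
  phantoms, mimicking the field-strength mismatch the pipeline is supposed
  to bridge. SNR targets are imposed in the frequency domain (peak height
  over noise SD) so they align with the QC estimator; per-voxel targets
  draw uniformly from [12, 35] by default.
* **Phantom geometry**: an elliptical solid core, an abnormal ring
  (tumor/normal infiltration mixture for glial cases, oedema-like mixture
  for meningioma/metastasis), normal tissue elsewhere, an optional
  ventricle patch of low-signal CSF-like voxels.
* **Partial-volume bleeding**: a voxel on a region boundary receives a 50%
  contribution from its most severe differing neighbor, with severity
  solid > abnormal > normal > ventricle — bleeding spreads the strong
  tumor signal *outward*. The symmetric alternative (blurring both sides
  of every interface) was rejected: it contaminates half of a small solid
  core, making a meningioma core read as low-grade glioma and the
  solid-tumor index structurally unable to reach the success range on
  artifact-free phantoms, which contradicts what the intact-data regime is
  meant to demonstrate. Directional bleeding matches the published
  description of necrotic lipids appearing in *neighboring* voxels.
* **Artifacts** (per-voxel, independent): FID negation (flip), residual
  water at 4.7 ± 0.05 ppm at 4× the largest metabolite amplitude,
  low-SNR override (target drawn from [2, 6]), Normal(0, `shift_sd`)
  frequency misalignment, and a random ghost peak.

What the generator does **not** emulate: multiplet structure (no lactate
doublet), baseline distortions beyond a single broad component, eddy
currents, chemical-shift displacement, spatial point-spread of CSI
encoding (bleeding is a one-voxel convex mixture, not a sinc kernel),
scanner-brand differences, and any field-strength-dependent chemical-shift
physics. A green end-to-end test therefore establishes that the pipeline's
plumbing, normalization compatibility and decision logic are correct under
the stated noise and artifact model — not that real 1.5 T→3 T transfer
reaches any particular accuracy.

## 5. Scores

STI = correctly classified solid-region voxels / (solid-region voxels −
QC-excluded solid-region voxels); success is STI > 0.50, strictly. Dice is
computed over non-excluded voxels per paired region: normal ↔ `no`,
solid ↔ the case's task class, abnormal ↔ `lgg` for glial cases in the
4-class task (infiltration reads as low grade); in the 3-class task the
abnormal region pairs with the case class — the closest consistent reading,
since no `lgg` prediction exists there. An empty-vs-empty Dice is reported
as missing, not 0. Grid-level BER/AUC use only solid (labelled with the
case class) and normal voxels; abnormal and excluded voxels never enter
them. Multi-slice phantoms report per-slice entries plus an overall row.
A per-grid AUC for a class with no positives or no negatives is reported
missing rather than imputed.

## 6. Numerical and degenerate-input conventions

* Unit-norm checks use 1e−9; XML round-trips store 17 significant digits
  (exact for doubles).
* cNMF multiplicative updates guard denominators with 1e−12; the
  monotonicity assertion allows 1e−8 relative slack for floating-point
  wobble.
* Ties: winning cNMF source → lowest index; winning class → task class
  order; correlation-dropping scans pairs in descending-ppm order.
* Degenerate inputs are errors, not silent repairs: zero spectra at
  normalization, dead [0, 4.2] sub-ranges, zero noise SD in the SNR
  estimator, empty candidate lists, masks that do not match voxel counts,
  geometry exceeding phantom dims.
* All randomness flows from explicit integer seeds; identical (config,
  seed) pairs give bitwise-identical simulators, fits and CLI output trees
  (no timestamps are written anywhere).

## 7. Known limitations

* The SFFS feature sets on default synthetic data reliably include the
  choline (3.21 ppm) and a lipid/macromolecule position, but typically not
  NAA (2.01 ppm): NAA is top-ranked univariately (the F filter places it
  in its top 10) yet multivariately redundant once choline, lipid and
  2.3–2.4 ppm features are in the set. This mirrors the published finding
  that the most important model feature was 2.382 ppm rather than an NAA
  bin, but it means "the selected set contains every prominent peak"
  should not be expected of a wrapper method.
* The in-package random forest and linear SVM are compact baselines, not
  tuned production classifiers; they exist to reproduce the comparison
  structure, and only LDA is used for the reference maps.
* HLSVD subtracts only damped in-region components; a pathological FID
  whose water energy sits in growing poles would pass through unfiltered
  (the water band is still zeroed downstream).
* The Boruta defaults (100 × 500 trees) are far too slow for a pure-R
  forest on full grids; tests and examples scale them down explicitly.
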