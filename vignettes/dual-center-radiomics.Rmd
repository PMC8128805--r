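---
title: "Dual-center HRCT texture radiomics: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-center HRCT texture radiomics: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cholesteatoma and middle ear inflammation (MEI) both present as soft-tissue
opacification of the tympanic cavity on temporal-bone HRCT, but demand very
different management (surgery versus conservative treatment). Texture
radiomics — many mathematical descriptors of the spatial gray-level structure
inside a region of interest — can separate the two, but texture features are
notoriously sensitive to acquisition parameters. When two centers image at
different reconstruction matrices (512×512 versus 768×768 over the same field
of view), the same physical tissue produces different feature values, and a
model trained on naively pooled data learns the scanner as much as the
biology.

`otoradiomics` implements the full analysis chain for studying this problem,
together with the two standard remedies: **image-domain resampling** of the
larger matrix onto the smaller one before feature extraction ("preimage"
correction), and **feature-domain empirical-Bayes harmonization** (ComBat)
after extraction ("post-image" correction). Because no patient images are
publicly available for this task, the package ships a first-class synthetic
cohort generator that reproduces the *structure* of the dual-center study with
a controllable center effect.

## The synthetic cohort

Each case is a stationary Gaussian random field: spectral synthesis shapes
complex white noise with a Gaussian transfer function on a common physical
grid at the finest center resolution (768² over a 102.4 mm field of view),
after which the field is sampled at each center's matrix by exact
fractional-area averaging. Within a class, the only systematic between-center
differences are therefore acquisition effects: pixel spacing (0.2 mm at
center A versus 0.1333 mm at center B), a Gaussian reconstruction-blur
surrogate, an additive intensity shift, and iid pixel noise added at the
center's own grid. The two classes differ **only** in the spatial correlation
length of their texture; their means are identical, so first-order (HIS)
features carry no class signal by construction — mirroring the clinical
observation that plain attenuation statistics do not separate the diseases.

Default study conditions (all configurable through `cohort_config()`):

* 50 cases per center, 23/27 and 25/25 cholesteatoma/MEI splits;
* correlation length 0.30 mm (cholesteatoma) versus 0.52 mm (MEI), both
  isotropic; texture amplitude 25, baseline 60 (arbitrary HU-like units);
* center effect: matrix size 512 vs 768, additive shift +30 at center B,
  blur 0.30 mm and noise sd 4 at both centers (equal *physical* values on
  different grids are still different acquisitions in the pixel domain);
* a single circular ROI of radius 2 mm (≈12.6 mm² > the 4 mm² minimum) at
  the lesion-field center.

Two quantitative considerations fixed these defaults. First, feature
estimates from a 2 mm ROI average only ≈20 independent texture patches of
size ≈0.45 mm (post-blur), so the class contrast must be large enough in
relative terms (ratio ≈1.6 in correlation length, compressed to ≈1.4 by
blur) to be detectable within one center. Second, the class ratio *in pixel
units* must stay below the 1.5 spacing ratio between matrices: then center
B's cholesteatoma texture falls, in pixel units, on top of center A's MEI
texture, and pixel-based features (co-occurrence offsets, run lengths,
gradients, dyadic wavelet scales — all defined in pixels) interleave the
classes across centers. That interleaving is the mechanism by which naive
pooling degrades, and both corrections remove it: resampling restores a
common pixel grid, harmonization re-aligns per-feature locations and scales.
Scale-free class cues (for example an anisotropy difference between classes)
were deliberately avoided in the defaults: being ratios, they are trivially
robust to pixel-spacing changes and would mask the acquisition effect the
design isolates.

What the generator does **not** emulate: anatomy (ossicles, bone
interfaces), lesion shape and size variability, manual-ROI placement
variability, scanner physics beyond blur/noise surrogates (beam hardening,
iterative-reconstruction nonlinearity, correlated CT noise), and slice
geometry. Passing tests on this cohort demonstrate that the *pipeline*
behaves correctly and that the center-effect mechanism and its corrections
work as theory predicts — not that any particular AUC is attainable on real
patients.

## Preprocessing

`make_roi_mask()` builds the circular mask by pixel-center distance
(0-based coordinates) and enforces the >4 mm² minimum area.
`normalize_quantize()` limits the ROI dynamics to μ ± 3σ (values outside are
saturated, not discarded, which keeps the pixel grid intact) and linearly
maps that interval onto 2^bits integer levels; 6 bits (64 levels) is the
default — the common texture-analysis compromise that keeps 64×64
co-occurrence matrices populated for ROIs of a few hundred pixels
(configurable 4–8 bits). Quantized levels feed the co-occurrence and
run-length families; the clipped but unquantized values feed the histogram,
gradient, autoregressive and wavelet families. Every feature is thereby
invariant to positive affine rescaling of the raw intensities — exactly so
for the quantized families, up to the clipping map otherwise.

`resample_image()` uses bilinear interpolation with the pixel-center
convention, the conservative default for matrix downscaling; the kernel
choice is a function argument so the decision stays auditable. For the
resampled study arm the ROIs are re-derived and features re-extracted on the
resampled images, and selection is repeated — normalization therefore runs
*after* resampling, the interpretation consistent with re-drawing ROIs anew.

## Feature families

271 features per case with the classical texture-analysis registry names:

* **HIS** (9): mean, variance, skewness, excess kurtosis, percentiles 1/10/50/90/99.
* **COM** (220): 11 Haralick statistics (`AngScMom`, `Contrast`, `Correlat`,
  `SumOfSqs`, `InvDfMom`, `SumAverg`, `SumVarnc`, `SumEntrp`, `Entropy`,
  `DifVarnc`, `DifEntrp`) for offsets (d,0), (0,d), (d,d), (d,−d), d = 1..5,
  named `S(dx,dy)Stat`. Matrices are symmetrized; entropies use the natural
  logarithm with 0·log 0 ≡ 0 (base is immaterial for selection and
  classification, which are monotone-invariant per feature).
* **RUN** (20): short/long-run emphasis, gray-level and run-length
  non-uniformity, and fraction of image in runs, in four directions
  (`Horzl_`, `Vertl_`, `45dgr_`, `135dr_`).
* **GRA** (5): moments of the central-difference gradient magnitude on
  interior ROI pixels.
* **ARM** (5): least-squares coefficients `Teta1..Teta4` of the causal
  autoregressive model (left, upper-left, upper, upper-right neighbours) and
  the residual scale `Sigma`.
* **WAV** (4 per scale, default 3 scales): non-standard Haar subband
  energies `WavEnLL_s-1` …, computed on the mask bounding box padded with
  the ROI mean; a coefficient contributes when its spatial support
  intersects the mask.

A total of 279 is sometimes quoted for this registry, but the per-family
counts it implies are inconsistent (and 73 wavelet features is not a
multiple of 4 subbands); the package treats the per-family counts as
authoritative and leaves the wavelet scale count configurable.

Features infeasible for a given ROI (for example d = 5 offsets on a tiny
mask) are reported as explicit `NA` markers, never silent zeros, and are
excluded feature-wise from selection.

## Feature selection: POE + ACC

Feature quality is the minimal class-prior-weighted misclassification rate
of a one-dimensional threshold classifier over all cut points and both
polarities (the classical probability-of-error estimate; resubstitution).
Selection is greedy: the first feature minimizes POE; each later step
minimizes POE(f) + ACC(f), where ACC is the mean absolute Pearson
correlation with the features already selected (unit weights; Spearman
available). Ties break deterministically towards the registry order.

One property of this criterion is worth knowing: features that all carry the
same class effect are mutually correlated through the class mixture (for a
standardized shift d the pooled correlation is (d²/4)/(1+d²/4) ≈ 0.36 at
d = 1.5), so after a few informative picks the ACC penalty exceeds a modest
POE advantage and the criterion deliberately alternates to uncorrelated —
including uninformative — features. That is redundancy avoidance working as
designed; it caps how many mutually redundant informative features can ever
be selected, and it is why the selected 10 are best read as a diverse panel
rather than a top-10 ranking.

## Classification protocols

**Single-center arm** (50 cases): the 10 selected features are z-scored,
projected on the Fisher discriminant axis w ∝ S_w⁻¹(m₁−m₂) (ridge 1e-6 only
if the pooled scatter is singular), and classified by k-NN with
leave-one-out cross-validation. k = 1 by default (the classical companion
default for this protocol; configurable, recorded in the report). Distance
ties break by case order, making the run fully deterministic. Selection and
standardization use all cases of the center — the resubstitution-flavoured
protocol of small single-center radiomics studies. This leaks: best-10-of-271
selection can separate even permuted labels at small n (the test suite
asserts this inflation explicitly), so single-center accuracies are
optimistic by construction and are reported for protocol fidelity, not as
unbiased estimates.

**Pooled arm** (100 cases): a feed-forward perceptron with one hidden layer
of 4 logistic units (satisfying the "at least one hidden layer, at least
three neurons" protocol floor), trained via `nnet` on cross-entropy with
weight decay 0.1 and at most 500 BFGS iterations. Decay 0.1 was chosen when
the classifier was designed: with 10 standardized inputs and ~70 training
cases, weaker regularization (0.01) drove training accuracy to ~99% and made
validation AUC medians unstable across splits. Splits are stratified 70/30
(plain random splits can produce degenerate single-class validation sets at
n = 100); feature standardization uses training-set statistics only. The
protocol repeats 5 times with fresh stratified splits (split seeds derived
from one master seed) and reports median (min–max) for validation AUC and
both accuracies. AUC is the Mann–Whitney statistic (ties count one half),
identical to trapezoidal ROC integration.

## Harmonization

`fit_combat()` implements the parametric empirical-Bayes location/scale
model: per-feature grand mean and pooled variance by least squares,
standardization, per-batch location γ̂ and scale δ̂² estimates, normal and
inverse-gamma priors across features by method of moments, and the standard
conditional updates iterated to a relative-change fixed point. The stopping
rule replicates the canonical implementation exactly (including its signed
denominator) so results are bit-comparable with reference implementations at
a matched tolerance; the package default (1e-6) is tighter than the common
1e-4. With a single batch the model is the identity; zero-variance features
pass through with a warning; unknown batches are refused at apply time (no
out-of-batch extrapolation).

Empirical-Bayes shrinkage means γ* ≠ γ̂, so harmonized per-batch means are
equal only up to shrinkage noise. `fit_combat(eb = FALSE)` provides the
unshrunk location/scale adjustment, for which mean and variance equalization
is exact and refitting finds no residual batch effect; the shrunk variant is
the pipeline default, as in the radiomics literature. By default no
biological covariates are protected (class labels are near-balanced across
centers, so harmonization removes little class signal); a class-protected
design can be passed explicitly and the model records it.

In the study pipeline, harmonization is fitted on the full pooled table
before the train/validation splits, and selection likewise runs once per arm
on all cases — the sequencing of the emulated study design. Both choices
leak information into validation; the repeated-split summaries should be
read accordingly.

## The four-condition study

`run_study()` executes, on one cohort and one master seed: (a) per-center
LDA + 1-NN LOO; (b) pooled unmodified → MLP; (c) pooled with center B
resampled to center A's matrix, features and selection redone → MLP; (d)
pooled with ComBat-harmonized features → MLP. Arms (b)–(d) differ only in
the correction stage. The negative-control configuration (no center effect,
equal matrices) makes arm (c) a no-op and leaves (d) as pure shrinkage noise
— corrections must not inflate AUC there, which the acceptance suite checks.

## Problem sizes and determinism

The test suite exercises the full default cohort (100 cases, 512/768
matrices) for the directional study checks — 10 cohort seeds for the
center-effect-on condition and 10 for the negative control — and small
grids (64/96 over a 12.8 mm field of view) elsewhere; a complete
four-condition study at default size runs in well under a minute on one
core. All randomness flows from explicit seeds: the cohort seed fixes the
images bit-for-bit, and the master seed fixes the split sequence, so every
reported number is exactly reproducible.

## Known limitations

* The synthetic cohort validates the pipeline, not clinical performance;
  absolute AUCs on real HRCT will differ.
* Single-center accuracies (and, to a lesser degree, pooled summaries)
  carry the selection/harmonization leakage discussed above.
* Only 2D circular ROIs are supported (3D/mesh ROIs are out of scope), and
  slice-thickness differences are not modelled or corrected.
* The nonparametric ComBat variant and image-domain harmonization (e.g.
  style transfer) are out of scope.
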