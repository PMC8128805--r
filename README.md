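# otoradiomics

Texture radiomics for separating **cholesteatoma** from **middle ear
inflammation (MEI)** on temporal-bone HRCT, with explicit handling of
**dual-center acquisition differences**. The package is aimed at researchers
studying multi-center reproducibility of CT texture features: it implements
the complete analysis chain and the two standard center-effect corrections,
and ships a synthetic dual-center cohort generator so every stage is testable
end to end without patient data.

## What it computes

* **Texture features** from a single 2D circular ROI (> 4 mm²) after
  gray-level normalization to μ ± 3σ and quantization to 2^bits levels:
  first-order histogram statistics (HIS, 9), gray-level co-occurrence
  statistics S(dx,dy)·{AngScMom, Contrast, Correlat, SumOfSqs, InvDfMom,
  SumAverg, SumVarnc, SumEntrp, Entropy, DifVarnc, DifEntrp} over 4
  directions × 5 distances (COM, 220), run-length statistics in 4 directions
  (RUN, 20), absolute-gradient moments (GRA, 5), causal autoregressive model
  coefficients (ARM, 5), and Haar wavelet subband energies (WAV, 4 per
  scale).
* **POE + ACC feature selection**: greedy minimization of the best-threshold
  probability of classification error plus the average absolute correlation
  with already-selected features; returns the 10-feature panel.
* **Classifiers**: Fisher LDA projection w ∝ S_w⁻¹(m₁ − m₂) with k-NN
  leave-one-out for single-center data; a 1×4 logistic multi-layer
  perceptron with repeated stratified 70/30 splits for pooled data; AUC as
  the Mann–Whitney statistic P(s⁺ > s⁻) + ½P(tie).
* **Center-effect corrections**: bilinear matrix resampling (768² → 512²
  over the same field of view, spacing × 1.5) before re-extraction, and
  parametric empirical-Bayes location/scale harmonization (ComBat) of the
  feature table, with per-batch γ*, δ*² shrinkage and an exact (unshrunk)
  variant.
* **The four-condition study** (`run_study()`): per-center LDA + k-NN, and
  pooled MLP under no correction / resampling / harmonization, sharing one
  cohort and master seed.

## Worked example

```r
library(otoradiomics)

report <- run_study(cohort_config(), master_seed = 1)
print(report)
```

```
Dual-center radiomics study report (seed 1 )
  center A: 42/50 cases (accuracy, 84%; misclassified: 4 cholesteatoma, 4 MEI)
  center B: 41/50 cases (accuracy, 82%; misclassified: 4 cholesteatoma, 5 MEI)
  pooled unmodified  AUC 0.74 (0.67-0.86), train acc 95.7 (94.3-95.7), val acc 70.0 (60.0-76.7)
  pooled resampled   AUC 0.86 (0.85-0.90), train acc 97.1 (95.7-100.0), val acc 80.0 (73.3-80.0)
  pooled harmonized  AUC 0.85 (0.76-0.87), train acc 97.1 (94.3-100.0), val acc 76.7 (66.7-83.3)
```

Reading the output: each center alone classifies well (the 10-feature panel
is selected per center), but naively pooling the two centers drops the
median validation AUC to 0.74 — the texture features are defined in pixel
units, and the 512 vs 768 matrix difference makes the same tissue class look
different across centers. Resampling center B onto center A's matrix before
re-extracting features, or harmonizing the pooled feature table with
empirical Bayes, recovers AUC ≈ 0.85–0.86. The `median (min–max)` format
summarizes the five repeated stratified splits.

Individual stages are available directly:

```r
cohort <- generate_cohort(cohort_config(seed = 7))
tab    <- extract_cohort(cohort)            # 100 x (3 + 271) feature table
model  <- fit_combat(tab)                   # center-effect model
harm   <- apply_combat(model, tab)
sel    <- select_features(harm)             # 10-feature POE+ACC panel
```

## Documentation

The methods vignette (`vignettes/dual-center-radiomics.Rmd`) describes the
synthetic cohort's design and its limitations, every tunable parameter with
its default and rationale, the numerical conventions (quantization,
entropies, tie-breaks, degenerate inputs), and the known leakage properties
of the emulated study protocol.
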