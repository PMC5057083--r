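---
title: "Metabolite-ratio index discrimination: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite-ratio index discrimination: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chronic fatigue syndrome has no established molecular diagnostic; diagnosis
rests on clinical criteria. Plasma metabolomics by capillary-electrophoresis
mass spectrometry offers a candidate route: intermediates of central energy
metabolism (glycolysis, the TCA cycle) and of the urea cycle shift in
patients relative to healthy controls. The catch is that absolute plasma
concentrations carry a large per-person, per-draw *global* component —
time-of-day, hydration, recent intake — that inflates the variance of any
single metabolite. The ratio of two metabolites connected by a short stretch
of a metabolic pathway cancels that global factor exactly, while still
reporting on the flux across the enzymes between them. Two such indexes are
the core of this package:

* **ornithine/citrulline** — the substrate and product of ornithine
  transcarbamylase (EC 2.1.3.3), the entry step of the urea cycle; and
* **pyruvate/isocitrate** — spanning pyruvate → citrate → *cis*-aconitate →
  isocitrate, the glycolysis-to-TCA handover through citrate synthase and
  aconitase.

A rise in either ratio indicates a relative slowdown of the downstream
segment (urea-cycle entry; aconitase-dependent flow into the TCA cycle).
The package implements the full discrimination workflow around these
indexes and a synthetic-cohort generator, because the original clinical
concentrations are not publicly deposited: every stage is exercised
end-to-end on simulated cohorts with the same statistical structure.

## Pipeline stages and their contracts

1. **Quantification.** Each peak area is divided by the internal-standard
   peak area of the same run (methionine sulfone for cations,
   D-camphor-10-sulfonic acid for anions), removing detector-sensitivity
   fluctuation, then mapped to micromolar through the standard-mixture
   calibration:
   `conc = (peak_area / is_area) / standard_relative_area × standard_concentration`.
   The operation is invariant to any common rescaling of detector response.
2. **Retention rules.** A metabolite is kept when its **median S/N across
   detected records is ≥ 10** (inclusive) and its missing fraction is
   ≤ 0.2 **within each group separately**. Both thresholds sit in
   `pipeline_config()`. The S/N rule is summarised per metabolite by the
   median because a per-metabolite criterion needs a summary statistic and
   the median is robust to a few saturated or weak runs; the 0.2 missingness
   cap operationalises "few missing values" at a common conservative level.
   Only metabolites surviving in *both* cohorts (training order preserved)
   continue.
3. **Half-minimum imputation.** Each missing cell becomes half the minimum
   observed value of that metabolite *in that cohort dataset* — the standard
   stand-in for left-censored values below the detection limit. It runs per
   cohort, after filtering and before any ratio, and is idempotent.
4. **Screening and ranking.** Univariate two-sided Mann–Whitney tests per
   metabolite (exact null for tie-free comparisons of total n ≤ 12, normal
   approximation with tie and continuity correction otherwise; reporting
   bands 0.10/0.05/0.01/0.001, no multiplicity correction at this
   descriptive stage). Multivariate ranking is linear soft-margin SVM
   recursive feature elimination: z-score features, fit, drop the smallest
   |weight|, repeat; rank is reverse elimination order. `C = 1` by default
   and exposed in the config; z-scoring makes the ranking invariant to
   affine rescaling of any feature.
5. **Ratio-index construction.** Every ordered pair of distinct top-k
   (default 5) metabolites with a directed pathway path of ≤ 4 edges becomes
   a candidate index (substrate over product; the bundled map covers
   glycolysis, the TCA cycle through malate, the urea cycle, glutamine
   exchange and the GABA shunt). Path length 4 admits pyruvate/isocitrate
   (3 edges) while excluding arbitrary long-range pairs. Candidates sort by
   combined rank, then path length, then lexically; the default selection
   keeps the top two after dropping reciprocal duplicates, since a ratio and
   its inverse carry the same ranking information. Which two pairs a
   data-driven run keeps is deliberately configurable — the defensible rules
   (pure combined rank, pathway diversity, expert choice) genuinely differ —
   and a fixed index list can be supplied to `run_pipeline()` to skip
   selection entirely.
6. **Model and validation.** Multiple logistic regression
   (maximum likelihood via IRLS; case = 1 by default, switchable since the
   opposite coding only flips coefficient signs), Wald CIs (profile
   likelihood optional), odds ratios `exp(β)`. Discrimination is summarised
   by the ROC AUC computed by the concordant-pair rule, which equals the
   trapezoidal area and the Mann–Whitney identity `U/(n₁n₂)` exactly (ties
   half-credit). The default AUC interval is closed-form Hanley–McNeil
   (`Q1 = A/(2−A)`, `Q2 = 2A²/(1+A)`); DeLong is available for real score
   vectors. Generalisability is assessed two ways, 200 trials each:
   stratified 10-fold cross-validation (per trial, out-of-fold scores are
   pooled into a single AUC — stable with only 4–5 held-out samples per
   class) and bootstrap resampling (refit on a stratified with-replacement
   resample of the training individuals, score the original training set and
   the untouched validation set). Summaries are medians with 2.5/97.5
   percentile intervals.

## Numerical choices

* IRLS convergence: deviance tolerance 1e-10, 100 iterations; the ridge
  fallback iterates until max |penalised score| < 1e-8.
* Perfect separation aborts the plain fit with advice to enable the ridge
  fallback (`ridge = TRUE`, λ = 1e-6 on non-intercept terms, intercept
  unpenalised). CV and bootstrap refits enable it by default because a
  small training fold can transiently separate; at λ = 1e-6 the estimates
  are numerically indistinguishable from the MLE whenever the MLE exists.
* SVM-RFE elimination ties break to the first (column-order) feature;
  constant columns z-score to all-zeros with a warning instead of dividing
  by zero.
* All randomness flows from one root seed with fixed stage offsets
  (+100 ranking, +200 CV, +300 bootstrap), so a whole run is reproducible
  from `rng_seed` alone.
* Matrix TSVs carry 17 significant digits so a write/read round trip is
  bit-identical; missing cells are written as `NA` (empty string also
  accepted on read).
* Ratio cancellation of a per-sample global factor is exact in real
  arithmetic and holds to one ulp in floating point ((a·s)/(b·s) may round
  one ulp away from a/b); tests assert it at 1e-14 relative tolerance.

## What the synthetic generator emulates

Latent concentration of sample *j*, metabolite *i*:

    baseline_i × fold_change_i^[case_j] × exp(σ_bio Z_ij) × exp(σ_diurnal Z_j)

with lognormal analytical noise multiplied onto the measured value, and
left-censoring to missing when the latent value falls below the
per-metabolite detection limit. S/N per record is
`measured / detection_limit × 5`, linking the S/N filter, the censoring and
the imputation to one mechanism. Peak areas are back-computed through the
calibration standards and per-run internal-standard areas, so
`quantify()` inverts the generator up to analytical noise.

Defaults, chosen once: baselines are typical plasma values (glucose 5 mM,
lactate 1.5 mM, pyruvate 60 µM, citrate 120 µM, isocitrate 5 µM, ornithine
60 µM, citrulline 30 µM, urea 4 mM, ...); σ_bio = 0.35 (≈ 36 % biological
CV, the usual plasma-metabolite range), σ_diurnal = 0.30 (a moderate
global draw-to-draw factor), analytical CV 5 % (routine CE-MS
repeatability). Case fold-changes follow the reported directions: ornithine
1.30, citrulline 0.78, urea 0.80, isocitrate 0.75, citrate 0.85, malate
0.85, *cis*-aconitate 0.90, pyruvate 1.12; glucose, glutamine, glutamate,
succinate and the branched-chain amino acids are null. Under these values
the closed-form binormal approximation puts the single-ratio AUCs near
0.77 (ornithine/citrulline) and 0.72 (pyruvate/isocitrate) and the
two-ratio model near 0.82 at n = 47/46 — the operating point of interest.
Two deliberately weak, low-abundance metabolites (argininosuccinate, GABA)
sit close to their detection limits so the S/N filter, the missingness
rule and the imputation all have real work to do. Cohort sizes default to
47/46 and 20/20.

What the generator does **not** emulate: between-metabolite correlation
beyond the shared global factor (real pathway neighbours co-vary),
batch/drift structure, the training-vs-validation sensitivity gap of the
original instruments, non-lognormal tails, and age/sex structure. Passing
tests therefore demonstrate that the *machinery* is correct and that the
diurnal-cancellation argument holds — not that the synthetic effect sizes
are those of real patients.

## Problem sizes used in the shipped checks

Unit tests run on micro-fixtures (3–50 samples per group). The protocol-
scale checks use the full study geometry — 47/46 + 20/20 samples, 200 CV
trials, 200 bootstrap trials — which completes in a few seconds; the
parameter-recovery check uses n = 5000 × 100 replicates; the binormal CV
oracle uses n = 200/200 averaged over five independent draws, since one
draw's empirical AUC carries ±0.025 sampling noise.

## Known limitations

* With two features and n ≈ 100 the Wald intervals are adequate but
  slightly liberal near separation; profile likelihood is available.
* The Hanley–McNeil interval is data-free given the AUC and group sizes;
  for very small validation sets (20/20) it is narrower than
  resampling-based intervals.
* The S/N rule assumes a per-metabolite summary; a per-sample rule would
  interact differently with the missingness filter.
* Reciprocal-pair deduplication keeps the first-sorted orientation, which
  depends on rank order, not on biology.
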