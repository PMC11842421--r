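---
title: "Methods: an untargeted MWAS workflow for newborn dried blood spots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an untargeted MWAS workflow for newborn dried blood spots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`mwasdbs` implements a metabolome-wide association study (MWAS) workflow
for untargeted LC-HRMS profiles of archived newborn dried blood spots,
with maternal smoking as the exposure of interest. The pipeline runs in
fixed order:

1. feature-level quality control and replicate summarization,
2. log2 transformation, per-batch centering, auto-scaling, kNN imputation,
3. exposure classification from nicotine-metabolite biomarkers,
4. covariate residualization,
5. PLS-DA with VIP feature selection and fold changes,
6. per-feature logistic regression with BH-FDR,
7. adduct-based annotation (confidence levels 1 and 4),
8. mummichog-style pathway enrichment (EASE score, gamma-modelled
   permutation null).

Because the motivating blood-spot data are access-restricted, the package
ships a first-class synthetic-data generator whose defaults encode the
study design, so every stage is testable end to end.

# Data model and quality control

A feature table holds one chromatography mode (HILIC with positive ESI or
C18 reversed phase with negative ESI): rows are (m/z, retention time)
features inside the instrument scan range m/z 85–1275, columns are
injections — three technical replicates per sample, analyzed in batches of
at most 40 samples. Missing intensities are `NA` in memory and empty cells
on disk; a zero is a measured value, never a missing sentinel.

QC retains a feature when all three hold (strict inequalities):

* **missingness < 30%**, counted at the sample level: a sample is missing
  only when all three of its replicates are absent;
* **median replicate CV < 30%**: per sample, CV = sd/mean of the observed
  raw (pre-log) replicates using the n−1 standard deviation, skipping
  samples with fewer than two observed replicates; the median is taken
  across samples;
* **median replicate Pearson r > 0.7**: for each replicate pair (1–2,
  1–3, 2–3) the correlation across samples over co-observed entries, then
  the median of the three.

The Pearson filter admits several readings (per-feature vs per-injection;
which entries enter each correlation). We chose the per-feature,
across-sample, median-of-three-pairs reading because it is well defined
for every feature and degrades gracefully under missingness; features for
which it is undefined fail QC.

Retained features are summarized per sample by the median of observed
replicates, log2 transformed (zeros first replaced by half the smallest
positive observed value of the feature — the standard half-minimum rule;
the sources are silent on zeros), centered by the per-batch median, and
auto-scaled to mean 0, sd 1 over observed entries. Per-batch **median
centering replaces the wavelet-based batch correction** used upstream of
the original feature tables: it is deterministic, testable, and removes
additive batch offsets exactly, but it does not model within-batch drift.

Missing entries of the auto-scaled matrix are imputed by kNN in feature
space (k = 10): candidate neighbours are features observed at the target
sample sharing at least one co-observed sample; distances are Euclidean
over co-observed samples normalized by their count; the imputed value is
the inverse-distance-weighted mean of the k nearest candidates (a
zero-distance neighbour is used directly). Observed entries are never
altered.

# Exposure classification

Cotinine (m/z 177.1023) and hydroxycotinine (m/z 193.0973) are extracted
from the raw summarized HILIC table by accurate mass (±5 ppm, nearest
wins) **before** QC filtering — both biomarkers are undetected in most
newborns and would never survive the 30% missingness filter. A mother is
classified as a smoker when any indicator fires:

* reported smoker on the birth record;
* cotinine detected (any non-absent summarized intensity);
* hydroxycotinine at or above the 86th percentile (top 14%) of all
  samples' values, with absent treated as 0 so that non-detects
  participate in the ranking; ties at the cutoff are included. A sample
  with no detected hydroxycotinine can never be flagged "high" even if
  more than 86% of samples are non-detects (the cutoff would then be 0 and
  the literal rule would flag everyone); the implementation adds this
  guard explicitly.

The two biomarker features are excluded from all discovery stages: they
define the outcome, and leaving them in X would let them dominate the
PLS-DA direction trivially.

Cohort bookkeeping reports overall prevalence (integer percent),
per-indicator percentages of all samples (1 decimal, overlapping counts),
the exclusive counts under the priority report > cotinine >
hydroxycotinine (the published indicator counts overlap: they sum past
the smoker total), and per-stratum column percentages within smokers and
non-smokers over non-missing values.

# Covariate adjustment

Confounders — maternal race/ethnicity (3 levels), maternal age band (5),
birth-year band (3), infant sex, and neighbourhood SES (5 levels) — enter
through a treatment-coded design matrix with intercept; each feature is
regressed on the design by OLS and replaced by its residuals. The
reference level is the first listed level of each factor; residuals do
not depend on that choice. Residualization happens after imputation (OLS
needs complete data; the source order is ambiguous), and the full order
is log2 → batch-center → auto-scale → impute → residualize. Education and
BMI are deliberately not adjusted for (high missingness in the source
records).

# PLS-DA, VIP and fold change

The discriminant analysis is NIPALS PLS1 on the single centered class
indicator: for components a = 1..A (default A = 2),

    w_a = X'y / ||X'y||,   t_a = X w_a,
    p_a = X't_a / (t_a't_a),  b_a = y't_a / (t_a't_a),
    X <- X - t_a p_a',     y <- y - b_a t_a,

with explained-Y sum of squares SSY_a = b_a² (t_a't_a). PLS1 on one
centered column is equivalent to two-class PLS-DA with dummy coding but
avoids the dummy-matrix ambiguity. Weights are sign-fixed so every score
correlates non-negatively with the class, making outputs run-stable.

VIP_j = sqrt( p Σ_a SSY_a w_ja² / Σ_a SSY_a ), so Σ_j VIP_j² = p. Features
with VIP ≥ 2 are selected. The number of components for VIP is not stated
in the source; A = 2 matches the two plotted latent variables and is
configurable. Fold change is 2^(smoker mean − non-smoker mean) of the
covariate-adjusted log2-scale intensity, obtained by back-mapping the
imputed auto-scaled matrix to the log2 scale (x·sd + mean) before
residualizing.

# Association testing

Each selected feature is tested by univariate logistic regression of
smoking status on its adjusted intensity, fitted by IRLS (|Δβ| < 1e-8,
at most 100 iterations), Wald p from β/se. Confounders enter through the
prior residualization, not as model terms, matching the two-stage
description of the source analysis. Perfect separation is flagged, the
row excluded from FDR, and no Firth-style rescue is attempted.
Benjamini–Hochberg FDR is computed within each chromatography mode (the
source treats modes separately in its per-mode figures; pooling is a
one-line change). The Manhattan export lists −log10 p against retention
time, marks direction, labels the 20 smallest p-values and annotates
p < 0.001.

# Annotation

Level 1 (confirmed): features are matched against an authentic-standard
mini-library within ±5 ppm and ±15 s; the nearest-ppm entry is primary.
The packaged library carries the 17 confirmed metabolites plus the two
biomarkers; biomarker retention times are synthetic placeholders (no
published value) and are flagged as such in the file. Level 4
(tentative): features are matched to formula masses over the mode's
adduct list — [M+H]+, [M+Na]+, [M+NH4]+, [M+H−H2O]+, [M]+ in positive
mode; [M−H]−, [M+Cl]−, [M−H2O−H]− in negative — within 10 ppm, no RT
constraint. The correlation-modularity annotation score of the original
toolchain is out of scope; a simple adduct-support count (how many
distinct adducts of the metabolite have a matching feature) is attached
instead and is explicitly not equivalent.

# Pathway enrichment

Following the mummichog idea, enrichment runs directly on m/z features:
every selected feature maps to all pathway metabolites whose adduct
masses fall within 10 ppm (ambiguity preserved); the detected-feature
mapping defines the metabolite universe N and each pathway's mappable
size m. The overlap k of significant-list metabolites with the pathway is
scored by the EASE statistic — the hypergeometric right tail
P(X ≥ k−1) — whose one-hit removal sends k ≤ 1 to p = 1. The null is
built by resampling feature lists of the same size from all detected
features (P = 100 by default; the source does not state its count),
pooling all pathway-permutation EASE p-values (a single pool across
pathways, matching the single fitted distribution described by the
source), and fitting a gamma distribution by maximum likelihood with
location 0 on values clipped to [1e-12, 1]. Observed EASE p-values are
converted to adjusted p-values on the fitted gamma CDF; pathways with
k ≥ 3 are reported, and adjusted p < 0.05 is flagged significant.

**A caveat the tests document rather than hide:** at desk scale most
resampled lists map 0 or 1 significant metabolites per pathway, so the
pooled null is dominated by an atom at exactly 1.0. No continuous gamma
can sit within Kolmogorov distance 0.15 of such a pool
(`null_model_ks()` measures ≈ 0.5 at the default scale). The gamma
conversion is kept because it is the published method and its *decisions*
remain well calibrated here — small EASE values are rare under the null,
so the flag rate at adjusted p < 0.05 stays far below 5% — but adjusted
p-values near the bulk of the pool should not be over-interpreted. A pool
whose values are all identical triggers an explicit empirical-quantile
fallback.

# The synthetic world

`sim_config()` encodes the stated study design; `simulate_mwas()` draws
everything from one RNG stream keyed by the seed.

* **Design**: 900 newborns, 2000 features per mode, triplicate
  injections, batches of 40 with additive per-batch log2 offsets
  (sd 0.3).
* **Intensities**: per-feature baseline log2 level ~ N(17, 2.5),
  biological sd ~ U(0.4, 1.2); replicate noise is multiplicative with
  per-feature CV ~ U(0.10, 0.40) so realized median CVs straddle the 30%
  QC threshold (the triplicate CV estimator shrinks the generating CV by
  ≈ 0.8, so the realized upper tail is thin — the filter rejects some but
  not most features, as intended).
* **Missingness**: left-censoring, P(missing) = plogis(11 − 0.8·log2
  intensity) per injection — monotone non-increasing in intensity, mean
  ≈ 13%, with low-abundance features exceeding the 30% filter.
* **Exposure**: a latent nicotine-exposed fraction (16.5%) trips three
  overlapping indicators — birth-record report (12% of exposed), cotinine
  detection (50% of exposed), and a heavy-tailed hydroxycotinine channel
  detected in ≈ 20% of all samples with a +3 log2 shift in the exposed —
  calibrated once so the union rule lands at ≈ 17% classified prevalence.
  The published per-indicator shares (1.9/7.0/10.4%) are emulated in
  spirit, not matched exactly. Covariates are drawn per exposure stratum
  from the published stratum frequencies, so confounding is present and
  residualization is exercised.
* **Biomarker channels are noise-free**: identical replicates, no batch
  offset, no censoring. This makes classification recover the generated
  truth exactly, which the oracle-equivalence tests rely on; it is the
  one deliberate departure from realism in those two rows.
* **Planted signal**: 60 features per mode receive a log2 shift of
  magnitude U(0.5, 1.5) in exposed samples (80% positive); six of them
  carry the [M+H]+ masses of metabolites of the planted pathway
  ("Vitamin A (retinol) metabolism" in the packaged synthetic database)
  and draw their effects from the upper part of the range (≥ 2/3 of the
  maximum), representing a strongly perturbed pathway so the
  end-to-end enrichment recovery is a test of the pipeline, not of
  borderline power.

What a green synthetic test establishes: the pipeline's stages compose
correctly, planted effects of the stated size are recovered at the stated
rates, and the nulls are calibrated. What it does not establish: realism
of intensity distributions (the sources publish none), correlated feature
structure (features are independent given exposure and batch),
within-batch drift, isotope envelopes, or adduct co-occurrence patterns.

# Numerical choices

* Proton mass 1.007276 Da; electron mass accounted for in sodiated,
  ammoniated, chlorinated and intact-cation adducts; atomic masses to
  ≥ 6 decimals.
* ppm error = 1e6 (observed − theoretical)/theoretical.
* IRLS weights floored at 1e-12; separation flagged at |β| > 1e3 or a
  saturated fit that did not converge.
* Gamma MLE solves log(α) − ψ(α) = log(mean) − mean(log) by uniroot from
  the standard closed-form starting value.
* Auto-scaling uses the n−1 standard deviation; constant features are
  dropped with a report entry.
* Quantiles use R's default type-7 definition (the top-14% worked example
  with ranks 1..100 yields exactly 14 flags).

# Known limitations

* Single-predictor logistic models only; no multi-feature or interaction
  models.
* BH-FDR assumes the usual positive-dependence conditions; features here
  are independent by construction, real features are not.
* The permutation count default (P = 100) is desk-scale; raise it for
  stable tail quantiles in real analyses.
* Annotation confidence is mass (+RT) based only; no isotope-pattern or
  MS/MS evidence.
* The CLI covers simulation and the full pipeline; individual stage
  subcommands are exposed programmatically rather than as separate shell
  verbs.
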