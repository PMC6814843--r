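---
title: "Methods: synthetic phantoms, the 271-feature bank, stability selection, consensus clustering and cross-validated Cox modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctradiomics)
```

This vignette records the models, conventions and numerical choices
behind `ctradiomics`, in the order the pipeline runs them. It states no
empirical result: the numbers the package produces come from the test
suite, the `analysis/` scripts and `scripts/acceptance.R`.

## Synthetic phantoms and cohorts

**What the generator emulates.** A non-contrast planning CT of a pelvic
tumor: an ellipsoidal ROI (semi-axes ~9–14 mm by default) on a grid with
1.12 mm voxels, mean intensity ~40 HU over a −70 HU background, with two
separable noise sources — a *correlated* Gaussian texture field
(standard deviation `texture_sd`, default 30 HU) representing intratumor
heterogeneity, and white scanner noise (`noise_sd`, default 10 HU,
consistent with a 120 kVp abdominal protocol). The texture field is
white noise circularly convolved with a Gaussian kernel of standard
deviation `texture_corr_length_mm`, centered and standardized; the
correlation length is the single heterogeneity dial, chosen because the
homogeneity-indexing features this class of study selects (run
percentage, gray-level nonuniformity) respond monotonically to it.

*Test-retest pairs* share the texture field and differ by independent
scanner-noise draws plus an optional whole-voxel rigid shift — the
repeat-scan situation. *Recontour pairs* displace the mask boundary
along its normal by a smooth random field (amplitude `boundary_sd_mm`,
correlation length 10 mm: observers disagree over boundary segments, not
voxels). The signed distance to the boundary is approximated from a
Gaussian-smoothed mask indicator (`d ≈ −σ·qnorm(g)`, σ = 2·max spacing),
which works for arbitrary mask shapes; displacements are saturated at
5σ, beyond which the approximation carries no geometry. No quantitative
inter-observer figure exists to calibrate against, so `boundary_sd_mm`
defaults to 1 mm — chosen once to produce Dice overlaps around 0.85,
the range typically reported for rectal tumor delineation — and the
selection thresholds are never tuned to it.

*Survival cohorts* follow a Weibull proportional-hazards law: log-hazard
= clinical effects · dummy covariates + `radiomic_effect` · latent
texture value; shape 1.2 and baseline median 60 months emulate a locally
advanced rectal-cancer OS scale, with per-endpoint baseline medians
(LC 1.4×, DC 1.2×, DFS 0.75× the OS median) and independent draws per
endpoint. Administrative censoring is uniform on (0, τ) with τ solved at
run time so the realized censored fraction matches `censor_rate`
(default 0.3). Clinical marginals (≈2/3 male, 80% cT3, nodal involvement
common, modest positive log-hazards 0.2–0.5) are fixed defaults, not
fitted values. `simulate_feature_cohort()` generates the same phenotype →
features → hazard structure directly at feature level for replicate
studies where re-rendering images would only add runtime.

**What it does not emulate:** CT physics (beam hardening, artifacts),
anatomy, non-ellipsoidal growth, scanner-protocol batch effects, or
informative censoring. Passing tests therefore demonstrate correctness
and calibration of the *pipeline*, not clinical performance on real
images.

## Discretization and the feature bank

Second-order features use a fixed **number** of bins (128) spanning the
ROI min–max range, the reading of "128 discretization" as a level count;
the maximum intensity maps into the top bin, a constant ROI collapses to
level 1 with a warning. Fixed-bin-count makes every second-order feature
invariant to positive affine rescaling of the intensities, which the
test suite asserts. No resampling or smoothing precedes extraction.

The manifest (`inst/extdata/feature_manifest.csv`) is configuration, not
code: 63 original-channel features (15 first-order, 8 shape, 24 GLCM,
16 GLRLM) plus 52 per wavelet sub-band (13 first-order, 23 GLCM,
16 GLRLM) × 4 = 271. The published feature list for this bank size is
not public, so the composition is the package's own; being a file, it
can be corrected without touching code. Notable conventions:

- GLCM: distance-1 offsets; 13 unique 3D directions on the original
  channel, 4 in-plane on sub-bands; symmetrization before normalization;
  directions aggregated by averaging normalized matrices. The GLCM
  family includes a marginal gray-level nonuniformity (`GLCM_GLN` =
  Σ p_x(i)², the co-occurrence analogue of the run-length GLN) because
  wavelet-GLCM-GLN features are exactly what such studies report; both
  matrix-type GLN formulas exist and the manifest disambiguates.
- GLRLM: runs break at the ROI boundary; Σᵢⱼ r(i,j)·j equals the ROI
  voxel count per direction (asserted on random phantoms); per-direction
  features are averaged.
- Wavelet: single-level slice-wise 2D Haar — the two-letter sub-band
  names (LL…HH) imply a 2D transform, and Haar is the minimal orthogonal
  basis, giving an exact Parseval check. Sub-band masks take a 2×2
  block-OR, so the ROI never vanishes at half resolution.
- Degenerate values use 0·log 0 = 0; dispersion features of a constant
  ROI are 0 with a `degenerate` flag.
- Surface area uses a coarea estimator (integral of |∇| of the smoothed
  indicator, σ = max spacing) rather than voxel-face counting, which is
  staircase-biased ~50% upward. Accuracy on voxelized balls is within
  ~1%; because the voxel-count volume is biased slightly *up* while the
  area is biased slightly *down*, sphericity of a ball can exceed 1 by
  ≲3%.

## Stability selection

Spearman correlations use midranks; an undefined coefficient (constant
feature) conservatively fails the filter. The criteria are ρ_pair > 0.7
and |ρ_volume| < 0.8 — the absolute value because anti-correlation with
volume is equally a volume surrogate — with ρ_volume computed on the
first pair member (scan 1 / contour 1; recorded in the report metadata,
since the convention is not standardized). "Combining" the retest and
recontour selections is set intersection: a feature must be robust to
both perturbation sources.

## NMF consensus clustering

Features are min-max scaled to [0, 1] (NMF needs nonnegativity; the
scaling choice is otherwise free and recorded here). Factorization is
Lee–Seung multiplicative updates on the Frobenius loss, whose monotone
non-increase is asserted per restart. The rank survey runs 20 restarts
per rank over 2–6 by default (2–4 in the demo analysis), builds
consensus matrices from dominant-component co-assignment, resamples
degenerate restarts (empty component) with fresh seeds, and selects the
rank with the highest cophenetic correlation of average-linkage
clustering on 1 − consensus; the full survey table is always emitted
because rank choice from consensus maps is conventionally a human call.
Cluster labels come from cutting the same dendrogram at the chosen rank,
so they are deterministic given the consensus matrix. Chi-square tests
use no continuity correction (so a covariate identical to the labels
scores statistic = n); zero-margin categories are dropped with a
warning. Kaplan–Meier and log-rank use `survival`'s standard
product-limit and hypergeometric-variance conventions.

## Cross-validated Cox modeling

Folds are random but stratified by the event indicator, avoiding
event-free folds. Within each training fold, in order: greedy
correlation filtering (drop the member of the worst |r| > 0.95 pair with
the larger mean absolute correlation; ties keep the earlier column —
deterministic given column order), median imputation with training-fold
medians only, univariate screening (log-rank for discrete variables, Cox
Wald for continuous, p < 0.05), and backward-stepwise AIC. The
"AIC" penalty is the standard k = 2; because descriptions of stepwise
rules are often ambiguous on this point, k is exposed as `aic_k`
(k = 1 selectable). Cox fits use Breslow ties throughout — after
128-level discretization tied times are common. Clinical covariates are
dummy-coded before modeling so held-out folds can never contain unseen
factor levels.

Harrell's c-index counts pairs in which the earlier observed time is an
event; tied risks score 0.5; the implementation is hand-written,
pair-exhaustive and cross-checked against `survival::concordance` in the
tests. Fold summaries use normal-approximation 95% intervals
(mean ± 1.96·SE over folds) — the CI method is not standardized for this
design, and the per-fold values are returned so any other summary can be
formed. When a majority of folds select no variable the report says "no
model can be established" rather than erroring: endpoints with few
events legitimately yield no model. The paired clinical-vs-combined
comparison is a t-test over held-out-fold c-indices (test folds, not
train); identical per-fold values give p = 1, and a zero-variance
nonzero shift is reported below machine precision rather than dividing
by zero. The nomogram export maps each selected variable's coefficient
range to a 0–100 point scale and tabulates total points against Breslow
baseline survival at 12/36/60 months; graphics are intentionally out of
scope.

## Problem sizes and determinism

Every stochastic artifact takes an explicit integer seed, and reruns are
byte-identical (asserted for the full pipeline). The shipped sizes are
deliberate: demo phantoms are 32³ voxels (feature extraction ~0.3 s
each), the analysis cohort has 80 patients with 15-patient retest and
recontour sub-studies, and the replicate-level recovery and calibration
studies use feature-level cohorts of 400 patients — the scale of the
motivating study design — with 50 (clustering) and 20 (cross-validation)
replicates. Image-level end-to-end behavior is exercised once per run
rather than per replicate, because re-rendering hundreds of phantoms
would test the random number generator more than the pipeline.

## Known limitations

- The phantom is stationary-Gaussian inside an ellipsoid; real tumors
  have structured sub-regions, necrosis and infiltrative margins, so
  absolute feature values are not comparable to clinical data.
- The signed-distance approximation behind the recontour generator is
  accurate only within a few voxels of the boundary; very thin or
  filamentous ROIs would be distorted.
- The feature manifest reproduces the *size and family structure* of the
  original bank, not its exact (unpublished) membership.
- The wavelet transform is slice-wise 2D; through-plane texture at
  half-resolution is not represented.
- `rank_survey` scores ranks by cophenetic correlation alone; other
  criteria (dispersion, silhouette) are not implemented.
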