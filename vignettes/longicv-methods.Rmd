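---
title: "Methods: two-step cross-validated brain-behaviour prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-step cross-validated brain-behaviour prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(longicv)
```

This vignette is the package's own account of its statistical machinery:
the models, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, the numerical
choices, and the design decisions that were genuinely open.

## The problem

Correlating a behavioural change with a structural brain change in the
*same* subjects that were used to find the responsive region inflates
the apparent effect ("circularity", "double dipping"). Cross-validation
removes the bias by splitting subjects into a training set that selects
the region and a validation set that supplies the prediction. With a
small cohort (n = 33 here), the two extreme k-fold schemes — k = n
(Leave-One-Out) and k = 2 (split-half) — can behave very differently,
and quantifying that difference is the point of this package.

## Step 1: the longitudinal GLM

Each subject contributes two scans. The design has one indicator per
subject (absorbing the subject's mean density), a time covariate
$\tau \in \{-1, +1\}$, and per IQ measure an encoded change covariate
equal to $-\Delta$ at Time 1 and $+\Delta$ at Time 2. Because the
encoded covariates sum to zero within subject, they are orthogonal to
the subject indicators, and the whole 2n-row fit collapses algebraically
to a regression of the within-subject difference image on
$(1, \Delta_{VIQ}, \Delta_{PIQ})$ — an equivalence the test suite
verifies voxel-by-voxel against `lm()` at $10^{-8}$. Error degrees of
freedom are $n - 3$ either way. The encoded covariate uses $\pm\Delta$
(not $\pm\Delta/2$); the Step-2 prediction regression is scale-free, so
this convention cannot alter any reported $R^2$.

Inference is one-sided per contrast: $(0,1,0)$ and $(0,0,1)$ for the
two measures, $(0,1,-1)$ and $(0,-1,1)$ for their difference. Reported
z-scores map the one-sided t p-value through the standard-normal
inverse, computed in log-p space; a zero-residual (noise-free) voxel
reports an infinite t and a z capped at 38.

## Multiple-comparison control

Whole-brain correction at the 5% family-wise level uses sign-flipping
permutation on the subject difference images: under the null the
subject-level relation between density change and the encoded covariate
is sign-symmetric (the shared time effect is absorbed by the difference
model's intercept, which never flips), so each permutation negates each
subject's covariates at random and records the maximal voxel t
(*height*) and the maximal supra-threshold cluster size (*extent*). The
observed map is included as the first permutation, which makes the test
exact rather than approximate; a cluster is selected when it beats the
95th-percentile critical value in height **or** extent. Random-field
theory, which the field's standard software uses for this step, needs
smoothness estimation that is out of proportion for a 32-cubed synthetic
grid and is not what this package studies; a Bonferroni height threshold
(`correction = "bonferroni"`) is provided as a cheap, more conservative
alternative and is used in some of the heavier simulation tests.

Cluster-forming thresholds default to one-sided p < 0.001 for VIQ and
p < 0.01 for PIQ; the source material is internally inconsistent about
these two values (its figure caption and its results table disagree), so
both are plain configuration (`forming_p`) and neither is asserted as
canonical. Connectivity defaults to 26-neighbour (18, the SPM
convention, and 6 are also supported and recorded in output).

A VIQ cluster must additionally show a VIQ-minus-PIQ difference at
p < 0.01 uncorrected (symmetrically for PIQ). Whether this conjunction
should be assessed at the peak voxel or over the whole cluster is not
specified by the procedure this package re-implements; the peak voxel is
used, and the difference t and p at the peak are reported per cluster so
a user can audit the choice.

When nothing survives correction — the typical outcome for half-sample
training sets — and a search mask is supplied, the most significant
contiguous supra-threshold cluster inside the mask is selected instead
(basis `search-space-max`), degrading to the mask's single peak voxel if
no voxel passes the forming threshold, so the fallback always returns a
selection. The `type2` flag records that correction failed, *before* the
conjunction: "type II" means the corrected search found nothing. The
fallback does not re-apply the conjunction, since its contract is a
non-empty selection.

## Step 2: prediction

Leave-One-Out: for each held-out subject, the training regression
`change ~ density` at the selected peak is applied to the held-out
subject's density change; across the n folds, the out-of-sample $R^2$ is
the squared correlation between predicted and measured change (the
package regresses measured on predicted, and asserts the identity with
the squared correlation on every run). Time 2 IQ is predicted by a joint
training-set OLS `t2 ~ t1 + density` — a residualised two-stage variant
would be an alternative; the joint fit is the implemented choice.

Split-half: region selection is out-of-sample (trained on the other
half) but the Step-2 regression parameters are estimated *within* the
test half, deliberately reproducing the asymmetry of the procedure this
package characterises; its hierarchical pair `t2 ~ t1` then
`t2 ~ t1 + density` yields a non-negative within-sample increment by
construction, which the suite asserts for every analysis. Stratification
ranks subjects on a full-scale-IQ proxy — the mean of the four printed
scores (VIQ and PIQ at both time points), since the original full-scale
score is not part of the published table — median-splits into high/low,
and randomly halves each stratum, the odd stratum's extra subject going
to the currently smaller group (coin flip on ties), so group sizes are
always {16, 17} at n = 33. Duplicate partitions across the 25 repeats
are permitted (they are not excluded by the procedure being emulated)
and can be detected from the run's fold table.

Degenerate folds (no selection without a mask, or zero training density
variance at the peak) are flagged, excluded from aggregation, and
counted in a warning — never silently dropped.

## The synthetic cohort

Real scans behind the original analysis were never published, so the
generator stands in for them with known ground truth:

$$GMD(i,t,v) = \mathrm{baseline}_i(v) + a(v)\,\tau_t + b_V(v)\,e_V(i,t)
  + b_P(v)\,e_P(i,t) + \varepsilon(i,t,v)$$

* behavioural tables are bivariate-normal per measure, parameterised by
  the reference cohort's marginals (Time 1 mean 113/108, SD 15.1/12.3,
  retest r 0.81/0.59, change mean 3.1/−0.9, change SD 10.6/10.2), with
  the Time 2 SD implied by those five numbers (it lands on the observed
  18.0/9.6), scores rounded to whole IQ points;
* the default grid is 32³ voxels at 4 mm — desk scale; a 1.5 mm
  whole-brain grid adds nothing to method validation — with 8 mm FWHM
  isotropic smoothing applied to the noise, matching the preprocessing
  the pipeline assumes, so the voxel noise is spatially autocorrelated
  and cluster inference is non-trivial;
* planted effects are two disjoint 27-voxel boxes (one per measure)
  with constant slope b in density units per encoded-IQ-point;
  `noise_sd` (default 0.02) is the pre-smoothing white-noise SD, and
  `noise_sd_effective()` measures the post-smoothing SD empirically from
  a noise-only simulation;
* subject baselines are smooth low-order random fields (white noise
  smoothed at twice the analysis FWHM, standardised to mean 0.5,
  SD 0.05), identical at both time points, so they cancel exactly in the
  difference images, as subject indicators make them cancel in the GLM;
* `theoretical_r2()` gives the peak proportion of density-change
  variance explained, $\mathrm{Var}(2bd)\,/\,(\mathrm{Var}(2bd) +
  2\sigma_{\mathrm{eff}}^2)$, and `slope_for_r2()` inverts it, so
  cohorts can be planted at a chosen effect size.

What the generator does **not** emulate: cortical anatomy, segmentation
and normalisation artefacts, site effects, non-Gaussian noise, or any
spatial structure in the age effect beyond a configurable map. Passing
tests therefore demonstrate that the *procedure* behaves correctly under
its own assumptions, not that real developmental data satisfy them.

One consequence of the smoothed noise is worth stating: within one
simulated dataset the whole planted region shares, per subject, an
effectively common noise draw, so the *realised* peak R² of a given
dataset scatters substantially around its theoretical value at n = 33
(roughly ±0.15). Comparisons between cross-validation schemes are
therefore designed as paired contrasts on a fixed dataset, letting seeds
vary only the schemes' internal randomness (partitions, permutation
draws); re-simulating the volumes per seed would confound
scheme-induced variability with between-dataset sampling noise, which
exhaustive Leave-One-Out — deterministic given the data — does not have.

## Numerical choices

* Gaussian smoothing is a separable truncated kernel (3σ), with rows
  renormalised so constants are preserved at the edges.
* Connected components use an explicit flood fill; the cluster peak is
  the maximal-t voxel, ties broken by the smallest linear index
  (x fastest), so extraction is independent of visit order.
* Permutation critical values are the ⌈0.95·n_perm⌉-th order statistic
  of the max distribution; exceeding it strictly has probability at most
  5% under exchangeability. `n_perm` must be ≥ 100.
* All voxel coordinates in user-facing tables are 0-based; world
  coordinates come only from the stored voxel size/affine.
* Every source of randomness flows from one master seed through
  purpose-tagged sub-seeds (`derive_seed()`), recorded in the run
  manifest, so runs reproduce bit-identically.

## Problem sizes

The shipped test suite validates behaviour at sizes chosen for a
single-CPU desk run: structural counts and parameter recovery on a 16³
grid (33 subjects, 100 permutations per training analysis); family-wise
error on 25 null cohorts at 10³; the scheme comparison over 10 scheme
seeds at 16³ with a cohort planted at peak R² 0.58 (VIQ) and 0.38
(PIQ) — the effect sizes the original in-sample analysis reported. The
acceptance script runs both schemes at the full 32³ default with 200
permutations per analysis.

## Known limitations

Single-peak, single-region prediction only (no multivariate or
multi-region models); no F-tests, covariate interactions or
non-sphericity handling; no random-field correction; k-fold for
2 < k < n is not implemented; the split-half Step 2 is within-sample by
design, so its R² values are not directly comparable to the
Leave-One-Out out-of-sample values — the package reports both and the
scheme comparison is explicit about which is which.
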