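---
title: "Predicting cochlear-implant language outcomes from contrast maps: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cochlear-implant language outcomes from contrast maps: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bowsvm)
```

## The problem

Infants with severe congenital sensorineural hearing loss can receive a
cochlear implant (CI), but roughly a third of recipients do not develop the
expected language skills. `bowsvm` implements a machine-learning pipeline
that predicts, from a candidate's *pre-implant* auditory fMRI contrast
t-maps, whether the child will be an *effective* or *ineffective* CI user
two years after surgery. The pipeline has five stages:

1. **Outcome labels.** Two years post-implant, each followed-up recipient
   has five CELF-P2 standard scores (each in 45–155). The five scores are
   highly correlated, and their sums fall into two well-separated groups;
   2-means clustering of the score vectors assigns the binary
   effective (+1) / ineffective (−1) labels. Recipients without follow-up
   scores stay unlabeled but are still usable by the semi-supervised model.
2. **Bag-of-words (BoW) featureization.** Each subject contributes one 3-D
   contrast t-map per stimulus contrast (speech vs. silence, noise vs.
   silence, speech vs. noise). Maps are thresholded at the Student-t
   quantiles for one-sided p ∈ {0.05, 0.025, 0.01, 0.005, 0.0025, 0.001,
   0.0005} at 60 degrees of freedom — 1.671, 2.000, 2.390, 2.660, 2.915,
   3.232, 3.460 — giving seven positive contrast ranges
   [1.671, 2.000), …, [3.460, ∞) and seven mirrored negative ranges
   (−∞, −3.460], …, (−2.000, −1.671]. Within each (subject, range), the
   selected voxels are split into maximal 26-connected components; every
   component is a *word*, and all words harvested across the builder
   cohort form a *dictionary*. A subject's feature vector has one entry
   per word: the mean of their map over the word's fixed template-space
   voxels. The voxel-wise baseline (`VOX`) uses each in-mask voxel as its
   own feature.
3. **Models.** A soft-margin linear SVM (`train_supervised()`), and a
   semi-supervised (transductive) linear SVM (`train_semisupervised()`)
   that also consumes the unlabeled subjects under a constraint that a
   fraction `r` of them is positive.
4. **Feature selection.** Recursive feature elimination: repeatedly train,
   rank features by |w|, drop the lowest 1% (one at a time below 100
   features) until a target count remains.
5. **Evaluation.** Leave-one-out cross-validation (LOOCV) over the labeled
   subjects; nested LOOCV when `r` must be selected; sensitivity,
   specificity, accuracy, the F-measure (harmonic mean of sensitivity and
   specificity), rank-based AUC, and Pearson/Spearman correlations between
   held-out decision scores and the CELF-P2 score sums.

## The semi-supervised objective and its training loop

The supervised model minimizes

$$\tfrac12\lVert w\rVert^2 + C\sum_{i=1}^{M}\xi_i,\qquad
  y_i(wX_i+b)\ge 1-\xi_i,\ \xi_i\ge 0 .$$

The semi-supervised model adds the $K$ unlabeled samples with their own
slack penalty and a positive-fraction constraint:

$$\tfrac12\lVert w\rVert^2 + C\sum_{i=1}^{M}\xi_i + U\sum_{j=1}^{K}\xi^*_j,
  \qquad \tfrac1K\sum_j \max(0, y^*_j) = r .$$

Training proceeds in three steps: (1) fit the supervised model and assign
+1 to the `round(K·r)` unlabeled samples with the highest decision scores;
(2) with a temporary penalty `U_tmp`, refit on all samples and, while some
(+1, −1) pair of unlabeled samples has both slacks positive and summing
above 2, switch the pair whose swap gives the maximal objective drop and
refit; (3) raise `U_tmp` geometrically and repeat until `U_tmp ≥ U`.

Design choices the published description leaves open, and how this package
resolves them:

* **The switching rule.** We adopt the classic transductive-SVM criterion
  ($\xi^*_+>0$, $\xi^*_->0$, $\xi^*_+ + \xi^*_- > 2$), which guarantees
  that the swap can lower the objective; among eligible pairs we evaluate
  the swap exactly (refit) and take the maximal drop, accepting only
  strict decreases. This makes the objective trace non-increasing within
  each `U_tmp` stage by construction, a property the test suite asserts.
* **Annealing schedule.** `u_anneal_start = 1e-5·C`, doubling each stage
  (`u_anneal_factor = 2`), capped at `U`. Both are configurable in
  `training_config()`. `U = C` and `C = 1` are the defaults used
  throughout.
* **Rounding.** `round(K·r)` uses half-away-from-zero rounding; at the
  study's K = 7, r = 0.6 this gives 4 positives, the case the tests pin.
* **Determinism.** The SMO solver, the initial assignment (score ties
  broken by row order), and the switching loop are fully deterministic, so
  every cross-validation result is reproducible without seeds.

The quadratic subproblems are solved by a sequential-minimal-optimization
solver (in C++) over the dual with *per-sample* box constraints — labeled
samples are capped at `C`, unlabeled ones at the current `U_tmp`. On small
instances its objective agrees with an exact KKT active-set enumeration to
better than 1e-6 (asserted in the tests at n = 8, where enumeration over
all 3^8 bound patterns is exact).

## Feature extraction choices

* **Boundary conventions** follow the printed interval notation: positive
  ranges are `[lo, hi)`, negative ranges `(lo, hi]`. A value of exactly
  2.000 falls in [2.000, 2.390); −2.000 falls in (−2.390, −2.000].
* **Thresholds** are recomputed from `qt()` and asserted equal to the
  printed values at 3 decimals; df = 60 is treated as a constant of the
  method.
* **Words are fixed voxel sets.** Applying a dictionary to a new subject
  averages that subject's map over each word's own coordinates, regardless
  of the new map's thresholds — all maps are assumed normalized to a
  common template. Extraction is therefore linear in the map.
* **Minimum word size** defaults to 1 voxel (no floor is stated for the
  method); it is configurable in `build_dictionary()`.
* **Dictionary order** is builder subject, then range, then smallest
  voxel, so dictionaries are append-only in the builder cohort and
  reproducible. Duplicate words from different subjects are kept — the
  resulting feature redundancy is intrinsic to the approach and is what
  the 0.99-correlation merge in `selection_frequency()` addresses.
* **VOX mask** is the intersection of the subjects' finite-value masks.

## What the synthetic cohort emulates

No imaging data were deposited with the study this package re-implements,
so the package ships a generator (`generate_cohort_maps()`) whose defaults
mirror the study conditions: 21 normal-hearing controls and 23 implant
candidates — 9 labeled effective, 7 labeled ineffective, 7 unlabeled — each
with one contrast map. Maps live on a 24×24×24 grid (the real data had
26,767 in-mask voxels; the smaller grid keeps tests fast while preserving
26-connectivity topology and is configurable upward). Two spherical
regions of radius 3 carry the group signal; voxelwise Gaussian noise
(SD 5) is added and the map is smoothed with a 2-voxel-FWHM separable
Gaussian, calibrated so the post-smoothing marginal noise SD is close to 1,
as in a unit-variance t-map with realistic spatial autocorrelation.

The default effect amplitudes make the two regions complementary:
effective users respond strongly in region 1 (amplitude 4) and weakly in
region 2 (amplitude 1); ineffective users are mirrored; controls respond
in both (4 and 3), so control-built dictionaries contain clean words for
both regions and controls lean toward the effective side of the
hyperplane, as the blind test expects. The effect fields accept one value
per region for exactly this reason. No effect sizes are reported for the
real discriminative regions; these values were chosen once for test power,
not biological realism.

The outcome-score generator (`generate_outcome_table()`) uses a
shared-factor construction — one common standard-normal factor per subject
plus five independent ones, mixed to a requested pairwise correlation
(default 0.9) — because only the observed correlation range is known, not
a generative model. Cluster means default to the observed group means
(ineffective ≈ (48, 50, 50, 50, 51), effective ≈ (72, 68, 77, 75, 85)),
with a 5-point within-cluster SD; a feasibility check rejects
configurations whose sum-space separation is under 4 SD, where 2-means
recovery of the planted split is no longer guaranteed.

The 2-D toy generator (`generate_toy2d()`) reproduces the qualitative
geometry of the published toy example — two separable clouds plus a sparse
"satellite" cluster on the positive side, populated by two labeled and two
unlabeled points. Its coordinates are not published; the geometry here
(clouds at (±1.6, 0) with SD 0.25, satellite at (−2.0, 3.0)) was chosen so
that the documented mechanism is realized: leaving a satellite point out
visibly tilts the supervised hyperplane while the unlabeled satellite
points hold the semi-supervised one in place. With
`satellite_amplitude = 0` the satellite collapses into the main cloud and
the two models coincide in LOOCV.

Artificial unlabeled samples (`simulate_unlabeled()`) implement
`x = m + alpha · s ⊙ z` with standard-normal `z` — white noise around a
group's empirical mean, scaled by its empirical SD.

**What passing on these generators does and does not show.** The synthetic
maps have stationary Gaussian noise, spherical effects, and perfect
template alignment; real contrast maps have anatomy-driven masks,
non-stationary smoothness, and registration error. Green tests certify the
machinery — thresholding, component merging, dictionary application,
solver optimality, cross-validation bookkeeping, the relative behavior of
the two model families on density-gap data — not clinical performance.
The study's headline numbers (LOOCV AUC 0.97 etc.) depend on the original
cohort's data, which cannot be reconstructed from the publication.

## Evaluation choices

* **AUC** uses the rank (Mann–Whitney) formulation with half-credit for
  ties; it is asserted equal to pair counting to 1e-12.
* **Inner-loop ties.** When several `r` values reach the same inner
  F-measure, the nested LOOCV prefers the `r` closest to the labeled
  positive fraction, then the smaller `r` — the observed selections in the
  study cluster at exactly that value (0.6 ≈ 9/16).
* **Correlation metrics** are computed against the sum of the five
  CELF-P2 scores of the held-out subjects.
* **Partial folds.** A fold whose training fails is recorded as
  unconverged and excluded from aggregates, which are then flagged
  `partial` — mirroring how inseparable random feature pairs are treated
  as failures rather than errors in the random-pair baseline.
* **Bias dispersion** in `fold_stability()` uses the sample (n−1) SD; the
  published convention is unstated.
* **RFE ties** in |w| remove the higher feature id first;
  the per-iteration count is `floor(0.01·n)` with a floor of one.
* **Single-feature models** are rejected in `sweep_rfe()` (`counts ≥ 2`):
  at one feature the margin problem routinely fails to converge.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data:
QP-oracle comparisons at 8 samples (active-set enumeration is exact
there), connected-component oracle checks on 16³ grids, toy-data
cross-validation at the study's 9/7/7 cohort shape, planted-feature RFE
recovery at 52 features, and full map-pipeline runs at the default
24³-grid, 44-subject cohort. These sizes were chosen so the whole suite
completes in minutes on one CPU while still exercising every code path at
the study's sample-size regime.

## Known limitations

* The annealing schedule and switching rule reproduce the *family* of the
  original solver's algorithm; the original package's exact schedule is
  not published, so per-fold models can differ from the original in ways
  that matter only when the objective has near-ties.
* `kmeans_labels()` clusters the five-score vectors by default; clustering
  the 1-D sums gives the identical partition on the shipped table (the
  285|331 gap), and the tests assert that equivalence on the fixture only.
* The printed correlation range of the score table (0.90–0.95 Pearson,
  0.87–0.92 Spearman) reproduces at the minima but not the maxima when
  recomputed from the printed table itself; `score_correlations()` reports
  what the data give.
* Dictionary redundancy means RFE's final feature *identities* are
  copy-sensitive at full map scale; stability statements should be made on
  merged identities (`selection_frequency()`), not raw word ids.
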