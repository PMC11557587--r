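---
title: "betapet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{betapet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what each stage computes, which assumptions it makes, where the design was
genuinely open and what was decided, and what a green test does and does not
establish. No empirical claim here goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The differential ROI model

A beta-PET dataset holds two registered FDG scans per subject: a baseline
session (F1, familiarization) and a task session (F3, contextual recall).
The quantity of interest is the per-region change in normalized uptake.

**Normalization.** Each scan is divided by its mean over the brain mask
(`normalize_to_brain_mean()`), so in-mask values are dimensionless with mean
exactly 1. This is intensity normalization, not a dose/body-weight SUV; the
field's "SUV" name is kept because each mask object's statistic is the mean
normalized uptake over its voxels. Whether the normalizing mean should be
taken over the brain mask or the whole cropped image was an open choice; the
brain mask is the default because out-of-brain voxels carry no tracer signal
after masking, and the mask used is configurable by supplying a different
`brain_mask`. Normalization is idempotent and makes the entire downstream
pipeline invariant to global scan scaling (both properties are tested).

**Region objects.** A region is a set of per-coronal-slice, per-hemisphere
mask objects. Hemispheres split at the grid's x-midline
(`floor(nx / 2)`, configurable), except midline prefrontal structures (PLC,
ILC), which are one object per slice. The SUV of an object is the unweighted
arithmetic mean over its voxels; ΔSUV = SUV(F3) − SUV(F1) object by object,
with strict key matching so a missing counterpart is an error, not an NA.

**Pooling.** `region_group_mean()` pools a region's objects across slices,
hemispheres and subjects *unweighted* — one value per object, mirroring the
record structure that feeds the mixed model — with a voxel-count-weighted
option for users who prefer volume weighting. `subject_region_mean()` is the
per-subject version that supplies classifier features and correlation
x-values.

## 2. Freezing scoring

Frames are classified inactive when the activity score is at or below the
threshold. Two details the upstream tracking software leaves open:

* **The threshold itself.** It is user-set per dataset (the acquisition
  software exports arbitrary activity units); the package treats it as
  required configuration with no default claim. The synthetic generator uses
  0.05 in [0, 1] units.
* **Tie rule.** A score exactly at the threshold counts as inactive
  (`tie_inactive = TRUE`, configurable). Continuous scores make ties
  measure-zero; the rule only matters for quantized scores.

Percent freezing is computed over sequential 10-s epochs (percentage of
inactive frames). A trailing partial epoch is reported separately and
excluded from averages — fixed-width bins keep epoch variances comparable.
Bouts are maximal inactive runs of at least 2 s computed from the unbinned
mask, not from the epochs. Window summaries (`window_mean()`) average the
complete epochs inside a window; the contextual-test analysis window
defaults to the last 5 min of the 8-min session, [180 s, 480 s].

## 3. Statistics

* **Pooled-variance Student's t** is the default two-sample test, from raw
  samples or from (n, mean, SEM) summaries. The pooled form is the one that
  reproduces published t statistics computed from mean ± SEM summaries
  (`t1 = 3.44`, `|t2| = 0.36` in the acceptance report); Welch is available
  by flag. The summary and raw routes are held equal by a property test.
* **Kolmogorov–Smirnov** uses the asymptotic two-sided p (bout samples are
  large, and the asymptotic form tolerates ties).
* **Mixed model.** Each mouse contributes many ΔSUV objects per region, so
  the group test is `delta_suv ~ group + (1 | subject_id)` (lme4), a random
  intercept per subject and nothing more: slice/hemisphere nesting is not
  modeled because the repeated-measures structure to absorb is "many values
  per mouse", and adding nesting levels at 24 objects per subject buys
  little and costs convergence robustness at small n. Inference is an F
  statistic (squared Wald t) against a residual-based denominator df
  (N − 2). Simulation at the design size (9 vs 15 subjects, 24 objects each,
  between-subject SD 0.03, within-subject SD 0.02) puts the type-I rate at
  ~0.05–0.06 and power for a 0.15 effect at ~100% (recomputed by the
  acceptance suite). Degenerate designs fall back: zero total variance
  returns F = 0, p = 1; one object per subject falls back to one-way ANOVA
  with a warning.
* **Correlations.** Pearson r with a least-squares line of behavior
  (dependent) on region-mean ΔSUV (independent); zero x-variance yields an
  NA correlation with a warning rather than an error.

## 4. Classification

Leave-one-out cross-validation, one fold per subject, with every
data-dependent choice made inside the training fold: feature
standardization uses training-fold means/SDs, and hyperparameters are
selected by stratified internal cross-validation on the training fold only.
The no-leakage property is tested directly: flipping a subject's class label
cannot change that subject's own score.

Model kinds:

* **linear-logistic** — maximum-likelihood logistic regression (no tuned
  hyperparameter; scores are class-1 probabilities).
* **max-margin** — linear soft-margin SVM trained by deterministic
  full-batch subgradient descent on the primal hinge loss (batch Pegasos;
  the bias rides as a regularized constant column, immaterial at these C
  values on standardized features). The cost grid {0.1, 1, 10} is selected
  internally. No SVM library is available in the supported environment, and
  at n ≤ 30 with a linear kernel the primal solver is adequate and exactly
  reproducible.
* **gradient-boosting** — GentleBoost with regression stumps, implemented
  from the original weight updates (weighted least-squares stump, additive
  F, weights `w * exp(-y f)`); the round count {10, 30, 50} is selected
  internally by staged evaluation.

ROC curves pool the held-out scores across folds (the standard LOOCV ROC
construction; whether to pool or refit-on-all was open and pooling is
documented as the choice) and step only at distinct score values, making the
trapezoid AUC equal to the concordance probability with ties counted ½. The
scrambled-label control permutes labels once per repetition, reruns the full
LOOCV against the permuted labels, and records the AUC; with 24 subjects the
scrambled mean sits slightly *below* 0.5 (≈0.42–0.45 at 50 reps) — the
well-known pessimistic bias of LOOCV under label permutation — within the
0.5 ± 0.1 acceptance band.

## 5. Ordinal-trends analysis

The published ORT procedure is a closed-source script; this package defines
a concrete, documented variant and does not claim numerical equivalence:

1. Scans are normalized (consistently with the ROI stage), flattened over
   the brain mask, and the per-voxel grand mean is removed
   (`build_scan_matrix()`; the stored mean restores the input exactly).
2. `fit_ort()` removes each subject's mean scan (isolating within-subject
   condition variance), takes PCs via the scan-space Gram matrix, and
   considers candidate subsets: single PCs and pairs among the first
   `max_pcs` (default 5). Within a subset, the combination weights are the
   least-squares fit of the centered condition indicator (±½) on the subset
   expressions — the combination maximizing the subject-wise F1→F3
   expression trend. The unit-norm pattern's expression is regressed on the
   condition indicator (subject intercepts vanish under subject centering)
   and the candidate is scored by AIC = m·ln(RSS/m) + 2k (m scans, k subset
   size); lowest AIC wins. The pattern is oriented so the majority of
   subjects increase.
3. **Permutation test**: per iteration each subject's condition labels flip
   independently with probability ½ (the within-subject scheme preserves
   subject structure; the alternative — permuting scans globally — breaks
   the pairing and was rejected), the whole fit is recomputed, and
   p = (1 + #{perm ≥ obs}) / (1 + n_iter), never zero by construction.
4. **Bootstrap**: subjects are resampled with replacement (pairs travel
   together, respecting the design), patterns are sign-aligned to the
   observed one, and a voxel's one-tailed p is the fraction of replicates
   crossing zero against the observed sign; p < 0.05 defines the
   significance mask.
5. **Nodal expression**: every scan — including the held-out group — is
   centered with the model's stored voxel means and projected on the
   pattern; expressions are z-scored across *all* projected scans (so both
   groups are on one scale; z-scoring within the fitted group alone was the
   alternative) and Δexpression = z(F3) − z(F1) per subject.

**Calibration, honestly stated.** The ordinal statistic is a count over n
subjects, so its permutation distribution is heavily tied. With the
prescribed "≥" counting the p-value is *valid but super-uniform*
(conservative): over 200 null datasets, P(p ≤ 0.05) ≈ 0.02 and
P(p ≤ 0.10) ≈ 0.04, while a Kolmogorov–Smirnov test against U(0,1)
decisively rejects (D ≈ 0.2) — no implementation of this statistic can be
KS-uniform, and the corresponding acceptance assertion is deliberately left
failing with this analysis. Power was characterized at an implementer-chosen
SNR (16 subjects, 150 variables, unit effect, noise SD 0.15): the planted
trend reaches p ≤ 0.05 in ~100% of simulations at 99 iterations. At lower
SNR the limiting factor is the observed statistic itself (per-subject
expression deltas cross zero), not the permutation null.

## 6. The synthetic world

`phantom_config()` states: an ellipsoidal brain (semi-axes 0.46 of the grid)
on a canonical 40 × 60 × 30 grid at the scanner's 0.78 × 0.78 × 0.8 mm
voxels; eight box regions placed at plausible relative anterior–posterior
positions (BA spanning 12 coronal slices, mirrored hemispheres except
midline PLC/ILC); 9 + 15 subjects; i.i.d. Gaussian voxel noise (SD 0.05 in
normalized-uptake units — chosen once so that large planted effects are
comfortably detectable and sub-0.005 effects are not, as in real data); and
per-(group, region) effects defaulting to the published group means (e.g.
basolateral amygdala 0.15 control-like vs 0.049 disease-like).

Two generator subtleties:

* **Effects are stated in normalized-uptake units**, so the generator solves
  for the raw region values whose *normalized* ΔSUV equals the configured
  effect exactly: with region baselines b_r, masks of m_r voxels, M brain
  voxels and targets t_r = b_r/μ1 + e_r, the session-2 mean satisfies
  μ3 = (M·μ1 − Σ m_r b_r) / (M − Σ m_r t_r) and region voxels take t_r·μ3.
  A naive raw additive effect would shift the whole-brain mean and break
  exact zero-noise recovery; with the solved values the roi pipeline
  recovers every planted effect to machine precision (tested).
* **Activity traces** place a deterministic count of bouts
  (`round(rate × minutes)` rather than a Poisson draw — the count noise
  would otherwise dominate between-subject variance), with gamma durations
  (mean 6 s, shape 9) truncated at the 2-s bout rule and quantized to the
  frame grid, separated by at least 2 frames, positioned by random gap
  allocation so coverage is uniform. Movement frames score uniform on
  (threshold, 1], bout frames exactly 0, keeping frame classification
  unambiguous for oracle tests. Default rates target ~73% (control-like)
  and ~45% (disease-like) freezing; `bout_rate_for_target()` converts any
  target.

What the phantom does *not* emulate: anatomy (boxes, not atlas regions),
spatial noise correlation (an optional Gaussian-blur switch exists but
defaults off — smoothing belongs to upstream preprocessing), scanner
physics, attenuation or scatter, partial-volume effects, or behavioral
idiosyncrasies (freezing outside bouts, drifting activity baselines). A
green pipeline test therefore establishes computational correctness of the
analysis on data satisfying its assumptions — not robustness to real
scanner artifacts.

The smoke test asserts that the end-to-end network map's node signs match
the planted effects — but only for nodes whose planted |effect| exceeds 4×
the analytic standard error of its estimator (computed from the mask sizes
and noise SD): the smallest planted effects (e.g. −0.00075) sit below the
noise floor of a 9/15-subject design by construction, and their recovered
sign is a coin flip no implementation could call.

## 7. Numerical choices and degenerate inputs

* NIfTI-1 I/O is built in (no R NIfTI package in the supported
  environment): single-file `.nii`, both endiannesses, datatypes
  uint8/int16/int32/float32/float64, slope/intercept honored on read;
  written volumes use float64 so round trips are bit-exact.
* Normalization requires a strictly positive in-mask mean; violations are
  typed errors, not NaN propagation.
* PC usability threshold: eigenvalues above `max(eig) · 1e-10`; candidate
  subsets with a condition number beyond 1e12 are skipped.
* All acceptance thresholds and generator parameters were fixed before the
  corresponding checks were frozen; seeds derive from a single user seed and
  stay below 2^31.
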