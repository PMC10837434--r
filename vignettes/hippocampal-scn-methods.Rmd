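---
title: "Methods: hippocampal structural covariance and intrusive-memory counts"
author: "hippoSCN authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hippocampal structural covariance and intrusive-memory counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, and design choices behind
`hippoSCN`. It states no empirical results beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## 1. The analysis in one paragraph

A cohort of trauma-exposed adults completes a two-week ecological momentary
assessment (EMA): five daily surveys for fourteen days, three per day
probing trauma-related intrusive memories (TR-IMs), for at most 42 TR-IM
surveys; TR-IM frequency is the total reported count. Anatomical MRI gives
per-subject modulated gray-matter (GM) density maps in a common space.
Study-specific anterior (head) and posterior (body + tail) hippocampus
templates are built by merging per-subject subregion masks, keeping voxels
present in at least 75% of the sample, and cutting the longitudinal axis at
y = −32 mm (posterior) and y = −21 mm (anterior) so the functionally mixed
middle portion belongs to neither. Seed-based non-rotated partial least
squares (PLS) with the a priori contrast (aHPC, pHPC) = (1, −1) extracts a
structural covariance pattern that differentiates the two seeds; permutation
tests assess its significance, bootstrap ratios (BSR) the reliability of
each voxel's weight, and each subject's brain score expresses how strongly
they show the pattern. Offset Poisson regressions then relate TR-IM
frequency to subregion volumes and to brain scores.

## 2. The synthetic cohort generator

The generator (`synthConfig()` / `generateCohort()`) is first-class,
tested code: it defines the conditions under which every downstream claim
is validated.

**Latent model.** Each subject carries two independent standard-normal
factors: `f` drives the anterior seed and a distributed set of "network"
voxels; `g` drives the posterior seed. Voxel densities are

```
x_v = baseline + loading_v * factor + noise,  noise ~ N(0, noise_sd^2),
```

clipped at zero, with `loading_v` equal to `latent_loading_seed` (0.6) in
the anterior and posterior regions, `latent_loading_network` (0.6) at
network voxels, and 0 elsewhere inside the brain. This is the simplest
structure for which the seed-PLS saliences have a known sign and support
pattern, and it gives closed forms the oracles use — e.g. the correlation
between an anterior-seed voxel and a network voxel is
`a·b / sqrt((a² + s²)(b² + s²)) = 0.36` at the defaults.

**Baseline density 3.0.** Real modulated GM density is O(1); we set the
in-brain baseline to 3.0 so that the clip at zero affects < 0.2% of draws
and the Gaussian closed forms stay exact. This is a deliberate departure
from realistic image scaling; correlations, PLS weights, and count models
are scale-free in the ways that matter, and the departure is confined to
the generator.

**Geometry.** Regions are separated along the second grid axis, with the
affine anchored so the anterior region's first slab sits exactly at
y = −21 mm and the posterior region ends at or below y = −32 mm — the
posterior/anterior cuts therefore never clip planted voxels, and "posterior"
means more negative y, as in MNI space. Hemispheres are mirrored blocks
with opposite x sign. The default grid is 28×44×28 voxels at 2 mm; any
grid of at least 8 voxels per axis that can host the regions at the given
voxel size is accepted, and the unit tests run on 12×18×12 at 3 mm.

**Mask jitter.** Per-subject label masks equal the truth except at region
boundaries (a labeled voxel with a 6-connected background neighbour, or a
background voxel adjacent to the region), where membership is
*re-randomized to a fair coin* with probability `mask_jitter_prob`. We
chose re-randomization (effective flip rate jitter/2) rather than a
deterministic flip because it yields the two endpoints one wants from a
segmentation-noise model: jitter 0 reproduces the truth exactly, and
jitter 1 makes boundary membership maximally uncertain, driving
probabilistic template values to 0.5 there. Interior voxels are never
touched.

**EMA counts.** Each of the 70 scheduled surveys completes independently
with `completion_prob` (default 0.835, matching a cohort that averages
~58/70 total and ~35/42 TR-IM surveys). Completed TR-IM surveys draw
counts from Poisson with log daily rate `beta0 + beta_brain · z(f)`, the
daily exposure split equally over the three TR-IM slots. Defaults
`beta0 = log(1.82)` and `beta_brain = −0.105` make the expected two-week
TR-IM frequency ≈ 21 and the planted IRR per SD `exp(−0.105) ≈ 0.90`.
Follow-up duration is the inclusive span from first to last completed
survey — exactly 14 days at full completion, which isolates the
offset-handling code path. Covariates (age, sex, CAPS composite) are drawn
from cohort-typical marginals and carry no planted effect on the counts.

**What the generator does not emulate.** No scanner artifacts,
registration error fields, cortical anatomy, spatial autocorrelation of
noise, or overdispersed counts. Passing tests demonstrate that the
*machinery* is correct under a known model — not that real data satisfy
that model.

## 3. Templates

Template values are exact fractions k/n of subjects containing each voxel,
so the 75% rule is an exact rational comparison (70/93 ≈ 0.7527 is
retained at 0.75; 69/93 ≈ 0.7419 is not). Thresholding is inclusive
(`>=`, "present at least in 75%") and idempotent. Axis cuts act on
voxel-centre y coordinates and are boundary-inclusive — y ≤ −32 stays
posterior, y ≥ −21 stays anterior — so the printed cut coordinates are
themselves retained; voxel membership is decided by the centre, not corner
overlap. Cuts are applied after probabilistic merging and thresholding;
for axis-aligned cuts the two orders commute, so the choice is one of
bookkeeping, not substance. Hemispheres are processed as separate masks
distinguished by the sign of x, because volumes are later summed over
hemispheres.

## 4. Morphometry

Subregion volume is mean in-mask density × voxel count summed over
hemispheres (identically, the sum of in-mask densities), reported in
density-weighted voxel units by default with an optional mm³ conversion,
since the source convention leaves units unstated. The analysis mask keeps
voxels whose across-subject mean density strictly exceeds a threshold; no
value is prescribed upstream, so the default is 0.1, the conventional GM
cutoff, and it is configurable. Smoothing (used only for brain-score
images) is separable Gaussian with σ = FWHM/(2√(2 ln 2)) per axis in mm;
the FWHM is likewise unstated upstream, so the default is 8 mm, the
standard VBM choice. Boundaries are mirrored (half-sample reflection),
which makes the 1-D operators symmetric and conserves total mass to
rounding error.

## 5. Seed PLS, permutation, bootstrap

The association matrix is Pearson correlation by default. The source
literature says "covariance", but the toolbox lineage this analysis
follows cross-correlates; a plain covariance option exists and all tests
pin the default. The matrix and both resampling procedures use unsmoothed
images (explicitly the convention for seed means); brain scores use
smoothed images (also explicit). This asymmetry is intentional and
documented here.

**Seed voxels are excluded from the voxelwise matrix in the pipeline**
(`runConfig(exclude_seeds = TRUE)`). The latent variable relates the seeds
to all the *other* brain voxels: a seed mean trivially correlates ~1/√m
with each of its own m constituent voxels, and keeping those voxels makes
the permutation test anticonservative under a null cohort — the observed
singular value then carries deterministic self-association that permuting
subject rows destroys. With exclusion, the null calibration suite (200
replicate null cohorts at 200 permutations each) shows uniform p-values
and a rejection rate inside the binomial band. Inclusion remains available
as an option; note that with our synthetic layout the planted subregions
coincide exactly with the seed templates, so under exclusion the cluster
table contains network clusters only. The middle-hippocampus voxels
(−32 < y < −21) are *not* excluded: they lie inside the analysis mask and
outside both templates.

**Permutation p** is the plain proportion `#(perm ≥ observed)/n_perm`,
matching the toolbox convention; `(count+1)/(n_perm+1)` is available by
flag. A perfect separation therefore reports p = 0. The permutation
permutes the seed table's subject rows; permuting image rows instead is
equivalent for this statistic.

**Bootstrap** resamples subjects with replacement and recomputes saliences
with the fixed contrast — no per-replicate re-standardization or
sign-flipping correction is needed because the contrast is a priori, not
data-driven. A resample that leaves a seed with zero variance (possible
only at tiny n) is skipped. Voxels with zero bootstrap SE get an undefined
BSR and are flagged, never reported as reliable. Cluster extraction
thresholds positive and negative BSR separately (default ±3.3), uses
26-connectivity by default, drops components under 100 voxels, and reports
each cluster's peak |BSR| voxel in mm.

All stochastic operations take an explicit seed and restore the caller's
RNG state; there is no hidden global state, and the pipeline derives each
stage's seed deterministically from the single run seed.

## 6. Count models

Fitting uses iteratively reweighted least squares (relative tolerance
1e-8, at most 100 iterations) with `log(followup_days)` as offset.
Continuous predictors are standardized so one unit is one SD; binary sex
is centred but not rescaled — "one unit = one SD" reads naturally for
continuous predictors only, and the binary handling is configurable via
the `binary` argument since the original coding convention is not stated.
Wald 95% intervals are `exp(b ± 1.96 se)` by definition, Nagelkerke R² is
the Cox–Snell ratio normalized by its maximum, and a Pearson
dispersion diagnostic (χ²/df) is reported because plain Poisson (no
overdispersion model) is the family this analysis uses. The sensitivity path adds
the CAPS-5 composite (non-intrusion symptom severity) as a covariate to
the brain-score model.

## 7. Numerical and degenerate-input conventions

* Zero-variance voxels get association 0 and a flag rather than NaN.
* An empty thresholded template is a warning, not an error (downstream
  code decides); an empty analysis mask is an error.
* `trimFrequency()` errors on a subject with zero completed surveys;
  compliance errors on duplicate (subject, day, slot) records.
* A model log-likelihood below the null's is treated as numerical
  pathology and raised as an error rather than clamped.
* Grid dimensions below 8 are rejected: too small to host disjoint
  anterior/posterior/network regions.

## 8. Problem sizes used by the test and acceptance suites

Unit and property tests run on 12×18×12-voxel grids at 3 mm with cohorts
of 20–100 subjects; calibration uses 200 replicate null cohorts at 200
permutations; Poisson recovery uses one n = 1000 cohort plus 400 replicate
n = 200 cohorts for interval coverage; the oracle comparison for PLS uses
50 subjects × 5000 voxels. `scripts/acceptance.R` runs the full default
configuration (93 subjects, 28×44×28 voxels at 2 mm, 1000 permutations
and 1000 bootstraps). These sizes were chosen so each suite completes in
minutes on one CPU while leaving the Monte Carlo bounds comfortably
non-trivial.

## 9. Known limitations

* The generator's planted posterior region is compact and exactly
  coincides with the posterior template, so the brain-score/posterior-
  volume correlation is mildly negative by construction (the score's
  negative-salience lobe), not near the zero a heterogeneous real network
  would give.
* Single-factor linear-Gaussian structure cannot express graded or
  nonlinear covariance, nor distance-dependent smoothness of real GM maps.
* Counts are conditionally Poisson; real EMA counts are typically
  overdispersed. The dispersion diagnostic will flag this on real data,
  but no negative-binomial alternative is provided.
* No atlas labeling of cluster peaks, no multi-LV (rotated) PLS, and no
  mixed-effects day-level models — out of scope by design.
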