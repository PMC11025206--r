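---
title: "Choroid-plexus volumetry by two-stage mixture clustering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choroid-plexus volumetry by two-stage mixture clustering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpseg)
```

## The problem

The choroid plexus (CP) is the epithelial structure inside the brain
ventricles that produces CSF and forms the blood–CSF barrier.  Its
volume, measured from T1-weighted structural MRI, has become a
candidate in-vivo marker of barrier dysfunction in neurodegenerative
disease.  The CP of the lateral ventricles is small (a few cubic
centimetres), bright on T1 relative to the surrounding CSF, and
bounded by a partial-volume rim along the ventricle wall whose
intensity falls between CSF and plexus — which is what makes a naive
threshold unreliable and motivates the two-stage mixture approach
implemented here.

`cpseg` provides three connected layers:

1. **Segmentation**: the label-seeded, two-stage Gaussian-mixture
   pipeline with edge-preserving (SUSAN) smoothing, producing a CP
   mask and its volume in mm³.
2. **Cohort statistics**: the albumin quotient, progression rate,
   covariate-adjusted general linear model with FWE-corrected post hoc
   contrasts, partial correlations, and summary-statistic
   t/ANOVA/χ² tests.
3. **Synthetic data**: a ventricular phantom generator with exact
   ground truth, and a cohort simulator calibrated to target group
   summaries and partial correlations, so the whole pipeline is
   testable without any imaging archive.

## The segmentation model

Let $I(x)$ be the T1 intensity at voxel $x$ and $L(x)$ an anatomical
label volume in FreeSurfer `aseg` coding, aligned to $I$.

**Initial mask.** The union of the six ventricular-system structures —
left/right lateral ventricle (4/43), inferior lateral ventricle
(5/44) and choroid plexus (31/63) — seeds the pipeline:

$$M_0 = \{x : L(x) \in \{4, 5, 31, 43, 44, 63\}\}.$$

Real `aparc+aseg` output can be used directly; the phantom generator
emits the same codes.

**Stage 1 — CSF versus CP + wall.** A 2-component univariate Gaussian
mixture is fitted to $\{I(x) : x \in M_0\}$ and every voxel is
hard-assigned to its maximum-responsibility component.  The component
with the larger mean is the CP-plus-ventricle-wall class $M_1$; the
other is CSF.  This works because on T1 the ventricular interior is a
roughly bimodal mixture of dark CSF and everything brighter.

**SUSAN smoothing.** Intensities on $M_1$ are denoised with a
structure-preserving filter: the smoothed value at $x_0$ is

$$J(x_0) = \frac{\sum_{x \ne x_0} I(x)\, w(x, x_0)}
                 {\sum_{x \ne x_0} w(x, x_0)},
\qquad
w = \exp\!\left(-\frac{\lVert x - x_0\rVert^2}{2\sigma^2}
                -\frac{(I(x) - I(x_0))^2}{t^2}\right),$$

where the sum runs over masked voxels within $3\sigma$ (distances in
mm, so anisotropic voxels are handled), $\sigma$ = 1 mm by default,
and $t$ is the brightness threshold.  Voxels across an intensity edge
(difference $\gg t$) get vanishing weight, so the wall–plexus edge
survives while within-tissue noise is averaged away.  A voxel with no
masked neighbour in range is returned unchanged (identity fallback;
FSL's implementation substitutes a local median here, a deliberate
divergence documented with the function).  The output is a convex
combination of masked input values — an invariant the test suite
asserts.

**Stage 2 — CP extraction.** A 3-component mixture is fitted to the
smoothed values on $M_1$; the voxels assigned to the highest-mean
component form the final CP mask.  Three components absorb the
tri-modal structure of the smoothed domain (wall partial volume,
mixed voxels, plexus) while the highest-mean rule pins down the
plexus.

**Edits and volumetry.** An optional, replayable edit list (remove
first, then add — so a voxel listed in both ends up present) stands in
for expert manual correction, and the volume is voxel count times
voxel volume.  Optional minimum-size filtering of the final mask
exists but is off by default, since no such filter is part of the
core procedure.

## The mixture fitter

Both stages share one univariate EM fitter (`fit_gmm()`), with two
modes:

* `"ml"`: classical maximum-likelihood EM.
* `"map"` (default): MAP-EM under weak conjugate priors — a
  Dirichlet($\alpha$) prior on the weights with $\alpha = 1 + 10^{-3}$
  and a Normal-Inverse-Gamma prior on each mean/variance centred on
  the sample moments ($\kappa_0 = 10^{-3}$, $a_0 = 1 + 10^{-3}$,
  $b_0 = 10^{-3}\,s^2$).  The priors are weak enough that estimates
  track the ML solution on any realistic sample, but they keep the
  M-step closed form and regularize near-degenerate configurations.

Numerical choices that matter:

* **Initialization** is deterministic by default: component means at
  the $(2i-1)/(2k)$ sample quantiles, shared sample variance, uniform
  weights.  This makes every segmentation bit-reproducible without a
  seed; random restarts are available behind an explicit seed.
* **Convergence**: relative objective change below $10^{-6}$, at most
  500 iterations.  The objective (log-likelihood or log-posterior) is
  recorded per iteration and is non-decreasing — a property test, not
  an assumption.
* **Variance floor**: component variances are clamped at
  $10^{-6}\times$ the sample variance.  A clamped fit is flagged
  (`variance_floored`); a sample with (near-)zero overall variance is
  a fit error, because no mixture structure is resolvable.  The clamp,
  rather than an error, is what lets noiseless phantoms — where a
  component can sit on an exactly constant intensity class — segment
  exactly.
* **Ties**: hard assignment prefers the higher-mean component, then
  the lower index; the "highest mean" selection breaks exact mean
  ties by larger variance, then lower index.  Component relabeling
  therefore never changes a mask (asserted as a property test).

## What the phantom emulates — and what it does not

`generate_phantom()` renders two ellipsoidal lateral ventricles (plus
a small temporal-horn ellipsoid each), a partial-volume rim of
intermediate intensity along every ventricle surface, and spherical CP
blobs spaced deterministically along each ventricle's long axis, over
a uniform background, with additive Gaussian noise.  Default
intensities (background 100, CSF 30, wall 70, CP 110, noise SD 5,
arbitrary units) reproduce the dark-CSF/bright-CP ordering that the
highest-mean rule needs on T1; the constructor enforces
CSF < wall < CP.  Geometry is deterministic given the spec — the noise
field is the only stochastic element — and a blob that would not fit
inside its ventricle raises a geometry error rather than being
truncated.

The phantom deliberately omits bias fields, k-space artifacts,
motion, anatomical variability and FreeSurfer segmentation error.
Passing the phantom suite therefore shows that the pipeline recovers
volumes when its intensity assumptions hold, with realistic additive
noise; it does not certify performance on scanner data, where the
label map itself is imperfect.  The default 96³ grid at 1 mm gives a
~19,000-voxel initial mask and a true CP volume of ~1,700 mm³, within
the anatomical range; the test suite also uses a 48³ phantom with
proportionally smaller structures so that single fits run in
milliseconds.  On the small grid the demo cohort scales CP volumes
down (~550–700 mm³) to keep the plexus the minority intensity class
inside the mask, as it is in real anatomy — mixture clustering
depends on that proportion, not on absolute size.

## The cohort simulator and its calibration

`generate_cohort()` draws per-group demographics, TIV
(Normal($1.45\times10^6$, $1.5\times10^5$) mm³, truncated positive —
the study literature uses TIV only as a covariate, so this is a
documented assumption, as is the absence of a sex effect on CP volume
in the generator), and CP volume from per-group Gaussians.  For
patient rows, ALSFRS-R and the albumin quotient come from a latent
linear model on the standardized CP volume $z_x$:

$$y = \mu_y + \sigma_y\!\left(r\, z_x + \sqrt{1 - r^2}\,\varepsilon\right),
\qquad \varepsilon \sim N(0, 1),$$

with $r$ the target partial correlation.  Because age, sex and TIV
are generated independently of CP volume, residualizing on them
leaves the $x$–$y$ correlation untouched, so the population partial
correlation equals $r$ — a closed-form calibration with no iterative
tuning, verified by Monte-Carlo in the test suite (200 cohorts; the
mean recovered $r$ must sit within 2 Monte-Carlo SEs of the target).
Scores are clipped to their natural ranges (ALSFRS-R to [0, 48], Qalb
positive); at the default means and SDs fewer than ~2% of draws hit a
bound, an attenuation small against the Monte-Carlo tolerance.
ALSFRS-R and Qalb use pooled patient-level means and SDs rather than
per-subgroup ones, so subgroup score differences emerge only through
the latent model; targets with $|r| \ge 1$ raise a calibration error.
Albumin data are assigned to a fixed-size random subset of patient
rows (115 of 155 by default), matching incomplete lumbar-puncture
coverage; the statistics layer is complete-case per variable.

## The statistics layer

* `glm_group_comparison()` fits outcome ~ group + age + sex + TIV by
  least squares, tests the omnibus group effect by nested-model
  partial F, and tests all pairwise group contrasts on the full
  model.  The FWE method across the pairwise family is Bonferroni by
  default — the simplest valid choice for a family of three — with
  Holm behind a flag.  Sex is coded 0/1 (F/M); two-sided p-values
  throughout, α = 0.05.
* `partial_correlation()` residualizes both variables on the
  covariates plus intercept and correlates the residuals, with
  $t = r\sqrt{df/(1-r^2)}$, $df = n - 2 - k$.  It matches the
  recursive one-covariate closed form to $10^{-10}$ (property test).
* `anova_from_summary()`, `ttest_from_summary()` and
  `chisq_contingency()` reconstruct the tests that cohort tables
  print from (n, mean, SD) summaries and counts; they agree exactly
  with raw-data computations whenever raw data are built to match the
  summaries (affine-reconstruction oracle in the tests).
* `qalb()` is CSF albumin (mg/L) over serum albumin (g/L), in mg/g;
  `bpr()` is (48 − ALSFRS-R)/duration in points per month.  Note that
  a cohort's mean progression rate is a mean of per-subject ratios,
  not the ratio of the mean score deficit to the mean duration.

## Problem sizes and reproducibility

The test suite validates volumetric recovery on 10 noisy phantoms at
the default 96³ spec (median relative volume error must be ≤ 15%; in
practice it sits around 4%) and calibration on 200 simulated cohorts
per target; the group-difference surrogate simulates 200 cohorts of
155 + 105 subjects.  These sizes give Monte-Carlo standard errors
well below the tolerances they are tested against while keeping the
whole suite under a minute of compute.  All randomness is seeded:
phantoms and cohorts carry their seed in the spec, the pipeline
derives per-subject seeds from one master seed, and every output
artifact records the hash of the configuration that produced it.

## A worked end-to-end run

```{r, eval = FALSE}
cfg <- pipeline_config(
  cohort = list(
    n_per_group = c(genetic_ALS = 4L, sporadic_ALS = 4L, HC = 3L),
    cpv_mean = c(genetic_ALS = 700, sporadic_ALS = 650, HC = 550),
    cpv_sd = 80, n_qalb = 8L),
  phantom = list(grid_shape = c(48L, 48L, 48L),
                 ventricle_semiaxes = c(8, 16, 7),
                 ventricle_separation = 11,
                 ilv_semiaxes = c(4, 6, 3), ilv_offset = c(3, -13, -5),
                 cp_blob_count = 2L),
  seed = 3L)
report <- run_pipeline(cfg, out_dir = "demo_out")
report
```

The report prints the median absolute volume error across the
simulated subjects, the covariate-adjusted omnibus test and the two
partial correlations, and writes `cohort.csv` and `report.json`
stamped with the configuration hash.

## Known limitations

* The segmentation covers the lateral-ventricle CP only (the six
  listed labels); fourth-ventricle and temporal-horn plexus beyond
  those labels are out of scope, as are bias-field correction,
  registration, and any re-implementation of FreeSurfer's anatomical
  segmentation or TIV estimation.
* "Bayesian" mixture hyperparameters, the SUSAN brightness threshold
  (default: $0.1 \times (P_{95} - P_{5})$ of the domain intensities)
  and the absence of size filtering are configurable defaults, since
  no canonical values exist for this pipeline; sensitivity to them is
  a property of the data, not of the implementation.
* The cohort simulator reproduces first and second moments and two
  targeted partial correlations; it does not model longitudinal
  change, non-Gaussian score distributions, or covariate–group
  confounding (covariates are independent of group by design, which
  is also what makes the calibration exact).
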