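# cpseg — choroid-plexus volumetry and cohort statistics

The choroid plexus (CP) produces cerebrospinal fluid and forms the
blood–CSF barrier; enlargement of its lateral-ventricle portion is an
emerging structural-MRI marker in neurodegenerative disease,
correlating with clinical disability and with barrier permeability as
indexed by the CSF/serum albumin quotient (Qalb).  `cpseg` is an R
package for researchers running such studies: it implements the
label-seeded CP segmentation pipeline, the downstream cohort
statistics, and — because imaging archives usually cannot be shared —
a synthetic phantom and cohort layer with exact ground truth so the
whole analysis chain is testable and demonstrable end to end.

## The method

Given a T1-weighted volume `I` and an aligned FreeSurfer-style label
volume, the segmentation runs:

1. **Initial mask** `M0`: union of the `aseg` codes 4/43 (lateral
   ventricle), 5/44 (inferior lateral ventricle), 31/63 (choroid
   plexus).
2. **Stage 1**: 2-component univariate Gaussian mixture on
   `{I(x) : x ∈ M0}` (MAP-EM with weak conjugate priors by default);
   the higher-mean component is the CP + ventricle-wall class `M1`,
   the lower is CSF.
3. **SUSAN smoothing** on `M1` (σ = 1 mm): each voxel becomes a
   weighted average of masked neighbours within 3σ, with weight
   `exp(−‖x−x0‖²/2σ² − (I(x)−I(x0))²/t²)` — spatially close,
   similar-intensity voxels dominate, so the wall–plexus edge is
   preserved.
4. **Stage 2**: 3-component mixture on the smoothed values; the
   highest-mean component is the CP mask.
5. Optional replayable manual-edit lists, then volumetry:
   `volume = voxel count × voxel volume` (mm³).

The statistics layer provides `qalb()` (CSF-albumin/serum-albumin,
mg/g), `bpr()` ((48 − ALSFRS-R)/duration, points/month),
covariate-adjusted GLM group comparison with Bonferroni/Holm-corrected
pairwise contrasts (`glm_group_comparison()`), partial correlations
(`partial_correlation()`), and χ²/t/ANOVA tests reconstructed from
published summary statistics (`chisq_contingency()`,
`ttest_from_summary()`, `anova_from_summary()`).

## Worked example

```r
library(cpseg)

# a 96^3 phantom: two ellipsoidal ventricles, wall rim, bright CP blobs
ph <- generate_phantom(phantom_spec(seed = 1))
ph
#> <cp_phantom> 96 x 96 x 96 voxels; true CP volume 1680 mm^3

seg <- segment_cp(ph$image, ph$labels)
seg
#> <segmentation_result>
#>   initial mask :    19476 voxels
#>   CP + wall    :    10546 voxels (stage-1 means 29.75, 75.31)
#>   choroid plexus:    1740 voxels (stage-2 means 69, 70.37, 107.6)
#>   CP volume    : 1740.0 mm^3
```

The estimated 1740 mm³ is within 4% of the 1680 mm³ ground truth at
the default noise level; the stage-1 means show the CSF/non-CSF split
(≈30 vs ≈75 intensity units) and the stage-2 means the wall/plexus
split (≈70 vs ≈108).

Cohort analysis on a simulated three-group study (12 genetic ALS, 143
sporadic ALS, 105 controls; CP volume/ALSFRS-R/Qalb correlation
structure built in):

```r
coh <- generate_cohort(cohort_spec(seed = 7))
glm_group_comparison(coh)
#> <glm_group_result> n = 260  groups: genetic_ALS, HC, sporadic_ALS
#>   omnibus F(2, 254) = 14.860, p = 7.89e-07
#>                    contrast estimate    se       t  df         p     p_fwe
#>            genetic_ALS - HC    748.7 243.0  3.0808 254 2.292e-03 6.875e-03
#>  genetic_ALS - sporadic_ALS    239.9 241.2  0.9944 254 3.210e-01 9.630e-01
#>           HC - sporadic_ALS   -508.9 100.3 -5.0742 254 7.522e-07 2.257e-06
```

Both patient groups exceed controls after family-wise error
correction while the two patient groups do not differ — the qualitative
pattern such cohorts show.  Summary-statistic reconstruction, e.g. a
three-group ANOVA from printed `(n, mean ± SD)` cells:

```r
res <- anova_from_summary(n    = c(12, 143, 105),
                          mean = c(3161.8, 2911.3, 2454.5),
                          sd   = c(735.1, 735.1, 781.3))
#> F(2, 257) = 13.09, p = 3.9e-06
```

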