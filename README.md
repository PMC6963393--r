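# iphquant

Quantification of carotid intraplaque hemorrhage (IPH) on T1-weighted
MPRAGE-like MR volumes, and agreement analysis between segmentation
methods — exercised end to end on synthetic phantoms with exact ground
truth.

## Who this is for

IPH shows up hyperintense on MPRAGE because methemoglobin shortens T1,
and the operational definition of "hyperintense" is a threshold relative
to adjacent muscle: a plaque voxel is IPH when its intensity exceeds a
multiple *r* of the mean sternocleidomastoid muscle (SCM) signal, with
*r* between 1.5 and 2.0 depending on the protocol. The choice of *r*
changes measured IPH volumes substantially, and comparing candidate
thresholds against manual segmentation requires an agreement analysis.
This package is for imaging scientists who want that whole design —
segmentation arms plus statistics — as reproducible, tested code.

## What it computes

**Semi-automatic arm** (`segment_iph`): with muscle reference
μ<sub>SCM</sub> = mean of three sampled SCM voxels, the candidate mask is
{v ∈ plaque : I(v) > r·μ<sub>SCM</sub>} for r ∈ {1.5, 1.75, 2.0}; 26-connected
components not spanning ≥ 2 consecutive slices are removed; metrics are
total volume (count × voxel volume), maximal axial volume (largest
single-slice contribution) and length (occupied slice span × slice
thickness).

**Manual proxy** (`segment_levelset`): two-phase piecewise-constant
region competition (Chan–Vese family) within the plaque,

E = λ<sub>in</sub> Σ<sub>in</sub>(I−c<sub>in</sub>)² + λ<sub>out</sub> Σ<sub>out</sub>(I−c<sub>out</sub>)² + μ·|∂M|,

minimized by monotone, deterministic discrete sweeps.

**Agreement** (`icc`, `compare_icc`, `bonferroni`): ANOVA-based ICCs
(two-way absolute agreement by default) with 95% CIs, the six-band scale
poor → almost perfect, one-sided Fisher z comparison of two ICCs
(z = atanh ρ, SE = √(1/(n₁−3) + 1/(n₂−3))), Bonferroni adjustment.

**Phantoms** (`phantom_config`, `generate_cohort`): tubular vessel +
sector plaque + ellipsoidal IPH at a configurable multiple of the muscle
mean, 0.31 × 0.31 × 1 mm voxels, Rician noise, exact voxel-count ground
truth.

## Worked example

```r
library(iphquant)

s <- generate_subject(phantom_config(iph = list(intensity_ratio = 1.8),
                                     seed = 42))
s$volume
#> <volume3d> 64 x 64 x 16 voxels, spacing 0.31 x 0.31 x 1.00 mm, range [0.5882, 190.4]
s$truth$true_iph_volume
#> [1] 14.415

roi <- sample_roi_points(s$truth$muscle_mask, seed = 42)
segment_iph(s$volume, s$truth$plaque_mask, roi, 1.5)
#> <iph_segmentation> >150% of muscle mean | total 14.415 mm^3, max axial 4.228 mm^3, length 4.0 mm
segment_iph(s$volume, s$truth$plaque_mask, roi, 2.0)
#> <iph_segmentation> >200% of muscle mean | total 0.000 mm^3, max axial 0.000 mm^3, length 0.0 mm
segment_levelset(s$volume, s$truth$plaque_mask)
#> <iph_segmentation> levelset | total 14.415 mm^3, max axial 4.228 mm^3, length 4.0 mm
```

The subject's IPH contrast is 1.8× muscle, so the 150% criterion and the
contrast-driven level-set proxy both recover the true 14.415 mm³ exactly,
while the 200% criterion finds nothing — the mechanism by which
aggressive thresholds lose agreement with manual segmentation.

The full simulated study (40 subjects, contrast uniform on [1.3, 3.0],
Rician noise):

```r
run_study(study_config(seed = 11))
#> <study_result> n = 40 subjects, seed 11
#>
#> ICC vs manual arm:
#>  method       icc    ci_low   ci_high           band  n            model
#>    150% 0.9605809 0.9262261 0.9791109 almost perfect 40 twoway-agreement
#>    175% 0.5056680 0.2304609 0.7059724       moderate 40 twoway-agreement
#>    200% 0.4000789 0.1011794 0.6327320       moderate 40 twoway-agreement
#>
#> Planned one-sided comparisons (Bonferroni-adjusted):
#>                             hypothesis statistic   p_adjusted significant
#>  ICC(manual, 150%) > ICC(manual, 200%) 6.5791864 4.730295e-11        TRUE
#>  ICC(manual, 175%) > ICC(manual, 200%) 0.5726971 5.668498e-01       FALSE
```

Agreement with the manual proxy decreases monotonically with the
threshold, and the 150% criterion sits in a higher interpretation band
than the 200% criterion.

A thin command-line front end wrapping these functions is installed at
`system.file("cli", "iphquant.R", package = "iphquant")` with subcommands
`simulate`, `segment`, `segment-manual`, `agree` and `run-study`; see the
header of that file for usage, and
`system.file("extdata", "study_default.yaml", package = "iphquant")` for
a study configuration template.

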