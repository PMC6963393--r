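---
title: "Quantifying carotid intraplaque hemorrhage: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying carotid intraplaque hemorrhage: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iphquant)
```

## The problem

Intraplaque hemorrhage (IPH) inside carotid atherosclerotic plaque is a
marker of plaque instability and a risk factor for ischemic stroke. On
T1-weighted MPRAGE-type MR sequences, IPH appears hyperintense because
methemoglobin shortens T1, and the standard way to make "hyperintense"
operational is to reference plaque signal to adjacent neck muscle:
a voxel is called IPH when its intensity exceeds a fixed multiple of the
mean sternocleidomastoid muscle (SCM) signal. Different groups use
different multiples (150%–200%), and the choice changes the measured IPH
volume substantially.

`iphquant` implements both arms of a method-agreement study of this
question entirely in silico:

* a **semi-automatic arm**: muscle-referenced intensity thresholding at
  configurable ratios (defaults 1.5, 1.75, 2.0) with a minimal-extent rule
  (hyperintensity must persist over at least two consecutive slices), and
  three metrics — total IPH volume, maximal axial IPH volume, and IPH
  length;
* a **manual-proxy arm**: a two-phase region-based level-set segmenter,
  standing in for a reader's manual delineation with clinical plaque
  software;
* the **agreement analysis**: intraclass correlation coefficients (ICC)
  with 95% confidence intervals and a six-band verbal scale, one-sided
  Fisher z comparisons of ICCs, and Bonferroni adjustment;
* a **phantom generator** supplying cohorts with exact ground truth, which
  is what makes the pipeline testable: no public dataset exists for this
  design, and real studies of it lack histologic ground truth entirely.

## The phantom and what it does (not) emulate

Each synthetic subject is a 64 × 64 × 16 voxel grid at 0.31 × 0.31 × 1 mm
(the reconstructed in-plane resolution and slice thickness typical of
carotid MPRAGE protocols), containing:

* a tubular vessel (suppressed lumen, 1 mm wall) along the slice axis;
* an angular-sector plaque (140°, 3.2 mm radial thickness, 12 slices) —
  thick enough that every phantom passes the plaque-qualification rule
  (wall > 2 mm in ≥ 2 consecutive slices, `qualify_plaque()`);
* an ellipsoidal IPH inside the plaque whose noiseless intensity is exactly
  `intensity_ratio ×` the configured muscle mean — the contrast is defined
  on the same scale the thresholds operate on;
* a rectangular muscle block (mean 100 a.u., voxelwise Gaussian
  variability sd 5) from which reference points are sampled;
* Rician noise (default σ = 5, i.e. SNR 20 at muscle — a realistic
  magnitude-image noise level at 3T), applied after composition. Gaussian
  noise is available for analytically simple checks.

Across a default cohort (n = 40, the typical single-centre series size),
the contrast ratio is uniform on [1.3, 3.0] — spanning clearly
sub-threshold to strongly hyperintense IPH — and the ellipsoid semi-axes
are uniform on [0.8, 1.4] mm in-plane and [1.5, 4.5] mm axially, giving
true volumes of roughly 4–37 mm³ (the small-IPH regime where threshold
choice matters most). These distributions are stand-ins, exposed in
`cohort_spec()`, not claims about any clinical population.

The geometry primitives are deliberately idealized — tube, sector,
axis-aligned ellipsoid, block — because they admit *exact* voxel-count
ground truth (`true_iph_volume` is literally the IPH voxel count times the
voxel volume). The phantom does **not** emulate pulse-sequence physics,
coil-sensitivity shading, partial-volume mixing at tissue interfaces,
motion or flow artifacts, or irregular IPH morphology. Consequently,
passing tests demonstrate that the *pipeline* is correct and that the
threshold-vs-contrast mechanism behaves as designed; they do not
demonstrate reader-level accuracy on clinical images.

## Semi-automatic segmentation: interpretation decisions

The reference is the arithmetic mean of exactly three sampled muscle
voxels by default (`sample_muscle_reference()`, relaxable for synthetic
experiments). Several details of the criteria are underdetermined by the
usual verbal description; the package fixes them as follows, each isolated
in one function:

* **Strict inequality.** A voxel qualifies iff `value > ratio × mean`,
  matching the ">150%" notation; ties at the exact threshold are excluded
  (`threshold_criterion(strict = TRUE)`).
* **Connectivity.** The consecutive-slice rule is applied per connected
  component under 26-connectivity (the most permissive standard 3-D
  choice); 6-connectivity and a whole-mask variant are configurable
  (`enforce_consecutive_slices()`). A 26-connected component's slice
  support is always a contiguous interval, so the rule reduces to "the
  component spans ≥ 2 adjacent slice indices".
* **Maximal axial volume** is the largest single-slice contribution
  (per-slice voxel count × voxel volume); **length** is the inclusive
  occupied-slice span × slice thickness (`compute_metrics()`).
* The plaque mask is an explicit input; estimating wall thickness from the
  image is out of scope (clinically it is read manually).

Two invariants follow from the construction and are asserted on random
inputs in the test suite: nesting (the 200% mask is a subset of the 175%
mask is a subset of the 150% mask, even after component filtering) and
invariance to global intensity rescaling (the criteria are ratios).

## The level-set proxy

Manual IPH delineation in clinical plaque software uses region-based
active contours. The package implements the piecewise-constant two-phase
member of that family: segment the plaque into IPH/non-IPH by minimizing

$$E(M, c_{in}, c_{out}) = \lambda_{in}\!\!\sum_{v \in M}(I_v - c_{in})^2
 + \lambda_{out}\!\!\sum_{v \notin M}(I_v - c_{out})^2 + \mu\,|\partial M|$$

restricted to the plaque, where $|\partial M|$ is counted as unlike
in-slice 4-neighbour pairs (contour evolution is slice-wise 2-D, matching
how axial plaque images are read, while the consecutive-slice rule and
metrics are then applied in 3-D with the same code path as the
semi-automatic arm). The piecewise-*smooth* variant is a documented
extension point; the constant variant is the standard reproducible choice
when no parameters of the original clinical tool are published.

**Optimization.** Instead of a gradient-descent PDE with a time step, the
energy is minimized by sequential single-voxel reassignment sweeps (each
move accepted only if it lowers the energy at the current phase means)
alternating with exact mean updates. Both step types are non-increasing,
so the recorded energy trace is monotone *by construction*, the result is
deterministic, and there is no step-size parameter to tune. Convergence is
declared when a sweep makes no moves and the relative change in the two
phase means falls below `tol` (default 1e-6); `max_iters` (default 200)
caps the outer loop and the convergence status is reported.

**Parameters.** `lambda_in = lambda_out = 1` treats both phases
symmetrically. The length weight defaults to `mu = 0.1 × var(plaque
intensities)`: tying it to the intensity variance makes the proxy, like
the threshold arm, invariant to global rescaling, and 0.1 is small enough
that on noiseless two-level phantoms the true boundary is a fixed point
(verified in the tests) while still suppressing isolated noise voxels.

**Initialization.** The contour needs a seed on the hyperintense side.
The default is the plaque voxels above `median + 3 × MAD` of the plaque
intensities: because IPH is a small hyperintense fraction, the median and
MAD are anchored to the tissue mode and the seed lands on IPH for any
contrast the cohort produces, including ratios below 1.5 where a
muscle-referenced seed would be empty and a symmetric two-class split
(2-means/Otsu) can bisect the dominant noise mode instead. A
muscle-referenced seed (`init = "threshold"`) and a user-supplied mask
(`init = "mask"`) remain available. A constant plaque (no contrast) is
rejected as a degenerate input rather than segmented.

Because the proxy classifies by *contrast within the plaque* rather than
against the muscle reference, it recovers IPH across the whole contrast
range — which is precisely the mechanism that makes high thresholds
disagree with it: a 200% criterion truncates every subject whose IPH sits
below twice the muscle mean to (near) zero volume, deflating agreement.
No claim is made that the proxy reproduces any particular human reader;
that cannot be validated without reader data.

## Agreement statistics

`icc()` computes single-rater ICCs from the two-way subjects × methods
ANOVA mean squares: one-way random (ICC(1,1)), two-way consistency
(ICC(3,1)), and the default two-way random absolute agreement (ICC(2,1)).
Absolute agreement is the default because an IPH *volume* must match in
value across methods — a threshold that halves every volume should not
receive a perfect score, as it would under consistency.

Confidence intervals default to the Fisher z construction,
$\tanh(\mathrm{atanh}\,\hat\rho \pm z_{1-\alpha/2}/\sqrt{n-3})$, which is
simple, respects the (−1, 1) range, and empirically holds its nominal
coverage here (0.9585 over 2,000 simulated n = 40 cohorts at true ICC
0.8, inside the tested band 0.95 ± 0.015). Exact F-based (Shrout–Fleiss)
intervals, with a Satterthwaite approximation for the agreement form, are
available via `ci_method = "f"`. Neither is claimed to be what any
particular clinical study used — that is generally unstated in this
literature, which is itself a reproducibility lesson.

`compare_icc()` tests H0: ρ_a = ρ_b by the difference of
Fisher-transformed estimates with standard error
$\sqrt{1/(n_a-3) + 1/(n_b-3)}$, one-sided by default. Two caveats are
explicit in the documentation: (i) the test assumes independent cohorts,
whereas comparing several thresholds against one shared manual arm induces
positive dependence — `compare_icc_boot()` provides a subject-resampling
alternative for that case; (ii) estimates exactly equal to 1 (which occur
on synthetic data when two methods select identical voxel sets) are
clamped to machine tolerance before the transform so that two perfect
ICCs compare as equal. `bonferroni()` multiplies each p-value by the
number of planned hypotheses (2 in the default study) and clips at 1.

Numerical edge cases: a zero-variance measurement table is an error (ICC
undefined); the raw agreement-form estimate can fall below −1 on
adversarial small samples, in which case the raw value is returned (so
oracle equivalence holds to 1e-10) but the band and CI use the value
truncated into [−1, 1]; n < 3 is an error and intervals require n ≥ 5 by
default.

## The simulated study

`run_study()` composes everything: generate the cohort, verify plaque
qualification, segment each subject with the manual proxy and each
threshold, tabulate per-subject metrics, and compute the ICC and
comparison tables. The whole result is a pure function of the master
seed. A `manual_arm = "truth"` mode substitutes the ground-truth volumes
for the proxy, for statistical experiments uncontaminated by segmentation
error. `export_comparison_plot_data()` emits the long-format per-subject
volume table behind a per-patient comparison chart.

Under the default conditions the study reproduces the qualitative
clinical finding that motivates threshold calibration: agreement with the
manual arm is ordered ICC(150%) ≥ ICC(175%) ≥ ICC(200%), with the 200%
criterion typically one or more interpretation bands below the 150%
criterion. The mechanism is visible in the per-subject table: subjects
with contrast below a criterion's ratio contribute zero or truncated
semi-automatic volumes while the contrast-free proxy recovers them.

## Validation problem sizes

The shipped test suite validates: exact noiseless recovery and the
threshold-ordering mechanism; bit-exact equivalence of the full
semi-automatic path against a naive loop/flood-fill reference on 50
random grids (up to 24 × 24 × 10); the consecutive-slice rule unit cases
and idempotence; mask nesting on 200 noisy phantoms; ICC equality with a
loop-based ANOVA oracle to 1e-10 on 100 random small tables; CI coverage
and test size with 2,000 Monte-Carlo replicates each; level-set recovery
(Dice ≥ 0.95 noiseless, ≥ 0.85 noisy), energy monotonicity and
determinism; and the qualitative study pattern over 25 master seeds of
the full 40-subject design. These sizes were chosen to give stable
Monte-Carlo margins at interactive runtimes.

## Known limitations

* The phantom's idealized geometry cannot probe partial-volume or
  morphology effects on the thresholds; quantitative ICC magnitudes on
  phantoms should not be read as predictions for clinical cohorts.
* The manual proxy is an algorithm, not a reader; inter-reader
  variability, editing behavior, and blinding are outside what software
  can reproduce.
* The Fisher z comparison of dependent ICCs is approximate (see above).
* DICOM ingestion, registration, resampling and coil-sensitivity
  correction are out of scope; volumes are interchanged as NIfTI with
  explicit spacing.
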