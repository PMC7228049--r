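---
title: "Methods: two-shell diffusion markers, QC and the synthetic cohort"
author: "dwimarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-shell diffusion markers, QC and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwimarkers)
```

## The measurement problem

Acute perturbations of brain-tissue microstructure — here the motivating
case is pharmacological inhibition of astrocytic aquaporin-4 water
channels — produce small, regionally specific changes in how hindered
water diffusion is. Conventional ADC mapping from b = 0 and b = 1000
s/mm² mixes perfusion effects into the low-b anchor and is weakly
sensitive to the non-Gaussian, high-b part of the decay where hindrance
expresses itself. The two markers implemented here instead use two
non-zero *key* shells, `Lb = 250` and `Hb = 1750` s/mm²: low enough to
retain signal, high enough (at `Lb`) to make intravoxel-incoherent-motion
perfusion contributions negligible, and far enough apart to span Gaussian
and non-Gaussian diffusion jointly.

All computations start from direction-averaged shell signals normalized
by the mean b = 0 signal (`normalize_and_average()`). Direction averaging
is appropriate because the analysis targets gray-matter regions with no
usable anisotropy at this resolution; fractional anisotropy is
deliberately out of scope.

## The two markers

The **shifted ADC** is the two-point log-slope over the key shells,

$$\mathrm{sADC} = \frac{\ln(S_{Lb}/S_{Hb})}{Hb - Lb} \quad [\mathrm{mm^2/s}],$$

an apparent diffusion coefficient that inherits sensitivity to hindrance
from the high shell. It satisfies exact identities used as test oracles:
`sadc(s, s) = 0`, halving `S_Hb` adds `ln 2 / (Hb − Lb)`, and an imposed
exponential decay rate is recovered exactly at any signal scale.

The **signature index** locates a voxel's (or ROI's) signal pair between
two reference *signatures*: `S_A`, a tissue with moderately increased
hindrance, and `S_B`, generic gray-matter-like tissue. With an
intermediate signal `S_N` and per-shell relative distances
$dS_X(b) = (S_X(b) - S_N(b))/S_N(b)$, each signature (and the voxel) is
summarised by its span $\Delta_X = dS_X(Hb) - dS_X(Lb)$, and

$$SI = \max(\Delta_V/\Delta_A,\, 0) - \max(\Delta_V/\Delta_B,\, 0), \qquad
\mathrm{Sindex} = (SI + 1)\cdot 25 + 25 .$$

The ratio form is the one consistent with the scale's anchors: a voxel
equal to signature A has $\Delta_V = \Delta_A$, hence $SI = +1$ and
Sindex 75; signature B gives $SI = -1$ and Sindex 25; a voxel at `S_N`
gives 50. The default `S_N` rule is the per-shell arithmetic mean of the
two signatures — the natural reading of an "intermediate" signal — under
which $\Delta_A = -\Delta_B$ and the index is antisymmetric about 50.
The rule is configurable (`signature_library(s_n_rule = ...)`); with an
asymmetric `S_N` the two max-branches genuinely differ.

`Sindex` is **not clamped** during computation: regional values outside
[25, 75] (even outside [0, 100]) are meaningful relative orderings, and
clamping would bias ROI averages. A display clamp, if desired, belongs in
rendering code only.

### ROI convention

ROI-level markers average the *signals* over the ROI's valid voxels first
and then apply the marker formulas. `sADC` is nonlinear in the signals,
so this is a real convention, not a detail; the mean-of-voxelwise-markers
variant is available as a diagnostic (`roi_markers(voxel_mean = TRUE)`)
but never used by the pipeline. (Under the symmetric mean `S_N` rule the
scaled index happens to be linear in the signals, so for Sindex the two
conventions coincide there.)

### The kurtosis signal model and the reference library

Signatures are built on the standard diffusion-kurtosis signal
representation

$$S(b)/S_0 = \exp\!\left(-bD + (bD)^2 K/6\right),$$

with diffusivity `D` (mm²/s) and excess kurtosis `K` (dimensionless).
Accepted parameters must give a positive, strictly decreasing signal over
the used b-range, which bounds `K < 3/(b_{max} D)`; `K > −3` is enforced
as a plausibility floor. Because only two shells are used, the model is
exactly invertible: `fit_two_point()` solves, with log-attenuations
$L_i = -\ln S_i$ and $r = Hb/Lb$,

$$D = \frac{L_2 - r^2 L_1}{Lb\, r (1 - r)}, \qquad
K = \frac{6 (Lb\, D - L_1)}{(Lb\, D)^2},$$

which the tests verify both as an identity (round trip to 1e-12) and
against a brute-force two-stage grid search. The shipped library —
`S_A = (0.858, 0.370)`, `S_B = (0.855, 0.317)` at (250, 1750) s/mm² —
corresponds to fits of `D ≈ 6.20×10⁻⁴, K ≈ +0.46` (A) and
`D ≈ 6.22×10⁻⁴, K ≈ −0.31` (B): signature A is the same tissue with
kurtosis (hindrance) raised. Along this model family, raising `K` at
fixed `D` strictly raises Sindex and strictly lowers sADC, which is why a
hindrance *decrease* appears as the joint Sindex-down / sADC-up pattern
the pipeline is built to detect.

## Quality control

Serial scans of an immobilised subject should be temporally stable; motion
and hardware instability are visible as temporal variance. For each shell
(b0, Lb, Hb) each scan's map is smoothed spatially (isotropic Gaussian,
default FWHM 2 voxels, edge-renormalised separable kernel) and the
temporal coefficient of variation CV = sd/mean is computed per voxel. A
voxel is flagged when CV *strictly* exceeds the threshold (default 4%) in
any shell. The percentage threshold only makes sense relative to the
mean, hence CV rather than raw sd; the statistic is computed on
direction-averaged shell maps (normalization cancels global gain drift,
which the b0 shell still catches). Because the temporal sd is a
session-level statistic, the discard unit is the whole subject session:
any flagged voxel inside any analysis ROI removes the subject
(`apply_discard_rule()`), with the removal logged.

Degenerate voxels (zero or undefined temporal mean) are flagged rather
than silently passed. Voxels with `s0` at or below an absolute noise
floor (default 1e-12) are masked at normalization time, never propagated
as exceptions.

## Cohort aggregation and statistics

* **Pre/post windows**: per subject, ROI and marker, the pre value is the
  mean of the scans with negative acquisition time (six of them in the
  default design) and the post value the mean of the session's final six
  scans — read literally as the last six of the twelve post-injection
  scans, when the effect has plateaued. Window selection is order-based
  on scan index, never interpolated; permuting table rows changes
  nothing.
* **Time courses**: consecutive triples of 5-minute scans are averaged
  into six points at 15-minute resolution, stamped at the triple's mean
  acquisition time (−25, −10, +5, +20, +35, +50 min in the default
  design).
* **Outlier filter**: at each time point, within each group, a
  single-pass |z| > 3 filter against the group mean and sd (candidate
  included, no re-iteration). Zero sd means no exclusions; fewer than
  three subjects skips the filter with a warning. The filter applies to
  time-course points only; window means use all non-discarded scans.
* **Tests**: paired two-sided t-tests pre vs post per group/ROI/marker;
  between-group Welch tests on the pre and post window means with Holm
  step-down correction within each marker's comparison family; and
  uncorrected per-time-point Welch tests. Holm was chosen over
  Bonferroni as uniformly more powerful without an independence
  assumption, and Welch over pooled-variance t because equal variances
  are not guaranteed; both choices are configurable and recorded in the
  report. Degenerate cases (single-subject groups, zero variance with
  unequal means) are reported as not computable rather than crashing;
  zero variance with equal means reports p = 1.

## The synthetic cohort generator

`phantom_spec()` fixes the study conditions the generator emulates:

| parameter | default | meaning |
|---|---|---|
| grid | 32 × 32 × 8 voxels | phantom volume |
| scheme | 1 × b0 + 6 × 250 + 6 × 1750 s/mm² | three shells, six directions |
| session | 18 scans of 5 min, 6 pre-injection | serial design |
| groups | vehicle / tgn020, 16 subjects each | two-arm cohort |
| noise | Rician, SNR 40 at b0 | magnitude-MRI standard |
| baseline | fit of signature B per ROI, small K offsets | regional contrast |
| effect | −9% noiseless cortical Sindex at plateau; ×1.3 in hippocampus (and CA3/DG); 0 in striatum and background | regional hindrance decrease |
| ramp | linear over 3 post-injection scans, then plateau | sustained effect |

The atlas (`make_atlas()`) is a deterministic function of the grid: a
cortical band along the slice perimeter, striatal and hippocampal blocks
inside, CA3 and DG carved out of the hippocampus, with voxel counts
strictly ordered DG < CA3 < hippocampus < striatum < cortex as in real
mouse-brain atlases. The 32 × 32 × 8 default keeps a full 32-subject
cohort simulation and analysis in the tens of seconds on one CPU while
leaving every ROI large enough for stable ROI means; it is a phantom
scale choice, not an imaging matrix.

The **effect model** moves each affected ROI's kurtosis parameters along
the negated B→A signature direction — the natural "hindrance decrease"
axis of the library — with `calibrate_effect()` solving one-dimensionally
for the plateau that produces the requested noiseless cortical Sindex
change (±0.1 percentage point; the search uses machine-precision root
finding). The calibration domain is bounded by parameter validity *and*
by the nominal Sindex floor of 0: beyond that the linear scaling of the
index no longer represents a position between the signatures, so targets
requiring it (e.g. −200%) raise a typed "unreachable" error.

**Noise** is Rician: the magnitude of the noiseless signal plus complex
Gaussian noise with per-channel sd `s0/SNR`. At SNR 40 the Rician bias on
b0 is below half a percent (guarded by a test); a Gaussian option exists
for analytic checks, and `snr = Inf` gives exact model signals, which is
how the closed-form oracles enter the integration tests.

**Instability injection** models motion-like artifacts for QC testing: a
sinusoidal temporal modulation of the diffusion-weighted volumes around
each listed locus, at full amplitude at the locus and Gaussian-tapered
with the spatial scale `instability_radius` (zero beyond three radii),
completing two cycles over the session. The modulation is regional by
design: the QC filter smooths spatially before computing temporal CV, so
a strictly single-voxel disturbance is attenuated roughly tenfold by the
default kernel and is not recoverable by *any* threshold near 4% — and
isolated one-voxel artifacts are not what temporal instability looks
like. A 10% amplitude yields a post-smoothing CV of ≈ 5.5–6% at the
locus, comfortably above the 4% threshold, while unmodulated voxels at
SNR 40 sit near 0.6%.

**Determinism**: every subject's seed is derived arithmetically from the
master seed; identical seeds give bit-identical volumes, and two
file-based pipeline runs with the same seed produce byte-identical
tables (manifests store paths relative to their own directory for this
reason).

### What the phantom does and does not show

The phantom is isotropic (no direction dependence), piecewise-constant
per ROI, free of partial-volume effects, EPI distortion, eddy currents
and motion, and its anatomy is schematic. Tests passing on it therefore
validate the *computational* pipeline — marker formulas, normalization,
QC logic, aggregation, statistics, determinism — under the study's
acquisition geometry and noise level. They do not validate registration,
bias-field or denoising quality (the pipeline assumes those were done
upstream), nor biological effect sizes: the −9% cortical calibration
target sets the simulated effect's scale, it does not predict a real
tissue's response.

## Numerical choices

* Noise floor for `s0` masking: absolute, default 1e-12 (normalized
  signals are undefined without b0 signal); configurable.
* Gaussian kernel truncated at 3σ with in-bounds renormalisation at
  edges — no padding bias for cortical-band voxels near the volume face.
* Strict inequality at the CV threshold (a voxel at exactly the
  threshold is kept), matching the reading of the threshold as an
  exceedance level; the boundary is tested with exactly representable
  values.
* Shell assignment uses greedy 1-D clustering of sorted b-values with a
  tolerance (default 50 s/mm²); a b-value within tolerance of two shells
  is rejected as ambiguous rather than assigned arbitrarily.
* Tables are serialised with 17 significant digits, so write→read is
  exact for doubles.

## Known limitations

* Whole-session discard is the only QC granularity wired into the
  pipeline; per-scan discard would require a different (windowed)
  stability statistic.
* Per-time-point tests are reported uncorrected across ROIs and time
  points, as is conventional for time-course figures; they should be
  read as descriptive, not confirmatory.
* The two-point kurtosis inversion is exact but propagates noise from
  exactly two measurements; it is a calibration and simulation tool, not
  a substitute for multi-shell kurtosis estimation.
* One-sided "z > 3" could be read literally in the outlier rule; the
  two-sided |z| form was adopted as the defensible interpretation and is
  configurable in spirit via the cutoff.

## A minimal end-to-end run

```{r example, eval = FALSE}
spec <- phantom_spec(seed = 42)
res <- simulate_and_analyze(spec, n_per_group = 4, master_seed = 42)
subset(res$prepost$groups, marker == "sindex")
plot_timecourse(res$course, "cortex", "sindex")
```
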