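# dwimarkers

Two-shell diffusion-MRI markers for longitudinal brain studies, in R.

Serial diffusion-weighted MRI can detect subtle microstructural change —
for example the decrease in water-diffusion hindrance that follows acute
pharmacological inhibition of astrocytic aquaporin-4 (AQP4) water channels
in the rodent brain. `dwimarkers` implements the two markers tailored for
that purpose and the full analysis pipeline around them, for imaging
scientists analysing serial multi-shell DWI of small-animal (or other)
brains.

## The markers

Both markers are computed from direction-averaged signals at two *key*
b-values, `Lb = 250` and `Hb = 1750` s/mm², normalized by the b = 0 signal.
The low key shell is high enough to suppress perfusion (IVIM) effects; the
high one is sensitive to non-Gaussian, hindrance-driven diffusion.

**Shifted ADC.** A two-point apparent diffusion coefficient over the key
shells:

    sADC = ln(S(Lb) / S(Hb)) / (Hb − Lb)        [mm²/s]

**Signature index (Sindex).** The tissue's signal pair is located between
two reference signatures — `S_A`, a tissue with moderately *increased*
diffusion hindrance, and `S_B`, generic brain tissue — via per-shell
relative distances to an intermediate signal `S_N` (per-shell mean of A
and B):

    dS_X(b) = (S_X(b) − S_N(b)) / S_N(b)
    Δ_X     = dS_X(Hb) − dS_X(Lb)
    SI      = max(Δ_V/Δ_A, 0) − max(Δ_V/Δ_B, 0)
    Sindex  = (SI + 1)·25 + 25

so a tissue matching signature A scores 75, one matching B scores 25, and
S_N scores 50. A *decrease* in hindrance shows up as a joint Sindex
decrease and sADC increase. The reference signatures ship with the package
(`default_signature_library()`), built on the diffusion-kurtosis signal
model `S/S0 = exp(−bD + (bD)²K/6)`; `fit_two_point()` inverts that model
from the two shells in closed form.

## The pipeline

* `read_dwi()`, `read_scheme()`, `read_labels()`, `read_manifest()` —
  NIfTI-1 volumes, FSL-style row bval/bvec tables, integer ROI atlases with
  a label dictionary, and a study manifest.
* `normalize_and_average()` — direction-averaged, normalized shell signals.
* `flag_unstable_voxels()` / `apply_discard_rule()` — temporal
  coefficient-of-variation QC (4% threshold after spatial smoothing);
  sessions with flagged voxels inside any analysis ROI are discarded.
* `marker_maps()`, `roi_markers()` — voxelwise parametric maps and
  ROI-level markers (signals averaged over the ROI first, then markers).
* `prepost_average()`, `build_timecourse()`, `exclude_outliers()`,
  `run_stats()` — pre/post window means (6 scans each), six-point time
  courses (triples of 5-minute scans), |z| > 3 outlier filtering, paired
  and between-group Welch tests with Holm correction.
* `phantom_spec()`, `simulate_subject()`, `simulate_cohort()`,
  `simulate_and_analyze()` — a seeded synthetic cohort generator
  (three-shell scheme, 18 serial scans, two 16-subject groups, Rician
  noise, calibrated regional effect) so the whole pipeline is testable
  end to end without data.
* `run_all()` and friends — file-based stages with provenance records; a
  thin CLI wrapper lives at `inst/scripts/dwi-pipeline.R`.

## Worked example

```r
library(dwimarkers)

lib <- default_signature_library()
sindex(0.858, 0.370, lib)   # 75  — signature A (more hindered)
sindex(0.855, 0.317, lib)   # 25  — signature B (generic tissue)
sadc(0.855, 0.317)          # 0.0006614665 mm^2/s

# simulate a small cohort (4 subjects/group) and analyse it end to end
spec <- phantom_spec(seed = 42)
res  <- simulate_and_analyze(spec, n_per_group = 4, master_seed = 42)
subset(res$prepost$groups, marker == "sindex")
#>    group         roi marker n p_paired mean_change pct_change
#>   tgn020      cortex sindex 4 3.85e-06     -2.2536    -8.7436
#>  vehicle      cortex sindex 4 5.04e-01      0.0238     0.0921
#>   tgn020 hippocampus sindex 4 1.89e-04     -3.0209   -11.5948
#>  vehicle hippocampus sindex 4 7.72e-01     -0.0484    -0.1852
#>   tgn020    striatum sindex 4 1.43e-01     -0.1191    -0.2897
#>  vehicle    striatum sindex 4 3.54e-01     -0.1739    -0.4228
```

The active (`tgn020`) group shows the simulated hindrance decrease — a
significant Sindex drop of ≈ 9% in cortex and ≈ 12% in hippocampus, no
change in striatum — while the vehicle group is flat everywhere; the sADC
rows show the mirror-image increase. Per-time-point tests
(`res$stats$timepoint`) are null at the two pre-injection points and
strongly significant from the first post-injection point on.

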