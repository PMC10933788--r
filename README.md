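# lsmsim

Simulation-based validation of voxel-wise lesion-symptom mapping (LSM),
with a focus on paired two-modality lesion-mask cohorts (e.g. CT- and
MR-derived masks of the same stroke patients).

## The problem

Mass-univariate LSM splits a patient cohort at every brain voxel into
lesioned and intact groups and tests whether the groups differ on a
behavioral score, yielding a thresholded z-map of candidate neural
correlates. Whether the method actually recovers the correlate it is
pointed at — and whether the answer depends on the imaging modality the
lesion masks were traced on — cannot be established on real behavior,
because the ground truth is unknown. `lsmsim` implements the standard
workaround: behavior is *simulated* from a known critical site, the full
analysis is run blind, and the result map is scored against that site.

For the researcher this answers concrete design questions: how much lesion
coverage a voxel needs before results become trustworthy, how far result
clusters sit from the true target, how Bonferroni compares with
max-statistic permutation correction, and how much two modality arms of
the same cohort can be expected to agree.

## What is implemented

* **Masks** — binary lesion masks on a shared grid, NIfTI I/O (RNifti),
  z-direction Gaussian smoothing with re-binarization at 0.5, overlay
  (patients-per-voxel) maps, coverage-based voxel inclusion
  (`counts ≥ n_min`, default 8), Dice overlap with exclusive fractions.
* **Synthetic cohorts** — a seedable generator of paired two-arm lesion
  cohorts: territory-clustered placement, log-normal volumes, calibrated
  cross-arm disagreement (default cohort: mean pair Dice ≈ 0.42,
  paired-volume r ≈ 0.78, ~30/30/40% shared/A-only/B-only overlap
  composition, arm B testable at more voxels than arm A), plus a toy
  connected ROI atlas.
* **Behavior simulation** — percent-of-ROI-damaged scores (ROI targets)
  and binary impairment at a critical voxel (voxel targets); noiseless.
* **LSM engine** — one-tailed pooled-variance t (continuous) and the
  Liebermeister quasi-exact test (binary): the hypergeometric upper tail
  `P(X ≥ a+1)` of the 2×2 table with concordant cells incremented,
  `X ~ Hypergeom(n+2, a+c+1, a+b+1)`. All statistics are mapped to one z
  scale; thresholds by Bonferroni (`Φ⁻¹(1−α/V)`) or max-statistic
  permutation FWE; optional lesion-volume control.
* **Evaluation** — hits, Dice versus target, peak-voxel sets with ties,
  center-of-mass and peak displacement, cluster-size-weighted
  displacement, the maximum achievable Dice bound
  `2·min(|A|,|B|)/(|A|+|B|)`, paired threshold sweeps, and hit-proportion
  chi-squared contrasts.
* **Pipeline** — `run_study()` orchestrates mask comparison, ROI-level
  simulations (both corrections), voxel-level simulations (every included
  voxel as a target), and the paired z-map sweep, with YAML config, CSV/JSON
  outputs and full seed-determinism. A thin CLI lives at
  `inst/cli/lsm_pipeline.R`.

## Worked example

Generate a small paired cohort, plant a deficit at the best-covered voxel
of arm A, run the Liebermeister analysis with Bonferroni correction, and
score the result against the planted target:

```r
library(lsmsim)

co  <- generate_cohort(cohort_params(n_patients = 30,
                                     grid = grid_spec(c(16, 16, 16), c(4, 4, 4)),
                                     seed = 1))
co
#> <cohort_pair> 30 patients on 16x16x16 grid
#>   pair Dice 0.444 (SD 0.191), volume r 0.613, both/A/B 30%/27%/43%

arm <- cohort_arm(co, "A")
ov  <- lesion_overlay(arm)
tgt <- included_voxels(ov, 8)[which.max(ov$counts[included_voxels(ov, 8)])]
beh <- simulate_behavior(arm, target_spec("voxel", voxel = tgt))
zm  <- run_lsm(arm, beh, lsm_config(n_min = 8))
zm
#> <lsm_zmap> liebermeister/bonferroni: 508 tested (0 skipped), threshold z >= 3.7230, 55 significant

evaluate_zmap(zm, target_spec("voxel", voxel = tgt))
#>    hit n_significant dice_vs_target com_distance_mm n_peak peak_distance_mm
#> 1 TRUE            55     0.03571429        1.590052      1                0
```

Reading the output: 508 voxels were lesioned in at least 8 of the 30
patients and therefore tested; at the Bonferroni z-cutoff 3.72, 55 voxels
are significant. The planted target voxel is inside the significant
cluster (`hit = TRUE`) and is the unique peak (`peak_distance_mm = 0`);
the cluster's center of mass sits 1.6 mm from the target. The Dice of the
55-voxel cluster against the 1-voxel target is low by construction — its
maximum achievable value is `2·1/(55+1) ≈ 0.036`, which is why cluster
Dice must always be read against the `max_achievable_dice()` bound.

The full study (descriptive mask comparison, ROI and voxel stages, paired
threshold sweep) is one call:

```r
report <- run_study(default_run_config(seed = 7, out_dir = "run1"))
```

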