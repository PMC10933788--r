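---
title: "Simulating and validating voxel-wise lesion-symptom mapping"
author: "lsmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and validating voxel-wise lesion-symptom mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsmsim)
```

## The problem

Voxel-based lesion-symptom mapping (LSM) relates the presence of brain
damage at each voxel, across a cohort of stroke patients, to a behavioral
score. At every voxel lesioned in at least `n_min` patients, the cohort is
split into lesioned and intact groups, a statistic is computed, and the
resulting 3D statistical map is thresholded under a family-wise error
correction. Whether such an analysis actually recovers the neural correlate
it is pointed at — and how strongly the answer depends on which imaging
modality the lesion masks were traced on — is an empirical question that
cannot be answered on real behavior, because the ground truth is unknown.

`lsmsim` implements the standard answer: *simulation*. A ground-truth
"critical site" (an atlas ROI or a single voxel) is chosen, behavior is
generated from the lesions themselves, the full LSM pipeline is run blind,
and the result map is scored against the known target. Because paired
two-modality cohorts (e.g. CT- and MR-derived masks of the same patients)
are central to the question, the package also ships a seedable synthetic
generator of paired lesion cohorts with calibrated cross-modality
disagreement, so the entire study runs from nothing but a seed.

## Behavior simulation

Both designs are noiseless and deterministic:

* **ROI targets** — each patient's score is the percent of the target ROI
  their lesion covers: `100 * |lesion ∩ ROI| / |ROI|`. A lesion covering
  60% of the target scores 60.
* **Voxel targets** — a patient is *impaired* (1) exactly when their lesion
  contains the critical voxel, otherwise *unimpaired* (0).

Higher score means more deficit, so all one-tailed tests look for
lesioned > intact. The simulations deliberately contain no behavioral
noise: they probe the spatial biases of the method itself (lesion
geometry, coverage, correction), not measurement error.

## Voxel-wise statistics

* **Pooled-variance t** (continuous scores): the classical equal-variance
  two-sample t with `df = n1 + n2 - 2`. Voxels with fewer than two
  patients in either group, or zero pooled variance, are skipped and
  counted.
* **Liebermeister quasi-exact test** (binary scores): for the 2×2 table
  (a = lesioned & impaired, b = lesioned & unimpaired, c = intact &
  impaired, d = intact & unimpaired), the one-tailed p-value is the
  hypergeometric upper tail of the table with both *concordant* cells
  incremented by one: with `N = n + 2`, `K = a + c + 1`, `m = a + b + 1`,

  `p = P(X ≥ a + 1),  X ~ Hypergeometric(N, K, m)`.

  This quasi-exact form, standard in the nonparametric lesion-mapping
  literature, is pinned in the test suite by brute-force enumeration of the
  hypergeometric mass over every table with `n ≤ 12`.
* **p → z** — every statistic is converted to a one-tailed z-score
  (`z = Φ⁻¹(1 - p)`) so that all thresholds live on a single z scale
  regardless of statistic. p is clamped to `[1e-300, 1 - 1e-16]` first, so
  perfect associations map to a large finite z rather than infinity.

### Corrections

* **Bonferroni**: `z_thr = Φ⁻¹(1 - α / V)` with `V` the number of tested
  voxels — so the cutoff depends on coverage and differs between arms that
  can test different numbers of voxels.
* **Max-statistic permutation FWE**: the behavior vector is permuted across
  patients (the same vector that entered the statistic, i.e. the
  volume-residualized one when volume control is on), the voxel-wise
  maximum z is recorded per permutation, and the threshold is the empirical
  `100(1-α)` percentile of that max-z sample. Conventions pinned for
  reproducibility: linear-interpolation quantile (R type 7), the observed
  statistic is *not* appended to the null sample, ties in the max are kept
  exactly, and the permutation stream is seeded from the configuration.

### Lesion-volume control

For continuous scores, volume control residualizes the behavior on total
lesion volume (least squares, intercept included) before testing. An exact
2×2 test admits no covariate, so binary analyses default to the raw-table
Liebermeister test; `binary_volume_control = "glm"` instead fits ordinary
least squares of impairment on (lesion status, volume) and uses the lesion
coefficient's one-tailed t. Both choices are deliberate conventions for a
step whose standard practice is genuinely underspecified; the default
keeps the exact test exact.

## Evaluation metrics

* **Hit** — the significant set intersects the target ROI / contains the
  target voxel.
* **Dice** — `2|A∩B| / (|A| + |B|)`; `Dice(∅, ∅)` is reported as missing,
  never 0 or 1, so empty result maps cannot fake perfect agreement.
* **Maximum achievable Dice** — `2·min(|A|,|B|) / (|A|+|B|)`: the bound
  imposed by unequal map sizes (a 2:1 ratio caps Dice at 2/3 ≈ 0.66). All
  cross-map Dice values should be read against this bound rather than 1.
* **Peak voxels** — all tested voxels attaining the maximum z; ties are
  kept as a set and peak displacement is the mean distance of the peak set
  to the target.
* **Center-of-mass distance** — unweighted centroid of the significant set
  to the target voxel, in mm.
* **Size-weighted displacement** — displacement divided by the
  equivalent-sphere radius `r = (3V/4π)^{1/3}` of the significant cluster,
  making displacement dimensionless relative to cluster size. The
  "cluster" here is the whole significant set (connected-component
  decomposition is available via `label_components()` but is not the
  default, since no connectivity convention is canonical).
* **Threshold sweep** — arm B's map is fixed at its own Bonferroni
  threshold while arm A's z-map is re-binarized at `k` evenly spaced
  thresholds (endpoints included) from a lower bound up to arm B's
  threshold; mean Dice per threshold is summarized with the argmax
  threshold (ties broken toward the lowest) and compared against the mean
  maximum-achievable Dice at that threshold. Pairs with undefined Dice are
  excluded from means, not zero-filled.

## The synthetic cohort generator

The generator emulates the *statistical* structure a paired-modality LSM
study rests on — not anatomy:

* **Territory clustering.** Six ellipsoidal "vascular territories" (two
  middle-, two posterior-, two anterior-circulation analogues per
  hemisphere, weights 0.35/0.35/0.06/0.06/0.09/0.09) inside an ellipsoidal
  brain region. A lesion picks a territory by weight, centers near its
  core (Gaussian jitter with SD one-eighth of the territory radii), and
  grows as a noisy blob: voxels are ranked by an anisotropic distance
  score, normalized to the lesion's own target radius, plus smoothed
  Gaussian shape noise (amplitude 0.35), and the top-V voxels connected to
  the peak form the lesion. The normalization matters: it keeps every
  sizable territory lesion anchored on the territory core, which is what
  gives real cohorts their deep overlay maxima (tens of patients at the
  core voxels).
* **Volumes.** Log-normal with median 18 cm³ and log-SD 1.1, truncated to
  the brain; at the default 4 mm grid this reproduces mean lesion volumes
  of roughly 33 (arm A) and 41 cm³ (arm B) with a 0.1–250 cm³ range.
* **Paired degradation.** Each arm re-derives its mask from the shared
  base lesion: smooth, shift by a small integer jitter, add smoothed noise
  of per-patient magnitude (log-normal around `perturb_mag`), and
  re-threshold to a log-normally drawn target size; arm B is inflated by
  1.33 on average. The per-arm log size error has SD 0.45, scaled by
  `(V_ref/V)^{1/6}` (boundary-localized disagreement is relatively smaller
  for large lesions) and truncated at ±1.8 SD (so one giant discordant
  pair cannot dominate the volume correlation). With some probability an
  arm drops one connected component of a multi-focal mask, emulating
  single-modality false negatives. Degraded masks may be multi-focal; only
  the base lesion is required to be connected.

### Calibration

`perturb_mag` and `arm_size_noise_sd` were fixed once by a pilot
one-dimensional search (`calibrate_perturbation()`) so that the default
85-patient cohort reproduces the agreement structure such paired cohorts
show: mean pair Dice ≈ 0.42, paired-volume Pearson r ≈ 0.78, and roughly
30/30/40% of union voxels shared / exclusive to A / exclusive to B, with
arm B passing the ≥ 8-patient coverage filter at more voxels than arm A.
At the default seed the achieved values are Dice 0.426 (SD 0.18) and
r 0.783; across seeds these statistics fluctuate by about ±0.05 and ±0.1
respectively, which is the inherent sampling spread of an 85-patient
cohort with heavy-tailed volumes.

### What the generator does *not* emulate

Real vascular anatomy, gray/white tissue boundaries, hemorrhagic versus
ischemic morphology, lesion evolution between scan dates, registration
distortion, and rater behavior. Passing tests on synthetic cohorts
therefore demonstrate that the *pipeline* recovers planted signal under
the assumed statistical structure — not that any particular real-world
modality is adequate.

## Numerical and design conventions

* Binarization threshold is closed at 0.5 (`≥ 0.5`), on read and after
  smoothing.
* Mask smoothing is 1-D Gaussian along z only
  (`σ = FWHM / (2√(2 ln 2)) / voxel size`), discrete kernel truncated at
  4σ and renormalized, zero-padded boundaries (tissue assumed absent
  outside the volume). An isolated voxel does not survive 5 mm FWHM
  smoothing on a 1 mm grid (center weight ≈ 0.19 < 0.5); a solid column
  does.
* Voxel indices are 1-based linear indices (R convention); world
  coordinates place voxel (1,1,1) at the origin and scale index
  differences by the voxel size, so all distances are unaffected by the
  origin convention.
* ROI analyzability: an analysis runs only if at least one voxel passes
  the coverage filter and the simulated behavior has non-zero variance.
  This is the minimal well-defined criterion; it is *not* tuned to
  reproduce any particular published inclusion count.
* The voxel-level stage computes all per-target tables by one co-occurrence
  cross-product of the binary patient × voxel design (exact integer counts),
  then a single vectorized hypergeometric tail call — bit-identical to the
  naive per-voxel loop, which the test suite asserts.
* Permutation count defaults to 500 in the ROI stage for desk-scale runs;
  the conventional 2000 is one flag away (`roi_n_permutations`, or
  `--permutations 2000` on the CLI).

## Problem sizes

The default configuration runs the whole study — cohort generation,
mask comparison, 24 ROI analyses × 2 arms × 2 corrections, every included
voxel of both arms as a target (a few thousand analyses), and the paired
threshold sweep — on a 32×40×32 grid at 4 mm with 85 patients, in about a
minute single-threaded. Grid, cohort size, ROI count, permutation count
and target subsampling are all configurable for larger runs.

## Known limitations

* Pearson correlation of heavy-tailed paired volumes is intrinsically
  noisy at n = 85; seed-to-seed spread of ±0.1 around the calibrated value
  is expected.
* The permutation threshold with a degenerate (constant) continuous
  behavior vector is undefined (no valid statistic anywhere); the analysis
  returns an empty, flagged result rather than a number.
* Only one covariate (lesion volume) is supported, matching standard
  practice; rank statistics and multivariate or disconnection-based
  mapping are out of scope.
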