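Package: lsmsim
Title: Simulation-Based Validation of Voxel-Wise Lesion-Symptom Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates behavioral deficits from ground-truth lesion targets,
    runs mass-univariate lesion-symptom mapping (pooled-variance t and
    Liebermeister quasi-exact statistics with Bonferroni and max-statistic
    permutation family-wise error corrections) on paired two-modality
    binary lesion-mask cohorts, and quantifies result accuracy and
    cross-modality agreement via hits, Dice overlap, peak and
    center-of-mass displacement, and threshold sweeps bounded by the
    maximum achievable Dice. Includes a seedable synthetic generator of
    territory-clustered paired lesion cohorts and a toy ROI atlas so the
    full study pipeline is reproducible without imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
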