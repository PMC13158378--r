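Package: lfamp
Title: Low-Frequency Amplitude and Connectivity Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resting-state BOLD low-frequency amplitude analysis: ALFF,
    fractional ALFF and temporal-SNR map computation with confound regression (no
    detrending), six-control-point framewise displacement and motion quality
    control, test-retest repeatability via ICC(2,1) and Bland-Altman agreement,
    voxelwise two-group inference with permutation maxT family-wise error control
    and cluster-extent filtering, and seed-based functional connectivity with a
    per-region linear mixed-effects group model under Benjamini-Yekutieli false
    discovery rate control. Includes a synthetic two-group, two-session BOLD
    cohort generator with known ground truth so every stage is testable without
    access to real imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    lme4,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
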