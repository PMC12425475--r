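Package: attfield
Title: Dynamic Estimation of the Spatial Attentional Field from Visual
    Cortical Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs one-dimensional polar-angle profiles of BOLD
    modulation from voxelwise population receptive field (pRF) estimates and
    fits a scaled, offset generalized Gaussian to recover the location, width
    (full width at half maximum), gain, and baseline of the spatial
    attentional field.  Includes a block-design fMRI simulator with known
    ground truth for end-to-end parameter-recovery validation, percent-signal-
    change and high-pass preprocessing, circular profile construction
    (binning, recentering, moving-average smoothing), two-dimensional visual
    field reconstruction for quality control, and group-level statistics
    (pooled goodness-of-fit exclusion, per-subject slope regressions, paired
    comparisons, behavioral accuracy tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
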