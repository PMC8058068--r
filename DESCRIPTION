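Package: itemconn
Title: Single-Trial Item-Series Connectivity for Slow Event-Related fMRI
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for slow event-related fMRI repetition-priming
    studies built around single-trial peak BOLD responses ("item series").
    Provides a synthetic-data generator with planted ground truth; behavioral
    trial filtering, item norms, a Primeability median split and Cohen's d
    priming effect sizes; FIR/TENT deconvolution with peak-beta and item-series
    extraction; whole-brain connectedness, seed maps, GCOR and sphere ROIs;
    covariance-based structural equation modeling with AIC-guided model search
    and per-condition parameterization; multi-voxel pattern similarity with a
    trialwise signal-to-noise adjustment; gamma-variate hemodynamic response
    fitting with peak-time contrasts; and shared linear mixed-effects and FDR
    inference utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    jsonlite,
    knitr
Config/testthat/edition: 3
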