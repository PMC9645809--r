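Package: respnet
Title: Respiration, Gamma-Band LFP, and Resting-State fMRI Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the coupling between slow respiration
    variations, gamma-band local field potential (LFP) power, and
    resting-state fMRI (rsfMRI) signals in simultaneously recorded rodent
    data. Includes MR gradient-artifact denoising of electrophysiology by
    slice-locked template regression, respiration metrics (peak/trough
    detection, respiration volume per time, RETROICOR phase regressors,
    respiration response function convolution), fMRI preprocessing
    (framewise-displacement scrubbing, nuisance regression, masked spatial
    smoothing, ROI extraction), coupling statistics (Welch coherence and
    cross-spectral phase, hemodynamic response convolution, voxel-wise
    correlation maps, confound regression, seedmaps, functional-connectivity
    matrices, group t-tests with Benjamini-Hochberg FDR), and a synthetic
    data generator that emulates the statistical structure of such
    recordings for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
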