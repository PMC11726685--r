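Package: nordicfmri
Title: Locally Low-Rank Thermal-Noise Denoising and Evaluation for fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: NORDIC-style locally low-rank denoising of complex-valued or
    magnitude fMRI time series with random-matrix singular-value
    thresholding, together with the evaluation machinery needed to
    quantify its effect on event-related data: a synthetic generator for
    complex-valued runs with known ground truth (g-factor maps, appended
    no-excitation noise scans, structured physiological noise), single
    trial GLM estimation with a canonical two-gamma HRF, temporal SNR and
    FDR activation maps, repeated split-half and leave-one-run-out
    reliability, sign-flip permutation tests and repeated-measures ANOVA
    with Greenhouse-Geisser correction, variance partitioning of the
    original series into denoised and removed components, and laminar /
    tonotopic profiling on label volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
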