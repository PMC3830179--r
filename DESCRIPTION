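Package: nirqc
Title: Near-Infrared Spectroscopic Quality Control of a Two-API Capsule
    Formulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Development and validation of near-infrared (NIR)
    diffuse-reflectance quality-control methods for a fixed-dose
    artesunate plus azithromycin powder blend in hard gelatin capsules.
    Provides blend-design generation over 80-120% of label claim, a
    synthetic NIR spectra simulator (Gaussian component bands,
    multiplicative scatter, baseline drift, repack averaging), dual-region
    spectral pre-processing (standard normal variate and Savitzky-Golay
    derivatives), PLS1 content calibration with cross-validated factor
    selection, PCA-based specificity screening against placebo and
    degradant challenges, and method validation by beta-expectation
    tolerance-interval accuracy profiles against fixed acceptance limits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: grDevices, graphics, jsonlite, signal, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
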