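Package: dichoptics
Title: Binocular Contrast Gain Control Modelling and Dichoptic Neuroimaging Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-stage binocular contrast gain-control model with
    tonic (attenuation) and dynamic (asymmetric interocular suppression)
    variants, together with the steady-state visual evoked potential (SSVEP)
    and fMRI analysis pipelines used to measure dichoptic contrast-response
    functions. Includes seedable generators for EEG-like and BOLD-like
    recordings whose signal structure follows the model, windowed Fourier and
    adjacent-bin signal-to-noise analysis with coherent averaging, block-design
    GLM estimation, travelling-wave coherence, population receptive field
    fitting, and group-level statistics with model fitting and AIC-based
    variant selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
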