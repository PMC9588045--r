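Package: lamina
Title: Laminar fMRI Analysis of Valence Modulation in Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for studying layer-specific and
    retinotopically-diffuse emotional-valence modulation in human visual
    cortex with block-design fMRI. Provides seeded synthetic-data
    generators that emulate three-condition face protocols at 3T and 7T
    (including interleaved blood-nulled/not-nulled VASO acquisitions and a
    cortical ribbon with depth-dependent cerebral-blood-volume effects);
    GLM fitting with a canonical haemodynamic response and FIR
    deconvolution of mean evoked responses; residual inter-area
    correlation analysis with per-condition epoching and valence
    contrasts; VASO BOLD-contamination correction and T1-EPI anatomical
    contrast; equidistant 21-depth cortical layering with
    uncertainty-weighted spline smoothing of depth profiles; a
    region-based Bayesian multilevel model with Student-t likelihood and
    crossed condition/region/subject varying effects fitted by a blocked
    Gibbs sampler with interweaved recentering moves; retinotopic
    eccentricity binning; and end-to-end orchestration of the whole
    analysis on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags,
    coda,
    knitr,
    rmarkdown
Config/testthat/edition: 3
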