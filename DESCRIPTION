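Package: ovoscope
Title: Calibrated Eggshell Appearance Analysis from VIS/UV Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for measuring avian eggshell appearance from pairs of
    calibrated visible-light and ultraviolet photographs and for modelling its
    spatial and environmental variation. Raw camera counts are linearized and
    normalized against a grey reflectance standard to percent reflectance;
    maculation spots are segmented inside a region of interest by local
    adaptive thresholding; the visible-frame spot mask is transferred into the
    UV frame through a Local Weighted Mean transform fitted to manually marked
    control points; egg volume and surface area follow from revolving the
    outline about its long axis. The statistical stage performs
    correlation-matrix PCA of the log trait variables, random-intercept mixed
    models with penalized-spline or polynomial fixed effects fitted by profiled
    (restricted) maximum likelihood, AICc model selection with Akaike weights,
    marginal and conditional R-squared, and concurvity diagnostics. A synthetic
    egg-image and trait-dataset generator with full ground truth makes every
    stage verifiable without the original photographs.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    tiff,
    igraph,
    splines,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mgcv,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
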