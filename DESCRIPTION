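Package: dcefit
Title: Pharmacokinetic Model Fitting for T1-Weighted DCE-MRI
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pixel-wise pharmacokinetic analysis of dynamic
    contrast-enhanced MRI (DCE-MRI) series. Implements the Tofts,
    extended Tofts, Hoffmann, Larsson and reference-region compartmental
    models, MR signal-to-concentration calibration for spin-echo and
    spoiled gradient-echo sequences, variable-TR T1 mapping,
    Levenberg-Marquardt estimation of parameter maps over regions of
    interest at selectable pixel resolutions, model-free semi-quantitative
    parameters (RCE, IAUC, TTM), and a self-contained digital reference
    object generator for validating the full pipeline against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
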