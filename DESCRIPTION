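Package: iamdist
Title: Biomimetic IAM Chromatography and In Vivo Distribution Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Calibration of gradient retention times measured on immobilized
    artificial membrane (IAM) HPLC columns to the chromatographic
    hydrophobicity index (CHI) scale, conversion of CHI(IAM) to the
    octanol/water-comparable log K(IAM) lipophilicity scale, and linear
    biomimetic-binding models that estimate human in vivo distribution
    properties (steady-state volume of distribution, unbound volume of
    distribution, tissue unbound fraction, brain tissue binding and drug
    efficiency) from IAM and human serum albumin binding.  Includes column
    system-suitability testing against reference CHI values, paired-column
    comparison statistics with a 2xSEE outlier rule, refitting of the
    distribution models on clinical data, and a synthetic compound-set
    generator for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
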