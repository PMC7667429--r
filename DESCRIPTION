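Package: MucosalScope
Title: Multimodal Widefield and Nonlinear Optical Microscopy Analysis of
    Oral Epithelial Neoplasia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of multimodal optical imaging of oral
    mucosa for neoplasia detection. Computes the internal-control-normalized
    red-to-green autofluorescence ratio from widefield images, extracts
    basal nuclear morphometry (coefficient of variance of nuclear area) and
    the epithelial-connective-tissue-interface contour (triangulated
    surface-area ratio via Heron's formula) from two-channel multiphoton /
    second-harmonic z-stacks, and classifies imaged sites as neoplastic or
    non-neoplastic with ROC analysis, logistic generalized linear models and
    forward selection. Includes a synthetic-data generator that emulates
    widefield scenes, nonlinear-microscopy stacks and class-conditional
    feature cohorts with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'calibration.R'
    'synthetic-table.R'
    'synthetic-wf.R'
    'synthetic-nlom.R'
    'widefield.R'
    'nlom-morphometry.R'
    'nlom-ecti.R'
    'classify.R'
    'io.R'
    'pipeline.R'
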