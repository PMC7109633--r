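Package: somiteCPM
Title: Compartmental Cellular Potts Model of Somite Division Under Axial Strain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-dimensional compartmental Cellular Potts Model (CPM) of a
    single somite embedded in an elastic extracellular-matrix mesh. Epithelial
    cells are polarized into apical, lateral and basal compartments; tight
    junctions between apical domains and intracellular cytoskeletal links are
    modelled as elastic springs. Axial tension applied to the matrix stretches
    the somite, ruptures the apical junction ring, and contact-timer rules
    convert mesenchymal somitocoel cells to epithelial cells
    (mesenchymal-to-epithelial transition, MET). The package includes shape
    morphometrics on labelled lattices (gyration-tensor aspect ratio,
    epithelial cell fraction, somitocoel size, division detection), ROC/AUC
    analysis of aspect ratio as a predictor of somite division with bootstrap
    confidence intervals, and seed-deterministic synthetic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'somiteCPM-package.R'
    'RcppExports.R'
    'params.R'
    'classes.R'
    'builder.R'
    'dynamics.R'
    'morphometrics.R'
    'roc.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
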