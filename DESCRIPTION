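Package: solshift
Title: Solubility-Shift Interactomics and Reporter Quantification for C. elegans Proteostasis Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification toolkit for fractionated co-immunoprecipitation
    LC-MS/MS experiments and the companion organismal assays used in
    C. elegans proteostasis and lipid-surveillance studies. Computes
    per-protein solubility ratios and destabilization indices from
    soluble/insoluble spectral-index tables, bait-normalized relative
    binding with a PSM detection filter, hypergeometric over-representation
    of selected protein sets with Benjamini-Hochberg correction,
    threshold-based cross-dataset classification of differential-expression
    tables, and the standard reporter quantification rules
    (nuclear/cytosolic fold scoring, time-of-flight-normalized large-particle
    flow cytometry, oil red O inverse-brightness density, electron-micrograph
    black-threshold fractions, delta-delta-Ct, and absorption impairment
    scoring). A seeded synthetic-data generator with ground-truth records
    allows every stage to be exercised end to end without raw instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'tables-io.R'
    'solubility.R'
    'interactome.R'
    'enrichment.R'
    'deg-compare.R'
    'reporter-quant.R'
    'synthetic-data.R'
    'pinned-bounds.R'
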