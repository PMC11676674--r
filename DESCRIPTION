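Package: cbmnassay
Title: Automated Scoring and Statistics for the In Vitro Cytokinesis-Block
    Micronucleus Assay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated analysis of the in vitro cytokinesis-block
    micronucleus (CBMN) genotoxicity assay. Provides a ground-truthed synthetic
    image generator for DNA-stained fields and single-cell tiles; a widefield
    microscopy scoring pipeline (nuclei segmentation, watershed declumping,
    mono-/bi-/poly-nucleated cell classification, micronucleus detection and
    parent assignment); an imaging-flow-cytometry-style route (morphological
    mask algebra, per-tile features, sequential gating to the binucleated-cell
    population, micronucleus spot counting); and the standard CBMN endpoints:
    cytokinesis-block proliferation index (CBPI), cytostasis and cell-number
    cytotoxicity, micronucleus frequency under both common denominator
    conventions, fold change and percent reduction contrasts, four-parameter
    logistic IC50 fitting for MTT viability data, and one-way ANOVA with Tukey
    multiple comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    EBImage,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, ImageAnalysis, Software
LinkingTo: Rcpp
VignetteBuilder: knitr
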