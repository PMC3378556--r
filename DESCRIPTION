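Package: rnacov
Title: Covariation Analysis of RNA Alignments with Phylogenetic Event Counting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies base pairs and weaker structural constraints in RNA
    multiple sequence alignments by combining a phylogenetic event counting
    (PEC) statistic computed on a non-binary phylogeny with frequency-based
    covariation measures (mutual information, its average-product-corrected
    form, and OMES). Candidate pairs pass an entropy/mutual-information
    coarse filter, significant pairs are called with a Joint N-Best ratio
    strategy, helices are extended with canonical-pair frequency rules,
    base-pair purity is scored, and residual "neighbor effect" covariations
    are annotated with three-dimensional base-center distances and evaluated
    against a reference secondary/tertiary structure. A seeded simulator
    produces alignments and trees with planted compensatory pairs so every
    stage can be validated against a known truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
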