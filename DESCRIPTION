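Package: replichore
Title: Inferring Bacterial Chromosome Topology from Interreplichore Translocations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for inferring gross bacterial
    chromosome topology (longitudinal versus transverse) from the frequency
    and symmetry of interreplichore gene translocations between closely
    related genome pairs. Provides an oriC-anchored circular coordinate
    system with chromosomal bins, annotation readers (NCBI PTT and GFF3),
    bidirectional best-hit orthology with a pluggable scorer, growth
    physiology annotation (R-factor), gene-order conservation and bin-wise
    translocation statistics, interreplichore symmetry (D_inter) with
    randomized nulls, strand-flip analysis, COG and horizontal-transfer
    positional enrichment, chromosome contact-map enrichment tests, and a
    synthetic genome-pair generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
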