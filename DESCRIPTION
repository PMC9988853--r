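Package: multiwayc
Title: Multiway Chromatin Contact Processing and Single-Allele Topology
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes long-read chromatin concatemer alignments into
    multiway contact records and analyses them: merging and filtering of
    per-read split alignments, in-silico restriction annotation,
    decomposition into virtual pairwise contacts, contact-matrix binning
    with iterative-correction balancing, compartment eigenvectors and
    insulation scores, structural-unit spanning statistics, negative
    binomial enrichment of trans-chromosomal 1-Mb bin pairs with hub
    partitioning, Ward clustering of read-by-bin occupancy matrices into
    single-allele topology clusters, regulatory multiway interaction
    models, and per-read CpG methylation analyses linked to chromatin
    structure. Includes a synthetic concatemer generator with planted
    compartments, TADs, loops, trans hubs and structured methylation so
    the whole pipeline can be exercised without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Matrix,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
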