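Package: loopcall4c
Title: Interaction Calling for 4C-Seq with Bayesian Log2-Proportion
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls chromatin interactions from circular chromosome
    conformation capture (4C-seq) read counts over restriction
    fragments. Builds in-silico restriction-fragment libraries, counts
    unique reads per fragment, estimates per-fragment expected
    log2-proportions under a Bayesian multinomial-Poisson (Dirichlet
    posterior) model, calls strongly positive interactions as the top
    decile of interacting sites, intersects replicates, and bins
    genome-wide profiles. Companion quantification tools cover 3C qPCR
    interaction frequencies with primer-efficiency correction,
    restriction-digestion quality control, allele-specific nucleosome
    occupancy by the delta-delta-Ct method, and 3D DNA-FISH
    co-localization. A seeded synthetic-data generator emulates the
    statistical structure of each assay so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
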