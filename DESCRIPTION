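Package: btudiv
Title: Host Specificity and Co-Divergence of Gut Microbiota at the Level
    of Binned Taxonomic Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes 16S rRNA amplicon sequence variant (ASV) tables
    into Binned Taxonomic Units (BTUs) by shared genus assignment or by
    complete-linkage sequence-similarity clustering, and quantifies for
    each BTU the strength of host-species specificity (PERMANOVA with
    adjusted R-squared) and of host-microbiota co-divergence
    (Procrustean cophylogeny on principal-coordinate embeddings, with a
    species-block permutation null), compositional and phylogenetic.
    Includes a Dirichlet-multinomial community simulator that plants
    null, host-specific and co-diverging BTUs so that every stage of the
    pipeline can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    vegan,
    phangorn,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
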