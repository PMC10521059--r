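Package: amoebaLGT
Title: Post-Assembly Genome Interrogation for Lateral Gene Transfer in
    Amoeba Draft Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-assembly interrogation of draft genomes from
    bacterivorous amoebae and other microbial eukaryotes: contamination
    triage of scaffolds by taxonomy, GC aberrance and read coverage;
    taxonomic partitioning of predicted gene models from protein best
    hits; Alien-Index scoring and calling of putative lateral gene
    transfers (LGT) with donor attribution, intron content and
    expression cross-referencing; a sex/meiosis gene-toolkit inventory
    with per-sample transcript detection matrices; intragenomic
    SSU-rDNA divergence assessment; and neighbor-joining corroboration
    of LGT candidates. A seeded synthetic-data generator emulates the
    statistical structure of a multinucleate marine amoeba draft
    genome and provides planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, Annotation, Software
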