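Package: quidsig
Title: Mutational Signatures and CpG-Island Mutation Enrichment in Tongue
    Carcinoma Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of somatic single-base-substitution (SBS)
    catalogs from tongue carcinoma cohorts, including those associated with
    betel-quid chewing: trinucleotide-context classification into the 96
    COSMIC classes, de-novo signature extraction by nonnegative matrix
    factorization with bootstrap-stability rank selection, cosine-similarity
    matching of extracted signatures to a reference panel with
    complete-linkage clustering, CpG-island core-versus-flank mutation-rate
    enrichment with Fisher's exact test, and cohort-level comparison
    statistics. A synthetic-data module simulates reference genomes with
    CpG islands and mutation catalogs drawn from signature mixtures so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    cluster,
    pracma,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
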