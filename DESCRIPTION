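Package: amptill
Title: Pooled Amplicon Sequencing Simulation and Mutant Retrieval for
    EMS-Mutagenized Populations
Version: 0.1.0
Authors@R:
    person("Mutant Screen", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and benchmarking TILLING-by-sequencing
    screens of chemically mutagenized (EMS) plant populations. Simulates a
    doubly-mutagenized selfing population with a configurable substitution
    spectrum, two-tier DNA pooling with dual sequencing indexes, and pooled
    paired-end amplicon reads with a known ground truth. Provides read
    trimming, gapless amplicon alignment to stranded pileups, a threshold
    based low-frequency pool variant caller, a cross-sample background
    polymorphism filter, codon-level effect annotation, mutation density and
    spectrum statistics, and deconvolution of pool-level calls back to
    individual plants with an end-to-end benchmark against simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
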