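Package: malines
Title: Mutation-Accumulation Line Analysis for Multicellular Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects line-specific accumulated mutations in mutation-accumulation
    (MA) experiments from multi-sample genotype data, estimates per-line
    single-nucleotide and indel mutation rates normalized by callable genome
    length and generations, characterizes mutation spectra (six-class SNV
    spectrum, ts/tv, AT bias, triplet context, indel length distributions,
    coding/noncoding annotation), compares groups with the rank-sum, variance-F
    and Fisher exact tests, and estimates false-positive and false-negative
    detection rates by planted-mutation benchmarking. A synthetic MA-experiment
    generator (founder genome, Poisson mutation accumulation per line, a
    sequencing/genotyping emulator with depth, genotype-quality and
    contamination noise) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
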