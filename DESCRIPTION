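Package: recombiscan
Title: Detection of Somatic Meiotic-Like Recombination from Short-Read
    Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A read-backed pipeline for detecting somatic meiotic-like
    recombination in fungal heterokaryons from aligned short reads.
    Calls biallelic heterozygous SNPs from mapping-quality-filtered
    pileups with inclusive depth and allele-balance thresholds, phases
    each read over windows of five consecutive heterozygous SNPs,
    classifies the two most frequent window haplotypes as parental and
    all others as recombinant, filters heterozygous SNPs and recombinant
    haplotypes shared with parental homokaryon samples, summarises
    per-sample recombinant read fractions, and computes fold enrichment
    of recombinant reads over genic and intergenic genome partitions.
    Includes a seeded synthetic-data generator (reference, clustered
    heterozygous SNPs, crossover molecules, error-bearing aligned reads
    with full ground truth) so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
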