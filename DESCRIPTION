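Package: viromer
Title: Long-Read Viral Metagenomics: Read QC, Population Dereplication and
    Microdiversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream informatics for short- and long-read viral
    metagenomes: Nanopore read trimming and quality filtering, chimeric read
    detection from all-vs-all overlaps, bootstrap comparisons of read-length
    distributions, ANI-based dereplication of viral contigs into populations,
    construction of multi-assembly "enhanced" viromes with shared/unique
    attribution, per-contig microdiversity (nucleotide diversity, pi) from
    base-quality-filtered pileups under explicit SNP-truth rules, and assembly
    error profiling (mismatches and indels per 100 kbp, N50, ORF length
    summaries). Ships a seeded mock-community simulator that emits genomes,
    strain variants, error-bearing long reads with chimeras, paired short
    reads and ground-truth alignments so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
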