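Package: lcrcall
Title: Multilocus Variant Calling in Low-Copy Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variant discovery and paralog-specific genotyping in low-copy
    repeats (segmental duplications) from short-read data. Reads mapped to
    any repeat copy are pooled onto a representative copy through a
    homology map, candidate variants are discovered with a polyploid
    multinomial genotype model at the aggregate copy number, informative
    paralogous sequence variants (PSVs) are selected using population
    reference-allele frequencies and a conflict-graph filter, and
    paralog-specific genotypes are assigned by probabilistically locating
    read pairs on repeat copies via the informative PSVs they cover.
    Includes a self-contained simulator of LCR loci, sample haplotypes and
    error-bearing paired reads so the whole pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
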