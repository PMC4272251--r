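Package: mitohet
Title: Mitochondrial DNA Heteroplasmy from Off-Target Exome Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies mitochondrial DNA (mtDNA) single-nucleotide variants
    and heteroplasmy from the off-target reads of whole-exome sequencing.
    Parses samtools-style text pileups over the mitochondrial contig, calls
    SNVs with configurable depth and variant-read thresholds, estimates
    heteroplasmy as the variant-read fraction with exact (Clopper-Pearson)
    binomial confidence intervals, flags recurrent cross-sample artifacts and
    the unstable poly-C tract, lifts variant calls from alternative
    mitochondrial references onto rCRS coordinates by pairwise alignment,
    computes per-base coverage profiles and QC summaries, and compares call
    sets between sequencing platforms with per-base error rates and exact
    Poisson rate-ratio tests. A deterministic cohort simulator generates
    pileups, truth tables and gold-standard call sets so the whole pipeline
    can be exercised and validated without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
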