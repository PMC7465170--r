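Package: tevariant
Title: Transposable Element Insertion Variants from Long and Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transposable element (TE) insertion variants from
    sequencing data. Global variants (insertions fixed enough to enter a de
    novo assembly) are extracted from assembly-versus-reference alignments
    and classified against a TE consensus library; minor insertional
    variants (MIVs), low-frequency LTR insertions carried by as little as a
    single long read, are mined from read-versus-assembly alignments and
    validated with identity, consensus-coverage and length filters. Putative
    LTR insertions are corroborated by detecting the target site duplication
    (TSD) flanking the integration junction within individual reads, with an
    empty-site guided error-correction mode for noisy long reads. Also
    includes a discordant-read-pair insertion caller for paired-end short
    reads, Kimura two-parameter intra-family divergence, a binomial
    "trap-model" test of piRNA-cluster insertion enrichment, piRNA cluster
    localization and quantification helpers, and a synthetic-data generator
    (genomes, implanted TE copies with TSDs, noisy long reads, paired-end
    reads) so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
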