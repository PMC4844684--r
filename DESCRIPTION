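Package: skewsel
Title: Mutation-Selection-Drift Analysis of Nucleotide Skews in Transcribed Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the evolutionary forces shaping strand-specific
    nucleotide usage (AT and GC skews) in prokaryotic genomes under a
    mutation-selection-drift equilibrium model. From an annotated circular
    chromosome with a known replication origin, the package classifies sites
    into interoperonic, fourfold-synonymous and nonsynonymous categories on
    leading and lagging replication strands, computes observed skews, and
    inverts the equilibrium model to obtain per-genome replication mutational
    biases, transcription-associated scaled selection coefficients (S_RNA)
    and translation-associated coefficients (S_AA), together with global
    amplification (tau) and free-site (f) parameters fitted across genomes.
    Companion simulations generate no-selection null genomes, explore the
    nucleotide-cost versus amino-acid-cost trade-off encoded in the codon
    table, and produce fully synthetic annotated genomes with known ground
    truth for end-to-end validation. Expression stratification via the tRNA
    adaptation index, Wright's effective number of codons, preferred-codon
    detection, and phylogenetically independent contrast statistics are
    included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
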