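Package: plastcmp
Title: Comparative Analysis of Chloroplast Genome Pairs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing pairs of near-identical plastomes
    (chloroplast genomes). Detects the quadripartite LSC/IRb/SSC/IRa
    architecture by exact inverted-repeat search, censuses mononucleotide
    microsatellites with a length-proportional goodness-of-fit test,
    aligns genome pairs with unique-anchor chaining and calls fully
    classified SNPs and indels (region, coding effect, transition/
    transversion, homopolymer association), estimates synonymous
    divergence (NG86 and YN00-style counting) with molecular-clock
    dating, and confirms variants and predicted C-to-U RNA-editing sites
    from short reads via a one-mismatch aligner and pileups. Includes a
    seeded synthetic plastome-pair and read simulator with full ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
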