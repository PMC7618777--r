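Package: qtsuite
Title: Fitness Landscapes, Copying Fidelity and Quasispecies Dynamics for
    Minimal Polymerase Ribozymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for selection experiments on short RNA
    polymerase ribozymes that use trinucleotide triphosphate (triplet)
    substrates. Estimates per-genotype fitness as log-normalized enrichment
    from one round of activity selection, computes pairwise epistasis and
    scores compensatory evidence for RNA base pairs, quantifies per-position
    copying fidelity and G:U wobble-biased error spectra from product
    sequencing reads, models mutation-selection balance (quasispecies) on an
    empirical fitness landscape together with Eigen error-threshold
    calculations, fits single-exponential cleavage kinetics and first-order
    decay, and estimates the abundance of functional motifs in random
    sequence pools. A seeded synthetic-data generator emulates every input so
    the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
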