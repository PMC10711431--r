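Package: ssapkit
Title: Pooled Recombineering Screens for Single-Stranded DNA-Annealing Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and characterizing single-stranded
    DNA-annealing proteins (SSAPs) used in bacterial recombineering.
    Provides iterative profile (PSSM) homolog mining with greedy identity
    clustering and candidate prioritization, design of 60-mer
    lagging-strand recombineering oligonucleotides with a nearest-neighbor
    hairpin free-energy filter, stochastic simulation of two-round pooled
    serial-enrichment screens with barcoded noisy long-read output,
    abundance-trajectory analysis with active-variant calling, and
    allelic-replacement-frequency statistics including control
    subtraction, replicate t-tests, action-rate time-course fits and
    parental-subtracted off-target summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
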