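Package: priormotif
Title: Combinatorial Motif Discovery Guided by Position-Specific Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers transcription-factor binding-site motifs in sets of
    co-regulated DNA sequences by seeding candidate consensus words with an
    exhaustive extension-based enumerator and greedily refining them over the
    IUPAC alphabet to maximise the Balanced Information Score, an
    information-theoretic objective that fuses motif over-representation with
    any number of position-specific priors (PSPs) through a convex
    combination. Includes PSP file input/output and validation, a ChIP-seq
    peak-summit prior builder (discretised Student-t step function), a
    planted-motif synthetic-data generator with priors of controllable
    informativeness, a recovery benchmark harness, and a command-line front
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    Biostrings,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
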