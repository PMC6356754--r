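Package: sqfilter
Title: Reference-Free Quality Scoring and Selection of Long Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the quality of third-generation (PacBio, Oxford Nanopore)
    long reads without a reference genome. Each read is summarised by the
    content of all 84 mono-, di- and trinucleotide combinations; a linear
    least-squares model is trained on self-supervised labels (raw reads as
    low quality, error-corrected reads as high quality), all raw reads are
    cross-scored in two folds, and the top-scored fraction is retained.
    Includes alignment-based evaluation metrics (aligned rate, identity,
    score-identity correlation) computed from PAF or SAM alignments, and a
    seeded long-read simulator with homopolymer-biased indel errors and
    per-read ground-truth identity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
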