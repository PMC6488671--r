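Package: bandmsa
Title: Progressive Multiple Alignment of Similar DNA/RNA with Suffix Trees
    and Knowledge-Guided Banded Dynamic Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Progressive multiple sequence alignment for highly similar
    DNA/RNA sequences. Sequences are partitioned into equal-size segments;
    an Ukkonen suffix tree over each partner sequence identifies segments
    that occur verbatim (skipped entirely) and yields alignment-free
    similarity features (percent identity, percent length difference) for
    guide-order construction. Unmatched segments are aligned with a banded
    Needleman-Wunsch restricted to a small number of diagonals, the band
    width chosen by nearest-neighbour lookup in a learned knowledge base
    mapping similarity features to the percentage of diagonals required for
    an optimal alignment; on a miss, a word-match dot plot estimates the
    band and the result is learned back into the knowledge base. Includes
    sum-of-pairs scoring against a reference alignment, a synthetic
    similar-sequence family generator with true-alignment bookkeeping, and
    a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
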