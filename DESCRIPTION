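Package: psse
Title: Pairwise Statistical Significance Estimation for Local Sequence Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the statistical significance of a Smith-Waterman local
    alignment score directly from a permutation null of the subject sequence,
    without reference to a sequence database. The subject is shuffled N times
    with a reproducible 48-bit linear congruential generator, the query is
    aligned against every shuffle under an affine gap penalty, and the null
    scores are fitted to a Gumbel (type-I extreme value) distribution by
    censored maximum likelihood, yielding Karlin-Altschul style K and lambda
    and hence an E-value and P-value for the observed score. Supports standard
    substitution matrices (BLOSUM62 bundled) and position-specific scoring
    matrices read from PSI-BLAST ASCII output, single-pair and batched
    multi-pair modes with three batching strategies, and an arithmetic SIMT
    occupancy/tile model for planning batch sizes on wide parallel devices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    fitdistrplus,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
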