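Package: linkclust
Title: Single-Linkage Record Linkage with l-mer Blocking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates person records from multiple delimited text files with
    differing column layouts onto a shared canonical attribute schema, collapses
    exact duplicates, generates candidate record pairs by blocking on substrings
    of length l (l-mers) of a chosen attribute, scores pairs with configurable
    string comparisons (Levenshtein edit distance, field-reversal distance, and
    truncated edit distance), and links records of the same individual as the
    connected components of the threshold graph -- equivalently, single-linkage
    hierarchical clusters cut at an error threshold. Includes a synthetic
    multi-file person-record generator with ground-truth labels and pairwise
    precision/recall evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
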