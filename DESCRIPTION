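Package: seedchain
Title: Seed-Chain-Extend Whole-Genome Alignment with Partition-Parallel Chaining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pairwise whole-genome aligner built on the
    seed-chain-extend paradigm: minimizer seeding of exact k-mer anchors,
    co-linear chaining by dynamic programming with anchors partitioned by
    (reference sequence, strand) so partitions chain independently and in
    parallel, interval-tree accelerated classification of chains as primary
    or secondary by query-interval overlap fraction, and affine-gap
    base-to-base extension emitting PAF records with CIGAR strings. All
    parallel code paths (partitioned chaining, chunked stable sorting,
    batched scheduling) are output-identical to their sequential references
    for any worker count. A synthetic-genome module generates
    reference/query pairs with known point mutations, inversions,
    duplications and translocations plus truth records, so the aligner is
    testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
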