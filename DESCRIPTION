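Package: jitterbc
Title: Jitter-Aware Cell Barcode Recovery for Combinatorial Single-Cell Libraries
Version: 0.1.0
Authors@R:
    person("David", "Ogilvy", email = "dogilvy@example.org", role = c("aut", "cre"))
Description: Recovers cell barcodes from single-cell combinatorial (split-pool)
    barcoding libraries in which barcode elements drift by a few nucleotides
    ("jitter") from their designed positions. A subsample of reads is profiled
    for exact whitelist occurrences (seed), per-element expected positions are
    derived with diagnostics (harvest), and all reads are then demultiplexed
    with jitter- and mismatch-tolerant approximate matching (reap), emitting
    unaligned SAM or interleaved FASTQ plus run statistics. Two matching
    backends with identical semantics are provided: a precomputed
    mismatch-variant set for small whitelists and a trie plus pigeonhole seed
    index for large ones. Utilities recover barcodes already consumed by
    provider demultiplexing from FASTQ headers (weed), filter reads with
    unmatched barcodes (sift), and simulate combinatorial libraries with a
    ground-truth ledger for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
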