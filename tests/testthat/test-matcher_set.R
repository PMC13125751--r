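# Set-based matcher: query windows, the mismatch-variant index, the ranked
# matching contract, and oracle equivalence.

test_that("query window covers the jitter interval (worked example)", {
  read <- paste0(rand_barcodes(1, 30))
  qw <- extract_query_window(read, expected_start = 10, n = 4, x = 2)
  expect_equal(nrow(qw), 5L)            # five candidate sequences
  expect_equal(qw$start, 8:12)          # span position 8 to 12
  expect_true(all(nchar(qw$seq) == 4L))
})

test_that("query window pads clipped edges with N and handles x = 0", {
  read <- "ACGTACGTACGTACGTACGT"  # length 20
  qw <- extract_query_window(read, expected_start = 1, n = 4, x = 1)
  expect_equal(qw$seq[qw$offset == -1], paste0("N", substr(read, 1, 3)))
  expect_equal(qw$pad[qw$offset == -1], 1L)
  qw0 <- extract_query_window(read, expected_start = 5, n = 4, x = 0)
  expect_equal(nrow(qw0), 1L)
  expect_equal(qw0$seq, substr(read, 5, 8))
  # candidates fully outside the read are all-N with full pad
  qw_out <- extract_query_window(read, expected_start = 40, n = 4, x = 1)
  expect_true(all(qw_out$seq == "NNNN"))
  expect_true(all(qw_out$pad == 4L))
  # right-edge clipping pads on the right
  qw_r <- extract_query_window(read, expected_start = 19, n = 4, x = 0)
  expect_equal(qw_r$seq, paste0(substr(read, 19, 20), "NN"))
})

test_that("mismatch index enumerates exactly the Hamming ball", {
  wl <- whitelist("ACGT", "w")
  idx0 <- build_mismatch_index(wl, 0)
  expect_equal(idx0$n_entries, 1L)
  expect_equal(idx0$dt$variant, "ACGT")
  expect_equal(idx0$dt$dist, 0L)

  # brute-force oracle: enumerate all 2-mers, keep those within distance 1
  wl2 <- whitelist("AA", "w")
  idx1 <- build_mismatch_index(wl2, 1)
  all2 <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T")), 1, paste0,
                collapse = "")
  ball <- all2[vapply(all2, function(s) oracle_hamming(s, "AA") <= 1,
                      logical(1))]
  expect_equal(idx1$n_entries, 7L)  # 1 + 2*3
  expect_setequal(idx1$dt$variant, ball)
  # every barcode maps to itself at distance 0
  expect_equal(idx1$dt[idx1$dt$variant == "AA", ]$dist, 0L)

  # a variant reachable from two barcodes records both at minimal distance
  wl3 <- whitelist(c("AA", "AT"), "w")
  idx2 <- build_mismatch_index(wl3, 1)
  ac <- idx2$dt[idx2$dt$variant == "AC", ]
  expect_equal(sort(ac$bc), c(1L, 2L))
  expect_equal(ac$dist, c(1L, 1L))
})

test_that("mismatch index enforces the capacity cap with trie advice", {
  wl <- whitelist(rand_barcodes(16, 12), "big")
  expect_error(build_mismatch_index(wl, 2, cap = 1000), "trie")
})

test_that("matching follows the exact > fewest-mismatch > nearest ranking", {
  wl <- whitelist(c("ACGTACGT", "TTGGCCAA"), "w")
  params <- match_params(jitter = 1, max_mismatches = 1)
  idx <- build_mismatch_index(wl, 1)
  ep <- list(start = 5L)

  # identity: barcode exactly at the expected start
  read <- paste0("CCCC", "ACGTACGT", "CCCCC")
  h <- match_barcode_set(read, ep, wl, params, idx)
  expect_equal(h[c("status", "barcode", "mismatches", "offset")],
               list(status = "exact", barcode = "ACGTACGT",
                    mismatches = 0L, offset = 0L))

  # a perfect match one base downstream beats a 1-mismatch at offset 0:
  # read has ACGTACGT starting at 6; at start 5 the window sees a shifted
  # (mismatched) copy
  read2 <- paste0("CCCCC", "ACGTACGT", "CCCC")
  h2 <- match_barcode_set(read2, ep, wl, params, idx)
  expect_equal(h2$status, "exact")
  expect_equal(h2$offset, 1L)
  expect_equal(h2$barcode, "ACGTACGT")

  # one window equidistant from two DISTINCT barcodes -> null
  wl_amb <- whitelist(c("AAAAAAAA", "AAAAAATT"), "amb")
  idx_amb <- build_mismatch_index(wl_amb, 1)
  h3 <- match_barcode_set(paste0("CCCC", "AAAAAAAT", "CCCCC"), ep, wl_amb,
                          match_params(jitter = 0, max_mismatches = 1),
                          idx_amb)
  expect_equal(h3$status, "ambiguous_null")
  expect_equal(h3$barcode, "NNNNNNNN")
  expect_true(is.na(h3$mismatches) && is.na(h3$offset))

  # two distinct barcodes, each at one mismatch, one base up/downstream of
  # the expected start: read TAAAGGGT, es 3 -> window -1 = AAAG (1 mm from
  # AAAA), window +1 = AGGG (1 mm from GGGG), window 0 = AAGG (2 mm)
  wl2 <- whitelist(c("AAAA", "GGGG"), "w2")
  idx2 <- build_mismatch_index(wl2, 1)
  h4 <- match_barcode_set("TAAAGGGT", list(start = 3L), wl2,
                          match_params(jitter = 1, max_mismatches = 1), idx2)
  expect_equal(h4$status, "ambiguous_null")

  # no survivor -> no_match_null with an all-N barcode
  h5 <- match_barcode_set(strrep("T", 16), ep, wl_amb,
                          match_params(jitter = 1, max_mismatches = 1),
                          idx_amb)
  expect_equal(h5$status, "no_match_null")
  expect_equal(h5$barcode, strrep("N", 8))
})

test_that("same barcode tied at both signs keeps the upstream offset", {
  # the smallest |offset| always wins outright when it matches
  wl <- whitelist("AAAA", "w")
  idx <- build_mismatch_index(wl, 0)
  h0 <- match_barcode_set("AAAAAA", list(start = 2L), wl,
                          match_params(jitter = 1, max_mismatches = 0), idx)
  expect_equal(h0$offset, 0L)
  # a genuine +-1 tie of the SAME barcode: period-2 barcode AGAG in
  # TAGAGAGT with es 3 -> windows -1 (start 2) and +1 (start 4) are both
  # AGAG, window 0 (GAGA) is not; scan order picks upstream, not null
  wl2 <- whitelist("AGAG", "w")
  idx2 <- build_mismatch_index(wl2, 0)
  h <- match_barcode_set("TAGAGAGT", list(start = 3L), wl2,
                         match_params(jitter = 1, max_mismatches = 0), idx2)
  expect_equal(h$status, "exact")
  expect_equal(h$barcode, "AGAG")
  expect_equal(h$offset, -1L)
})

test_that("direct Hamming fallback treats N as a mismatch", {
  wl <- whitelist("ACGT", "w")
  cand <- extract_query_window("CGTACGT", expected_start = 0, n = 4, x = 0)
  expect_equal(cand$seq, "NCGT")  # clipped at the read start
  r <- match_barcode_direct(cand, wl, m = 1)
  expect_equal(nrow(r), 1L)
  expect_equal(r$barcode, "ACGT")
  expect_equal(r$mismatches, 1L)
  # two Ns exceed m = 1
  cand2 <- data.frame(offset = 0L, start = -1L, seq = "NNGT", pad = 2L)
  expect_equal(nrow(match_barcode_direct(cand2, wl, m = 1)), 0L)
  # all-N never matches while m < n
  cand3 <- data.frame(offset = 0L, start = -3L, seq = "NNNN", pad = 4L)
  expect_equal(nrow(match_barcode_direct(cand3, wl, m = 3)), 0L)
})

test_that("edge-truncated barcodes are recovered iff the clip fits m", {
  wl <- whitelist(c("ACGTACGT", "TTGGCCAA"), "w")
  for (t in 0:2) {
    read <- paste0(substr("ACGTACGT", t + 1, 8), strrep("C", 12))
    for (m in 0:2) {
      idx <- build_mismatch_index(wl, m)
      h <- match_barcode_set(read, list(start = 1L), wl,
                             match_params(jitter = 2, max_mismatches = m),
                             idx)
      if (t <= m) {
        expect_equal(h$barcode, "ACGTACGT")
        expect_equal(h$mismatches, t)
        expect_equal(h$offset, -t)
      } else {
        expect_match(h$status, "null")
      }
    }
  }
})

test_that("set matcher equals the brute-force oracle on random instances", {
  set.seed(7)
  n_cfg <- 40
  per_cfg <- 40
  for (cc in seq_len(n_cfg)) {
    cfg <- rand_config()
    wl <- whitelist(cfg$barcodes, "w")
    params <- match_params(jitter = cfg$x, max_mismatches = cfg$m)
    idx <- build_mismatch_index(wl, cfg$m)
    for (tt in seq_len(per_cfg)) {
      inst <- rand_read_instance(cfg)
      got <- hit_to_list(match_barcode_set(inst$read,
                                           list(start = inst$expected_start),
                                           wl, params, idx))
      want <- oracle_match(inst$read, inst$expected_start, cfg$barcodes,
                           cfg$n, cfg$x, cfg$m)
      expect_identical(got, want,
                       label = sprintf("read=%s es=%d n=%d x=%d m=%d wl=%s",
                                       inst$read, inst$expected_start, cfg$n,
                                       cfg$x, cfg$m,
                                       paste(cfg$barcodes, collapse = ",")))
    }
  }
})

test_that("x = 0, m = 0 reduces to fixed-position exact matching", {
  set.seed(11)
  wl <- whitelist(rand_barcodes(16, 6), "w")
  idx <- build_mismatch_index(wl, 0)
  params <- match_params(jitter = 0, max_mismatches = 0)
  for (i in 1:50) {
    read <- paste0(sample(c("A","C","G","T"), 20, replace = TRUE),
                   collapse = "")
    es <- sample(1:15, 1)
    h <- match_barcode_set(read, list(start = es), wl, params, idx)
    sub <- substr(read, es, es + 5)
    if (sub %in% wl$barcodes) {
      expect_equal(h$status, "exact")
      expect_equal(h$barcode, sub)
      expect_equal(h$offset, 0L)
    } else {
      expect_equal(h$status, "no_match_null")
    }
  }
})

test_that("valid-hit count is monotone in jitter and mismatch budget", {
  set.seed(13)
  wl <- whitelist(rand_barcodes(24, 8), "w")
  reads <- character(120)
  for (i in seq_along(reads)) {
    cfg <- list(n = 8, barcodes = wl$barcodes, x = 2, m = 2)
    reads[i] <- rand_read_instance(cfg)$read
  }
  count_valid <- function(x, m) {
    idx <- build_mismatch_index(wl, m)
    params <- match_params(jitter = x, max_mismatches = m)
    sum(vapply(reads, function(r) {
      match_barcode_set(r, list(start = 6L), wl, params, idx)$status %in%
        c("exact", "corrected")
    }, logical(1)))
  }
  grid <- expand.grid(x = 0:2, m = 0:2)
  v <- mapply(count_valid, grid$x, grid$m)
  dim(v) <- c(3, 3)
  # non-decreasing along x for every m, and along m for every x
  expect_true(all(diff(v) >= 0))
  expect_true(all(apply(v, 1, diff) >= 0))
})

test_that("matching is deterministic", {
  set.seed(17)
  cfg <- rand_config()
  wl <- whitelist(cfg$barcodes, "w")
  idx <- build_mismatch_index(wl, cfg$m)
  params <- match_params(jitter = cfg$x, max_mismatches = cfg$m)
  inst <- rand_read_instance(cfg)
  h1 <- match_barcode_set(inst$read, list(start = inst$expected_start), wl,
                          params, idx)
  h2 <- match_barcode_set(inst$read, list(start = inst$expected_start), wl,
                          params, idx)
  expect_identical(h1, h2)
  # index content independent of barcode insertion order
  wl_rev <- whitelist(rev(cfg$barcodes), "w")
  idx_rev <- build_mismatch_index(wl_rev, cfg$m)
  h3 <- match_barcode_set(inst$read, list(start = inst$expected_start),
                          wl_rev, params, idx_rev)
  expect_equal(h3$status, h1$status)
  expect_equal(h3$barcode, h1$barcode)
})
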