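# Independent brute-force oracle for jitter-aware barcode matching.
# Implemented from the matching contract alone (window candidates x every
# whitelist barcode, literal ranked-tie rules); shares no code with the
# package's matchers.

oracle_window <- function(read_seq, expected_start, n, x) {
  L <- nchar(read_seq)
  offs <- -x:x
  seqs <- vapply(offs, function(o) {
    s <- expected_start + o
    chars <- vapply(seq.int(s, s + n - 1L), function(p) {
      if (p < 1L || p > L) "N" else substring(read_seq, p, p)
    }, character(1))
    paste0(chars, collapse = "")
  }, character(1))
  list(offset = offs, seq = seqs)
}

oracle_hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  sum(va != vb)
}

# Literal implementation of the prioritisation contract:
# exact -> fewest mismatches -> smallest |offset| (upstream first at equal
# |offset|); top rank shared by distinct barcodes -> ambiguous null.
oracle_match <- function(read_seq, expected_start, barcodes, n, x, m) {
  w <- oracle_window(read_seq, expected_start, n, x)
  off <- integer(0); bc <- integer(0); dist <- integer(0); sq <- character(0)
  for (i in seq_along(w$offset)) {
    for (b in seq_along(barcodes)) {
      d <- oracle_hamming(w$seq[i], barcodes[b])
      off <- c(off, w$offset[i]); bc <- c(bc, b); dist <- c(dist, d)
      sq <- c(sq, w$seq[i])
    }
  }
  observed0 <- w$seq[w$offset == 0L]
  exact <- dist == 0L
  keep <- if (any(exact)) exact else dist <= m
  if (!any(keep))
    return(list(status = "no_match_null", barcode = strrep("N", n),
                mismatches = NA_integer_, offset = NA_integer_,
                observed = observed0))
  off <- off[keep]; bc <- bc[keep]; dist <- dist[keep]; sq <- sq[keep]
  o <- order(dist, abs(off), off)
  first <- o[1]
  top <- o[dist[o] == dist[first] & abs(off[o]) == abs(off[first])]
  if (length(unique(bc[top])) > 1L)
    return(list(status = "ambiguous_null", barcode = strrep("N", n),
                mismatches = NA_integer_, offset = NA_integer_,
                observed = observed0))
  list(status = if (dist[first] == 0L) "exact" else "corrected",
       barcode = barcodes[bc[first]], mismatches = dist[first],
       offset = off[first], observed = sq[first])
}

# Vectorised oracle for large whitelists: same contract, byte-matrix
# arithmetic instead of per-character loops (still independent of the
# package's matcher internals).
oracle_match_big <- function(read_seq, expected_start, barcodes, n, x, m) {
  w <- oracle_window(read_seq, expected_start, n, x)
  mat <- matrix(charToRaw(paste0(barcodes, collapse = "")), nrow = n)
  off <- integer(0); bc <- integer(0); dist <- integer(0); sq <- character(0)
  for (i in seq_along(w$offset)) {
    d <- colSums(mat != charToRaw(w$seq[i]))
    off <- c(off, rep(w$offset[i], length(d)))
    bc <- c(bc, seq_along(d)); dist <- c(dist, d)
    sq <- c(sq, rep(w$seq[i], length(d)))
  }
  observed0 <- w$seq[w$offset == 0L]
  exact <- dist == 0L
  keep <- if (any(exact)) exact else dist <= m
  if (!any(keep))
    return(list(status = "no_match_null", barcode = strrep("N", n),
                mismatches = NA_integer_, offset = NA_integer_,
                observed = observed0))
  off <- off[keep]; bc <- bc[keep]; dist <- as.integer(dist[keep]); sq <- sq[keep]
  o <- order(dist, abs(off), off)
  first <- o[1]
  top <- o[dist[o] == dist[first] & abs(off[o]) == abs(off[first])]
  if (length(unique(bc[top])) > 1L)
    return(list(status = "ambiguous_null", barcode = strrep("N", n),
                mismatches = NA_integer_, offset = NA_integer_,
                observed = observed0))
  list(status = if (dist[first] == 0L) "exact" else "corrected",
       barcode = barcodes[bc[first]], mismatches = dist[first],
       offset = off[first], observed = sq[first])
}

hit_to_list <- function(h) {
  list(status = h$status, barcode = h$barcode, mismatches = h$mismatches,
       offset = h$offset, observed = h$observed)
}

rand_barcodes <- function(size, n) {
  repeat {
    bcs <- unique(replicate(size, paste0(sample(c("A", "C", "G", "T"), n,
                                                replace = TRUE),
                                         collapse = "")))
    if (length(bcs) == size) return(bcs)
  }
}

# Random matcher instance: a config (whitelist + params) plus a read and an
# expected start. Reads either embed a (possibly mutated, shifted) barcode
# or are fully random; expected starts sometimes sit at the read edges so
# the N-padding rule is exercised.
rand_config <- function() {
  n <- sample(4:8, 1)
  size <- sample(c(2, 4, 8, 16, 32), 1)
  x <- sample(0:3, 1)
  m <- sample(0:min(2, n - 1), 1)
  list(n = n, barcodes = rand_barcodes(size, n), x = x, m = m)
}

rand_read_instance <- function(cfg) {
  n <- cfg$n
  L <- n + sample(4:20, 1)
  read <- paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
  edge <- runif(1) < 0.25
  es <- if (edge) sample(c(1 - cfg$x, 1, 2, L - n, L - n + 1 + cfg$x), 1)
        else sample(seq_len(max(1, L - n + 1)), 1)
  es <- max(es, 1 - cfg$x - n)  # keep the window at least partly defined
  if (runif(1) < 0.6) {
    # plant a barcode near the expected start with some corruption
    b <- sample(cfg$barcodes, 1)
    o <- sample(seq.int(-cfg$x - 1, cfg$x + 1), 1)
    nmut <- sample(0:min(cfg$m + 1, n), 1)
    bchars <- strsplit(b, "")[[1]]
    if (nmut > 0) {
      ps <- sample(n, nmut)
      for (p in ps)
        bchars[p] <- sample(setdiff(c("A", "C", "G", "T"), bchars[p]), 1)
    }
    s <- es + o
    for (j in seq_len(n)) {
      p <- s + j - 1L
      if (p >= 1L && p <= L)
        substr(read, p, p) <- bchars[j]
    }
  }
  list(read = read, expected_start = es)
}
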