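# Set-based jitter-aware approximate matcher: a precomputed "mismatches" set
# maps every sequence within Hamming distance <= m of a whitelist barcode back
# to its origin(s); query windows around the expected start are looked up in
# it and ranked (exact first, then fewest mismatches, then smallest |offset|).

#' Construct a barcode match result
#'
#' @param status One of `exact`, `corrected`, `ambiguous_null`,
#'   `no_match_null`. Null statuses carry an all-N barcode and `NA`
#'   mismatch/offset sentinels.
#' @param barcode Matched whitelist sequence, or `N^n` for null statuses.
#' @param mismatches Hamming substitutions of the accepted candidate
#'   (N pad positions count); `NA` for null statuses.
#' @param offset Found start minus expected start; `NA` for null statuses.
#' @param observed The n-length query substring that was accepted (for null
#'   statuses, the window at the expected start), possibly containing pad Ns.
#' @return A `barcode_hit` object.
#' @export
barcode_hit <- function(status, barcode, mismatches, offset, observed) {
  stopifnot(status %in% c("exact", "corrected", "ambiguous_null", "no_match_null"))
  structure(list(status = status, barcode = barcode,
                 mismatches = as.integer(mismatches),
                 offset = as.integer(offset), observed = observed),
            class = "barcode_hit")
}

null_hit <- function(status, n, observed) {
  barcode_hit(status, strrep("N", n), NA_integer_, NA_integer_, observed)
}

#' @export
print.barcode_hit <- function(x, ...) {
  cat(sprintf("barcode_hit: %s %s (mismatches=%s, offset=%s)\n",
              x$status, x$barcode,
              ifelse(is.na(x$mismatches), ".", x$mismatches),
              ifelse(is.na(x$offset), ".", x$offset)))
  invisible(x)
}

# Fast internal form of the query window: plain vectors, no data.frame.
qw_fast <- function(read_seq, expected_start, n, x) {
  L <- nchar(read_seq)
  offs <- seq.int(-x, x)
  starts <- as.integer(expected_start + offs)
  ends <- starts + as.integer(n) - 1L
  core_s <- pmax(starts, 1L)
  core_e <- pmin(ends, L)
  seqs <- character(length(offs))
  pads <- integer(length(offs))
  for (i in seq_along(offs)) {
    if (core_s[i] > core_e[i]) {
      seqs[i] <- strrep("N", n)
      pads[i] <- n
    } else {
      core <- substr(read_seq, core_s[i], core_e[i])
      lp <- core_s[i] - starts[i]
      rp <- n - lp - nchar(core)
      seqs[i] <- if (lp == 0L && rp == 0L) core
                 else paste0(strrep("N", lp), core, strrep("N", rp))
      pads[i] <- lp + rp
    }
  }
  list(offset = as.integer(offs), start = starts, seq = seqs, pad = pads)
}

#' Extract the jitter query window around an expected barcode start
#'
#' Produces the `2x + 1` candidate n-length substrings whose starts cover
#' `[expected_start - x, expected_start + x]`. Candidates that run past
#' either read end are trimmed there and padded with `N` on the out-of-range
#' side (so every candidate has length exactly `n`); candidates falling
#' entirely outside the read are all-N. This is a total function: no input
#' errors are possible.
#'
#' @param read_seq Read sequence (non-empty string).
#' @param expected_start 1-based expected start of the barcode.
#' @param n Barcode length.
#' @param x Jitter radius (non-negative).
#' @return A data.frame of class `query_window` with columns `offset`,
#'   `start`, `seq`, `pad` (number of N pad bases added).
#' @export
extract_query_window <- function(read_seq, expected_start, n, x) {
  stopifnot(nchar(read_seq) >= 1L, n >= 1L, x >= 0L)
  q <- qw_fast(read_seq, expected_start, n, x)
  structure(data.frame(offset = q$offset, start = q$start,
                       seq = q$seq, pad = q$pad, stringsAsFactors = FALSE),
            class = c("query_window", "data.frame"),
            n = as.integer(n), x = as.integer(x),
            expected_start = as.integer(expected_start))
}

#' Build the mismatch-variant index for a whitelist
#'
#' Enumerates every sequence within Hamming distance `m` of each whitelist
#' barcode and stores `(variant, barcode index, distance)` rows in a keyed
#' [data.table::data.table]. A variant reachable from several barcodes keeps
#' one row per origin, so equal-minimal-distance ambiguity is detectable.
#' The entry count is `|whitelist| * sum_{d=0..m} C(n,d) 3^d`; if the
#' estimate exceeds `cap` a capacity error recommends the trie backend.
#'
#' @param wl A [whitelist()].
#' @param m Maximum mismatches (must be `< wl$n`).
#' @param cap Capacity guard on the estimated entry count (default 5e7).
#' @return A `mismatch_index` object.
#' @export
build_mismatch_index <- function(wl, m, cap = 5e7) {
  stopifnot(inherits(wl, "whitelist"))
  m <- as.integer(m)
  if (m >= wl$n)
    stop(sprintf("max mismatches (%d) must be < barcode length (%d)", m, wl$n))
  n <- wl$n
  B <- length(wl$barcodes)
  est <- B * sum(choose(n, 0:m) * 3^(0:m))
  if (est > cap)
    stop(sprintf(paste0(
      "mismatch set for whitelist '%s' would hold ~%.3g entries ",
      "(cap %.3g); use the trie backend (--backend trie) instead"),
      wl$name, est, cap))

  M <- matrix(seq_to_int(paste0(wl$barcodes, collapse = "")), nrow = n)
  starts <- seq(1L, n * B, by = n)
  stops <- seq(n, n * B, by = n)
  ints_to_seqs <- function(mat) {
    substring(rawToChar(.BASE_RAW[as.vector(mat)]), starts, stops)
  }
  variants <- vector("list", 64L)
  bcs <- vector("list", 64L)
  dists <- integer(0)
  k <- 0L
  bc_idx <- seq_len(B)
  for (d in 0:m) {
    combos <- if (d == 0L) matrix(integer(0), nrow = 0L, ncol = 1L)
              else utils::combn(n, d)
    subs <- if (d == 0L) matrix(integer(0), nrow = 1L, ncol = 0L)
            else as.matrix(expand.grid(rep(list(1:3), d)))
    for (ci in seq_len(ncol(combos))) {
      pos <- combos[, ci]
      for (si in seq_len(nrow(subs))) {
        v <- subs[si, ]
        newM <- M
        for (j in seq_along(pos)) {
          r <- M[pos[j], ]
          newM[pos[j], ] <- ((r - 1L + v[j]) %% 4L) + 1L
        }
        k <- k + 1L
        if (k > length(variants)) {
          length(variants) <- 2L * k
          length(bcs) <- 2L * k
        }
        variants[[k]] <- ints_to_seqs(newM)
        bcs[[k]] <- bc_idx
        dists[k] <- d
      }
    }
  }
  dt <- data.table::data.table(
    variant = unlist(variants[seq_len(k)], use.names = FALSE),
    bc = unlist(bcs[seq_len(k)], use.names = FALSE),
    dist = rep(dists[seq_len(k)], each = B))
  data.table::setkey(dt, variant)
  # for small indexes, an environment hash makes per-read lookups ~100x
  # cheaper than a keyed join; large indexes stay data.table-only
  env <- NULL
  if (nrow(dt) <= 3e5) {
    spl_bc <- split(dt$bc, dt$variant)
    spl_d <- split(dt$dist, dt$variant)
    env <- list2env(mapply(function(b, d) list(bc = b, dist = d),
                           spl_bc, spl_d, SIMPLIFY = FALSE),
                    hash = TRUE, size = length(spl_bc) * 2L)
  }
  structure(list(whitelist_name = wl$name, dt = dt, env = env, m = m, n = n,
                 n_entries = nrow(dt),
                 mat = seq_byte_matrix(wl$barcodes, n),
                 barcodes = wl$barcodes),
            class = "mismatch_index")
}

# Look up candidate sequences in the mismatch set; returns a data.table of
# (variant, bc, dist) rows, one per (sequence, origin barcode, distance).
mm_lookup <- function(idx, seqs) {
  idx$dt[list(unique(seqs)), nomatch = NULL]
}

#' Direct Hamming scan of query candidates against a whitelist
#'
#' Fallback path used for candidates containing `N` (edge pads or sequenced
#' Ns), which the 4-letter mismatch set cannot enumerate. Every N position
#' counts as a mismatch against every base. Returns all (barcode, mismatches,
#' offset) tuples with `mismatches <= m`, ranked by the phase-2 contract
#' (fewest mismatches, then smallest |offset|, upstream before downstream).
#'
#' @param candidates A [extract_query_window()] result (or compatible
#'   data.frame with `offset` and `seq` columns).
#' @param wl A [whitelist()].
#' @param m Maximum mismatches.
#' @return data.frame with columns `barcode`, `mismatches`, `offset`, `seq`.
#' @export
match_barcode_direct <- function(candidates, wl, m) {
  mat <- seq_byte_matrix(wl$barcodes, wl$n)
  rows <- direct_pairs(candidates, mat, m)
  if (nrow(rows) == 0L)
    return(data.frame(barcode = character(0), mismatches = integer(0),
                      offset = integer(0), seq = character(0),
                      stringsAsFactors = FALSE))
  o <- order(rows$dist, abs(rows$offset), rows$offset)
  rows <- rows[o, , drop = FALSE]
  data.frame(barcode = wl$barcodes[rows$bc], mismatches = rows$dist,
             offset = rows$offset, seq = rows$seq,
             stringsAsFactors = FALSE, row.names = NULL)
}

# (offset, seq, bc, dist) pairs by direct scan, filtered to dist <= m.
direct_pairs <- function(candidates, mat, m) {
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    d <- hamming_to_matrix(candidates$seq[i], mat)
    keep <- which(d <= m)
    if (length(keep))
      out[[i]] <- data.frame(offset = candidates$offset[i],
                             seq = candidates$seq[i],
                             bc = keep, dist = d[keep],
                             stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(offset = integer(0), seq = character(0),
                      bc = integer(0), dist = integer(0)))
  do.call(rbind, out)
}

# Shared ranking/tie resolution over parallel vectors: one entry per
# (candidate, barcode) pair. Scan order: mismatches ascending, |offset|
# ascending, upstream (negative) before downstream. If the top
# (dist, |offset|) rank is shared by DISTINCT barcodes the result is
# ambiguous; the same barcode at both signs keeps the scan-order offset.
resolve_vec <- function(off, seqv, bc, dist, barcodes, n, observed0) {
  if (!length(off)) return(NULL)
  o <- order(dist, abs(off), off)
  first <- o[1]
  top <- o[dist[o] == dist[first] & abs(off[o]) == abs(off[first])]
  b0 <- bc[first]
  if (length(top) > 1L && any(bc[top] != b0))
    return(null_hit("ambiguous_null", n, observed0))
  barcode_hit(status = if (dist[first] == 0L) "exact" else "corrected",
              barcode = barcodes[b0], mismatches = dist[first],
              offset = off[first], observed = seqv[first])
}

# data.frame adapter kept for the exported direct-scan API
resolve_pairs <- function(pairs, barcodes, n, observed0) {
  resolve_vec(pairs$offset, pairs$seq, pairs$bc, pairs$dist,
              barcodes, n, observed0)
}

#' Match one barcode element in one read (set backend)
#'
#' Implements the prioritized jitter-aware matching contract: (i) a perfect
#' whitelist match, (ii) fewest nucleotide substitutions, (iii) smallest
#' distance from the expected start. Phase 1 considers only exact whitelist
#' members among the query-window candidates; phase 2 (entered only when
#' phase 1 is empty) ranks mismatch-set hits, with N pad positions counted
#' as mismatches and candidates exceeding `m` excluded. A top rank shared by
#' distinct barcodes returns an ambiguous null; no surviving candidate
#' returns a no-match null (`N^n`).
#'
#' @param read_seq Read sequence.
#' @param ep An expected position: any list/row with `$start` (1-based).
#' @param wl The [whitelist()] to match against.
#' @param params [match_params()]; `jitter` and `max_mismatches` are used.
#' @param idx A [build_mismatch_index()] for `wl` at `params$max_mismatches`.
#' @return A [barcode_hit()].
#' @export
match_barcode_set <- function(read_seq, ep, wl, params, idx) {
  n <- wl$n
  m <- params$max_mismatches
  check_params_vs_whitelist(params, wl)
  q <- qw_fast(read_seq, ep$start, n, params$jitter)
  observed0 <- q$seq[params$jitter + 1L]

  # Phase 1: exact whitelist members (N-containing candidates can never be
  # exact because whitelists are ACGT-only).
  cm <- data.table::chmatch(q$seq, wl$barcodes)
  ex <- which(!is.na(cm))
  if (length(ex))
    return(resolve_vec(q$offset[ex], q$seq[ex], cm[ex],
                       rep(0L, length(ex)), wl$barcodes, n, observed0))

  # Phase 2: mismatch-set lookup for clean candidates, direct Hamming
  # fallback for N-containing ones; ranked jointly.
  has_n <- grepl("N", q$seq, fixed = TRUE)
  a_off <- vector("list", length(q$seq))
  a_seq <- a_off; a_bc <- a_off; a_dist <- a_off
  k <- 0L
  clean <- which(!has_n)
  if (length(clean)) {
    if (!is.null(idx$env)) {
      vals <- mget(q$seq[clean], envir = idx$env, ifnotfound = list(NULL))
      for (j in seq_along(clean)) {
        v <- vals[[j]]
        if (is.null(v)) next
        k <- k + 1L
        nb <- length(v$bc)
        a_off[[k]] <- rep(q$offset[clean[j]], nb)
        a_seq[[k]] <- rep(q$seq[clean[j]], nb)
        a_bc[[k]] <- v$bc
        a_dist[[k]] <- v$dist
      }
    } else {
      hits <- mm_lookup(idx, q$seq[clean])
      if (nrow(hits)) {
        pos <- match(hits$variant, q$seq[clean])
        k <- k + 1L
        a_off[[k]] <- q$offset[clean][pos]
        a_seq[[k]] <- hits$variant
        a_bc[[k]] <- hits$bc
        a_dist[[k]] <- hits$dist
        # a sequence occurring at several offsets needs one entry per offset
        dup_off <- which(duplicated(q$seq[clean]))
        for (j in dup_off) {
          sel <- hits$variant == q$seq[clean][j]
          if (any(sel)) {
            k <- k + 1L
            a_off[[k]] <- rep(q$offset[clean][j], sum(sel))
            a_seq[[k]] <- hits$variant[sel]
            a_bc[[k]] <- hits$bc[sel]
            a_dist[[k]] <- hits$dist[sel]
          }
        }
      }
    }
  }
  for (i in which(has_n)) {
    d <- hamming_to_matrix(q$seq[i], idx$mat)
    keep <- which(d <= m)
    if (length(keep)) {
      k <- k + 1L
      a_off[[k]] <- rep(q$offset[i], length(keep))
      a_seq[[k]] <- rep(q$seq[i], length(keep))
      a_bc[[k]] <- keep
      a_dist[[k]] <- d[keep]
    }
  }
  if (k == 0L) return(null_hit("no_match_null", n, observed0))
  off <- unlist(a_off[seq_len(k)], use.names = FALSE)
  seqv <- unlist(a_seq[seq_len(k)], use.names = FALSE)
  bc <- unlist(a_bc[seq_len(k)], use.names = FALSE)
  dist <- unlist(a_dist[seq_len(k)], use.names = FALSE)
  sel <- dist <= m
  hit <- resolve_vec(off[sel], seqv[sel], bc[sel], dist[sel],
                     wl$barcodes, n, observed0)
  if (is.null(hit)) null_hit("no_match_null", n, observed0) else hit
}
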