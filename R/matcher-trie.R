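# Hybrid trie + seed-index matcher for large whitelists. Exact matches come
# from 4-ary prefix-tree traversal; approximate matches are retrieved via a
# pigeonhole seed index (or an optional overlapping k-mer filter) and then
# verified by full-length Hamming distance, so the output is contractually
# identical to the set backend.

#' Build a 4-ary prefix tree over a whitelist
#'
#' Terminal nodes carry the whitelist barcode index; membership lookups cost
#' at most `n` node visits and agree exactly with set membership.
#'
#' @param wl A [whitelist()].
#' @return A `barcode_trie` object.
#' @export
build_trie <- function(wl) {
  stopifnot(inherits(wl, "whitelist"))
  n <- wl$n
  B <- length(wl$barcodes)
  cap <- B * n + 1L
  child <- matrix(0L, nrow = 4L, ncol = cap)
  term <- integer(cap)
  n_nodes <- 1L
  ints <- matrix(seq_to_int(paste0(wl$barcodes, collapse = "")), nrow = n)
  for (b in seq_len(B)) {
    node <- 1L
    for (i in seq_len(n)) {
      ch <- ints[i, b]
      nxt <- child[ch, node]
      if (nxt == 0L) {
        n_nodes <- n_nodes + 1L
        child[ch, node] <- n_nodes
        nxt <- n_nodes
      }
      node <- nxt
    }
    term[node] <- b
  }
  structure(list(child = child[, seq_len(n_nodes), drop = FALSE],
                 term = term[seq_len(n_nodes)], n = n,
                 whitelist_name = wl$name),
            class = "barcode_trie")
}

#' Exact membership lookup in a barcode trie
#'
#' @param trie A [build_trie()] result.
#' @param s Query string.
#' @return The whitelist barcode index, or 0 on a miss (wrong length,
#'   non-ACGT characters, or absent sequence).
#' @export
trie_lookup <- function(trie, s) {
  if (nchar(s) != trie$n) return(0L)
  ints <- seq_to_int(s)
  if (anyNA(ints)) return(0L)
  node <- 1L
  child <- trie$child
  for (i in seq_len(trie$n)) {
    node <- child[ints[i], node]
    if (node == 0L) return(0L)
  }
  trie$term[node]
}

#' Build the approximate-match candidate index for the trie backend
#'
#' Default `type = "seed"` partitions each barcode into `m + 1` contiguous
#' seeds with lengths differing by at most one; by pigeonhole, any sequence
#' within Hamming distance `m` of a barcode matches at least one seed
#' exactly, so retrieval is complete for the mismatch budget. The optional
#' `type = "kmer"` indexes all overlapping k-mers by position with
#' `k <= floor(n / (m + 1))` (default equality), which preserves the same
#' completeness guarantee; both modes feed identical full-length Hamming
#' verification.
#'
#' @param wl A [whitelist()].
#' @param m Mismatch budget; requires `m + 1 <= n`.
#' @param type `"seed"` (default) or `"kmer"`.
#' @param k k-mer length for `type = "kmer"`; defaults to
#'   `floor(n / (m + 1))`.
#' @return A `seed_index` object.
#' @export
build_seed_index <- function(wl, m, type = c("seed", "kmer"), k = NULL) {
  stopifnot(inherits(wl, "whitelist"))
  type <- match.arg(type)
  m <- as.integer(m)
  n <- wl$n
  if (m + 1L > n)
    stop(sprintf("seed index needs m + 1 <= n (m=%d, n=%d)", m, n))
  B <- length(wl$barcodes)
  if (type == "seed") {
    base <- n %/% (m + 1L)
    rem <- n %% (m + 1L)
    lens <- c(rep(base + 1L, rem), rep(base, m + 1L - rem))
    starts <- cumsum(c(1L, lens[-length(lens)]))
  } else {
    kmax <- n %/% (m + 1L)
    if (is.null(k)) k <- kmax
    k <- as.integer(k)
    if (k < 1L || k > kmax)
      stop(sprintf(
        "k-mer length %d loses completeness for m=%d, n=%d (need 1 <= k <= %d)",
        k, m, n, kmax))
    starts <- seq_len(n - k + 1L)
    lens <- rep(k, length(starts))
  }
  keys <- character(0)
  ids <- integer(0)
  for (s in seq_along(starts)) {
    keys <- c(keys, paste0(s, "|", substr(wl$barcodes, starts[s],
                                          starts[s] + lens[s] - 1L)))
    ids <- c(ids, seq_len(B))
  }
  env <- list2env(split(ids, keys), hash = TRUE)
  structure(list(env = env, starts = starts, lens = lens, type = type,
                 m = m, n = n, whitelist_name = wl$name,
                 mat = seq_byte_matrix(wl$barcodes, n),
                 barcodes = wl$barcodes),
            class = "seed_index")
}

# Candidate barcode indices sharing at least one seed/k-mer with `s`.
seed_candidates <- function(index, s) {
  keys <- paste0(seq_along(index$starts), "|",
                 substring(s, index$starts, index$starts + index$lens - 1L))
  found <- mget(keys, envir = index$env, ifnotfound = list(NULL))
  unique(unlist(found, use.names = FALSE))
}

#' Match one barcode element in one read (trie backend)
#'
#' Output is identical to [match_barcode_set()] on every input (the binding
#' backend contract). Exact matches come from trie traversal; otherwise
#' seed-index candidates are verified by full Hamming distance `<= m` before
#' the shared (exact, fewest mismatches, smallest |offset|) ranking.
#' N-containing candidates bypass the index and use the direct Hamming scan.
#'
#' @inheritParams match_barcode_set
#' @param trie A [build_trie()] for `wl`.
#' @param index A [build_seed_index()] for `wl` at `params$max_mismatches`.
#' @return A [barcode_hit()].
#' @export
match_barcode_trie <- function(read_seq, ep, wl, params, trie, index) {
  n <- wl$n
  m <- params$max_mismatches
  check_params_vs_whitelist(params, wl)
  q <- qw_fast(read_seq, ep$start, n, params$jitter)
  observed0 <- q$seq[params$jitter + 1L]
  has_n <- grepl("N", q$seq, fixed = TRUE)

  # Phase 1: trie traversal on clean candidates.
  ex_bc <- integer(length(q$seq))
  for (i in which(!has_n)) ex_bc[i] <- trie_lookup(trie, q$seq[i])
  ex <- which(ex_bc > 0L)
  if (length(ex))
    return(resolve_vec(q$offset[ex], q$seq[ex], ex_bc[ex],
                       rep(0L, length(ex)), wl$barcodes, n, observed0))

  # Phase 2: seed retrieval + verification; direct fallback for N candidates.
  a_off <- vector("list", length(q$seq))
  a_seq <- a_off; a_bc <- a_off; a_dist <- a_off
  k <- 0L
  for (i in seq_along(q$seq)) {
    if (has_n[i]) {
      d <- hamming_to_matrix(q$seq[i], index$mat)
      keep <- which(d <= m)
      cand <- keep
    } else {
      cand <- seed_candidates(index, q$seq[i])
      if (!length(cand)) next
      d <- hamming_to_matrix(q$seq[i], index$mat, cols = cand)
      keep0 <- which(d <= m)
      d <- d[keep0]
      keep <- keep0
      cand <- cand[keep0]
    }
    if (!length(cand)) next
    k <- k + 1L
    a_off[[k]] <- rep(q$offset[i], length(cand))
    a_seq[[k]] <- rep(q$seq[i], length(cand))
    a_bc[[k]] <- cand
    a_dist[[k]] <- if (has_n[i]) d[keep] else d
  }
  if (k == 0L) return(null_hit("no_match_null", n, observed0))
  hit <- resolve_vec(unlist(a_off[seq_len(k)], use.names = FALSE),
                     unlist(a_seq[seq_len(k)], use.names = FALSE),
                     unlist(a_bc[seq_len(k)], use.names = FALSE),
                     unlist(a_dist[seq_len(k)], use.names = FALSE),
                     wl$barcodes, n, observed0)
  if (is.null(hit)) null_hit("no_match_null", n, observed0) else hit
}
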