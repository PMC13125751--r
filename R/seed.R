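# The `seed` stage: scan a subsample of reads for EXACT whitelist occurrences
# at every position (no jitter, no mismatches) and build a per-position
# support histogram from which expected positions are later derived.

# Start positions (1-based) of exact whitelist occurrences within one read.
scan_positions <- function(read_seq, wl, backend = "set", trie = NULL) {
  n <- wl$n
  L <- nchar(read_seq)
  if (L < n) return(integer(0))
  starts <- seq_len(L - n + 1L)
  subs <- substring(read_seq, starts, starts + n - 1L)
  if (backend == "set") {
    starts[data.table::`%chin%`(subs, wl$barcodes)]
  } else {
    if (is.null(trie)) trie <- build_trie(wl)
    starts[vapply(subs, function(s) trie_lookup(trie, s) > 0L, logical(1),
                  USE.NAMES = FALSE)]
  }
}

#' Scan one read for exact whitelist occurrences at every position
#'
#' Every start position `p` in `[1, len - n + 1]` whose n-length substring is
#' a whitelist member yields one hit; multiple whitelists are scanned
#' independently. Reads shorter than a whitelist's barcode length yield no
#' hits for that whitelist.
#'
#' @param read_seq Read sequence.
#' @param whitelists A list of [whitelist()] objects (or a single one).
#' @param backend `"set"` (vectorised membership) or `"trie"` (prefix-tree
#'   lookups); identical results.
#' @param tries Optional named list of prebuilt [build_trie()] objects keyed
#'   by whitelist name (built on the fly when absent).
#' @return data.frame with columns `whitelist`, `barcode`, `start`.
#' @export
scan_read_exact <- function(read_seq, whitelists, backend = c("set", "trie"),
                            tries = NULL) {
  backend <- match.arg(backend)
  if (inherits(whitelists, "whitelist")) whitelists <- list(whitelists)
  out <- vector("list", length(whitelists))
  for (w in seq_along(whitelists)) {
    wl <- whitelists[[w]]
    pos <- scan_positions(read_seq, wl, backend,
                          if (!is.null(tries)) tries[[wl$name]] else NULL)
    if (length(pos))
      out[[w]] <- data.frame(whitelist = wl$name,
                             barcode = substring(read_seq, pos, pos + wl$n - 1L),
                             start = pos, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(whitelist = character(0), barcode = character(0),
                      start = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Profile exact barcode positions over a read subsample (`seed` stage)
#'
#' Runs the exact scan over a subsample of reads (both files of a pair when
#' given) for ONE whitelist, and accumulates, per read file and start
#' position, the number of sampled reads with at least one exact hit starting
#' there (each read contributes at most once per position; a read matching at
#' several positions contributes to each, preserving the evidence the
#' harvest-stage multimodality diagnostics need). The profile is written as a
#' TSV with columns `whitelist read_index start count reads_sampled`.
#'
#' @param fastqs Character vector of 1 or 2 FASTQ paths.
#' @param wl The [whitelist()] to profile (one whitelist per invocation).
#' @param n_sample Reads to sample (default 10000).
#' @param out_path Output TSV path, or `NULL` to skip writing.
#' @param mode,rng_seed Passed to [sample_reads()].
#' @param backend Matching backend for the exact scan.
#' @param hits_path Optional per-hit TSV path
#'   (`read_id read_index whitelist barcode start`).
#' @return A `position_profile` object: list with `whitelist_name`,
#'   `reads_sampled` and `counts` (data.frame `read_index`, `start`,
#'   `count`).
#' @export
run_seed <- function(fastqs, wl, n_sample = 10000L, out_path = NULL,
                     mode = "head", rng_seed = 1L, backend = "set",
                     hits_path = NULL) {
  stopifnot(inherits(wl, "whitelist"))
  reads <- sample_reads(fastqs, n_sample, mode, rng_seed)
  n_used <- nrow(reads[[1]])
  trie <- if (backend == "trie") build_trie(wl) else NULL
  want_hits <- !is.null(hits_path)
  count_rows <- list()
  hit_acc <- list(id = list(), ri = list(), start = list(), bc = list())
  for (ri in seq_along(reads)) {
    df <- reads[[ri]]
    n <- wl$n
    maxpos <- max(nchar(df$seq), n)
    cnt <- integer(maxpos)
    # vectorised across reads, one position at a time: a read contributes at
    # most once per position by construction
    short_ids <- if (want_hits) sub(" .*", "", df$id) else NULL
    for (p in seq_len(maxpos - n + 1L)) {
      subs <- substr(df$seq, p, p + n - 1L)
      hit <- if (backend == "set") {
        nchar(subs) == n & data.table::`%chin%`(subs, wl$barcodes)
      } else {
        nchar(subs) == n &
          vapply(subs, function(s) trie_lookup(trie, s) > 0L, logical(1),
                 USE.NAMES = FALSE)
      }
      nh <- sum(hit)
      if (nh) {
        cnt[p] <- nh
        if (want_hits) {
          k <- length(hit_acc$id) + 1L
          hit_acc$id[[k]] <- short_ids[hit]
          hit_acc$ri[[k]] <- rep(ri, nh)
          hit_acc$start[[k]] <- rep(p, nh)
          hit_acc$bc[[k]] <- subs[hit]
        }
      }
    }
    nz <- which(cnt > 0L)
    if (length(nz))
      count_rows[[ri]] <- data.frame(read_index = ri, start = nz,
                                     count = cnt[nz])
  }
  count_rows <- count_rows[!vapply(count_rows, is.null, logical(1))]
  counts <- if (length(count_rows)) do.call(rbind, count_rows)
            else data.frame(read_index = integer(0), start = integer(0),
                            count = integer(0))
  profile <- structure(list(whitelist_name = wl$name, reads_sampled = n_used,
                            counts = counts),
                       class = "position_profile")
  if (!is.null(out_path)) write_profile_tsv(profile, out_path)
  if (want_hits) {
    id <- unlist(hit_acc$id, use.names = FALSE) %||% character(0)
    ri <- unlist(hit_acc$ri, use.names = FALSE) %||% integer(0)
    st <- unlist(hit_acc$start, use.names = FALSE) %||% integer(0)
    bc <- unlist(hit_acc$bc, use.names = FALSE) %||% character(0)
    hits <- data.frame(read_id = id, read_index = ri,
                       whitelist = rep(wl$name, length(st)),
                       barcode = bc, start = st,
                       stringsAsFactors = FALSE)
    utils::write.table(hits, hits_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  profile
}

#' Write / read a seed position profile TSV
#'
#' Tab-separated columns: `whitelist`, `read_index`, `start`, `count`,
#' `reads_sampled`; one row per (read file, start position) with at least one
#' exact hit. An empty profile writes only the header plus a metadata comment
#' so round-trips preserve `reads_sampled`.
#'
#' @param profile A `position_profile` from [run_seed()].
#' @param path TSV path.
#' @return `path` (write) or a `position_profile` (read).
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "position_profile"))
  df <- profile$counts
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("whitelist", "read_index", "start", "count",
                     "reads_sampled"), collapse = "\t"), con)
  if (nrow(df)) {
    out <- data.frame(whitelist = profile$whitelist_name,
                      read_index = df$read_index, start = df$start,
                      count = df$count,
                      reads_sampled = profile$reads_sampled)
    writeLines(do.call(paste, c(out, sep = "\t")), con)
  } else {
    writeLines(sprintf("#whitelist=%s reads_sampled=%d",
                       profile$whitelist_name, profile$reads_sampled), con)
  }
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("profile TSV not found: %s", path))
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  need <- c("whitelist", "read_index", "start", "count", "reads_sampled")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("profile TSV '%s': missing column(s): %s",
                 path, paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) {
    if (!length(meta))
      stop(sprintf("profile TSV '%s' is empty and has no metadata line", path))
    wl_name <- sub(".*whitelist=(\\S+).*", "\\1", meta[1])
    rs <- as.integer(sub(".*reads_sampled=(\\d+).*", "\\1", meta[1]))
    return(structure(list(whitelist_name = wl_name, reads_sampled = rs,
                          counts = data.frame(read_index = integer(0),
                                              start = integer(0),
                                              count = integer(0))),
                     class = "position_profile"))
  }
  if (length(unique(df$whitelist)) != 1L)
    stop(sprintf("profile TSV '%s' mixes whitelists: %s", path,
                 paste(unique(df$whitelist), collapse = ", ")))
  structure(list(whitelist_name = df$whitelist[1],
                 reads_sampled = df$reads_sampled[1],
                 counts = df[, c("read_index", "start", "count")]),
            class = "position_profile")
}
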