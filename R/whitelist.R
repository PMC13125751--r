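#' Construct a barcode whitelist
#'
#' A whitelist is the ordered set of legitimate barcode sequences used at one
#' round of combinatorial (split-pool) barcoding. All barcodes must share one
#' length and be plain A/C/G/T; sequences are matched exactly as given (no
#' reverse complementing), so they must be supplied in read orientation.
#'
#' @param barcodes Character vector of barcode sequences (uppercased on
#'   input). Order is preserved.
#' @param name Short identifier for the barcoding round, e.g. `"bc1"`.
#' @return An object of class `whitelist` with fields `name`, `barcodes`
#'   and `n` (barcode length in nucleotides).
#' @export
whitelist <- function(barcodes, name) {
  stopifnot(is.character(barcodes), length(barcodes) >= 1L,
            is.character(name), length(name) == 1L, nzchar(name))
  barcodes <- toupper(barcodes)
  lens <- nchar(barcodes)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1])[1]
    stop(sprintf(
      "whitelist '%s': inconsistent barcode length at entry %d ('%s', %d nt; expected %d nt)",
      name, bad, barcodes[bad], lens[bad], lens[1]))
  }
  if (anyDuplicated(barcodes)) {
    dup <- barcodes[duplicated(barcodes)][1]
    stop(sprintf("whitelist '%s': duplicate barcode '%s'", name, dup))
  }
  if (any(grepl("[^ACGT]", barcodes))) {
    bad <- which(grepl("[^ACGT]", barcodes))[1]
    stop(sprintf(
      "whitelist '%s': barcode '%s' (entry %d) contains characters outside A/C/G/T (IUPAC ambiguity codes and N are rejected)",
      name, barcodes[bad], bad))
  }
  structure(list(name = name, barcodes = barcodes, n = lens[1]),
            class = "whitelist")
}

#' Load a barcode whitelist from a text file
#'
#' Reads a plain-text whitelist with one barcode per line. Blank lines are
#' ignored and lowercase sequences are uppercased. Validation errors (mixed
#' lengths, duplicates, non-ACGT characters) name the offending entry.
#'
#' @param path Path to the whitelist file.
#' @param name Identifier for the barcoding round this whitelist represents.
#' @return A [whitelist()] object preserving file order.
#' @export
load_whitelist <- function(path, name) {
  if (!file.exists(path)) stop(sprintf("whitelist file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  if (!any(keep)) stop(sprintf("whitelist file '%s' contains no barcodes", path))
  bcs <- lines[keep]
  lineno <- which(keep)
  lens <- nchar(bcs)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1])[1]
    stop(sprintf(
      "whitelist '%s' (%s): line %d has length %d, expected %d",
      name, path, lineno[bad], lens[bad], lens[1]))
  }
  tryCatch(whitelist(bcs, name), error = function(e)
    stop(sprintf("while loading '%s': %s", path, conditionMessage(e)), call. = FALSE))
}

#' Write a whitelist to a text file (one barcode per line)
#' @param wl A [whitelist()] object.
#' @param path Output path.
#' @export
write_whitelist <- function(wl, path) {
  stopifnot(inherits(wl, "whitelist"))
  writeLines(wl$barcodes, path)
  invisible(path)
}

#' @export
print.whitelist <- function(x, ...) {
  cat(sprintf("whitelist '%s': %d barcodes of %d nt\n",
              x$name, length(x$barcodes), x$n))
  invisible(x)
}

#' Matching parameters for jitter-aware barcode recovery
#'
#' @param jitter Maximum positional deviation `x` (nucleotides) of a barcode
#'   from its expected start; the query window spans `2*jitter + 1` candidate
#'   start positions. Default 1.
#' @param max_mismatches Maximum Hamming substitutions `m` tolerated when
#'   correcting a barcode (N pad bases count as mismatches). Must be smaller
#'   than every matched barcode length. Default 1.
#' @param backend `"set"` (precomputed mismatch-variant set; reference
#'   semantics, suited to round whitelists of ~96 barcodes) or `"trie"`
#'   (prefix tree + pigeonhole seed index; suited to large whitelists). Both
#'   return identical hits.
#' @param index_type For the trie backend: `"seed"` (default; `m + 1`
#'   near-equal contiguous seeds, complete by pigeonhole) or `"kmer"`
#'   (overlapping k-mer filter with identical verification).
#' @param kmer_length Optional k for `index_type = "kmer"`; defaults to
#'   `floor(n / (m + 1))`, the largest k preserving completeness.
#' @param variant_cap Capacity guard for the set backend: maximum estimated
#'   number of mismatch-set entries per whitelist (default 5e7). Beyond it
#'   the set backend refuses and recommends the trie backend.
#' @return A `match_params` object.
#' @export
match_params <- function(jitter = 1L, max_mismatches = 1L,
                         backend = c("set", "trie"),
                         index_type = c("seed", "kmer"),
                         kmer_length = NULL, variant_cap = 5e7) {
  jitter <- as.integer(jitter)
  max_mismatches <- as.integer(max_mismatches)
  stopifnot(length(jitter) == 1L, jitter >= 0L,
            length(max_mismatches) == 1L, max_mismatches >= 0L)
  structure(list(jitter = jitter, max_mismatches = max_mismatches,
                 backend = match.arg(backend),
                 index_type = match.arg(index_type),
                 kmer_length = if (is.null(kmer_length)) NULL else as.integer(kmer_length),
                 variant_cap = variant_cap),
            class = "match_params")
}

check_params_vs_whitelist <- function(params, wl) {
  if (params$max_mismatches >= wl$n)
    stop(sprintf(
      "max_mismatches (%d) must be < barcode length (%d) for whitelist '%s'",
      params$max_mismatches, wl$n, wl$name))
  invisible(TRUE)
}

#' Construct a table of expected barcode positions
#'
#' One row per barcode element: which whitelist, which read of the pair, the
#' 1-based expected start, and the fraction of profiled reads supporting that
#' start. Row order is not significant; consumers sort by
#' `(read_index, start)`, which defines barcode concatenation order.
#'
#' @param whitelist Character vector of whitelist names.
#' @param read_index Integer vector (1 or 2), file of the pair.
#' @param start Integer vector of 1-based inclusive start positions.
#' @param read_fraction Numeric vector in `[0, 1]`.
#' @return A data.frame of class `expected_positions`.
#' @export
expected_positions <- function(whitelist, read_index, start, read_fraction) {
  df <- data.frame(whitelist = as.character(whitelist),
                   read_index = as.integer(read_index),
                   start = as.integer(start),
                   read_fraction = as.numeric(read_fraction),
                   stringsAsFactors = FALSE)
  validate_positions(df)
  class(df) <- c("expected_positions", "data.frame")
  df
}

validate_positions <- function(df, where = "positions") {
  need <- c("whitelist", "read_index", "start", "read_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", where, paste(miss, collapse = ", ")))
  if (any(!df$read_index %in% c(1L, 2L)))
    stop(sprintf("%s: read_index must be 1 or 2", where))
  if (any(is.na(df$start)) || any(df$start < 1L))
    stop(sprintf("%s: start must be >= 1", where))
  if (any(is.na(df$read_fraction)) ||
      any(df$read_fraction < 0) || any(df$read_fraction > 1))
    stop(sprintf("%s: read_fraction must lie in [0, 1]", where))
  invisible(TRUE)
}

#' Write / read the expected-positions CSV
#'
#' Plain CSV with header `whitelist,read_index,start,read_fraction`
#' (UTF-8, LF). `read_positions_csv(write_positions_csv(p)) == p`.
#' If `element_lengths` (a named vector of barcode lengths per whitelist) is
#' supplied at write time, overlapping `[start, start + n)` element intervals
#' on the same read trigger a warning but are still written.
#'
#' @param positions An [expected_positions()] table (non-empty).
#' @param path CSV path.
#' @param element_lengths Optional named integer vector, barcode length per
#'   whitelist name, used only for the overlap diagnostic.
#' @return `path`, invisibly.
#' @export
write_positions_csv <- function(positions, path, element_lengths = NULL) {
  validate_positions(positions)
  if (nrow(positions) == 0L) stop("positions table is empty")
  if (!is.null(element_lengths)) warn_position_overlaps(positions, element_lengths)
  utils::write.csv(as.data.frame(positions)[, c("whitelist", "read_index",
                                                "start", "read_fraction")],
                   path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

warn_position_overlaps <- function(positions, element_lengths) {
  for (ri in unique(positions$read_index)) {
    p <- positions[positions$read_index == ri, , drop = FALSE]
    if (nrow(p) < 2L) next
    n <- element_lengths[p$whitelist]
    if (any(is.na(n))) next
    o <- order(p$start)
    p <- p[o, ]; n <- n[o]
    ends <- p$start + n - 1L
    olap <- which(p$start[-1L] <= ends[-length(ends)])
    for (i in olap) {
      warning(sprintf(
        "elements '%s' and '%s' overlap on read %d ([%d,%d] vs [%d,%d])",
        p$whitelist[i], p$whitelist[i + 1L], ri,
        p$start[i], ends[i], p$start[i + 1L], ends[i + 1L]), call. = FALSE)
    }
  }
  invisible(NULL)
}

#' @rdname write_positions_csv
#' @export
read_positions_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("positions CSV not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop(sprintf("failed to parse '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  need <- c("whitelist", "read_index", "start", "read_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("positions CSV '%s': missing column(s): %s",
                 path, paste(miss, collapse = ", ")))
  parse_int <- function(col, nm) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad) || anyNA(v))
      stop(sprintf("positions CSV '%s': bad %s at data line %d",
                   path, nm, (if (length(bad)) bad[1] else which(is.na(v))[1])))
    v
  }
  ri <- parse_int("read_index", "read_index")
  st <- parse_int("start", "start")
  rf <- suppressWarnings(as.numeric(df$read_fraction))
  if (anyNA(rf))
    stop(sprintf("positions CSV '%s': bad read_fraction at data line %d",
                 path, which(is.na(rf))[1]))
  expected_positions(df$whitelist, ri, st, rf)
}
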