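# Optional stages: recover a barcode that provider demultiplexing already
# consumed from the FASTQ header (`weed`), and drop reads whose barcode
# elements failed to match (`sift`).

#' Describe how to pull a barcode out of a FASTQ header
#'
#' Token mode splits the header on whitespace, keeps the last field, splits
#' that on `token_delimiter` and takes `token_index` counting from the END
#' (1 = last token), which covers Illumina CASAVA-style headers like
#' `@r1 1:N:0:ACGTACGT`. Regex mode applies `pattern` (one capture group) to
#' the whole header.
#'
#' @param whitelist_name Whitelist the extracted barcode is validated
#'   against.
#' @param mode `"token"` or `"regex"`.
#' @param token_delimiter Delimiter within the last whitespace field
#'   (default `":"`).
#' @param token_index Token position counting from the end (default 1).
#' @param pattern Regex with exactly one capture group (regex mode).
#' @param insert_index Position of this element in the barcode concatenation
#'   order (default 1, i.e. first).
#' @return A `header_barcode_spec` object.
#' @export
header_barcode_spec <- function(whitelist_name, mode = c("token", "regex"),
                                token_delimiter = ":", token_index = 1L,
                                pattern = NULL, insert_index = 1L) {
  mode <- match.arg(mode)
  if (mode == "regex" && is.null(pattern))
    stop("regex mode needs a 'pattern' with one capture group")
  structure(list(whitelist_name = whitelist_name, mode = mode,
                 token_delimiter = token_delimiter,
                 token_index = as.integer(token_index), pattern = pattern,
                 insert_index = as.integer(insert_index)),
            class = "header_barcode_spec")
}

extract_header_token <- function(header, spec) {
  if (spec$mode == "token") {
    fields <- strsplit(trimws(header), "[[:space:]]+")[[1]]
    if (!length(fields)) return(NA_character_)
    last <- fields[length(fields)]
    toks <- strsplit(last, spec$token_delimiter, fixed = TRUE)[[1]]
    if (length(toks) < spec$token_index) return(NA_character_)
    toks[length(toks) - spec$token_index + 1L]
  } else {
    m <- regmatches(header, regexec(spec$pattern, header))[[1]]
    if (length(m) < 2L) return(NA_character_)
    m[2]
  }
}

#' Recover a barcode from one FASTQ header (`weed`)
#'
#' The extracted token is matched against the whitelist with zero jitter
#' (header fields have no positional uncertainty) and up to
#' `params$max_mismatches` substitutions, with the same ranking and
#' ambiguity rules as read matching. Extraction failures and wrong-length
#' tokens yield a no-match null rather than an error.
#'
#' @param header Full FASTQ header line (with or without the leading `@`).
#' @param spec A [header_barcode_spec()].
#' @param wl The [whitelist()] to validate against.
#' @param params [match_params()]; only `max_mismatches` is used.
#' @return A [barcode_hit()].
#' @export
weed_extract <- function(header, spec, wl, params = match_params()) {
  stopifnot(nzchar(header))
  tok <- extract_header_token(sub("^@", "", header), spec)
  n <- wl$n
  if (is.na(tok) || nchar(tok) != n)
    return(null_hit("no_match_null", n,
                    if (is.na(tok)) strrep("N", n)
                    else substr(paste0(tok, strrep("N", n)), 1L, n)))
  tok <- toupper(tok)
  cands <- data.frame(offset = 0L, start = 1L, seq = tok, pad = 0L,
                      stringsAsFactors = FALSE)
  mat <- seq_byte_matrix(wl$barcodes, n)
  pairs <- direct_pairs(cands, mat, params$max_mismatches)
  hit <- resolve_pairs(pairs, wl$barcodes, n, tok)
  if (is.null(hit)) null_hit("no_match_null", n, tok) else hit
}

#' Run weed over a FASTQ file
#'
#' Applies [weed_extract()] to every read header and writes a TSV
#' (`read_id status barcode mismatches`). Extraction failures are counted,
#' not fatal.
#'
#' @param fastq FASTQ path (headers are taken from this file).
#' @param spec A [header_barcode_spec()].
#' @param wl The [whitelist()].
#' @param params [match_params()].
#' @param out_tsv Output TSV path, or `NULL`.
#' @return Invisibly, a list with `hits` (data.frame) and `counts` (status
#'   table).
#' @export
run_weed <- function(fastq, spec, wl, params = match_params(),
                     out_tsv = NULL) {
  reads <- read_fastq(fastq)
  hits <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads)))
    hits[[i]] <- weed_extract(reads$id[i], spec, wl, params)
  df <- data.frame(read_id = sub("/[12]$", "", sub(" .*", "", reads$id)),
                   status = vapply(hits, `[[`, character(1), "status"),
                   barcode = vapply(hits, `[[`, character(1), "barcode"),
                   mismatches = vapply(hits, `[[`, integer(1), "mismatches"),
                   stringsAsFactors = FALSE)
  counts <- table(factor(df$status, levels = c("exact", "corrected",
                                               "ambiguous_null",
                                               "no_match_null")))
  n_fail <- sum(df$status %in% c("ambiguous_null", "no_match_null"))
  if (n_fail)
    msg("weed: %d/%d headers yielded no valid barcode", n_fail, nrow(df))
  if (!is.null(out_tsv))
    utils::write.table(df, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(hits = df, counts = counts))
}

parse_sift_policy <- function(policy) {
  if (identical(policy, "any_null_drop")) return(0L)
  m <- regmatches(policy, regexec("^max_invalid:([0-9]+)$", policy))[[1]]
  if (!length(m))
    stop(sprintf("bad sift policy '%s'; use 'any_null_drop' or 'max_invalid:<j>'",
                 policy))
  as.integer(m[2])
}

#' Filter reap output records on barcode validity (`sift`)
#'
#' Operates on the text lines of a reap output. For SAM, a record's invalid
#' count is the number of null statuses in its `XS` tag (absence of `CB`
#' alone counts as one when `XS` is missing); for interleaved FASTQ, it is
#' the number of barcode elements whose segment of the A record contains
#' `N` (requires `element_lengths`), or a single indicator of any `N` in the
#' barcode region when only its total length is known. The default policy
#' drops a read iff at least one element is null; `max_invalid:j` keeps
#' reads with at most `j` invalid elements. A/B pairing is preserved and the
#' filter is idempotent and order-preserving.
#'
#' @param lines Character vector: SAM lines (header included) or interleaved
#'   FASTQ lines.
#' @param format `"sam"` or `"interleaved_fastq"`.
#' @param policy `"any_null_drop"` (default) or `"max_invalid:<j>"`.
#' @param element_lengths Integer vector of per-element barcode lengths, in
#'   concatenation order (FASTQ format only).
#' @param barcode_length Total barcode length; fallback when
#'   `element_lengths` is unknown (FASTQ only; any `N` in the first
#'   `barcode_length` bases counts as one invalid element).
#' @return A list: `lines` (kept lines), `kept`, `dropped` (read counts).
#' @export
sift_filter <- function(lines, format = c("sam", "interleaved_fastq"),
                        policy = "any_null_drop", element_lengths = NULL,
                        barcode_length = NULL) {
  format <- match.arg(format)
  j <- parse_sift_policy(policy)
  if (format == "sam") {
    is_hdr <- startsWith(lines, "@")
    rec <- lines[!is_hdr]
    nulls <- integer(length(rec))
    has_xs <- grepl("\tXS:Z:", rec, fixed = TRUE)
    nulls[has_xs] <- vapply(regmatches(rec[has_xs],
                                       regexpr("\tXS:Z:[^\t]*", rec[has_xs])),
                            function(s) {
                              sts <- strsplit(sub("\tXS:Z:", "", s), ",")[[1]]
                              sum(sts %in% c("ambiguous_null", "no_match_null"))
                            }, integer(1), USE.NAMES = FALSE)
    nulls[!has_xs] <- ifelse(grepl("\tCB:Z:", rec[!has_xs], fixed = TRUE),
                             0L, 1L)
    keep <- nulls <= j
    list(lines = c(lines[is_hdr], rec[keep]),
         kept = sum(keep), dropped = sum(!keep))
  } else {
    if (length(lines) %% 8L != 0L)
      stop(sprintf("interleaved FASTQ: %d lines is not a multiple of 8 (odd record count or truncation)",
                   length(lines)))
    npairs <- length(lines) %/% 8L
    a_seq <- lines[seq(2L, by = 8L, length.out = npairs)]
    nulls <- integer(npairs)
    if (!is.null(element_lengths)) {
      stops <- cumsum(element_lengths)
      starts <- c(1L, stops[-length(stops)] + 1L)
      for (e in seq_along(element_lengths))
        nulls <- nulls + grepl("N", substr(a_seq, starts[e], stops[e]),
                               fixed = TRUE)
    } else {
      bl <- barcode_length %||% nchar(a_seq)
      nulls <- as.integer(grepl("N", substr(a_seq, 1L, bl), fixed = TRUE))
    }
    keep_pair <- nulls <= j
    idx <- rep(keep_pair, each = 8L)
    list(lines = lines[idx], kept = sum(keep_pair),
         dropped = sum(!keep_pair))
  }
}

#' Sift a reap output file
#'
#' File-level wrapper around [sift_filter()]; reads `in_path`, writes the
#' kept records to `out_path` (gzipped if it ends in `.gz`) and reports
#' kept/dropped counts.
#'
#' @param in_path Reap output (SAM or interleaved FASTQ; `.gz` accepted).
#' @param out_path Filtered output path.
#' @inheritParams sift_filter
#' @return The `sift_filter()` count list, invisibly.
#' @export
run_sift <- function(in_path, out_path, format = c("sam", "interleaved_fastq"),
                     policy = "any_null_drop", element_lengths = NULL,
                     barcode_length = NULL) {
  format <- match.arg(format)
  con <- open_maybe_gz(in_path, "rt")
  lines <- readLines(con)
  close(con)
  res <- sift_filter(lines, format, policy, element_lengths, barcode_length)
  out <- open_maybe_gz(out_path, "w")
  writeLines(res$lines, out)
  close(out)
  msg("sift: kept %d, dropped %d", res$kept, res$dropped)
  invisible(res[c("kept", "dropped")])
}
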