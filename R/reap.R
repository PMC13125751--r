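# The `reap` stage: match every barcode element of every read under jitter
# and mismatch budgets, assemble the corrected barcode + UMI, and emit
# unaligned SAM or interleaved FASTQ plus run statistics.

# Parse a region spec like "read1:65-74" or "read2:all".
parse_region_spec <- function(spec, what = "region") {
  if (is.null(spec)) return(NULL)
  m <- regmatches(spec, regexec("^read([12]):(all|([0-9]+)-([0-9]+))$", spec))[[1]]
  if (!length(m))
    stop(sprintf("bad %s spec '%s'; expected 'read<1|2>:<start>-<end>' or 'read<1|2>:all'",
                 what, spec))
  ri <- as.integer(m[2])
  if (m[3] == "all") return(list(read = ri, all = TRUE))
  s <- as.integer(m[4]); e <- as.integer(m[5])
  if (s < 1L || e < s) stop(sprintf("bad %s spec '%s': need 1 <= start <= end", what, spec))
  list(read = ri, all = FALSE, start = s, end = e)
}

extract_region <- function(seqs, quals, region, shift = 0L) {
  if (region$all) return(list(seq = seqs, qual = quals))
  s <- pmax(1L, region$start + shift)
  e <- region$end + shift
  list(seq = substr(seqs, s, e), qual = substr(quals, s, e))
}

# Backend bundle: everything needed to match one element repeatedly.
build_backend <- function(wl, params) {
  check_params_vs_whitelist(params, wl)
  if (params$backend == "set") {
    list(kind = "set",
         idx = build_mismatch_index(wl, params$max_mismatches,
                                    cap = params$variant_cap))
  } else {
    list(kind = "trie", trie = build_trie(wl),
         index = build_seed_index(wl, params$max_mismatches,
                                  type = params$index_type,
                                  k = params$kmer_length))
  }
}

match_element <- function(read_seq, ep, wl, params, backend) {
  if (backend$kind == "set")
    match_barcode_set(read_seq, ep, wl, params, backend$idx)
  else
    match_barcode_trie(read_seq, ep, wl, params, backend$trie, backend$index)
}

#' Extract and error-correct barcodes across a library (`reap` stage)
#'
#' For every read (pair), matches each barcode element listed in the
#' positions table under the jitter/mismatch budgets, concatenates the
#' corrected barcodes in `(read_index, start)` order, extracts the UMI and
#' target regions, and writes either an unaligned SAM or an interleaved
#' FASTQ. Reads with null elements are still emitted (use [run_sift()] to
#' drop them). Run statistics are serialised as JSON alongside the output.
#'
#' @param fastqs Character vector of 1 or 2 FASTQ paths (plain or .gz).
#' @param positions An [expected_positions()] table, a positions CSV path,
#'   or the result of [run_harvest()].
#' @param whitelists Named list of [whitelist()] objects covering every
#'   whitelist named in `positions` (plus the weed whitelist, if any).
#' @param params [match_params()].
#' @param target_spec Region of the cDNA target, e.g. `"read2:all"`.
#' @param umi_spec Optional UMI region, e.g. `"read1:37-44"`.
#' @param umi_anchor Optional whitelist name; the UMI window is shifted by
#'   that element's matched offset (useful when the UMI sits downstream of a
#'   jittered barcode block). Default: no shift.
#' @param out_format `"sam"` or `"interleaved_fastq"`.
#' @param out_path Output path (`.gz` suffix gzips FASTQ output).
#' @param header_spec Optional [header_barcode_spec()]: recover one
#'   already-demultiplexed barcode from the read-1 FASTQ header (the weed
#'   path) and insert it into the concatenation at its `insert_index`.
#' @param stats_path JSON stats path (default `out_path` + `".stats.json"`;
#'   `NULL` to skip).
#' @param chunk_size Reads per processing chunk (default 20000).
#' @param command_line Free-text provenance recorded in the SAM `@PG` line
#'   and the stats JSON.
#' @return A `reap_stats` list: `total_reads`, `reads_all_elements_valid`,
#'   `reads_all_elements_exact`, `per_element` status counters,
#'   `offset_hist` per element.
#' @export
run_reap <- function(fastqs, positions, whitelists, params = match_params(),
                     target_spec, umi_spec = NULL, umi_anchor = NULL,
                     out_format = c("sam", "interleaved_fastq"),
                     out_path, header_spec = NULL, stats_path = NA,
                     chunk_size = 20000L, command_line = "") {
  out_format <- match.arg(out_format)
  if (is.character(positions)) positions <- read_positions_csv(positions)
  if (is.list(positions) && !is.data.frame(positions) &&
      !is.null(positions$positions)) positions <- positions$positions
  validate_positions(positions)
  positions <- positions[order(positions$read_index, positions$start), ,
                         drop = FALSE]
  if (anyDuplicated(positions$whitelist))
    stop("positions table names a whitelist more than once")
  missing_wl <- setdiff(positions$whitelist, names(whitelists))
  if (length(missing_wl))
    stop(sprintf("whitelist(s) named in positions but not supplied: %s",
                 paste(missing_wl, collapse = ", ")))
  if (any(positions$read_index == 2L) && length(fastqs) < 2L)
    stop("positions reference read 2 but only one FASTQ was supplied")
  wls <- whitelists[positions$whitelist]
  backends <- lapply(wls, build_backend, params = params)
  lens <- vapply(wls, function(w) w$n, integer(1))
  warn_position_overlaps(positions, stats::setNames(lens, positions$whitelist))

  target <- parse_region_spec(target_spec, "target")
  umi <- parse_region_spec(umi_spec, "umi")
  if (!is.null(target) && target$read > length(fastqs))
    stop("target spec references read 2 but only one FASTQ was supplied")
  if (!is.null(umi) && umi$read > length(fastqs))
    stop("umi spec references read 2 but only one FASTQ was supplied")
  if (!is.null(umi_anchor) && !umi_anchor %in% positions$whitelist)
    stop(sprintf("umi_anchor '%s' is not an element in the positions table",
                 umi_anchor))
  weed_wl <- NULL
  if (!is.null(header_spec)) {
    weed_wl <- whitelists[[header_spec$whitelist_name]]
    if (is.null(weed_wl))
      stop(sprintf("header spec references whitelist '%s' which was not supplied",
                   header_spec$whitelist_name))
    check_params_vs_whitelist(params, weed_wl)
  }

  n_el <- nrow(positions)
  el_names <- positions$whitelist
  status_levels <- c("exact", "corrected", "ambiguous_null", "no_match_null")
  per_element <- matrix(0L, nrow = n_el, ncol = 4L,
                        dimnames = list(el_names, status_levels))
  offset_hist <- stats::setNames(vector("list", n_el), el_names)
  for (i in seq_len(n_el)) offset_hist[[i]] <- integer(0)
  weed_counts <- stats::setNames(integer(4), status_levels)
  total <- 0L
  all_valid <- 0L
  all_exact <- 0L

  con <- if (out_format == "sam") file(out_path, "w")
         else open_maybe_gz(out_path, "w")
  on.exit(close(con), add = TRUE)
  if (out_format == "sam") {
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 paste0("@PG\tID:jitterbc\tPN:jitterbc\tVN:",
                        as.character(utils::packageVersion("jitterbc")),
                        "\tCL:", if (nzchar(command_line)) command_line
                                 else "run_reap")), con)
  }

  skip <- 0L
  repeat {
    r1 <- read_fastq(fastqs[1], n_records = chunk_size, skip = skip)
    if (nrow(r1) == 0L) break
    r2 <- if (length(fastqs) == 2L)
            read_fastq(fastqs[2], n_records = chunk_size, skip = skip)
          else NULL
    if (!is.null(r2) && nrow(r2) != nrow(r1))
      stop(sprintf("paired FASTQ record counts differ at records %d-%d",
                   skip + 1L, skip + max(nrow(r1), nrow(r2))))
    skip <- skip + nrow(r1)
    nreads <- nrow(r1)
    seqs <- list(r1$seq, if (is.null(r2)) NULL else r2$seq)
    quals <- list(r1$qual, if (is.null(r2)) NULL else r2$qual)

    corrected <- character(nreads)
    raw <- character(nreads)
    bc_qual <- character(nreads)
    n_null <- integer(nreads)
    mm_total <- integer(nreads)
    off_str <- character(nreads)
    st_str <- character(nreads)
    anchor_shift <- integer(nreads)
    exact_all <- logical(nreads)

    hit_order <- seq_len(n_el)
    insert_at <- if (is.null(header_spec)) NA_integer_
                 else min(header_spec$insert_index, n_el + 1L)
    for (i in seq_len(nreads)) {
      hits <- vector("list", n_el)
      for (e in seq_len(n_el)) {
        ri <- positions$read_index[e]
        hits[[e]] <- match_element(seqs[[ri]][i],
                                   list(start = positions$start[e]),
                                   wls[[e]], params, backends[[e]])
        st <- hits[[e]]$status
        per_element[e, st] <- per_element[e, st] + 1L
        if (!is.na(hits[[e]]$offset)) {
          key <- as.character(hits[[e]]$offset)
          cur <- offset_hist[[e]][key]
          offset_hist[[e]][key] <- if (is.na(cur)) 1L else cur + 1L
        }
      }
      if (!is.null(header_spec)) {
        whit <- weed_extract(r1$id[i], header_spec, weed_wl, params)
        weed_counts[whit$status] <- weed_counts[whit$status] + 1L
        hits <- append(hits, list(whit), after = insert_at - 1L)
      }
      statuses <- vapply(hits, `[[`, character(1), "status")
      mms <- vapply(hits, `[[`, integer(1), "mismatches")
      offs <- vapply(hits, `[[`, integer(1), "offset")
      corrected[i] <- paste0(vapply(hits, `[[`, character(1), "barcode"),
                             collapse = "")
      raw[i] <- paste0(vapply(hits, `[[`, character(1), "observed"),
                       collapse = "")
      n_null[i] <- sum(statuses %in% c("ambiguous_null", "no_match_null"))
      mm_total[i] <- sum(mms, na.rm = TRUE)
      off_str[i] <- paste(ifelse(is.na(offs), ".", offs), collapse = ",")
      st_str[i] <- paste(statuses, collapse = ",")
      exact_all[i] <- all(statuses == "exact")
      # per-element quality for the barcode block (window quals, '#' pads)
      bq <- character(length(hits))
      for (e in seq_along(hits)) {
        h <- hits[[e]]
        is_weed <- !is.null(header_spec) && e == insert_at
        if (is_weed || is.na(h$offset)) {
          bq[e] <- strrep("#", nchar(h$barcode))
        } else {
          eidx <- if (is.null(header_spec) || e < insert_at) e else e - 1L
          ri <- positions$read_index[eidx]
          s <- positions$start[eidx] + h$offset
          n <- lens[eidx]
          qread <- quals[[ri]][i]
          Lq <- nchar(qread)
          cs <- max(1L, s); ce <- min(Lq, s + n - 1L)
          core <- if (cs <= ce) substr(qread, cs, ce) else ""
          bq[e] <- paste0(strrep("#", max(0L, cs - s)), core,
                          strrep("#", n - max(0L, cs - s) - nchar(core)))
        }
      }
      bc_qual[i] <- paste0(bq, collapse = "")
      if (!is.null(umi_anchor)) {
        ai <- match(umi_anchor, positions$whitelist)
        aoff <- hits[[if (is.null(header_spec) || ai < insert_at) ai
                      else ai + 1L]]$offset
        anchor_shift[i] <- if (is.na(aoff)) 0L else aoff
      }
    }

    tgt <- if (is.null(target)) list(seq = seqs[[1]], qual = quals[[1]])
           else extract_region(seqs[[target$read]], quals[[target$read]], target)
    um <- if (is.null(umi)) list(seq = rep("", nreads), qual = rep("", nreads))
          else {
            if (any(anchor_shift != 0L)) {
              us <- character(nreads); uq <- character(nreads)
              for (i in seq_len(nreads)) {
                z <- extract_region(seqs[[umi$read]][i], quals[[umi$read]][i],
                                    umi, shift = anchor_shift[i])
                us[i] <- z$seq; uq[i] <- z$qual
              }
              list(seq = us, qual = uq)
            } else extract_region(seqs[[umi$read]], quals[[umi$read]], umi)
          }

    ids <- sub("/[12]$", "", sub(" .*", "", r1$id))
    tagged <- data.frame(id = ids, target_seq = tgt$seq, target_qual = tgt$qual,
                         corrected = corrected, raw = raw,
                         bc_qual = bc_qual, umi = um$seq, umi_qual = um$qual,
                         n_null = n_null, mm_total = mm_total,
                         off_str = off_str, st_str = st_str,
                         stringsAsFactors = FALSE)
    if (out_format == "sam") emit_sam(tagged, con)
    else emit_interleaved_fastq(tagged, con)

    total <- total + nreads
    all_valid <- all_valid + sum(n_null == 0L)
    all_exact <- all_exact + sum(exact_all & n_null == 0L)
    if (nrow(r1) < chunk_size) break
  }

  stats <- structure(list(
    total_reads = total,
    reads_all_elements_valid = all_valid,
    reads_all_elements_exact = all_exact,
    per_element = lapply(stats::setNames(seq_len(n_el), el_names),
                         function(e) as.list(per_element[e, ])),
    offset_hist = lapply(offset_hist, function(h) as.list(h)),
    weed = if (is.null(header_spec)) NULL else as.list(weed_counts),
    params = list(jitter = params$jitter,
                  max_mismatches = params$max_mismatches,
                  backend = params$backend),
    command_line = command_line,
    out_path = out_path, out_format = out_format),
    class = "reap_stats")
  if (!is.null(stats_path)) {
    if (length(stats_path) == 1L && is.na(stats_path))
      stats_path <- paste0(out_path, ".stats.json")
    jsonlite::write_json(unclass(stats), stats_path, auto_unbox = TRUE,
                         null = "null", digits = NA, pretty = TRUE)
  }
  stats
}

#' Emit tagged reads as unaligned SAM
#'
#' One record per read pair: flag 4, `RNAME/POS/CIGAR` unset, SEQ/QUAL = the
#' target region. Tags: `CR` raw (observed) barcode, `CB` corrected barcode
#' (omitted when any element is null), `UR`/`UY` UMI sequence/qualities when
#' present, `XM` total mismatches over non-null elements, `XJ` comma-joined
#' per-element offsets (`.` for null), `XS` comma-joined per-element
#' statuses.
#'
#' @param tagged A chunk data.frame assembled by [run_reap()].
#' @param con Open writable connection (header already written).
#' @return Invisibly, the number of records written.
#' @export
emit_sam <- function(tagged, con) {
  if (!nrow(tagged)) return(invisible(0L))
  seqs <- ifelse(nzchar(tagged$target_seq), tagged$target_seq, "*")
  quals <- ifelse(nzchar(tagged$target_qual), tagged$target_qual, "*")
  tags <- paste0("CR:Z:", tagged$raw)
  has_cb <- tagged$n_null == 0L
  tags <- paste0(tags, ifelse(has_cb, paste0("\tCB:Z:", tagged$corrected), ""))
  has_umi <- nzchar(tagged$umi)
  tags <- paste0(tags, ifelse(has_umi,
                              paste0("\tUR:Z:", tagged$umi,
                                     "\tUY:Z:", tagged$umi_qual), ""))
  tags <- paste0(tags, "\tXM:i:", tagged$mm_total,
                 "\tXJ:Z:", tagged$off_str,
                 "\tXS:Z:", tagged$st_str)
  writeLines(paste(tagged$id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                   seqs, quals, tags, sep = "\t"), con)
  invisible(nrow(tagged))
}

#' Emit tagged reads as interleaved FASTQ
#'
#' Records alternate A,B per input pair: record A (`/1`) carries the
#' corrected barcode concatenation plus UMI as its sequence (qualities taken
#' from the matched windows, `#` for pad/null bases), record B (`/2`)
#' carries the target sequence and qualities. Reads with null elements keep
#' their `N` runs and are still emitted; [run_sift()] removes them.
#'
#' @inheritParams emit_sam
#' @return Invisibly, the number of FASTQ records written (2 per pair).
#' @export
emit_interleaved_fastq <- function(tagged, con) {
  if (!nrow(tagged)) return(invisible(0L))
  a_seq <- paste0(tagged$corrected, tagged$umi)
  a_qual <- paste0(tagged$bc_qual, tagged$umi_qual)
  lines <- paste0("@", tagged$id, "/1\n", a_seq, "\n+\n", a_qual, "\n",
                  "@", tagged$id, "/2\n", tagged$target_seq, "\n+\n",
                  tagged$target_qual)
  writeLines(lines, con)
  invisible(2L * nrow(tagged))
}
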