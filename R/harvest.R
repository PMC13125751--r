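# The `harvest` stage: aggregate seed position profiles into an
# expected-positions CSV and diagnose library-structure problems (low read
# fraction -> barcode likely consumed by provider demultiplexing; multimodal
# profile -> jitter or layout ambiguity; absent -> wrong whitelist or
# orientation).

#' Pick the expected position from one position profile
#'
#' The expected start is the argmax of the per-position exact-hit counts
#' across both read files (ties broken toward the smaller
#' `(read_index, start)`); `read_fraction` is the peak count over reads
#' sampled. Diagnostics: `absent` (no counts at all), `low_read_fraction`
#' (`read_fraction < low_fraction_threshold`, suggesting the barcode was
#' already demultiplexed and should be recovered from headers with the weed
#' path), `multimodal` (second-highest count exceeds
#' `multimodal_threshold * peak`).
#'
#' @param profile A `position_profile` from [run_seed()].
#' @param low_fraction_threshold Default 0.05.
#' @param multimodal_threshold Default 0.5.
#' @return A list with `position` (an [expected_positions()] row or `NULL`
#'   when absent) and `report` (one-row data.frame: `whitelist`,
#'   `read_index`, `start`, `read_fraction`, `peak_count`,
#'   `secondary_peak_fraction`, `flags`).
#' @export
pick_expected_position <- function(profile, low_fraction_threshold = 0.05,
                                   multimodal_threshold = 0.5) {
  stopifnot(inherits(profile, "position_profile"))
  cnt <- profile$counts
  if (nrow(cnt) == 0L) {
    report <- data.frame(whitelist = profile$whitelist_name,
                         read_index = NA_integer_, start = NA_integer_,
                         read_fraction = 0, peak_count = 0L,
                         secondary_peak_fraction = 0,
                         flags = "absent", stringsAsFactors = FALSE)
    return(list(position = NULL, report = report))
  }
  o <- order(-cnt$count, cnt$read_index, cnt$start)
  cnt <- cnt[o, , drop = FALSE]
  peak <- cnt[1, ]
  secondary <- if (nrow(cnt) > 1L) cnt$count[2] else 0L
  spf <- secondary / peak$count
  rf <- peak$count / profile$reads_sampled
  flags <- character(0)
  if (rf < low_fraction_threshold) flags <- c(flags, "low_read_fraction")
  if (spf > multimodal_threshold) flags <- c(flags, "multimodal")
  pos <- expected_positions(profile$whitelist_name, peak$read_index,
                            peak$start, rf)
  report <- data.frame(whitelist = profile$whitelist_name,
                       read_index = peak$read_index, start = peak$start,
                       read_fraction = rf, peak_count = peak$count,
                       secondary_peak_fraction = spf,
                       flags = paste(flags, collapse = ","),
                       stringsAsFactors = FALSE)
  list(position = pos, report = report)
}

#' Aggregate seed profiles into an expected-positions CSV (`harvest` stage)
#'
#' Reads one profile TSV per whitelist, picks each whitelist's expected
#' position with [pick_expected_position()], and writes a positions CSV with
#' one row per non-absent whitelist ordered by `(read_index, start)` - the
#' order that defines barcode concatenation downstream. A human-readable
#' report is written alongside. Whitelist names must be unique across
#' profiles.
#'
#' @param profile_paths Character vector of profile TSVs (or a list of
#'   `position_profile` objects).
#' @param out_csv Output positions CSV path, or `NULL` to skip writing.
#' @param report_path Plain-text report path (default `out_csv` +
#'   `".report.txt"`); `NULL` to skip.
#' @param low_fraction_threshold,multimodal_threshold Passed through.
#' @return A list with `positions` (the [expected_positions()] table) and
#'   `report` (data.frame over all whitelists, including absent ones).
#' @export
run_harvest <- function(profile_paths, out_csv = NULL, report_path = NULL,
                        low_fraction_threshold = 0.05,
                        multimodal_threshold = 0.5) {
  profiles <- lapply(profile_paths, function(p) {
    if (inherits(p, "position_profile")) p else read_profile_tsv(p)
  })
  if (!length(profiles)) stop("run_harvest needs at least one profile")
  nms <- vapply(profiles, function(p) p$whitelist_name, character(1))
  if (anyDuplicated(nms))
    stop(sprintf("duplicate whitelist name across profiles: %s",
                 nms[duplicated(nms)][1]))
  picks <- lapply(profiles, pick_expected_position,
                  low_fraction_threshold = low_fraction_threshold,
                  multimodal_threshold = multimodal_threshold)
  report <- do.call(rbind, lapply(picks, `[[`, "report"))
  pos_list <- Filter(Negate(is.null), lapply(picks, `[[`, "position"))
  for (i in seq_len(nrow(report))) {
    fl <- report$flags[i]
    if (fl == "absent")
      msg("whitelist '%s': no exact hits in the sampled reads; omitted from the positions CSV (check whitelist orientation and file)",
          report$whitelist[i])
    else if (grepl("low_read_fraction", fl))
      msg("whitelist '%s': read fraction %.3f at start %d is low; if reads were already demultiplexed on this barcode, recover it from headers (weed) and drop it from the positions CSV",
          report$whitelist[i], report$read_fraction[i], report$start[i])
    if (grepl("multimodal", fl))
      msg("whitelist '%s': secondary peak at %.2f of primary; check for jitter or layout ambiguity",
          report$whitelist[i], report$secondary_peak_fraction[i])
  }
  if (!length(pos_list))
    stop("no whitelist produced a usable position (all absent)")
  positions <- do.call(rbind, pos_list)
  o <- order(positions$read_index, positions$start)
  positions <- positions[o, , drop = FALSE]
  rownames(positions) <- NULL
  class(positions) <- c("expected_positions", "data.frame")
  if (!is.null(out_csv)) {
    write_positions_csv(positions, out_csv)
    if (is.null(report_path)) report_path <- paste0(out_csv, ".report.txt")
  }
  if (!is.null(report_path)) {
    lines <- c("harvest report",
               sprintf("%-12s read=%s start=%s fraction=%s peak=%s secondary=%.3f flags=%s",
                       report$whitelist,
                       ifelse(is.na(report$read_index), ".", report$read_index),
                       ifelse(is.na(report$start), ".", report$start),
                       sprintf("%.4f", report$read_fraction),
                       report$peak_count, report$secondary_peak_fraction,
                       ifelse(nzchar(report$flags), report$flags, "-")))
    writeLines(lines, report_path)
  }
  list(positions = positions, report = report)
}
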