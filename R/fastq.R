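# FASTQ I/O thin wrappers around Biostrings. Records are handled as plain
# data.frames (id = full header line minus '@', seq, qual) because every
# stage needs header text, sequence and quality together.

read_fastq <- function(path, n_records = -1L, skip = 0L) {
  x <- tryCatch(
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path,
                                                quality.scoring = "phred",
                                                nrec = n_records,
                                                skip = skip)),
    error = function(e) stop(sprintf("failed to parse FASTQ '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

count_fastq_records <- function(path) {
  con <- open_maybe_gz(path, "rt")
  on.exit(close(con))
  n <- 0L
  repeat {
    chunk <- readLines(con, n = 40000L)
    if (!length(chunk)) break
    n <- n + length(chunk)
  }
  if (n %% 4L != 0L)
    stop(sprintf("truncated FASTQ '%s': %d lines is not a multiple of 4 (record %d incomplete)",
                 path, n, n %/% 4L + 1L))
  n %/% 4L
}

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

write_fastq_records <- function(con, ids, seqs, quals) {
  if (!length(ids)) return(invisible(NULL))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  invisible(NULL)
}

#' Sample reads from one or two FASTQ files
#'
#' `mode = "head"` deterministically takes the first `n_sample` records;
#' `mode = "reservoir"` draws a uniform sample reproducible from `rng_seed`.
#' Paired files are sampled in lockstep (the same record indices from both)
#' and must hold equal record counts. If fewer than `n_sample` records exist,
#' all records are returned with a warning.
#'
#' @param fastq_paths Character vector of 1 or 2 FASTQ paths (plain or .gz).
#' @param n_sample Number of read (pairs) to sample (default 10000).
#' @param mode `"head"` or `"reservoir"`.
#' @param rng_seed Seed for reservoir sampling.
#' @return A list of data.frames (one per input file, columns `id`, `seq`,
#'   `qual`), all with identical row counts.
#' @export
sample_reads <- function(fastq_paths, n_sample = 10000L,
                         mode = c("head", "reservoir"), rng_seed = 1L) {
  mode <- match.arg(mode)
  n_sample <- as.integer(n_sample)
  stopifnot(length(fastq_paths) %in% c(1L, 2L), n_sample >= 1L)
  counts <- vapply(fastq_paths, count_fastq_records, integer(1))
  if (length(counts) == 2L && counts[1] != counts[2])
    stop(sprintf("paired FASTQ record counts differ: %d (%s) vs %d (%s)",
                 counts[1], fastq_paths[1], counts[2], fastq_paths[2]))
  total <- counts[1]
  if (total < n_sample) {
    warning(sprintf("requested %d reads but only %d available; using all",
                    n_sample, total), call. = FALSE)
    n_sample <- total
  }
  if (mode == "head") {
    lapply(fastq_paths, read_fastq, n_records = n_sample)
  } else {
    keep <- sort(with_seed(rng_seed, sample.int(total, n_sample)))
    lapply(fastq_paths, function(p) read_fastq(p)[keep, , drop = FALSE])
  }
}
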