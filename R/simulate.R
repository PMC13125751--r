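# Synthetic combinatorial-library generator with a ground-truth ledger.
# Emulates split-pool reads: a fixed layout of barcode elements, linkers and
# UMI on read 1, cDNA on read 2, with injected per-read jitter (a single
# offset applied to the whole barcode block, as produced by upstream
# slippage/ligation artifacts), substitutions, and read-start truncations.

#' Generate a random barcode whitelist
#'
#' Draws random barcodes by greedy rejection until `size` sequences satisfy
#' a minimum pairwise Hamming distance. Optional shift-robustness
#' constraints additionally bound the Hamming distance between every
#' barcode's prefix and every barcode's suffix at small relative shifts,
#' emulating the synchronization-robust barcode sets shipped with
#' combinatorial kits: they guarantee that a barcode seen through a window
#' displaced by `s` positions can never masquerade as (or be one
#' substitution away from) a different whitelist member, which is what makes
#' in-budget jitter + mismatch errors uniquely decodable.
#'
#' @param size Number of barcodes.
#' @param n Barcode length.
#' @param min_pairwise_hamming Minimum Hamming distance between any two
#'   barcodes.
#' @param rng_seed Seed; the same seed reproduces the same whitelist.
#' @param name Whitelist name (default `"wl"`).
#' @param shift_min_dist Optional integer vector: element `s` is the minimum
#'   Hamming distance required between `b[(1+s)..n]` and `b'[1..(n-s)]` (and
#'   the mirrored alignment) for ALL ordered barcode pairs including
#'   self-pairs. `NULL` disables shift constraints.
#' @param max_attempts Candidate draws before giving up (infeasible
#'   constraints fail explicitly rather than looping forever).
#' @return A [whitelist()].
#' @export
generate_whitelist <- function(size, n, min_pairwise_hamming, rng_seed = 1L,
                               name = "wl", shift_min_dist = NULL,
                               max_attempts = 50000L) {
  if (min_pairwise_hamming > n)
    stop(sprintf("min pairwise Hamming %d cannot exceed barcode length %d",
                 min_pairwise_hamming, n))
  if (!is.null(shift_min_dist) && length(shift_min_dist) >= n)
    stop("shift_min_dist longer than barcode allows")
  with_seed(rng_seed, {
    accepted <- character(0)
    attempts <- 0L
    while (length(accepted) < size) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(
          "could not reach %d barcodes (n=%d, min_d=%d%s) after %d draws; constraints look infeasible",
          size, n, min_pairwise_hamming,
          if (is.null(shift_min_dist)) "" else ", shift-robust",
          max_attempts))
      cand <- random_dna(1L, n)
      if (cand %in% accepted) next
      pool <- c(accepted, cand)
      ok <- TRUE
      if (length(accepted)) {
        d <- vapply(accepted, function(b) hamming(b, cand), integer(1))
        if (any(d < min_pairwise_hamming)) ok <- FALSE
      }
      if (ok && !is.null(shift_min_dist)) {
        for (s in seq_along(shift_min_dist)) {
          need <- shift_min_dist[s]
          if (need <= 0L) next
          pre <- substr(pool, 1L, n - s)        # b'[1..n-s]
          suf <- substr(pool, s + 1L, n)        # b[(1+s)..n]
          cand_pre <- substr(cand, 1L, n - s)
          cand_suf <- substr(cand, s + 1L, n)
          d1 <- vapply(pre, function(p) hamming(cand_suf, p), integer(1))
          d2 <- vapply(suf, function(p) hamming(cand_pre, p), integer(1))
          if (any(d1 < need) || any(d2 < need)) { ok <- FALSE; break }
        }
      }
      if (ok) accepted <- pool
    }
    whitelist(accepted, name)
  })
}

#' Describe a synthetic combinatorial read layout and error model
#'
#' Read 1 carries the ordered `elements` (barcode slots bound to whitelists,
#' fixed linkers, a UMI) followed by random filler up to `read_length`;
#' read 2 is random cDNA of `read2_length`. Errors: `offset_probs` is the
#' per-read distribution of a single jitter offset applied to the whole
#' barcode block (positive offsets insert random pad bases before the block,
#' negative offsets delete leading bases); `one_sub_frac` reads receive
#' exactly one substitution at a uniform position inside one barcode
#' element; `sub_rate` applies independent per-base substitutions across
#' read 1; `trunc_probs` is the distribution of read-start truncation
#' lengths. Substituted-read and shifted-read classes are drawn disjointly
#' (a read gets at most one of the two) so the two error modes stay
#' separately diagnosable; see the methods vignette.
#'
#' @param elements A list of element descriptors, each
#'   `list(type = "barcode", whitelist = <whitelist>)`,
#'   `list(type = "linker", seq = "CAGTGA")` or
#'   `list(type = "umi", length = 8)`.
#' @param read_length Read-1 length (layout + max positive offset must fit).
#' @param read2_length Read-2 (cDNA) length.
#' @param offset_probs Named numeric vector, names are signed offsets
#'   (e.g. `c("0" = .7, "1" = .3)`); must sum to 1.
#' @param one_sub_frac Fraction of reads with exactly one barcode-element
#'   substitution.
#' @param sub_rate Independent per-base substitution rate on read 1.
#' @param trunc_probs Named numeric vector of read-start truncation lengths
#'   (default no truncation); must sum to 1.
#' @return A `library_design` object.
#' @export
library_design <- function(elements, read_length, read2_length = 60L,
                           offset_probs = c("0" = 1), one_sub_frac = 0,
                           sub_rate = 0, trunc_probs = c("0" = 1)) {
  stopifnot(is.list(elements), length(elements) >= 1L)
  lens <- integer(length(elements))
  names_ <- character(length(elements))
  n_bc <- 0L
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    if (el$type == "barcode") {
      stopifnot(inherits(el$whitelist, "whitelist"))
      lens[i] <- el$whitelist$n
      n_bc <- n_bc + 1L
      names_[i] <- el$whitelist$name
    } else if (el$type == "linker") {
      lens[i] <- nchar(el$seq)
      names_[i] <- sprintf("linker%d", i)
    } else if (el$type == "umi") {
      lens[i] <- as.integer(el$length)
      names_[i] <- "umi"
    } else stop(sprintf("unknown element type '%s'", el$type))
  }
  if (n_bc == 0L) stop("design needs at least one barcode element")
  offs <- as.integer(names(offset_probs))
  if (anyNA(offs)) stop("offset_probs names must be signed integers")
  if (abs(sum(offset_probs) - 1) > 1e-9) stop("offset_probs must sum to 1")
  if (abs(sum(trunc_probs) - 1) > 1e-9) stop("trunc_probs must sum to 1")
  if (one_sub_frac < 0 || one_sub_frac > 1) stop("one_sub_frac in [0,1]")
  if (one_sub_frac + max(0, offset_probs[offs != 0L] |> sum()) > 1 + 1e-9)
    stop("one_sub_frac plus shifted fraction exceeds 1 (classes are disjoint)")
  layout_len <- sum(lens)
  if (layout_len + max(c(0L, offs)) > read_length)
    stop(sprintf("layout (%d nt) plus max positive offset does not fit read length %d",
                 layout_len, read_length))
  starts <- cumsum(c(1L, lens[-length(lens)]))
  structure(list(elements = elements, lens = lens, starts = starts,
                 names = names_, read_length = as.integer(read_length),
                 read2_length = as.integer(read2_length),
                 offset_probs = offset_probs, one_sub_frac = one_sub_frac,
                 sub_rate = sub_rate, trunc_probs = trunc_probs),
            class = "library_design")
}

#' Designed (unjittered) start positions of the barcode elements
#' @param design A [library_design()].
#' @return An [expected_positions()] table (read_fraction 1).
#' @export
design_positions <- function(design) {
  is_bc <- vapply(design$elements, function(e) e$type == "barcode", logical(1))
  expected_positions(design$names[is_bc], 1L, design$starts[is_bc], 1)
}

#' Simulate a combinatorial library with a ground-truth ledger
#'
#' Assembles `n_reads` read pairs per the design, injects the error model,
#' and writes FASTQ files plus a TSV ledger recording, per read: the true
#' barcode of every element, the jitter offset, the substitution (element,
#' position within element, new base), the truncation length and the true
#' UMI. Byte-identical across reruns with the same seed.
#'
#' @param design A [library_design()].
#' @param n_reads Number of read pairs.
#' @param out_prefix Path prefix; writes `<prefix>_R1.fastq`,
#'   `<prefix>_R2.fastq` and `<prefix>_ledger.tsv` (set `write = FALSE` to
#'   skip files).
#' @param rng_seed Seed.
#' @param write Whether to write the FASTQ/ledger files.
#' @return Invisibly, a list with `ledger` (data.frame), `r1`, `r2`
#'   (character vectors of sequences) and the output paths (when written).
#' @export
generate_library <- function(design, n_reads, out_prefix = NULL,
                             rng_seed = 1L, write = !is.null(out_prefix)) {
  stopifnot(inherits(design, "library_design"))
  n_reads <- as.integer(n_reads)
  with_seed(rng_seed, {
    nel <- length(design$elements)
    parts <- vector("list", nel)
    is_bc <- vapply(design$elements, function(e) e$type == "barcode", logical(1))
    bc_names <- design$names[is_bc]
    true_bc <- list()
    umi_true <- rep("", n_reads)
    for (i in seq_len(nel)) {
      el <- design$elements[[i]]
      if (el$type == "barcode") {
        pick <- sample.int(length(el$whitelist$barcodes), n_reads,
                           replace = TRUE)
        parts[[i]] <- el$whitelist$barcodes[pick]
        true_bc[[el$whitelist$name]] <- parts[[i]]
      } else if (el$type == "linker") {
        parts[[i]] <- rep(el$seq, n_reads)
      } else {
        parts[[i]] <- random_dna(n_reads, el$length)
        umi_true <- parts[[i]]
      }
    }
    block <- do.call(paste0, parts)
    block_len <- sum(design$lens)

    # disjoint error classes: shifted reads first, then substituted reads
    # among the remaining unshifted ones
    offs <- as.integer(names(design$offset_probs))
    offset <- offs[sample.int(length(offs), n_reads, replace = TRUE,
                              prob = as.numeric(design$offset_probs))]
    sub_el <- rep(NA_integer_, n_reads)
    sub_pos <- rep(NA_integer_, n_reads)
    sub_base <- rep(NA_character_, n_reads)
    if (design$one_sub_frac > 0) {
      unshifted <- which(offset == 0L)
      n_sub <- round(design$one_sub_frac * n_reads)
      if (n_sub > length(unshifted))
        stop("not enough unshifted reads for the requested one_sub_frac")
      chosen <- sample(unshifted, n_sub)
      bc_slots <- which(is_bc)
      sl <- bc_slots[sample.int(length(bc_slots), n_sub, replace = TRUE)]
      sub_el[chosen] <- sl
      sub_pos[chosen] <- vapply(design$lens[sl], function(l)
        sample.int(l, 1L), integer(1))
      for (k in seq_along(chosen)) {
        i <- chosen[k]
        gpos <- design$starts[sub_el[i]] + sub_pos[i] - 1L
        old <- substr(block[i], gpos, gpos)
        newb <- sample(setdiff(.BASES, old), 1L)
        substr(block[i], gpos, gpos) <- newb
        sub_base[i] <- newb
      }
    }

    pad <- character(n_reads)
    pos_shift <- which(offset > 0L)
    if (length(pos_shift))
      pad[pos_shift] <- vapply(offset[pos_shift], function(o)
        random_dna(1L, o), character(1))
    shifted <- paste0(pad, block)
    neg_shift <- which(offset < 0L)
    if (length(neg_shift))
      shifted[neg_shift] <- substr(shifted[neg_shift],
                                   1L - offset[neg_shift], block_len)

    fill_len <- design$read_length - nchar(shifted)
    filler <- character(n_reads)
    need <- which(fill_len > 0L)
    for (i in need) filler[i] <- random_dna(1L, fill_len[i])
    r1 <- substr(paste0(shifted, filler), 1L, design$read_length)

    # per-base substitution noise (independent of the one-sub class)
    if (design$sub_rate > 0) {
      nsub <- stats::rbinom(n_reads, design$read_length, design$sub_rate)
      for (i in which(nsub > 0L)) {
        ps <- sample.int(design$read_length, nsub[i])
        for (p in ps) {
          old <- substr(r1[i], p, p)
          substr(r1[i], p, p) <- sample(setdiff(.BASES, old), 1L)
        }
      }
    }

    trunc_lens <- as.integer(names(design$trunc_probs))
    trunc <- trunc_lens[sample.int(length(trunc_lens), n_reads,
                                   replace = TRUE,
                                   prob = as.numeric(design$trunc_probs))]
    tr <- which(trunc > 0L)
    if (length(tr))
      r1[tr] <- substr(r1[tr], trunc[tr] + 1L, design$read_length)

    r2 <- random_dna(n_reads, design$read2_length)
    ids <- sprintf("sim%06d", seq_len(n_reads))

    ledger <- data.frame(read_id = ids, offset = offset,
                         truncation = trunc, umi = umi_true,
                         stringsAsFactors = FALSE)
    for (nm in bc_names) ledger[[paste0("barcode_", nm)]] <- true_bc[[nm]]
    ledger$sub_element <- ifelse(is.na(sub_el), "",
                                 design$names[ifelse(is.na(sub_el), 1L, sub_el)])
    ledger$sub_pos <- sub_pos
    ledger$sub_base <- ifelse(is.na(sub_base), "", sub_base)

    paths <- NULL
    if (write) {
      p1 <- paste0(out_prefix, "_R1.fastq")
      p2 <- paste0(out_prefix, "_R2.fastq")
      pl <- paste0(out_prefix, "_ledger.tsv")
      con <- file(p1, "w")
      write_fastq_records(con, ids, r1, strrep("I", nchar(r1)))
      close(con)
      con <- file(p2, "w")
      write_fastq_records(con, ids, r2, strrep("I", nchar(r2)))
      close(con)
      utils::write.table(ledger, pl, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- list(r1 = p1, r2 = p2, ledger = pl)
    }
    invisible(list(ledger = ledger, r1 = r1, r2 = r2, paths = paths))
  })
}
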