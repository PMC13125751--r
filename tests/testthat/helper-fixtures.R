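# Shared synthetic fixtures, generated once per test run and cached.
# Seeds are fixed constants: they define the simulated world, they are not
# tuned per test.

.fix <- new.env(parent = emptyenv())

# The acceptance fixture: 10000 read pairs, three rounds of 96 shift-robust
# 8-nt barcodes (pairwise Hamming >= 3), 30% of reads with the barcode block
# at offset +1, a disjoint 10% with exactly one barcode substitution.
acc_fixture <- function(n_reads = 10000L) {
  key <- paste0("acc", n_reads)
  if (!is.null(.fix[[key]])) return(.fix[[key]])
  fx <- standard_fixture_design(rng_seed = 101L)
  dir <- tempfile("accfix")
  dir.create(dir)
  lib <- generate_library(fx$design, n_reads,
                          out_prefix = file.path(dir, "lib"),
                          rng_seed = 202L)
  .fix[[key]] <- list(fx = fx, lib = lib, dir = dir,
                      r1 = file.path(dir, "lib_R1.fastq"),
                      r2 = file.path(dir, "lib_R2.fastq"))
  .fix[[key]]
}

# Expected positions for the acceptance fixture, derived through the real
# seed -> harvest path.
acc_positions <- function(n_reads = 10000L) {
  key <- paste0("accpos", n_reads)
  if (!is.null(.fix[[key]])) return(.fix[[key]])
  fix <- acc_fixture(n_reads)
  profs <- lapply(fix$fx$whitelists, function(w)
    run_seed(c(fix$r1, fix$r2), w, n_sample = n_reads))
  .fix[[key]] <- run_harvest(profs)
  .fix[[key]]
}

# Cached reap runs over the acceptance fixture (SAM output kept on disk).
acc_reap <- function(x, m, n_reads = 10000L, backend = "set") {
  key <- sprintf("reap_%d_%d_%d_%s", x, m, n_reads, backend)
  if (!is.null(.fix[[key]])) return(.fix[[key]])
  fix <- acc_fixture(n_reads)
  pos <- acc_positions(n_reads)$positions
  out <- file.path(fix$dir, paste0(key, ".sam"))
  stats <- run_reap(c(fix$r1, fix$r2), pos, fix$fx$whitelists,
                    match_params(jitter = x, max_mismatches = m,
                                 backend = backend),
                    target_spec = "read2:all", umi_spec = "read1:37-44",
                    out_format = "sam", out_path = out)
  .fix[[key]] <- list(stats = stats, sam = out)
  .fix[[key]]
}

ledger_truth_barcode <- function(ledger) {
  paste0(ledger$barcode_bc1, ledger$barcode_bc2, ledger$barcode_bc3)
}

sam_records <- function(path) {
  lines <- readLines(path)
  lines[!startsWith(lines, "@")]
}

sam_tag <- function(records, tag) {
  pat <- paste0(tag, ":[ZiA]:[^\t]*")
  out <- rep(NA_character_, length(records))
  mm <- regexpr(pat, records)
  hit <- mm > 0
  out[hit] <- sub(paste0(tag, ":[ZiA]:"), "",
                  regmatches(records, mm))
  out
}

# A small error-free design with one 8-nt barcode round, used by unit tests.
tiny_design <- function(wl, offset_probs = c("0" = 1), one_sub_frac = 0,
                        trunc_probs = c("0" = 1), read_length = 40L) {
  library_design(
    elements = list(list(type = "barcode", whitelist = wl),
                    list(type = "linker", seq = "ACGGTC"),
                    list(type = "umi", length = 6L)),
    read_length = read_length, read2_length = 30L,
    offset_probs = offset_probs, one_sub_frac = one_sub_frac,
    trunc_probs = trunc_probs)
}

write_tmp_fastq <- function(ids, seqs, quals = strrep("I", nchar(seqs)),
                            path = tempfile(fileext = ".fastq")) {
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), path)
  path
}
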