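# The reap stage: extraction orchestration, SAM/interleaved-FASTQ emission,
# statistics, UMI handling.

reap_tiny <- function(offset_probs = c("0" = 1), one_sub_frac = 0,
                      x = 1, m = 1, n_reads = 200, out_format = "sam",
                      umi_spec = "read1:15-20", umi_anchor = NULL,
                      seed = 50) {
  wl <- generate_whitelist(24, 8, 3, rng_seed = seed, name = "bcA",
                           shift_min_dist = c(2L, 1L, 1L))
  design <- tiny_design(wl, offset_probs = offset_probs,
                        one_sub_frac = one_sub_frac)
  dir <- tempfile(); dir.create(dir)
  lib <- generate_library(design, n_reads, out_prefix = file.path(dir, "t"),
                          rng_seed = seed + 1)
  out <- file.path(dir, paste0("t.", out_format))
  st <- run_reap(c(file.path(dir, "t_R1.fastq"), file.path(dir, "t_R2.fastq")),
                 design_positions(design), list(bcA = wl),
                 match_params(jitter = x, max_mismatches = m),
                 target_spec = "read2:all", umi_spec = umi_spec,
                 umi_anchor = umi_anchor, out_format = out_format,
                 out_path = out)
  list(st = st, out = out, lib = lib, wl = wl, dir = dir, design = design)
}

test_that("reap recovers jittered and substituted reads within budget", {
  r <- reap_tiny(offset_probs = c("0" = 0.7, "1" = 0.3), one_sub_frac = 0.1)
  led <- r$lib$ledger
  expect_equal(r$st$total_reads, 200L)
  expect_equal(r$st$reads_all_elements_valid, 200L)
  rec <- sam_records(r$out)
  cb <- sam_tag(rec, "CB")
  expect_identical(cb, led$barcode_bcA)
  # offsets recorded per read match the ledger
  xj <- as.integer(sam_tag(rec, "XJ"))
  expect_identical(xj, led$offset)
  # mismatch totals match the ledger's substitution record
  xm <- as.integer(sam_tag(rec, "XM"))
  expect_identical(xm, as.integer(led$sub_element != ""))
  # without jitter, shifted reads null out
  r0 <- reap_tiny(offset_probs = c("0" = 0.7, "1" = 0.3), one_sub_frac = 0.1,
                  x = 0)
  led0 <- r0$lib$ledger
  expect_equal(r0$st$reads_all_elements_valid, sum(led0$offset == 0L))
})

test_that("stats counters are consistent and serialised as JSON", {
  r <- reap_tiny(offset_probs = c("0" = 0.6, "1" = 0.4))
  pe <- r$st$per_element$bcA
  expect_equal(sum(unlist(pe)), r$st$total_reads)
  expect_equal(pe$exact, r$st$total_reads)  # all in-budget, x=1
  js <- jsonlite::read_json(paste0(r$out, ".stats.json"))
  expect_equal(js$total_reads, r$st$total_reads)
  expect_equal(js$reads_all_elements_valid, r$st$reads_all_elements_valid)
  oh <- r$st$offset_hist$bcA
  expect_equal(sum(unlist(oh)), r$st$total_reads)
  expect_equal(oh[["1"]], sum(r$lib$ledger$offset == 1L))
})

test_that("SAM output carries the documented tag vocabulary", {
  r <- reap_tiny()
  lines <- readLines(r$out)
  expect_match(lines[1], "^@HD\tVN:1.6")
  expect_match(lines[2], "^@PG\tID:jitterbc")
  rec <- sam_records(r$out)
  f <- strsplit(rec[1], "\t")[[1]]
  expect_equal(f[2], "4")          # unmapped flag
  expect_equal(f[3], "*")          # RNAME unset
  expect_equal(f[4], "0")          # POS unset
  expect_equal(f[6], "*")          # CIGAR unset
  expect_equal(nchar(f[10]), 30L)  # target = read2 (30 nt in tiny design)
  # all-exact read: CB == CR, XM 0, XJ all zeros
  exact <- rec[sam_tag(rec, "XS") == "exact"]
  expect_gt(length(exact), 0)
  expect_identical(sam_tag(exact, "CB"), sam_tag(exact, "CR"))
  expect_true(all(sam_tag(exact, "XM") == "0"))
  expect_true(all(sam_tag(exact, "XJ") == "0"))
  expect_true(all(nchar(sam_tag(rec, "UR")) == 6L))
  expect_true(all(nchar(sam_tag(rec, "UY")) == 6L))
})

test_that("null elements drop CB but keep CR and statuses in SAM", {
  # library whose whitelist is wrong for 'bcA': everything nulls out
  wl_wrong <- generate_whitelist(8, 8, 5, rng_seed = 77, name = "bcA")
  r <- reap_tiny()
  st2 <- run_reap(c(file.path(r$dir, "t_R1.fastq"),
                    file.path(r$dir, "t_R2.fastq")),
                  design_positions(r$design), list(bcA = wl_wrong),
                  match_params(jitter = 0, max_mismatches = 0),
                  target_spec = "read2:all", out_format = "sam",
                  out_path = file.path(r$dir, "wrong.sam"),
                  stats_path = NULL)
  rec <- sam_records(file.path(r$dir, "wrong.sam"))
  nulls <- grepl("null", sam_tag(rec, "XS"))
  expect_true(any(nulls))
  expect_true(all(is.na(sam_tag(rec[nulls], "CB"))))
  expect_true(all(!is.na(sam_tag(rec[nulls], "CR"))))
  expect_true(all(sam_tag(rec[nulls], "XJ") == "."))
  expect_equal(substr(sam_tag(rec[nulls], "XS")[1], 1, 13), "no_match_null")
})

test_that("interleaved FASTQ alternates A,B and conserves structure", {
  r <- reap_tiny(out_format = "interleaved_fastq")
  lines <- readLines(r$out)
  expect_equal(length(lines), 200L * 8L)
  ids <- lines[seq(1, length(lines), by = 4)]
  expect_true(all(grepl("/1$", ids[seq(1, length(ids), by = 2)])))
  expect_true(all(grepl("/2$", ids[seq(2, length(ids), by = 2)])))
  # parse through a FASTQ reader: record count and lengths conserved
  parsed <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r$out))
  expect_equal(length(parsed), 400L)
  a_rec <- parsed[seq(1, 400, by = 2)]
  expect_true(all(Biostrings::width(a_rec) == 8L + 6L))  # barcode + UMI
  b_rec <- parsed[seq(2, 400, by = 2)]
  expect_true(all(Biostrings::width(b_rec) == 30L))
  # A-record sequences equal ledger truth barcode + UMI
  expect_identical(as.character(a_rec, use.names = FALSE),
                   paste0(r$lib$ledger$barcode_bcA, r$lib$ledger$umi))
})

test_that("gzip output is honoured for interleaved FASTQ", {
  r <- reap_tiny()
  out_gz <- file.path(r$dir, "t.fastq.gz")
  run_reap(c(file.path(r$dir, "t_R1.fastq"), file.path(r$dir, "t_R2.fastq")),
           design_positions(r$design), list(bcA = r$wl),
           match_params(), target_spec = "read2:all",
           out_format = "interleaved_fastq", out_path = out_gz,
           stats_path = NULL)
  con <- gzfile(out_gz, "rt")
  lines <- readLines(con)
  close(con)
  expect_equal(length(lines), 200L * 8L)
})

test_that("UMI anchoring follows the matched element offset", {
  r <- reap_tiny(offset_probs = c("0" = 0.5, "1" = 0.5),
                 umi_anchor = "bcA")
  led <- r$lib$ledger
  ur <- sam_tag(sam_records(r$out), "UR")
  # anchored UMI window tracks the jitter, so it equals the true UMI even
  # for shifted reads
  expect_identical(ur, led$umi)
  # unanchored, shifted reads see a displaced UMI window
  r2 <- reap_tiny(offset_probs = c("0" = 0.5, "1" = 0.5), seed = 50)
  ur2 <- sam_tag(sam_records(r2$out), "UR")
  led2 <- r2$lib$ledger
  shifted <- led2$offset == 1L
  expect_identical(ur2[!shifted], led2$umi[!shifted])
  # the displaced window sees the linker's last base plus 5 nt of UMI
  expect_identical(ur2[shifted],
                   paste0("C", substr(led2$umi[shifted], 1, 5)))
})

test_that("reap validates configuration before processing", {
  r <- reap_tiny()
  fq <- c(file.path(r$dir, "t_R1.fastq"), file.path(r$dir, "t_R2.fastq"))
  pos <- design_positions(r$design)
  expect_error(run_reap(fq, pos, list(), match_params(),
                        target_spec = "read2:all", out_format = "sam",
                        out_path = tempfile()), "not supplied")
  expect_error(run_reap(fq[1], pos, list(bcA = r$wl), match_params(),
                        target_spec = "read2:all", out_format = "sam",
                        out_path = tempfile()), "only one FASTQ")
  expect_error(run_reap(fq, pos, list(bcA = r$wl), match_params(),
                        target_spec = "read3:all", out_format = "sam",
                        out_path = tempfile()), "bad target spec")
  expect_error(run_reap(fq, pos, list(bcA = r$wl), match_params(),
                        target_spec = "read2:all", umi_spec = "read1:9-2",
                        out_format = "sam", out_path = tempfile()),
               "start <= end")
  expect_error(run_reap(fq, pos, list(bcA = r$wl), match_params(),
                        target_spec = "read2:all", umi_anchor = "nope",
                        out_format = "sam", out_path = tempfile()),
               "umi_anchor")
})
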