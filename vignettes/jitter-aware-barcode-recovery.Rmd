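---
title: "Jitter-aware barcode recovery for combinatorial single-cell libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Jitter-aware barcode recovery for combinatorial single-cell libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jitterbc)
```

## The problem

Split-pool (combinatorial) barcoding tags each cell with a concatenation of
round barcodes read out from fixed slots of a sequencing read. In practice
those slots drift: incomplete barcode synthesis, polymerase slippage during
amplification, and rare indels introduced at ligation or tagmentation shift
barcode elements by one or two nucleotides relative to their designed
positions. A demultiplexer that assumes fixed positions loses every read
whose barcode moved -- or worse, accepts a one-mismatch barcode at the fixed
position when a perfect match sits one base away, silently assigning the
read to the wrong cell.

`jitterbc` treats the positional drift ("jitter") as a first-class part of
the error model. The workflow has three mandatory stages and two optional
ones:

1. **seed** -- scan a subsample of reads (default 10 000) for *exact*
   whitelist occurrences at *every* position, producing a per-position
   support histogram per whitelist. No mismatches, no jitter: the point is
   to learn where each element really lives.
2. **harvest** -- reduce each histogram to an expected start position plus
   diagnostics, and write the expected-positions CSV that fixes the barcode
   concatenation order (`read_index`, then `start`).
3. **reap** -- re-scan every read, matching each element inside a window of
   `±x` positions around its expected start with up to `m` substitutions,
   and emit unaligned SAM (CR/CB/UR/UY tags) or interleaved FASTQ plus a
   stats JSON.
4. **weed** (optional) -- when the sequencing provider already demultiplexed
   on one barcode, recover it from the FASTQ header instead; **sift**
   (optional) -- drop reads with unmatched (all-N) elements.

## The matching rule

For an element of length $n$ expected at start $s$ with jitter radius $x$,
the query window is the set of $2x+1$ substrings starting at
$s-x, \dots, s+x$. A window that runs past a read end is trimmed there and
padded with `N` on the out-of-range side, and every `N` counts as a
mismatch; this is what lets a barcode whose first $t$ bases were clipped
off the read start be recovered whenever $t \le m$.

Candidates are ranked lexicographically:

1. a perfect whitelist match beats everything;
2. then fewest substitutions;
3. then smallest $|{\rm offset}|$ from the expected start.

If the best rank is shared by two *different* whitelist barcodes the
element is ambiguous and an all-`N` null of length $n$ is returned rather
than a guess. The ranking leaves the sign of the offset open at
equal $|{\rm offset}|$; we scan upstream (negative) before downstream so
that a tie involving only a *single* barcode resolves deterministically
while distinct-barcode ties still null out.

Two backends implement this contract with byte-identical results:

* **set** -- a precomputed "mismatches" table mapping every sequence within
  Hamming distance $m$ of a whitelist barcode back to its origin(s)
  ($|W| \sum_{d\le m}\binom{n}{d}3^d$ entries; a capacity guard at $5\times
  10^7$ entries refuses and points at the trie backend). Suited to the
  ~96-barcode whitelists of each combinatorial round.
* **trie** -- a 4-ary prefix tree for exact lookups plus a pigeonhole seed
  index for approximate retrieval: each barcode is split into $m+1$
  contiguous seeds (lengths differing by at most one), so any sequence
  within $m$ substitutions shares at least one seed exactly; retrieved
  candidates are verified by full Hamming distance before the shared
  ranking. An overlapping k-mer filter (with $k \le \lfloor n/(m+1)\rfloor$
  so the same completeness bound holds) is available behind the same
  interface; both feed identical verification, so the choice is purely an
  indexing trade-off.

The equivalence of the two backends, and of both against a brute-force
oracle that enumerates every window candidate against every barcode and
applies the ranking literally, is the headline property of the test suite
(10 000 randomized instances each, including a 10 000-barcode whitelist).

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `jitter` ($x$) | max positional deviation, nt | 1 | matches the drift magnitude (1--2 nt) reported for these chemistries; the window grows linearly and false-hit risk grows with it |
| `max_mismatches` ($m$) | max substitutions per element | 1 | comparable to mainstream single-cell demultiplexers (1--2); must satisfy $m < n$ |
| `n_sample` | reads profiled by seed | 10 000 | enough for a stable per-position histogram at the read fractions seen in practice |
| `low_fraction_threshold` | harvest flag | 0.05 | a peak supported by under 5% of reads usually means the barcode was consumed by provider demultiplexing (use weed) |
| `multimodal_threshold` | harvest flag | 0.5 | a secondary peak above half the primary signals jitter or a layout mis-assumption worth inspecting |

Elements that start at the very beginning of a read (or end at its last
base) lose bases to clipping and are recovered through the N-padding rule,
where each pad base costs one mismatch -- give such elements a larger `m`.
Longer barcodes tolerate larger `m` because the whitelist collision risk
falls. Whitelists must be supplied in read orientation (no reverse
complementing is attempted), and adapter trimming is best done *after*
extraction so that designed positions stay stable.

The UMI is extracted from a fixed window by default. Jitter upstream of the
UMI displaces it equally, so `umi_anchor = "<element>"` shifts the UMI
window by that element's matched offset; both behaviours are explicit
because neither is universally right (the anchor is only as reliable as the
element's match).

## What the simulator emulates -- and what it does not

`generate_library()` assembles reads from a declared layout (barcode slots
bound to whitelists, fixed linkers, a UMI, random cDNA) and injects:

* a single per-read jitter offset applied to the *whole* barcode block
  (random pad bases inserted before it, or leading bases deleted), matching
  the upstream-indel origin of real jitter rather than independent
  per-element drift;
* substitutions -- either exactly one per read inside a random barcode
  element (a calibrated stressor) or an independent per-base rate;
* read-start truncations of a configurable length distribution.

Every read's true barcodes, offset, substitution and UMI are recorded in a
ledger, so recovery can be scored exactly. The generator is deterministic
from its seed.

Two modelling decisions deserve justification:

* **Shift-robust whitelists.** Random barcode sets constrained only by
  pairwise Hamming distance admit rare accidents in which a barcode seen
  through a window displaced by one or two positions (its prefix preceded
  by linker/pad context) coincides with -- or sits one substitution from --
  a *different* whitelist member. At a rate of roughly $10^{-4}$ to
  $10^{-3}$ per read such accidents make "100% recovery of in-budget
  errors" unattainable even though every injected error is within $(x, m)$.
  Real kits design their barcode sets against exactly this failure;
  `generate_whitelist(shift_min_dist = ...)` reproduces it by bounding the
  Hamming distance between every barcode's prefix and every barcode's
  suffix at small relative shifts. With the bounds used by the standard
  fixture (distance $\ge 2$ at shift 1, $\ge 1$ at shifts 2--3), in-budget
  errors are *uniquely decodable by construction*, which is what turns the
  closed-loop recovery test into a deterministic statement instead of a
  high-probability one.
* **Disjoint error classes.** The standard fixture draws its shifted reads
  (30%) and substituted reads (10%) as disjoint classes. A read carrying
  both a shift and a substitution is not uniquely decodable in general at
  $(x{=}1, m{=}1)$ -- the substituted off-window can tie with the true hit
  -- so compound errors would turn exact closed-loop claims probabilistic.
  Keeping the classes disjoint keeps each error mode separately
  diagnosable; the per-base `sub_rate` channel remains available for
  compound-noise stress tests.

The simulator does **not** model quality-score-correlated errors, indels
inside barcodes (jitter displaces an intact element; `reap` likewise does
not align through internal indels), chimeric reads, or realistic
transcriptome content (cDNA is uniform random). A green closed-loop test
therefore establishes the correctness of the matching and bookkeeping
machinery under the declared error model -- not performance on any
particular chemistry.

## Numerical and formatting choices

* Coordinates are 1-based inclusive everywhere -- in the CSV/TSV schemas,
  the logs, and internally (R's native convention; no 0-based layer).
* Harvest peak ties break toward the smaller start; the jitter window in
  `reap` absorbs the ±1 uncertainty this leaves.
* Pad/null bases are written with quality `#` (Phred 2), the conventional
  minimum-confidence placeholder.
* In SAM output `CB` is *omitted* when any element is null (tag-aware
  consumers treat a missing tag correctly), while interleaved FASTQ keeps
  the `N` runs (sequence-based consumers need fixed-length records);
  `sift` understands both conventions.
* Null elements report sentinel `NA` mismatch/offset values, shown as `.`
  in the `XJ` tag.
* The mismatch-variant table is held in a keyed `data.table`; whitelists
  small enough (≤ 3×10^5 entries) additionally get an environment hash,
  which changes nothing observable but makes per-read lookups cheap.

## Known limitations

* Matching is substitution-only within an element; an indel *inside* a
  barcode is at best recovered as a shifted near-match of the budget
  allows, at worst nulled.
* `seed` profiles exact occurrences only, so an element whose every copy
  carries an error never appears in the profile (a deliberate design:
  harvest's `absent` flag is the signal to inspect whitelist orientation).
* The trie backend rebuilds its structures per run; they are not
  serialized (build cost is negligible at whitelist scales).
* Stats JSON and SAM `@PG` record parameters for provenance, but no
  attempt is made at byte-stable output across package versions.
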