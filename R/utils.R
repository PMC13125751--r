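# Internal low-level sequence helpers shared across modules.

.BASES <- c("A", "C", "G", "T")
.BASE_RAW <- charToRaw("ACGT")

# byte value -> base index 1..4 (NA for anything else, including 'N')
.BYTE2INT <- local({
  v <- rep(NA_integer_, 256L)
  v[as.integer(.BASE_RAW)] <- 1:4
  v
})

seq_to_int <- function(s) .BYTE2INT[as.integer(charToRaw(s))]

# Hamming distance between two equal-length strings; every byte that differs
# counts, so 'N' mismatches all of A/C/G/T (whitelists never contain N).
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# n x B raw-byte matrix of equal-length sequences, one column per sequence.
seq_byte_matrix <- function(seqs, n) {
  stopifnot(all(nchar(seqs) == n))
  matrix(charToRaw(paste0(seqs, collapse = "")), nrow = n)
}

# Hamming distance of one query against every column of a byte matrix.
hamming_to_matrix <- function(query, mat, cols = NULL) {
  q <- charToRaw(query)
  if (!is.null(cols)) mat <- mat[, cols, drop = FALSE]
  if (ncol(mat) == 0L) return(integer(0))
  .colSums(mat != q, nrow(mat), ncol(mat))
}

# Run code with a private RNG stream; restores the caller's .Random.seed.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  force(code)
}

random_dna <- function(n_seq, len) {
  if (n_seq == 0L) return(character(0))
  s <- paste0(sample(.BASES, n_seq * len, replace = TRUE), collapse = "")
  substring(s, seq(1L, n_seq * len, by = len), seq(len, n_seq * len, by = len))
}

msg <- function(...) message("[jitterbc] ", sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a
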