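# Internal utilities: deterministic RNG substreams and small helpers.
#
# Every randomised operation takes an explicit seed and derives a private
# stream from it, so no function ever consumes or perturbs the caller's
# global RNG state.

# Deterministic 31-bit hash of arbitrary tag values (seed, replicate,
# stage names ...). Stable across sessions and platforms.
hash_seed <- function(...) {
  parts <- vapply(list(...), function(x) paste(format(x, scientific = FALSE), collapse = ","),
                  character(1))
  bytes <- utf8ToInt(paste(parts, collapse = "|"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a private Mersenne-Twister stream seeded with
# `seed`, restoring the caller's RNG state afterwards.
with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

is_nonempty_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Nearest integer, half away from zero (positive arguments only here).
round_half_up <- function(x) floor(x + 0.5)
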