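# Negative-control datasets: random sequences and off-target surrogate
# gene regions.

#' Default surrogate-region length windows per marker
#'
#' Length ranges (bp) chosen so surrogate regions match the typical
#' primer-trimmed product lengths of the three markers: 12S (164-191),
#' 16S (149-240), COI (310-313).
#'
#' @format Named list of integer vectors `c(min, max)`.
#' @export
MARKER_LENGTH_RANGES <- list(`12S` = c(164L, 191L),
                             `16S` = c(149L, 240L),
                             COI = c(310L, 313L))

#' Generate random-sequence negative controls
#'
#' Emits `n` sequences of i.i.d.-uniform bases over A/C/G/T. The
#' defaults (100 sequences of 170 bp) produce a random negative-control
#' library of roughly 16S-product length; no classifier should assign
#' any species to these sequences against a marker reference database.
#'
#' @param n Number of sequences (default 100).
#' @param length Sequence length in bp (default 170).
#' @param seed Integer seed; output is deterministic given `seed`.
#' @return Named character vector of sequences (ids `random_001`, ...).
#' @export
random_genes <- function(n = 100L, length = 170L, seed = 1L) {
  if (!is.numeric(n) || n < 0) stop("n must be >= 0", call. = FALSE)
  if (!is.numeric(length) || length < 1) stop("length must be >= 1", call. = FALSE)
  n <- as.integer(n); length <- as.integer(length)
  if (n == 0L) return(setNames(character(0), character(0)))
  with_rng(hash_seed(seed, "random_genes"), {
    seqs <- vapply(seq_len(n), function(i) random_dna(length), character(1))
    setNames(seqs, sprintf("random_%03d", seq_len(n)))
  })
}

#' Extract surrogate gene regions as negative controls
#'
#' For each input gene of length at least `length_range[1]`, extracts
#' one contiguous subregion whose length is drawn uniformly from
#' `[min, max]` (capped at the gene length) at a uniformly drawn start.
#' Genes shorter than the minimum are skipped with a warning. Used to
#' turn off-target sequences (e.g. bacterial genes) into controls of
#' marker-product length.
#'
#' @param genes Named character vector of source gene sequences.
#' @param length_range Integer vector `c(min, max)`; see
#'   [MARKER_LENGTH_RANGES] for the per-marker defaults.
#' @param seed Integer seed; output is deterministic given `seed`.
#' @return Named character vector of subregions (one per retained gene,
#'   original ids preserved).
#' @export
surrogate_regions <- function(genes, length_range, seed = 1L) {
  stopifnot(is.character(genes), length(length_range) == 2L,
            length_range[1] > 0, length_range[1] <= length_range[2])
  if (length(genes) == 0L) return(setNames(character(0), character(0)))
  lens <- nchar(genes)
  short <- lens < length_range[1]
  if (any(short))
    warning(sum(short), " gene(s) shorter than ", length_range[1],
            " bp skipped: ", paste(names(genes)[short], collapse = ", "),
            call. = FALSE)
  genes <- genes[!short]; lens <- lens[!short]
  if (length(genes) == 0L) return(setNames(character(0), character(0)))
  with_rng(hash_seed(seed, "surrogate"), {
    pick1 <- function(from, to) if (from == to) from else sample(seq(from, to), 1L)
    out <- character(length(genes))
    for (i in seq_along(genes)) {
      hi <- min(length_range[2], lens[i])
      w <- pick1(length_range[1], hi)
      s <- pick1(1L, lens[i] - w + 1L)
      out[i] <- substr(genes[[i]], s, s + w - 1L)
    }
    setNames(out, names(genes))
  })
}

#' Generate compositionally biased "foreign" genes
#'
#' Random genes drawn from a skewed base composition (default GC-rich),
#' giving negative-control source material with a k-mer composition
#' distinct from the uniform-random control - a synthetic surrogate for
#' off-target (e.g. bacterial) gene sets.
#'
#' @param n Number of genes.
#' @param length Gene length in bp.
#' @param base_probs Sampling probabilities for A, C, G, T.
#' @param seed Integer seed.
#' @return Named character vector of sequences (ids `foreign_001`, ...).
#' @export
foreign_genes <- function(n = 100L, length = 1200L,
                          base_probs = c(A = 0.17, C = 0.33, G = 0.33, T = 0.17),
                          seed = 1L) {
  stopifnot(n >= 0, length >= 1, length(base_probs) == 4L)
  if (n == 0L) return(setNames(character(0), character(0)))
  with_rng(hash_seed(seed, "foreign_genes"), {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(DNA_BASES, length, replace = TRUE, prob = base_probs),
            collapse = ""), character(1))
    setNames(seqs, sprintf("foreign_%03d", seq_len(n)))
  })
}
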