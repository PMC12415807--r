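# Native in-silico PCR, representative selection, paired-end read
# simulation and expected-ASV derivation.

#' Define a primer pair
#'
#' @param name Primer pair name (e.g. `"12S_toy"`).
#' @param forward Forward primer, 5'->3', IUPAC alphabet.
#' @param reverse Reverse primer, written 5'->3' on the opposing strand
#'   (its reverse complement is searched on the template's plus strand).
#' @param max_mismatch Maximum mismatches tolerated per primer site
#'   (substitutions only, no indels; default 4).
#' @param product_range Length bounds `(min, max)` for the inter-primer
#'   (primer-trimmed) product.
#' @return An object of class `primer`.
#' @export
primer <- function(name, forward, reverse, max_mismatch = 4L,
                   product_range = c(1L, 10000L)) {
  stopifnot(is_nonempty_string(name), is_nonempty_string(forward),
            is_nonempty_string(reverse),
            is.numeric(max_mismatch), max_mismatch >= 0,
            length(product_range) == 2L,
            product_range[1] > 0, product_range[1] <= product_range[2])
  structure(list(name = name, forward = toupper(forward),
                 reverse = toupper(reverse),
                 max_mismatch = as.integer(max_mismatch),
                 product_range = as.integer(product_range)),
            class = "primer")
}

# all match start positions of an IUPAC pattern in a template,
# substitutions only (IUPAC-compatible positions count as matches)
primer_sites <- function(pattern, template, max_mismatch) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(template),
                                max.mismatch = max_mismatch,
                                with.indels = FALSE, fixed = FALSE)
  BiocGenerics::start(m)
}

#' In-silico PCR amplification of a template
#'
#' Finds all forward-primer sites and all reverse-primer sites (on the
#' opposite strand) within `primer$max_mismatch` substitutions under
#' IUPAC compatibility, on both template strands, and emits every
#' forward/reverse pairing whose primer-trimmed product length lies
#' within `primer$product_range`. Amplicon sequences are reported in
#' forward-primer orientation with primers trimmed (set
#' `keep_primers = TRUE` to retain them); duplicates arising from
#' palindromic matches on both strands are removed.
#'
#' @param template Nucleotide string over ACGTN/IUPAC (template-side
#'   ambiguity codes are treated permissively: a primer base matches
#'   whenever the two IUPAC sets intersect).
#' @param primer A [primer()].
#' @param keep_primers Retain the primer-matching template bases in the
#'   reported sequence.
#' @return A data.frame with one row per amplicon: `start`, `end`
#'   (1-based closed coordinates of the reported region on the plus
#'   strand of `template`), `strand` and `sequence`. Zero rows when no
#'   site pairing qualifies.
#' @export
amplify <- function(template, primer, keep_primers = FALSE) {
  stopifnot(inherits(primer, "primer"), is_nonempty_string(template))
  template <- toupper(template)
  n <- nchar(template)
  flen <- nchar(primer$forward); rlen <- nchar(primer$reverse)
  scan_strand <- function(tmpl) {
    # forward primer on plus strand; revcomp(reverse) downstream
    fs <- primer_sites(primer$forward, tmpl, primer$max_mismatch)
    rs <- primer_sites(revcomp(primer$reverse), tmpl, primer$max_mismatch)
    out <- list()
    for (f in fs) for (r in rs) {
      core_start <- f + flen           # first base after forward primer
      core_end <- r - 1L               # last base before reverse site
      core_len <- core_end - core_start + 1L
      if (core_len < primer$product_range[1] ||
          core_len > primer$product_range[2]) next
      if (keep_primers) {
        out[[length(out) + 1L]] <- c(f, r + rlen - 1L)
      } else {
        out[[length(out) + 1L]] <- c(core_start, core_end)
      }
    }
    out
  }
  hits <- list()
  plus <- scan_strand(template)
  for (h in plus)
    hits[[length(hits) + 1L]] <- data.frame(
      start = h[1], end = h[2], strand = "+",
      sequence = substr(template, h[1], h[2]), stringsAsFactors = FALSE)
  rc <- revcomp(template)
  minus <- scan_strand(rc)
  for (h in minus)
    hits[[length(hits) + 1L]] <- data.frame(
      # map coordinates on the reverse strand back to plus-strand space
      start = n - h[2] + 1L, end = n - h[1] + 1L, strand = "-",
      sequence = substr(rc, h[1], h[2]), stringsAsFactors = FALSE)
  if (length(hits) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out[, c("start", "end", "sequence")]), , drop = FALSE]
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' In-silico PCR over a whole reference database
#'
#' Runs [amplify()] on every record and annotates each amplicon with its
#' source sequence id and source lineage.
#'
#' @param db A `reference_db`.
#' @param primer A [primer()].
#' @param keep_primers See [amplify()].
#' @return An amplicon table: data.frame with columns `amplicon_id`,
#'   `seqid`, `start`, `end`, `strand`, `sequence` and the five lineage
#'   rank columns of the source record.
#' @export
amplify_db <- function(db, primer, keep_primers = FALSE) {
  stopifnot(inherits(db, "reference_db"))
  rows <- list()
  for (sid in names(db$sequences)) {
    amps <- amplify(db$sequences[[sid]], primer, keep_primers = keep_primers)
    if (nrow(amps) == 0L) next
    lin <- db$taxonomy[db$taxonomy$seqid == sid, TAX_RANKS, drop = FALSE]
    rows[[sid]] <- cbind(data.frame(seqid = sid, stringsAsFactors = FALSE),
                         amps, lin, row.names = NULL)
  }
  if (length(rows) == 0L)
    return(cbind(data.frame(amplicon_id = character(), seqid = character(),
                            start = integer(), end = integer(),
                            strand = character(), sequence = character(),
                            stringsAsFactors = FALSE),
                 as.data.frame(setNames(rep(list(character()), 5), TAX_RANKS))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- cbind(data.frame(amplicon_id = sprintf("amp%04d", seq_len(nrow(out))),
                          stringsAsFactors = FALSE), out)
  out
}

#' Write amplicons to FASTA with provenance headers
#'
#' Headers follow `>ampN src=<seqid> species=<name> loc=<start>-<end>(<strand>)`.
#'
#' @param amplicons Amplicon table from [amplify_db()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_amplicon_fasta <- function(amplicons, path) {
  headers <- sprintf("%s src=%s species=%s loc=%d-%d(%s)",
                     amplicons$amplicon_id, amplicons$seqid,
                     gsub(" ", "_", amplicons$species),
                     amplicons$start, amplicons$end, amplicons$strand)
  seqs <- Biostrings::DNAStringSet(setNames(amplicons$sequence, headers))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# k-mer set of one sequence (exact k, ACGT windows only)
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Greedy maximum-diversity representative selection
#'
#' Picks `n` sequences spreading over k-mer space: the first pick
#' maximises mean Jaccard distance to all other sequences, and each
#' subsequent pick maximises its minimum distance to the already-chosen
#' set (greedy max-min). This is a k-mer stand-in for phylogeny-based
#' representative selection; exact ties are broken by a seeded random
#' draw so the result is deterministic given `seed`.
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @param n Number of representatives (>= 1); when `n` is at least the
#'   number of sequences, all ids are returned.
#' @param seed Integer seed (used only for tie-breaking).
#' @param k k-mer length for the Jaccard distance (default 8).
#' @return Character vector of selected ids, in pick order.
#' @export
select_representatives <- function(sequences, n, seed = 1L, k = 8L) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  stopifnot(is.character(sequences), length(sequences) >= 1L,
            !is.null(names(sequences)))
  ids <- names(sequences)
  if (n >= length(ids)) return(ids)
  sets <- lapply(sequences, kmer_set, k = k)
  m <- length(ids)
  d <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    uni <- length(union(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <- if (uni == 0) 0 else 1 - inter / uni
  }
  with_rng(hash_seed(seed, "representatives"), {
    pick_max <- function(vals, pool) {
      best <- pool[vals[pool] >= max(vals[pool]) - 1e-12]
      if (length(best) > 1L) best <- sample(best, 1L)
      best
    }
    chosen <- pick_max(rowMeans(d), seq_len(m))
    while (length(chosen) < n) {
      pool <- setdiff(seq_len(m), chosen)
      min_d <- apply(d[pool, chosen, drop = FALSE], 1, min)
      chosen <- c(chosen, pool[pick_max(setNames(min_d, NULL),
                                        seq_along(pool))])
    }
    ids[chosen]
  })
}

#' Simulate paired-end reads from an amplicon
#'
#' Read 1 is the 5' prefix of the amplicon and read 2 the reverse
#' complement of its 3' suffix, each truncated to
#' `min(read_length, amplicon length)`. Sequencing error is modelled as
#' independent per-base substitutions at `substitution_rate` (the
#' substituted base is drawn uniformly from the three alternatives);
#' base qualities are a flat Phred value. Pairs whose mean quality falls
#' below `min_quality` are regenerated up to `max_retries` times;
#' exactly `n_pairs` pairs are emitted. Deterministic given `seed`.
#'
#' @param amplicon Amplicon nucleotide string.
#' @param n_pairs Number of read pairs (default 500, the per-gene-copy
#'   simulation depth).
#' @param read_length Read length in bp (e.g. 130 for short-marker
#'   libraries, 230 for COI-length products).
#' @param substitution_rate Per-base substitution probability in
#'   `[0, 1)`.
#' @param base_quality Flat Phred quality assigned to every base
#'   (default 35).
#' @param min_quality Minimum mean read quality (default 0; e.g. 28 to
#'   emulate a quality floor).
#' @param seed Integer seed.
#' @param max_retries Regeneration budget for pairs failing the quality
#'   floor.
#' @return A data.frame with columns `pair_id`, `read1`, `read2`,
#'   `qual1`, `qual2` (Phred+33 strings).
#' @export
simulate_reads <- function(amplicon, n_pairs = 500L, read_length = 130L,
                           substitution_rate = 0.001, base_quality = 35L,
                           min_quality = 0L, seed = 1L, max_retries = 10L) {
  stopifnot(is_nonempty_string(amplicon), read_length >= 1,
            substitution_rate >= 0, substitution_rate < 1, n_pairs >= 0)
  len <- min(read_length, nchar(amplicon))
  r1_t <- substr(amplicon, 1L, len)
  r2_t <- revcomp(substr(amplicon, nchar(amplicon) - len + 1L, nchar(amplicon)))
  qual <- strrep(intToUtf8(base_quality + 33L), len)
  mean_q <- base_quality  # flat quality profile
  if (n_pairs == 0L)
    return(data.frame(pair_id = integer(), read1 = character(),
                      read2 = character(), qual1 = character(),
                      qual2 = character(), stringsAsFactors = FALSE))
  if (mean_q < min_quality)
    stop("mean read quality ", mean_q, " cannot reach min_quality ",
         min_quality, " after ", max_retries, " retries", call. = FALSE)
  with_rng(hash_seed(seed, "simreads"), {
    mutate_read <- function(tmpl) {
      if (substitution_rate == 0) return(tmpl)
      b <- strsplit(tmpl, "")[[1]]
      hit <- which(runif(length(b)) < substitution_rate)
      for (i in hit) b[i] <- sample(setdiff(DNA_BASES, b[i]), 1L)
      paste(b, collapse = "")
    }
    r1 <- vapply(seq_len(n_pairs), function(i) mutate_read(r1_t), character(1))
    r2 <- vapply(seq_len(n_pairs), function(i) mutate_read(r2_t), character(1))
    data.frame(pair_id = seq_len(n_pairs), read1 = r1, read2 = r2,
               qual1 = qual, qual2 = qual, stringsAsFactors = FALSE)
  })
}

#' Write simulated read pairs as paired gzipped FASTQ
#'
#' @param reads Read-pair table from [simulate_reads()] (optionally with
#'   an `amplicon_id` column used in read names).
#' @param prefix Output path prefix; files `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz` are written.
#' @return Invisibly, the two file paths.
#' @export
write_fastq_pairs <- function(reads, prefix) {
  ids <- if ("amplicon_id" %in% names(reads))
    paste0(reads$amplicon_id, "/", reads$pair_id) else paste0("pair", reads$pair_id)
  write_one <- function(seqs, quals, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(seqs, ids)),
      Biostrings::PhredQuality(quals))
    Biostrings::writeQualityScaledXStringSet(x, path, compress = TRUE)
  }
  p1 <- paste0(prefix, "_R1.fastq.gz"); p2 <- paste0(prefix, "_R2.fastq.gz")
  write_one(reads$read1, reads$qual1, p1)
  write_one(reads$read2, reads$qual2, p2)
  invisible(c(p1, p2))
}

# merge one read pair into a single sequence by best exact-scored
# overlap between read1 and revcomp(read2); returns NA when no overlap
# of at least min_overlap reaches min_identity
merge_read_pair <- function(read1, read2, min_overlap = 10L, min_identity = 0.9) {
  r2 <- revcomp(read2)
  n1 <- nchar(read1); n2 <- nchar(r2)
  best <- NULL; best_frac <- -1
  for (ov in seq(min(n1, n2), min_overlap)) {
    a <- substr(read1, n1 - ov + 1L, n1)
    b <- substr(r2, 1L, ov)
    eq <- sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    frac <- eq / ov
    if (frac >= min_identity && frac > best_frac) {
      best_frac <- frac
      best <- paste0(read1, substr(r2, ov + 1L, n2))
    }
  }
  if (is.null(best)) NA_character_ else best
}

#' Derive expected amplicon sequence variants (ASVs)
#'
#' Collapses identical sequences into ASVs by exact dereplication (the
#' package's stand-in for error-model denoising). Provenance is the
#' multiset union of the source species of the collapsed inputs; ASVs
#' with read support below `min_support` are dropped and ids are
#' assigned in decreasing support, then lexicographic sequence order.
#'
#' @param x For mode `"dereplicate-amplicons"`: an amplicon table from
#'   [amplify_db()]. For mode `"dereplicate-merged-reads"`: a read-pair
#'   table carrying `read1`/`read2` plus the five lineage rank columns
#'   per pair (pairs failing overlap-merging are dropped with a
#'   warning).
#' @param mode Dereplication mode.
#' @param min_support Minimum read support per ASV (default 1).
#' @return An ASV table: data.frame with columns `asv_id`, `sequence`,
#'   `support` and a list-column `provenance` holding one lineage
#'   data.frame (rows = source species occurrences) per ASV.
#' @export
derive_asvs <- function(x, mode = c("dereplicate-amplicons",
                                    "dereplicate-merged-reads"),
                        min_support = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0L) stop("no input sequences to dereplicate", call. = FALSE)
  if (mode == "dereplicate-amplicons") {
    seqs <- x$sequence
  } else {
    seqs <- vapply(seq_len(nrow(x)),
                   function(i) merge_read_pair(x$read1[i], x$read2[i]),
                   character(1))
    bad <- is.na(seqs)
    if (any(bad)) {
      warning(sum(bad), " read pair(s) could not be merged and were dropped",
              call. = FALSE)
      x <- x[!bad, , drop = FALSE]; seqs <- seqs[!bad]
    }
    if (length(seqs) == 0L) stop("no mergeable read pairs", call. = FALSE)
  }
  groups <- split(seq_along(seqs), seqs)
  asvs <- data.frame(sequence = names(groups),
                     support = lengths(groups), stringsAsFactors = FALSE)
  asvs$provenance <- lapply(groups, function(idx) {
    prov <- x[idx, TAX_RANKS, drop = FALSE]
    rownames(prov) <- NULL
    prov
  })
  asvs <- asvs[asvs$support >= min_support, , drop = FALSE]
  asvs <- asvs[order(-asvs$support, asvs$sequence), , drop = FALSE]
  if (nrow(asvs) > 0L)
    asvs <- cbind(data.frame(asv_id = sprintf("ASV_%d", seq_len(nrow(asvs))),
                             stringsAsFactors = FALSE), asvs)
  else asvs <- cbind(data.frame(asv_id = character(), stringsAsFactors = FALSE),
                     asvs)
  rownames(asvs) <- NULL
  asvs
}

#' Write ASVs as FASTA plus provenance TSV
#'
#' @param asvs ASV table from [derive_asvs()].
#' @param fasta Output FASTA path.
#' @param provenance_tsv Output TSV path
#'   (`asv_id<TAB>support<TAB>species list`).
#' @return Invisibly, the two paths.
#' @export
write_asvs <- function(asvs, fasta, provenance_tsv) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(asvs$sequence, asvs$asv_id)), fasta)
  prov <- vapply(asvs$provenance, function(p)
    paste(p$species, collapse = ";"), character(1))
  writeLines(paste(asvs$asv_id, asvs$support, prov, sep = "\t"), provenance_tsv)
  invisible(c(fasta, provenance_tsv))
}
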