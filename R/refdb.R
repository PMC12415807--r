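# Marker reference databases: construction, I/O, mislabel detection and
# clade-exclusion variants.

#' Construct a marker reference database
#'
#' @param marker Marker name (e.g. `"12S"`, `"16S"`, `"COI"`).
#' @param sequences Named character vector of nucleotide sequences
#'   (names = unique sequence ids, alphabet ACGTN/IUPAC).
#' @param taxonomy A `taxonomy_table` ([build_taxonomy()]) covering every
#'   sequence id; every lineage must carry a family.
#' @return An object of class `reference_db` with elements `marker`,
#'   `sequences` and `taxonomy` (restricted to the held sequences, in
#'   sequence order).
#' @export
reference_db <- function(marker, sequences, taxonomy) {
  stopifnot(is_nonempty_string(marker), is.character(sequences))
  if (length(sequences) == 0L) stop("reference database is empty", call. = FALSE)
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("sequences must be named by sequence id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (any(!nzchar(sequences)))
    stop("empty sequence(s): ", paste(ids[!nzchar(sequences)], collapse = ", "),
         call. = FALSE)
  missing <- setdiff(ids, taxonomy$seqid)
  if (length(missing))
    stop("no lineage for sequence(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  taxonomy <- taxonomy[match(ids, taxonomy$seqid), , drop = FALSE]
  rownames(taxonomy) <- NULL
  if (anyNA(taxonomy$family))
    stop("lineage(s) without family", call. = FALSE)
  structure(list(marker = marker,
                 sequences = toupper(sequences),
                 taxonomy = taxonomy),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db '%s': %d sequences, %d families, %d species\n",
              x$marker, length(x$sequences), length(db_families(x)),
              length(unique(stats::na.omit(x$taxonomy$species)))))
  invisible(x)
}

#' @export
length.reference_db <- function(x) length(x$sequences)

#' Families present in a reference database
#'
#' @param db A `reference_db`.
#' @return Sorted character vector of family names.
#' @export
db_families <- function(db) sort(unique(db$taxonomy$family))

#' Subset a reference database by sequence id
#'
#' @param db A `reference_db`.
#' @param ids Sequence ids to keep.
#' @return A `reference_db` with only those records (byte-identical
#'   sequences and lineages).
#' @export
db_subset <- function(db, ids) {
  keep <- intersect(names(db$sequences), ids)
  if (length(keep) == 0L) stop("subset removes every record", call. = FALSE)
  reference_db(db$marker, db$sequences[keep],
               db$taxonomy[db$taxonomy$seqid %in% keep, , drop = FALSE])
}

#' Read a reference database from FASTA + lineage TSV
#'
#' FASTA headers are taken as sequence ids (first whitespace-delimited
#' token); lineages come from the TSV dialect of [read_lineage_tsv()].
#'
#' @param fasta Path to the reference FASTA.
#' @param lineage_tsv Path to the lineage TSV.
#' @param marker Marker name.
#' @return A `reference_db`.
#' @export
read_reference_db <- function(fasta, lineage_tsv, marker) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  reference_db(marker, setNames(as.character(seqs), names(seqs)),
               read_lineage_tsv(lineage_tsv))
}

#' Write a reference database to FASTA + lineage TSV
#'
#' @param db A `reference_db`.
#' @param fasta Output FASTA path.
#' @param lineage_tsv Output lineage TSV path.
#' @return Invisibly, `db`.
#' @export
write_reference_db <- function(db, fasta, lineage_tsv) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(db$sequences), fasta)
  write_lineage_tsv(db$taxonomy, lineage_tsv)
  invisible(db)
}

#' Detect mislabelled reference sequences
#'
#' Self-comparison screen for entries whose sequence is near-identical to
#' records of a different family. Every record is aligned (end-gap-free,
#' see [align_semiglobal()]) against all others; subjects with identity
#' strictly above `min_identity` and query coverage at least
#' `min_query_coverage` are retained. If the lowest common ancestor of
#' the query plus retained subjects is shallower than family, the
#' families in the conflict set are tallied and every sequence of the
#' minority family within that set is flagged. A tie between family
#' counts flags nothing and raises a warning (deleting on a tie risks
#' removing correct data).
#'
#' @param db A `reference_db` with at least two records.
#' @param min_identity Identity threshold, exclusive (default 0.97:
#'   subjects above 97% identity participate).
#' @param min_query_coverage Minimum fraction of the query covered by
#'   the alignment (default 1.0 = full coverage).
#' @return A data.frame with columns `seqid`, `family` and `reason`,
#'   deduplicated and sorted by id. Zero rows when nothing is flagged.
#' @export
detect_mislabels <- function(db, min_identity = 0.97, min_query_coverage = 1.0) {
  stopifnot(inherits(db, "reference_db"))
  if (length(db$sequences) < 2L)
    stop("mislabel detection needs at least two records", call. = FALSE)
  ids <- names(db$sequences)
  fams <- setNames(db$taxonomy$family, db$taxonomy$seqid)
  flagged <- list()
  for (i in seq_along(ids)) {
    qid <- ids[i]
    hits <- align_to_db(db$sequences[[qid]],
                        db$sequences[setdiff(ids, qid)],
                        both_strands = FALSE)
    hits <- hits[hits$identity > min_identity &
                   hits$coverage >= min_query_coverage, , drop = FALSE]
    if (nrow(hits) == 0L) next
    set_ids <- c(qid, hits$subject_id)
    set_lca <- lca(lapply(set_ids, taxonomy_lineage, taxonomy = db$taxonomy))
    if (!is.na(set_lca["family"])) next       # agreement at family or deeper
    counts <- sort(table(fams[set_ids]))
    if (length(counts) >= 2L && counts[1] == counts[2]) {
      warning("family vote tie for conflict set around '", qid,
              "'; nothing flagged", call. = FALSE)
      next
    }
    minority <- names(counts)[1]
    bad <- sort(set_ids[fams[set_ids] == minority])
    for (b in bad)
      flagged[[b]] <- data.frame(
        seqid = b, family = minority,
        reason = sprintf("family '%s' outvoted %d:%d in conflict set of %d sequences",
                         minority, as.integer(counts[length(counts)]),
                         as.integer(counts[1]), length(set_ids)),
        stringsAsFactors = FALSE)
  }
  if (length(flagged) == 0L)
    return(data.frame(seqid = character(), family = character(),
                      reason = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, flagged[sort(names(flagged))])
  rownames(out) <- NULL
  out
}

#' Plan a family-level clade exclusion
#'
#' Picks `round(fraction * n_families)` families (nearest integer, half
#' away from zero, at least 1 when `fraction > 0`) uniformly at random
#' from the database's families. The choice is a pure function of
#' `(db, fraction, seed, replicate)`: each `(seed, replicate)` pair
#' derives its own named pseudorandom stream, so plans are reproducible
#' and independent of the caller's RNG state.
#'
#' @param db A `reference_db`.
#' @param fraction Fraction of families to exclude, in `[0, 1]`.
#' @param seed Integer seed for the exclusion design.
#' @param replicate Replicate index (1-based).
#' @return An `exclusion_plan`: list with `fraction`, `seed`,
#'   `replicate` and `excluded` (sorted family names; empty when
#'   `fraction == 0`).
#' @export
plan_exclusion <- function(db, fraction, seed, replicate = 1L) {
  stopifnot(inherits(db, "reference_db"))
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  fams <- db_families(db)
  n_excl <- if (fraction == 0) 0L else
    max(1L, min(length(fams), as.integer(round_half_up(fraction * length(fams)))))
  excluded <- if (n_excl == 0L) character(0) else
    sort(with_rng(hash_seed(seed, replicate, "exclude"),
                  sample(fams, n_excl)))
  structure(list(fraction = fraction, seed = as.integer(seed),
                 replicate = as.integer(replicate), excluded = excluded),
            class = "exclusion_plan")
}

#' Apply an exclusion plan to a reference database
#'
#' @param db A `reference_db`.
#' @param plan An `exclusion_plan` whose excluded families are all
#'   present in `db`.
#' @return A `reference_db` with every record of the excluded families
#'   removed (records retained are byte-identical to the parent's).
#' @export
apply_exclusion <- function(db, plan) {
  stopifnot(inherits(plan, "exclusion_plan"))
  stray <- setdiff(plan$excluded, db_families(db))
  if (length(stray))
    stop("plan excludes families absent from the database: ",
         paste(stray, collapse = ", "), call. = FALSE)
  if (length(plan$excluded) == 0L) return(db)
  keep <- db$taxonomy$seqid[!(db$taxonomy$family %in% plan$excluded)]
  if (length(keep) == 0L)
    stop("exclusion plan removes every record", call. = FALSE)
  db_subset(db, keep)
}

#' Exclude a random fraction of families from a reference database
#'
#' Convenience wrapper around [plan_exclusion()] + [apply_exclusion()].
#' Whole families are always removed together: no record of an excluded
#' family survives, and no family is partially removed.
#'
#' @inheritParams plan_exclusion
#' @return A list with elements `db` (the reduced `reference_db`) and
#'   `plan` (the `exclusion_plan`).
#' @examples
#' \dontrun{
#' res <- exclude_families(db, fraction = 0.3, seed = 42, replicate = 1)
#' db_families(res$db)  # 70% of the parent's families
#' }
#' @export
exclude_families <- function(db, fraction, seed, replicate = 1L) {
  plan <- plan_exclusion(db, fraction, seed, replicate)
  list(db = apply_exclusion(db, plan), plan = plan)
}

#' Plan a full exclusion design
#'
#' Builds the full grid of exclusion plans for a benchmark: every listed
#' fraction, each repeated `replicates` times with its own random family
#' draw (the default design is 30%, 50% and 70% of families, 10
#' replicates each, for 30 exclusion databases).
#'
#' @param db A `reference_db`.
#' @param fractions Numeric vector of family fractions to exclude.
#' @param replicates Number of random replicates per fraction.
#' @param seed Integer seed for the whole design.
#' @return A list of `exclusion_plan`s of length
#'   `length(fractions) * replicates`, ordered by fraction then
#'   replicate.
#' @export
plan_exclusions <- function(db, fractions = c(0.3, 0.5, 0.7), replicates = 10L,
                            seed = 1L) {
  stopifnot(replicates >= 1L)
  plans <- list()
  for (f in fractions)
    for (r in seq_len(replicates))
      plans[[length(plans) + 1L]] <- plan_exclusion(db, f, seed, r)
  plans
}

#' Serialize an exclusion plan to JSON
#'
#' @param plan An `exclusion_plan`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
write_exclusion_plan <- function(plan, path = NULL) {
  js <- jsonlite::toJSON(unclass(plan), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read an exclusion plan from JSON
#'
#' @param path Path to a JSON file written by [write_exclusion_plan()].
#' @return An `exclusion_plan`.
#' @export
read_exclusion_plan <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(fraction = x$fraction, seed = as.integer(x$seed),
                 replicate = as.integer(x$replicate),
                 excluded = as.character(x$excluded %||% character(0))),
            class = "exclusion_plan")
}
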