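# Classification results, top-hit + LCA classification, and adapters
# for external classifier output.

# canonical prediction row; lineage may be an eb_lineage or NULL (empty
# prediction)
prediction_row <- function(asv_id, lin, confidence, classifier) {
  if (is.null(lin)) lin <- lineage()
  data.frame(asv_id = asv_id, rank = lineage_rank(lin),
             t(unclass(lin)[TAX_RANKS]),
             confidence = confidence, classifier = classifier,
             stringsAsFactors = FALSE)
}

empty_predictions <- function() {
  cbind(data.frame(asv_id = character(), rank = character(),
                   stringsAsFactors = FALSE),
        as.data.frame(setNames(rep(list(character()), 5), TAX_RANKS)),
        data.frame(confidence = numeric(), classifier = character(),
                   stringsAsFactors = FALSE))
}

#' Top-hit + LCA classification of ASVs
#'
#' Aligns each ASV (both orientations) against every reference record
#' with the end-gap-free aligner, retains hits with identity at least
#' `min_identity` and query coverage at least `min_coverage`, and
#' predicts the lowest common ancestor of the retained hits' lineages.
#' No qualifying hit yields an empty prediction. Confidence is the best
#' retained identity. `min_identity = 0.97` reproduces the lenient
#' "canonical" metabarcoding configuration; `min_identity = 1` is the
#' stringent exact-match configuration.
#'
#' @param asvs ASV table from [derive_asvs()], or any data.frame with
#'   `asv_id` and `sequence` columns.
#' @param db A non-empty `reference_db`.
#' @param min_identity Identity threshold, inclusive (default 0.97).
#' @param min_coverage Query-coverage threshold, inclusive (default 1).
#' @return A predictions table: one row per ASV with columns `asv_id`,
#'   `rank`, the five lineage rank columns (all `NA` for an empty
#'   prediction), `confidence` and `classifier`.
#' @export
tophit_lca_classify <- function(asvs, db, min_identity = 0.97,
                                min_coverage = 1.0) {
  stopifnot(inherits(db, "reference_db"), is.data.frame(asvs),
            all(c("asv_id", "sequence") %in% names(asvs)))
  name <- sprintf("tophit_lca(id=%.2f,cov=%.2f)", min_identity, min_coverage)
  if (nrow(asvs) == 0L) return(empty_predictions())
  rows <- lapply(seq_len(nrow(asvs)), function(i) {
    hits <- align_to_db(asvs$sequence[i], db$sequences, both_strands = TRUE)
    hits <- hits[hits$identity >= min_identity &
                   hits$coverage >= min_coverage, , drop = FALSE]
    if (nrow(hits) == 0L)
      return(prediction_row(asvs$asv_id[i], NULL, NA_real_, name))
    lin <- lca(lapply(hits$subject_id, taxonomy_lineage, taxonomy = db$taxonomy))
    prediction_row(asvs$asv_id[i], lin, max(hits$identity), name)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parse and score external classifier output
#'
#' Adapts the two common output shapes of third-party classifiers so
#' their predictions can be scored with [score_predictions()] without
#' re-implementing the tools.
#'
#' * `"tabular-hits"`: a 12-column tab-separated hit table
#'   (`qseqid sseqid pident length mismatch gapopen qstart qend sstart
#'   send evalue bitscore`). Hits are filtered by identity, e-value and
#'   query coverage and reduced per query to the lowest common ancestor
#'   of the passing subjects' lineages, exactly as
#'   [tophit_lca_classify()]. Computing query coverage requires the
#'   query lengths (the format does not carry them), supplied via
#'   `query_lengths`.
#' * `"per-read-taxa"`: lines `read_id<TAB>taxon`. Each reported taxon
#'   name is mapped to a lineage by matching, in order, the species,
#'   genus and family names of the reference taxonomy; the prediction
#'   is truncated at the matched rank.
#'
#' Records naming an unknown subject or taxon are skipped with a
#' warning and counted in the parse report.
#'
#' @param path Path to the predictions file.
#' @param dialect `"tabular-hits"` or `"per-read-taxa"`.
#' @param db A `reference_db` supplying subject/taxon lineages.
#' @param min_identity,min_coverage Filters for the tabular dialect.
#' @param max_evalue E-value pass-through threshold for the tabular
#'   dialect (default 1e-5).
#' @param query_lengths Named numeric vector of query lengths (tabular
#'   dialect; required when `min_coverage > 0`).
#' @param classifier Name recorded in the output rows.
#' @return A predictions table (see [tophit_lca_classify()]) with a
#'   `parse_report` attribute: list with `n_rows`, `n_used`,
#'   `n_skipped`.
#' @export
parse_external <- function(path, dialect = c("tabular-hits", "per-read-taxa"),
                           db, min_identity = 0.97, min_coverage = 1.0,
                           max_evalue = 1e-5, query_lengths = NULL,
                           classifier = "external") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(db, "reference_db"))
  empty <- empty_predictions()
  attr(empty, "parse_report") <- list(n_rows = 0L, n_used = 0L, n_skipped = 0L)
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0L) return(empty)
  if (dialect == "tabular-hits") {
    cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
    raw <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                      quote = "", comment.char = "#", col.names = cols)
    if (nrow(raw) == 0L) return(empty)
    if (min_coverage > 0 && is.null(query_lengths))
      stop("query_lengths is required to apply a coverage filter to ",
           "tabular hits (the 12-column format has no query-length field)",
           call. = FALSE)
    known <- raw$sseqid %in% db$taxonomy$seqid
    if (any(!known))
      warning(sum(!known), " hit(s) with unknown subject id skipped",
              call. = FALSE)
    n_skipped <- sum(!known)
    raw <- raw[known, , drop = FALSE]
    raw$qcov <- if (is.null(query_lengths)) 1 else
      (raw$qend - raw$qstart + 1) / as.numeric(query_lengths[raw$qseqid])
    pass <- raw$pident / 100 >= min_identity & raw$evalue <= max_evalue &
      !is.na(raw$qcov) & raw$qcov >= min_coverage
    used <- raw[pass, , drop = FALSE]
    rows <- lapply(split(used, used$qseqid), function(h) {
      lin <- lca(lapply(h$sseqid, taxonomy_lineage, taxonomy = db$taxonomy))
      prediction_row(h$qseqid[1], lin, max(h$pident) / 100, classifier)
    })
    out <- if (length(rows)) do.call(rbind, rows) else empty_predictions()
    rownames(out) <- NULL
    attr(out, "parse_report") <- list(n_rows = nrow(raw) + n_skipped,
                                      n_used = nrow(used),
                                      n_skipped = n_skipped)
    return(out)
  }
  # per-read-taxa
  raw <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "#",
                    col.names = c("read_id", "taxon"), colClasses = "character")
  if (nrow(raw) == 0L) return(empty)
  tax <- db$taxonomy
  map_taxon <- function(taxon) {
    for (rank in c("species", "genus", "family")) {
      hit <- match(taxon, tax[[rank]])
      if (!is.na(hit))
        return(truncate_lineage(row_to_lineage(tax[hit, ]), rank))
    }
    NULL
  }
  n_skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(raw))) {
    lin <- map_taxon(raw$taxon[i])
    if (is.null(lin)) { n_skipped <- n_skipped + 1L; next }
    rows[[length(rows) + 1L]] <-
      prediction_row(raw$read_id[i], lin, NA_real_, classifier)
  }
  if (n_skipped > 0L)
    warning(n_skipped, " record(s) with unknown taxon skipped", call. = FALSE)
  out <- if (length(rows)) do.call(rbind, rows) else empty_predictions()
  rownames(out) <- NULL
  attr(out, "parse_report") <- list(n_rows = nrow(raw),
                                    n_used = nrow(raw) - n_skipped,
                                    n_skipped = n_skipped)
  out
}

#' Write a predictions table as TSV
#'
#' Columns: `asv_id<TAB>rank<TAB>lineage<TAB>confidence<TAB>classifier`.
#'
#' @param predictions Predictions table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_predictions_tsv <- function(predictions, path) {
  strings <- vapply(seq_len(nrow(predictions)), function(i)
    format_lineage(row_to_lineage(predictions[i, ])), character(1))
  writeLines(c("#asv_id\trank\tlineage\tconfidence\tclassifier",
               paste(predictions$asv_id, predictions$rank, strings,
                     format(predictions$confidence, digits = 6),
                     predictions$classifier, sep = "\t")),
             path)
  invisible(path)
}
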