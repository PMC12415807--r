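# Ground-truth labels for simulated ASVs.
#
# Truth is a function of simulation provenance only: it derives from the
# source sequences of the query community, never from the classifier's
# reference database, which is what makes clade-exclusion tests
# meaningful (excluding families from the reference cannot change what
# the right answer is).

#' Assign ground-truth labels to ASVs from provenance
#'
#' For each ASV, the set of distinct source species in its provenance is
#' examined. A single source species yields an unambiguous species-level
#' truth label. When distinct species contributed literally identical
#' amplicons, no species-level truth exists: the label is the lowest
#' common ancestor of the provenance lineages and the ASV is marked
#' species-ambiguous.
#'
#' @param asvs ASV table from [derive_asvs()] (requires the `provenance`
#'   list-column; every ASV must have non-empty provenance).
#' @return A truth table: data.frame with columns `asv_id`, `rank`
#'   (deepest unambiguous rank, `"none"` when even class disagrees), the
#'   five lineage rank columns truncated at that rank, `ambiguous`
#'   (logical, `TRUE` iff the deepest rank is shallower than species)
#'   and `sources` (distinct source species, `;`-joined).
#' @export
assign_truth <- function(asvs) {
  stopifnot(is.data.frame(asvs), "provenance" %in% names(asvs))
  if (nrow(asvs) == 0L)
    return(empty_truth_table())
  rows <- lapply(seq_len(nrow(asvs)), function(i) {
    prov <- asvs$provenance[[i]]
    if (is.null(prov) || nrow(prov) == 0L)
      stop("ASV '", asvs$asv_id[i], "' has empty provenance", call. = FALSE)
    lins <- lapply(seq_len(nrow(prov)), function(j) row_to_lineage(prov[j, ]))
    species <- unique(prov$species)
    if (length(species) == 1L && !is.na(species)) {
      label <- lins[[1]]
    } else {
      # identical amplicon from >1 species: no species-level truth; the
      # lca is necessarily shallower than species
      label <- lca(lins)
    }
    data.frame(asv_id = asvs$asv_id[i], rank = lineage_rank(label),
               t(unclass(label)[TAX_RANKS]),
               ambiguous = lineage_rank(label) != "species",
               sources = paste(sort(species), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_truth_table <- function() {
  cbind(data.frame(asv_id = character(), rank = character(),
                   stringsAsFactors = FALSE),
        as.data.frame(setNames(rep(list(character()), 5), TAX_RANKS)),
        data.frame(ambiguous = logical(), sources = character(),
                   stringsAsFactors = FALSE))
}

#' Write a truth table as TSV
#'
#' Columns: `asv_id<TAB>truth_rank<TAB>lineage<TAB>ambiguous<TAB>sources`.
#'
#' @param truth Truth table from [assign_truth()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_tsv <- function(truth, path) {
  strings <- vapply(seq_len(nrow(truth)), function(i)
    format_lineage(row_to_lineage(truth[i, ])), character(1))
  writeLines(c("#asv_id\trank\tlineage\tambiguous\tsources",
               paste(truth$asv_id, truth$rank, strings,
                     tolower(truth$ambiguous), truth$sources, sep = "\t")),
             path)
  invisible(path)
}

#' Read a truth table from TSV
#'
#' @param path Path written by [write_truth_tsv()].
#' @return A truth table as from [assign_truth()].
#' @export
read_truth_tsv <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "",
                    col.names = c("asv_id", "rank", "lineage", "ambiguous",
                                  "sources"),
                    colClasses = "character")
  if (nrow(raw) == 0L) return(empty_truth_table())
  lins <- lineages_to_frame(lapply(raw$lineage, parse_lineage))
  cbind(data.frame(asv_id = raw$asv_id, rank = raw$rank,
                   stringsAsFactors = FALSE),
        lins,
        data.frame(ambiguous = raw$ambiguous == "true",
                   sources = raw$sources, stringsAsFactors = FALSE))
}
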