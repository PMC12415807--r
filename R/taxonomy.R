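# Ranked lineages and lowest-common-ancestor queries.
#
# A lineage is a named character vector over the canonical ranks
# (class, order, family, genus, species), ordered shallow to deep.
# Ranks below the truncation depth are NA; no "holes" are allowed
# (a named deeper rank implies all shallower ranks are named).

#' Canonical taxonomic ranks, shallowest first
#'
#' The package evaluates classifications at species, genus and family
#' level and excludes reference data at family level, so lineages carry
#' exactly these five ranks; deeper or shallower ranks in input data are
#' ignored.
#'
#' @format Character vector of rank names, shallowest first.
#' @export
TAX_RANKS <- c("class", "order", "family", "genus", "species")

#' Construct a lineage
#'
#' @param class,order,family,genus,species Taxon names (character
#'   scalars) or `NA` for ranks below the truncation depth.
#' @return A named character vector of length 5 with class `"eb_lineage"`.
#' @examples
#' lineage(class = "Actinopteri", order = "Perciformes",
#'         family = "Lutjanidae", genus = "Lutjanus",
#'         species = "Lutjanus jocu")
#' @export
lineage <- function(class = NA, order = NA, family = NA, genus = NA,
                    species = NA) {
  x <- c(class = as.character(class), order = as.character(order),
         family = as.character(family), genus = as.character(genus),
         species = as.character(species))
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  validate_lineage(x)
  structure(x, class = "eb_lineage")
}

validate_lineage <- function(x) {
  stopifnot(identical(names(x), TAX_RANKS))
  named <- !is.na(x)
  if (any(named)) {
    deepest <- max(which(named))
    gaps <- which(!named[seq_len(deepest)])
    if (length(gaps))
      stop("lineage has a gap: rank '", TAX_RANKS[gaps[1]],
           "' is missing but a deeper rank is named", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.eb_lineage <- function(x, ...) {
  cat(format_lineage(x), "\n")
  invisible(x)
}

#' Depth of a lineage
#'
#' @param x A lineage.
#' @return Integer depth: 0 for an empty lineage, 5 for a full
#'   species-level lineage.
#' @export
lineage_depth <- function(x) {
  named <- which(!is.na(unclass(x)[TAX_RANKS]))
  if (length(named) == 0L) 0L else max(named)
}

#' Deepest named rank of a lineage
#'
#' @param x A lineage.
#' @return Rank name, or `"none"` for an empty lineage.
#' @export
lineage_rank <- function(x) {
  d <- lineage_depth(x)
  if (d == 0L) "none" else TAX_RANKS[d]
}

#' Truncate a lineage at a rank
#'
#' @param x A lineage.
#' @param rank One of [TAX_RANKS] or `"none"`.
#' @return The lineage with all ranks deeper than `rank` set to `NA`.
#' @export
truncate_lineage <- function(x, rank) {
  if (identical(rank, "none")) keep <- 0L
  else keep <- match(match.arg(rank, TAX_RANKS), TAX_RANKS)
  y <- unclass(x)[TAX_RANKS]
  if (keep < length(TAX_RANKS)) y[seq_along(y) > keep] <- NA_character_
  structure(y, class = "eb_lineage")
}

#' Format a lineage as a delimited string
#'
#' @param x A lineage.
#' @param sep Field separator.
#' @param dialect `"deepest-last"` writes class;order;...;species.
#' @return A character scalar; `NA` ranks render as empty fields.
#' @export
format_lineage <- function(x, sep = ";", dialect = c("deepest-last", "deepest-first")) {
  dialect <- match.arg(dialect)
  v <- unclass(x)[TAX_RANKS]
  v[is.na(v)] <- ""
  if (dialect == "deepest-first") v <- rev(v)
  paste(v, collapse = sep)
}

#' Parse a rank-delimited lineage string
#'
#' @param string Lineage string with 5 fields (class to species); empty
#'   fields denote missing ranks.
#' @param dialect Whether the deepest rank comes last (default) or first.
#' @param sep Field separator.
#' @return A [lineage()].
#' @export
parse_lineage <- function(string, dialect = c("deepest-last", "deepest-first"),
                          sep = ";") {
  dialect <- match.arg(dialect)
  # sentinel keeps trailing empty fields (truncated deep ranks)
  fields <- strsplit(paste0(string, sep, "\x01"), sep, fixed = TRUE)[[1]]
  fields <- trimws(fields[-length(fields)])
  if (length(fields) != length(TAX_RANKS))
    stop("lineage string must have ", length(TAX_RANKS), " fields, got ",
         length(fields), ": '", string, "'", call. = FALSE)
  if (dialect == "deepest-first") fields <- rev(fields)
  fields[!nzchar(fields)] <- NA_character_
  lineage(fields[1], fields[2], fields[3], fields[4], fields[5])
}

# data.frame row (class..species columns) -> lineage
row_to_lineage <- function(row) {
  structure(setNames(as.character(unlist(row[TAX_RANKS])), TAX_RANKS),
            class = "eb_lineage")
}

# list of lineages -> data.frame with one column per rank
lineages_to_frame <- function(lins) {
  as.data.frame(do.call(rbind, lapply(lins, function(l) unclass(l)[TAX_RANKS])),
                stringsAsFactors = FALSE)
}

#' Lowest common ancestor of a set of lineages
#'
#' Returns the input lineages' deepest shared taxon: ranks are compared
#' by name from shallowest to deepest and the result is truncated at the
#' first rank where the inputs disagree (or where any input is itself
#' truncated). With a single input the lineage is returned unchanged.
#'
#' @param lineages Non-empty list of [lineage()] objects.
#' @return A lineage truncated at the deepest rank on which all inputs
#'   agree (possibly empty).
#' @examples
#' a <- lineage("Actinopteri", "Perciformes", "Lutjanidae", "Lutjanus",
#'              "Lutjanus argentimaculatus")
#' b <- lineage("Actinopteri", "Perciformes", "Lutjanidae", "Lutjanus",
#'              "Lutjanus jocu")
#' lca(list(a, b))  # truncated at genus Lutjanus
#' @export
lca <- function(lineages) {
  if (!is.list(lineages) || length(lineages) == 0L)
    stop("lca() requires a non-empty list of lineages", call. = FALSE)
  mat <- do.call(rbind, lapply(lineages, function(l) unclass(l)[TAX_RANKS]))
  out <- rep(NA_character_, length(TAX_RANKS))
  for (r in seq_along(TAX_RANKS)) {
    col <- mat[, r]
    if (anyNA(col) || length(unique(col)) != 1L) break
    out[r] <- col[1]
  }
  structure(setNames(out, TAX_RANKS), class = "eb_lineage")
}

#' Build a taxonomy table from sequence-id / lineage-string rows
#'
#' @param rows A data.frame with columns `seqid` and `lineage` (a
#'   rank-delimited string), or a named character vector of lineage
#'   strings (names = sequence ids).
#' @param dialect Lineage string dialect, see [parse_lineage()].
#' @param sep Field separator inside lineage strings.
#' @return A `taxonomy_table`: a data.frame with columns `seqid` and one
#'   column per canonical rank. Every row is guaranteed to carry a
#'   non-empty family.
#' @details Rows lacking a family, rows with malformed lineage strings,
#'   and duplicated sequence ids raise errors naming the offending row.
#' @export
build_taxonomy <- function(rows, dialect = c("deepest-last", "deepest-first"),
                           sep = ";") {
  dialect <- match.arg(dialect)
  if (is.character(rows))
    rows <- data.frame(seqid = names(rows), lineage = unname(rows),
                       stringsAsFactors = FALSE)
  stopifnot(is.data.frame(rows), all(c("seqid", "lineage") %in% names(rows)))
  if (nrow(rows) == 0L) stop("no taxonomy rows supplied", call. = FALSE)
  dup <- rows$seqid[duplicated(rows$seqid)]
  if (length(dup))
    stop("duplicate sequence ids in taxonomy: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  lins <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    lin <- tryCatch(parse_lineage(rows$lineage[i], dialect = dialect, sep = sep),
                    error = function(e)
                      stop("row '", rows$seqid[i], "': ", conditionMessage(e),
                           call. = FALSE))
    if (is.na(lin["family"]))
      stop("row '", rows$seqid[i], "' has no family rank", call. = FALSE)
    lins[[i]] <- lin
  }
  out <- cbind(data.frame(seqid = rows$seqid, stringsAsFactors = FALSE),
               lineages_to_frame(lins))
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

#' Family index of a taxonomy table
#'
#' @param taxonomy A `taxonomy_table` (see [build_taxonomy()]).
#' @return Named list mapping family name to the character vector of
#'   sequence ids in that family.
#' @export
family_index <- function(taxonomy) {
  stopifnot(is.data.frame(taxonomy), all(c("seqid", "family") %in% names(taxonomy)))
  split(taxonomy$seqid, taxonomy$family)
}

# lineage of one seqid from a taxonomy table
taxonomy_lineage <- function(taxonomy, seqid) {
  i <- match(seqid, taxonomy$seqid)
  if (is.na(i)) stop("unknown sequence id: ", seqid, call. = FALSE)
  row_to_lineage(taxonomy[i, ])
}

#' Read a lineage TSV
#'
#' Expected format: `seqid<TAB>class;order;family;genus;species`
#' (deepest-last), UTF-8, `#` comment lines allowed.
#'
#' @param path File path.
#' @param dialect Lineage string dialect.
#' @return A `taxonomy_table`.
#' @export
read_lineage_tsv <- function(path, dialect = "deepest-last") {
  raw <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "", col.names = c("seqid", "lineage"),
                    colClasses = "character")
  build_taxonomy(raw, dialect = dialect)
}

#' Write a lineage TSV
#'
#' @param taxonomy A `taxonomy_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lineage_tsv <- function(taxonomy, path) {
  strings <- vapply(seq_len(nrow(taxonomy)), function(i)
    format_lineage(row_to_lineage(taxonomy[i, ])), character(1))
  writeLines(paste(taxonomy$seqid, strings, sep = "\t"), path)
  invisible(path)
}
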