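# Shared pairwise alignment core.
#
# All identity/coverage filtering in the package runs through an
# end-gap-free (overlap) alignment with unit scores: match +1,
# mismatch -1, gap -1 per gapped column. Identity is
# matches / aligned columns with internal gaps counted as mismatching
# columns; query coverage is aligned query bases / query length.

unit_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

#' Semi-global (overlap) pairwise alignment
#'
#' End-gap-free alignment of two nucleotide sequences under unit costs
#' (match +1, mismatch -1, gap -1). End gaps are free, so the alignment
#' may cover only an overlap of the two sequences.
#'
#' @param query,subject Non-empty nucleotide strings.
#' @return A list with `identity` (matches / aligned columns, internal
#'   gaps counted as mismatching columns), `coverage` (aligned query
#'   bases / query length), `score` (alignment score) and `columns`
#'   (aligned column count).
#' @examples
#' align_semiglobal("ACGTACGT", "ACGTACGT")$identity  # 1
#' @export
align_semiglobal <- function(query, subject) {
  if (!is_nonempty_string(query) || !is_nonempty_string(subject))
    stop("query and subject must be non-empty strings", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(subject),
    type = "overlap", substitutionMatrix = unit_submat(),
    gapOpening = 0, gapExtension = 1)
  cols <- Biostrings::nchar(aln)
  pat <- Biostrings::pattern(aln)
  qspan <- BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L
  list(identity = if (cols > 0) Biostrings::nmatch(aln) / cols else 0,
       coverage = qspan / nchar(query),
       score = BiocGenerics::score(aln),
       columns = as.integer(cols))
}

# Vectorised one-query-vs-many alignment used by mislabel detection and
# top-hit classification. Returns one row per subject (best strand when
# both_strands). Coverage is of the query.
align_to_db <- function(query, subjects, both_strands = TRUE) {
  stopifnot(is_nonempty_string(query), length(subjects) >= 1L)
  subj_set <- Biostrings::DNAStringSet(subjects)
  score_pass <- function(q) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = subj_set, subject = Biostrings::DNAString(q),
      type = "overlap", substitutionMatrix = unit_submat(),
      gapOpening = 0, gapExtension = 1)
    cols <- Biostrings::nchar(aln)
    sub <- Biostrings::subject(aln)   # the query side
    qspan <- BiocGenerics::end(sub) - BiocGenerics::start(sub) + 1L
    data.frame(subject_id = names(subjects),
               identity = ifelse(cols > 0, Biostrings::nmatch(aln) / cols, 0),
               coverage = qspan / nchar(q),
               score = BiocGenerics::score(aln),
               strand = "+", stringsAsFactors = FALSE)
  }
  fwd <- score_pass(query)
  if (!both_strands) return(fwd)
  rev <- score_pass(revcomp(query))
  rev$strand <- "-"
  better <- rev$score > fwd$score
  fwd[better, ] <- rev[better, ]
  fwd
}
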