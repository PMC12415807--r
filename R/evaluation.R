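# Species-level scoring of predictions against simulation ground truth.
#
# Confusion definitions (evaluated at species level):
#   TP - truth has a species and the classifier predicts that species;
#   FP - the classifier predicts a species different from the truth, or
#        predicts any species where the ASV is species-ambiguous;
#   TN - the ASV is species-ambiguous and the classifier predicts no
#        species;
#   FN - truth has a species but the classifier predicts no species.
# Every scored ASV falls in exactly one of the four cells.

#' Score predictions against ground truth
#'
#' Joins truth and predictions by `asv_id` and applies the species-level
#' confusion rules above. In the default `"strict"` mode a species
#' prediction on a species-ambiguous ASV is a false positive even when
#' the predicted species is one of the colliding sources (no true
#' species label exists, so any species claim is unfounded); the
#' `"lenient"` mode scores such calls as true positives for sensitivity
#' analysis.
#'
#' @param truth Truth table from [assign_truth()].
#' @param predictions Predictions table (built-in classifiers or
#'   [parse_external()]); must cover exactly the same `asv_id` set.
#' @param mode `"strict"` (default) or `"lenient"`, see above.
#' @return A list with `counts` (named integer vector `tp`, `fp`, `tn`,
#'   `fn`) and `verdicts` (per-ASV table with the verdict plus logical
#'   `genus_match`/`family_match` columns recording agreement of the
#'   prediction with the truth lineage at those ranks).
#' @export
score_predictions <- function(truth, predictions, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(truth), is.data.frame(predictions))
  orphan_t <- setdiff(truth$asv_id, predictions$asv_id)
  orphan_p <- setdiff(predictions$asv_id, truth$asv_id)
  if (length(orphan_t) || length(orphan_p))
    stop("truth/prediction id mismatch; missing predictions for [",
         paste(orphan_t, collapse = ", "), "], missing truth for [",
         paste(orphan_p, collapse = ", "), "]", call. = FALSE)
  if (anyDuplicated(truth$asv_id) || anyDuplicated(predictions$asv_id))
    stop("duplicate asv ids", call. = FALSE)
  p <- predictions[match(truth$asv_id, predictions$asv_id), , drop = FALSE]
  verdict <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    t_sp <- truth$species[i]
    p_sp <- p$species[i]
    verdict[i] <-
      if (!is.na(p_sp)) {
        if (!is.na(t_sp) && p_sp == t_sp) "TP"
        else if (mode == "lenient" && is.na(t_sp) &&
                 p_sp %in% strsplit(truth$sources[i] %||% "", ";")[[1]]) "TP"
        else "FP"
      } else {
        if (is.na(t_sp)) "TN" else "FN"
      }
  }
  verdicts <- data.frame(
    asv_id = truth$asv_id,
    truth_rank = truth$rank,
    truth_species = truth$species,
    truth_genus = truth$genus,
    truth_family = truth$family,
    pred_species = p$species,
    pred_genus = p$genus,
    pred_family = p$family,
    confidence = p$confidence,
    classifier = p$classifier,
    verdict = verdict,
    genus_match = !is.na(p$genus) & !is.na(truth$genus) &
      p$genus == truth$genus,
    family_match = !is.na(p$family) & !is.na(truth$family) &
      p$family == truth$family,
    stringsAsFactors = FALSE)
  counts <- c(tp = sum(verdict == "TP"), fp = sum(verdict == "FP"),
              tn = sum(verdict == "TN"), fn = sum(verdict == "FN"))
  list(counts = counts, verdicts = verdicts)
}

#' Compute evaluation metrics from confusion counts
#'
#' Accuracy `(TN+TP)/(TN+TP+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, `F1 = 2PR/(P+R)` and
#' `F0.5 = (1+0.5^2) P R / (0.5^2 P + R)` (F-score weighting precision
#' over recall). Any 0/0 yields `NA` (the undefined marker), never an
#' error.
#'
#' @param counts Named numeric vector with elements `tp`, `fp`, `tn`,
#'   `fn` (as from [score_predictions()]), not all zero.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`,
#'   `f0.5` with `NA` for undefined values.
#' @examples
#' compute_metrics(c(tp = 3, fp = 1, tn = 4, fn = 2))
#' @export
compute_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  counts <- counts[c("tp", "fp", "tn", "fn")]
  if (any(counts < 0) || anyNA(counts))
    stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_ else
    safe_div(2 * precision * recall, precision + recall)
  f05 <- if (is.na(precision) || is.na(recall)) NA_real_ else
    safe_div((1 + 0.5^2) * precision * recall, 0.5^2 * precision + recall)
  c(accuracy = (tn + tp) / total, precision = precision, recall = recall,
    f1 = f1, f0.5 = f05)
}

#' Hierarchical breakdown of classification outcomes
#'
#' Buckets every scored ASV by how deep the prediction agrees with the
#' truth lineage: correct species; wrong species but correct genus;
#' wrong genus but correct family; wrong family; or unassigned (no
#' species-level prediction). Buckets are disjoint and sum to the ASV
#' count.
#'
#' @param verdicts Verdict table from [score_predictions()].
#' @return Named integer vector over the five buckets.
#' @export
hierarchical_breakdown <- function(verdicts) {
  stopifnot(is.data.frame(verdicts),
            all(c("pred_species", "truth_species", "genus_match",
                  "family_match") %in% names(verdicts)))
  bucket <- character(nrow(verdicts))
  for (i in seq_len(nrow(verdicts))) {
    ps <- verdicts$pred_species[i]
    ts <- verdicts$truth_species[i]
    bucket[i] <-
      if (is.na(ps)) "unassigned"
      else if (!is.na(ts) && ps == ts) "correct_species"
      else if (verdicts$genus_match[i]) "wrong_species_correct_genus"
      else if (verdicts$family_match[i]) "wrong_genus_correct_family"
      else "wrong_family"
  }
  levels <- c("correct_species", "wrong_species_correct_genus",
              "wrong_genus_correct_family", "wrong_family", "unassigned")
  out <- table(factor(bucket, levels = levels))
  setNames(as.integer(out), levels)
}

#' Species richness of predictions
#'
#' Counts the distinct species names predicted at species rank,
#' optionally grouped (e.g. by classifier, exclusion fraction and
#' replicate), and - when a truth table is supplied - how many of those
#' species never occur in the truth (false-positive species).
#'
#' @param predictions Predictions table, or a table with grouping
#'   columns added.
#' @param group_by Character vector of grouping column names (default
#'   none: one overall row).
#' @param truth Optional truth table from [assign_truth()]; its species
#'   labels and ambiguous-source lists define the set of species that
#'   were actually simulated.
#' @return data.frame with the grouping columns, `richness` and (when
#'   `truth` is given) `false_positive_species`.
#' @export
species_richness <- function(predictions, group_by = character(0),
                             truth = NULL) {
  stopifnot(is.data.frame(predictions))
  truth_species <- if (is.null(truth)) NULL else
    unique(c(stats::na.omit(truth$species),
             unlist(strsplit(truth$sources[nzchar(truth$sources)], ";"))))
  one_group <- function(df) {
    sp <- unique(stats::na.omit(df$species))
    row <- data.frame(richness = length(sp))
    if (!is.null(truth_species))
      row$false_positive_species <- sum(!(sp %in% truth_species))
    row
  }
  if (length(group_by) == 0L) return(one_group(predictions))
  keys <- predictions[, group_by, drop = FALSE]
  groups <- split(predictions, keys, drop = TRUE)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    cbind(groups[[g]][1, group_by, drop = FALSE], one_group(groups[[g]]))
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate metric sets across replicates
#'
#' Reports the median (plus min and max) of each metric across replicate
#' runs; undefined (`NA`) values are excluded from the aggregation and
#' counted.
#'
#' @param metric_rows data.frame whose rows are [compute_metrics()]
#'   outputs (one per replicate), plus any id columns.
#' @param metrics Metric column names to aggregate.
#' @return data.frame with one row per metric: `metric`, `median`,
#'   `min`, `max`, `n`, `n_undefined`.
#' @export
aggregate_metrics <- function(metric_rows,
                              metrics = c("accuracy", "precision", "recall",
                                          "f1", "f0.5")) {
  stopifnot(is.data.frame(metric_rows))
  metrics <- intersect(metrics, names(metric_rows))
  out <- lapply(metrics, function(m) {
    v <- metric_rows[[m]]
    ok <- !is.na(v)
    data.frame(metric = m,
               median = if (any(ok)) stats::median(v[ok]) else NA_real_,
               min = if (any(ok)) min(v[ok]) else NA_real_,
               max = if (any(ok)) max(v[ok]) else NA_real_,
               n = sum(ok), n_undefined = sum(!ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
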