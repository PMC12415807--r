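mk_truth <- function(ids, species, ambiguous = rep(FALSE, length(ids)),
                     genus = "Lut", family = "FamA", sources = species) {
  data.frame(asv_id = ids, rank = ifelse(ambiguous, "genus", "species"),
             class = "C", order = "O", family = family, genus = genus,
             species = ifelse(ambiguous, NA_character_, species),
             ambiguous = ambiguous,
             sources = sources, stringsAsFactors = FALSE)
}

mk_pred <- function(ids, species, genus = "Lut", family = "FamA") {
  data.frame(asv_id = ids, rank = ifelse(is.na(species), "none", "species"),
             class = "C", order = "O",
             family = ifelse(is.na(species), NA_character_, family),
             genus = ifelse(is.na(species), NA_character_, genus),
             species = species, confidence = 0.99, classifier = "test",
             stringsAsFactors = FALSE)
}

test_that("the four confusion rules fire on their defining cases", {
  truth <- mk_truth(c("a", "b", "c", "d"),
                    c("Lutjanus argentimaculatus", "Lutjanus argentimaculatus",
                      NA, "Lutjanus argentimaculatus"),
                    ambiguous = c(FALSE, FALSE, TRUE, FALSE),
                    sources = c(rep("Lutjanus argentimaculatus", 2),
                                "Lutjanus argentimaculatus;Lutjanus jocu",
                                "Lutjanus argentimaculatus"))
  pred <- mk_pred(c("a", "b", "c", "d"),
                  c("Lutjanus argentimaculatus",   # agrees -> TP
                    "Lutjanus jocu",               # different species -> FP
                    NA,                            # ambiguous, no call -> TN
                    NA))                           # possible, no call -> FN
  sc <- score_predictions(truth, pred)
  expect_equal(sc$counts, c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  expect_equal(sc$verdicts$verdict, c("TP", "FP", "TN", "FN"))
})

test_that("species calls on ambiguous ASVs are FP strictly, TP leniently", {
  truth <- mk_truth("x", NA, ambiguous = TRUE,
                    sources = "Lutjanus argentimaculatus;Lutjanus jocu")
  pred <- mk_pred("x", "Lutjanus jocu")
  expect_equal(score_predictions(truth, pred)$counts[["fp"]], 1L)
  expect_equal(score_predictions(truth, pred, mode = "lenient")$counts[["tp"]],
               1L)
  # a species outside the colliding sources stays FP even leniently
  pred2 <- mk_pred("x", "Pagrus auratus")
  expect_equal(score_predictions(truth, pred2, mode = "lenient")$counts[["fp"]],
               1L)
})

test_that("every ASV lands in exactly one confusion cell", {
  set.seed(90)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    ids <- sprintf("a%d", seq_len(n))
    amb <- runif(n) < 0.3
    truth <- mk_truth(ids, ifelse(amb, NA, sprintf("Sp %d", seq_len(n))),
                      ambiguous = amb)
    pick <- sample(c(NA, "Sp 1", "Sp 2"), n, replace = TRUE)
    pred <- mk_pred(ids, pick)
    sc <- score_predictions(truth, pred)
    expect_equal(sum(sc$counts), n)
    expect_true(all(table(sc$verdicts$verdict) >= 0))
  }
})

test_that("id mismatches error listing the orphans", {
  truth <- mk_truth(c("a", "b"), c("X y", "X z"))
  pred <- mk_pred(c("a", "c"), c("X y", "X z"))
  expect_error(score_predictions(truth, pred), "b.*c")
})

test_that("metric formulas match hand evaluation", {
  m <- compute_metrics(c(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(m[["accuracy"]], 0.7)
  expect_equal(m[["precision"]], 0.75)
  expect_equal(m[["recall"]], 0.6)
  expect_equal(m[["f1"]], 2 * 0.75 * 0.6 / (0.75 + 0.6))
  expect_equal(m[["f0.5"]], 1.25 * 0.75 * 0.6 / (0.25 * 0.75 + 0.6))
  # perfect classifier
  expect_equal(unname(compute_metrics(c(tp = 9, fp = 0, tn = 0, fn = 0))),
               rep(1, 5))
})

test_that("degenerate denominators yield NA markers, never errors", {
  m <- compute_metrics(c(tp = 0, fp = 2, tn = 1, fn = 0))
  expect_equal(m[["precision"]], 0)
  expect_true(is.na(m[["recall"]]))
  expect_true(is.na(m[["f1"]]))
  m2 <- compute_metrics(c(tp = 0, fp = 0, tn = 3, fn = 0))
  expect_true(is.na(m2[["precision"]]))
  expect_equal(m2[["accuracy"]], 1)
  expect_error(compute_metrics(c(tp = 0, fp = 0, tn = 0, fn = 0)), "zero")
})

test_that("metrics agree with direct formula evaluation on a random grid", {
  set.seed(91)
  for (rep in 1:1000) {
    c4 <- as.numeric(rbinom(4, 30, 0.4))
    if (sum(c4) == 0) c4[1] <- 1
    counts <- c(tp = c4[1], fp = c4[2], tn = c4[3], fn = c4[4])
    m <- compute_metrics(counts)
    tp <- c4[1]; fp <- c4[2]; tn <- c4[3]; fn <- c4[4]
    expect_equal(m[["accuracy"]], (tn + tp) / (tn + tp + fp + fn))
    p <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    r <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    expect_equal(m[["precision"]], p)
    expect_equal(m[["recall"]], r)
    if (!is.na(p) && !is.na(r) && p + r > 0) {
      expect_equal(m[["f1"]], 2 * p * r / (p + r))
      expect_equal(m[["f0.5"]], (1 + 0.25) * p * r / (0.25 * p + r))
      # identities: F1 below the larger of P/R; F0.5 favours precision
      expect_lte(m[["f1"]], max(p, r) + 1e-12)
      if (p > r) expect_gt(m[["f0.5"]], m[["f1"]])
    }
  }
})

test_that("hierarchical breakdown recovers a planted 2/1/1/1/1 design", {
  truth <- mk_truth(sprintf("a%d", 1:6),
                    c("Lut one", "Lut one", "Lut two", "Lut tre", "Lut qua",
                      "Lut qui"))
  pred <- data.frame(
    asv_id = sprintf("a%d", 1:6),
    rank = c("species", "species", "species", "species", "species", "none"),
    class = "C", order = "O",
    family = c("FamA", "FamA", "FamA", "FamA", "FamB", NA),
    genus = c("Lut", "Lut", "Lut", "Spa", "Ger", NA),
    species = c("Lut one", "Lut one", "Lut nine", "Spa eight", "Ger seven",
                NA),
    confidence = 1, classifier = "test", stringsAsFactors = FALSE)
  bd <- hierarchical_breakdown(score_predictions(truth, pred)$verdicts)
  expect_equal(unname(bd), c(2L, 1L, 1L, 1L, 1L))
  expect_equal(sum(bd), 6)
  # all-correct collapses into a single bucket
  pred_ok <- mk_pred(truth$asv_id, truth$species)
  bd_ok <- hierarchical_breakdown(score_predictions(truth, pred_ok)$verdicts)
  expect_equal(unname(bd_ok["correct_species"]), 6L)
  expect_equal(sum(bd_ok), 6)
})

test_that("species richness counts distinct species and false-positive species", {
  pred <- mk_pred(c("a", "b", "c"), c("Sp A", "Sp A", "Sp B"))
  expect_equal(species_richness(pred)$richness, 2)
  expect_equal(species_richness(mk_pred("a", NA))$richness, 0)
  truth <- mk_truth(c("a", "b", "c"), c("Sp A", "Sp A", "Sp A"))
  pred2 <- mk_pred(c("a", "b", "c"), c("Sp A", "Ghost one", "Ghost two"))
  r <- species_richness(pred2, truth = truth)
  expect_equal(r$richness, 3)
  expect_equal(r$false_positive_species, 2)
  # grouped by classifier
  pred2$classifier <- c("x", "x", "y")
  rg <- species_richness(pred2, group_by = "classifier", truth = truth)
  expect_equal(sort(rg$richness), c(1, 2))
})

test_that("replicate aggregation reports medians and excludes NA", {
  rows <- data.frame(f1 = c(0.5, 0.7, NA, 0.6), precision = c(1, 1, 1, NA))
  agg <- aggregate_metrics(rows, metrics = c("f1", "precision"))
  expect_equal(agg$median[agg$metric == "f1"], 0.6)
  expect_equal(agg$n_undefined[agg$metric == "f1"], 1)
  expect_equal(agg$median[agg$metric == "precision"], 1)
})
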