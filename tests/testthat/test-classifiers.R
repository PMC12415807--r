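test_that("alignment identity and coverage behave on exact and near matches", {
  set.seed(70)
  s <- rand_seq(100)
  perfect <- align_semiglobal(s, s)
  expect_equal(perfect$identity, 1.0)
  expect_equal(perfect$coverage, 1.0)
  one_off <- paste0(substr(s, 1, 49),
                    setdiff(c("A", "C", "G", "T"), substr(s, 50, 50))[1],
                    substr(s, 51, 100))
  expect_equal(align_semiglobal(s, one_off)$identity, 0.99)
  expect_error(align_semiglobal("", s), "non-empty")
})

test_that("alignment matches the full-DP oracle on mutated 60-nt pairs", {
  set.seed(71)
  for (rep in 1:50) {
    a <- rand_seq(60)
    b <- strsplit(a, "")[[1]]
    nmut <- sample(0:5, 1)
    pos <- sample(60, nmut)
    for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
    b <- paste(b, collapse = "")
    got <- align_semiglobal(a, b)
    want <- oracle_overlap_align(a, b)
    expect_equal(got$score, want$score)
    expect_equal(got$identity, want$identity)
    expect_equal(got$coverage, want$coverage)
  }
})

test_that("alignment scores match the DP oracle on fully random pairs", {
  set.seed(72)
  for (rep in 1:20) {
    a <- rand_seq(sample(40:70, 1)); b <- rand_seq(sample(40:70, 1))
    expect_equal(align_semiglobal(a, b)$score, oracle_overlap_align(a, b)$score)
  }
})

test_that("top-hit LCA resolves exact, congeneric and absent matches", {
  set.seed(73)
  sp1 <- rand_seq(150)
  # congener 2 nt away from sp1
  sp2 <- sp1
  substr(sp2, 10, 10) <- setdiff(c("A","C","G","T"), substr(sp1, 10, 10))[1]
  substr(sp2, 80, 80) <- setdiff(c("A","C","G","T"), substr(sp1, 80, 80))[1]
  outlier <- rand_seq(150)
  db <- quick_db(c("r1", "r2", "r3"), c(sp1, sp2, outlier),
                 c(lin_str("C", "O", "FamA", "Lut", "Lut one"),
                   lin_str("C", "O", "FamA", "Lut", "Lut two"),
                   lin_str("C", "O", "FamB", "Spa", "Spa three")))
  q <- data.frame(asv_id = "q1", sequence = sp1, stringsAsFactors = FALSE)
  # exact single-species hit at 100%
  hit100 <- tophit_lca_classify(q, db, min_identity = 1.0)
  expect_equal(hit100$rank, "species")
  expect_equal(hit100$species, "Lut one")
  # at 97% both congeners hit -> LCA backs off to genus
  hit97 <- tophit_lca_classify(q, db, min_identity = 0.97)
  expect_equal(hit97$rank, "genus")
  expect_equal(hit97$genus, "Lut")
  expect_true(is.na(hit97$species))
  # a query below the threshold stays unassigned
  far <- data.frame(asv_id = "q2", sequence = rand_seq(150))
  expect_equal(tophit_lca_classify(far, db, min_identity = 0.97)$rank, "none")
  # reverse-complement queries hit equally
  rcq <- data.frame(asv_id = "q3",
                    sequence = as.character(Biostrings::reverseComplement(
                      Biostrings::DNAString(sp1))))
  expect_equal(tophit_lca_classify(rcq, db, min_identity = 1.0)$species,
               "Lut one")
})

test_that("nbc separates divergent species and is confident on training data", {
  fx <- make_toy_refdb(fixture_spec(n_families = 3, genera_per_family = 1,
                                    species_per_genus = 2,
                                    seqs_per_species = 2, seed = 74))
  db <- fx$db
  model <- train_nbc(db, feature_dim = 2^14, seed = 75)
  queries <- data.frame(asv_id = names(db$sequences),
                        sequence = unname(db$sequences),
                        stringsAsFactors = FALSE)
  pred <- classify_nbc(model, queries, prob_cutoff = 0.97, seed = 75)
  truth_sp <- db$taxonomy$species
  expect_true(all(pred$rank == "species"))
  expect_true(all(pred$species == truth_sp))
  expect_true(all(pred$confidence > 0.97))
})

test_that("identical training sequences split the posterior and back off", {
  seqs <- c(a = strrep("ACGTTGCA", 20), b = strrep("ACGTTGCA", 20),
            c = paste(rep(c("TTGACCGA"), 20), collapse = ""))
  db <- quick_db(names(seqs), unname(seqs),
                 c(lin_str("C", "O", "FamA", "Lut", "Lut one"),
                   lin_str("C", "O", "FamA", "Lut", "Lut two"),
                   lin_str("C", "O", "FamB", "Spa", "Spa tre")))
  model <- train_nbc(db, k_range = c(6, 8), feature_dim = 2^12, seed = 76)
  q <- data.frame(asv_id = "q", sequence = seqs[["a"]])
  # raw posterior splits evenly between the twin species
  post <- classify_nbc(model, q, prob_cutoff = 0.97,
                       confidence = "posterior", seed = 76)
  expect_equal(post$rank, "genus")
  expect_equal(post$genus, "Lut")
  expect_gte(post$confidence, 0.97)
  # bootstrap agreement reaches the same genus-level backoff
  boot <- classify_nbc(model, q, prob_cutoff = 0.97, seed = 76)
  expect_equal(boot$rank, "genus")
  # strict abstention mode never backs off
  strict <- classify_nbc(model, q, prob_cutoff = 0.97, backoff = FALSE,
                         seed = 76)
  expect_equal(strict$rank, "none")
})

test_that("raising the cutoff never deepens a prediction", {
  fx <- make_toy_refdb(fixture_spec(n_families = 2, seed = 77))
  model <- train_nbc(fx$db, feature_dim = 2^14, seed = 78)
  noisy <- mutate_dna(setNames(fx$db$sequences[1], "q"), 0.08, seed = 79)
  q <- data.frame(asv_id = "q", sequence = unname(noisy))
  depth <- function(cutoff) {
    r <- classify_nbc(model, q, prob_cutoff = cutoff, seed = 80)$rank
    match(r, c("none", "class", "order", "family", "genus", "species"))
  }
  depths <- vapply(c(0.5, 0.8, 0.97, 1.0), depth, numeric(1))
  expect_true(all(diff(depths) <= 0))
  expect_equal(depth(1.0 + 1e-9), 1)  # cutoff above 1 can never be met
})

test_that("large smoothing with uniform priors flattens the posterior", {
  seqs <- c(a = strrep("ACGTTGCA", 10), b = strrep("TTGACCGA", 10))
  db <- quick_db(names(seqs), unname(seqs),
                 c(lin_str("C", "O", "FamA", "Ga", "Ga one"),
                   lin_str("C", "O", "FamB", "Gb", "Gb two")))
  model <- train_nbc(db, k_range = c(6, 6), feature_dim = 2^10,
                     alpha = 1e6, fit_prior = FALSE, seed = 81)
  q <- data.frame(asv_id = "q", sequence = seqs[["a"]])
  res <- classify_nbc(model, q, prob_cutoff = 0.97,
                      confidence = "posterior", seed = 81)
  expect_equal(res$rank, "none")
  expect_lt(res$confidence, 0.6)   # ~0.5 each
})

test_that("grid optimisation prefers the sane configuration and is reproducible", {
  fx <- make_toy_refdb(fixture_spec(n_families = 2, genera_per_family = 1,
                                    species_per_genus = 2,
                                    seqs_per_species = 3, seed = 82))
  grid <- data.frame(kmin = c(1, 8), kmax = c(1, 10), alpha = 0.01)
  w <- capture_warnings(
    res <- optimize_nbc(fx$db, grid, folds = 3, feature_dim = 2^12,
                        seed = 83, n_boot = 40))
  expect_equal(nrow(res$report), 2)
  expect_gt(res$report$mean_f1[2], res$report$mean_f1[1])
  expect_equal(res$model$k_range, c(8L, 10L))
  res2 <- suppressWarnings(
    optimize_nbc(fx$db, grid, folds = 3, feature_dim = 2^12, seed = 83,
                 n_boot = 40))
  expect_identical(res$report, res2$report)
  # single-point grids return that configuration
  one <- suppressWarnings(
    optimize_nbc(fx$db, grid[2, ], folds = 3, feature_dim = 2^12, seed = 83,
                 n_boot = 40))
  expect_equal(nrow(one$report), 1)
})

test_that("tabular hit files parse, filter and LCA-reduce like the built-in", {
  db <- quick_db(c("r1", "r2", "r3"),
                 c(rand_seq(100), rand_seq(100), rand_seq(100)),
                 c(lin_str("C", "O", "FamA", "Lut", "Lut one"),
                   lin_str("C", "O", "FamA", "Spa", "Spa two"),
                   lin_str("C", "O", "FamB", "Ger", "Ger tre")))
  path <- withr::local_tempfile(fileext = ".tsv")
  hit_row <- function(q, s, pid, qs, qe, ev)
    paste(q, s, pid, qe - qs + 1, 0, 0, qs, qe, 1, qe - qs + 1, ev, 200,
          sep = "\t")
  # q1: one passing hit; q2: two genera in one family -> family-level;
  # q3: unknown subject skipped; q4: fails e-value
  writeLines(c(hit_row("q1", "r1", 99.0, 1, 100, 1e-30),
               hit_row("q2", "r1", 98.0, 1, 100, 1e-30),
               hit_row("q2", "r2", 98.0, 1, 100, 1e-30),
               hit_row("q3", "nope", 99.0, 1, 100, 1e-30),
               hit_row("q4", "r3", 99.0, 1, 100, 1)), path)
  w <- capture_warnings(
    res <- parse_external(path, "tabular-hits", db,
                          query_lengths = c(q1 = 100, q2 = 100, q3 = 100,
                                            q4 = 100)))
  expect_true(any(grepl("unknown subject", w)))
  expect_equal(attr(res, "parse_report")$n_skipped, 1)
  expect_equal(res$species[res$asv_id == "q1"], "Lut one")
  q2 <- res[res$asv_id == "q2", ]
  expect_equal(q2$rank, "family")
  expect_equal(q2$family, "FamA")
  expect_false("q4" %in% res$asv_id)
  # coverage filtering needs query lengths
  expect_error(parse_external(path, "tabular-hits", db), "query_lengths")
  # empty files yield empty results with a zero-row report
  empty <- withr::local_tempfile(fileext = ".tsv"); file.create(empty)
  res0 <- parse_external(empty, "tabular-hits", db, query_lengths = c())
  expect_equal(nrow(res0), 0)
  expect_equal(attr(res0, "parse_report")$n_rows, 0)
})

test_that("per-read taxon files map names to lineages at the right rank", {
  db <- quick_db(c("r1", "r2"), c(rand_seq(80), rand_seq(80)),
                 c(lin_str("C", "O", "FamA", "Lut", "Lut one"),
                   lin_str("C", "O", "FamA", "Spa", "Spa two")))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("x1\tLut one", "x2\tSpa", "x3\tFamA", "x4\tUnknownium"), path)
  w <- capture_warnings(res <- parse_external(path, "per-read-taxa", db))
  expect_true(any(grepl("unknown taxon", w)))
  expect_equal(res$rank, c("species", "genus", "family"))
  expect_equal(attr(res, "parse_report")$n_skipped, 1)
})
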