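# Hashed k-mer multinomial naive Bayes classifier.
#
# Features are counts of all k-mers for k in [kmin, kmax], hashed into a
# fixed number of buckets (collisions are additive). The class model is
# a multinomial distribution with additive (Laplace) smoothing over the
# hashed buckets, one class per reference species. Confidence is, by
# default, a bootstrap agreement score over resampled query k-mers
# (see classify_nbc); the raw posterior is available as an alternative.

# hash every k-mer occurrence of `seq` (k in kmin..kmax) into 1..dim;
# windows containing non-ACGT characters are dropped
kmer_hashes <- function(seq, kmin, kmax, dim) {
  code <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES) - 1
  n <- length(code)
  out <- list()
  for (k in seq(kmin, kmax)) {
    if (n < k) next
    m <- n - k + 1L
    h <- rep(k %% dim, m)
    ok <- rep(TRUE, m)
    for (off in 0:(k - 1L)) {
      v <- code[(1L + off):(m + off)]
      ok <- ok & !is.na(v)
      v[is.na(v)] <- 0
      h <- (h * 131 + v) %% dim
    }
    out[[length(out) + 1L]] <- h[ok]
  }
  as.integer(unlist(out)) + 1L
}

#' Train the k-mer naive Bayes classifier
#'
#' Builds one multinomial class per reference species from hashed k-mer
#' counts pooled over that species' sequences, with additive smoothing
#' `alpha`. Priors are empirical sequence frequencies when
#' `fit_prior = TRUE`, uniform otherwise.
#'
#' @param db A `reference_db`; every species contributes at least one
#'   sequence.
#' @param k_range Integer vector `c(kmin, kmax)` of k-mer lengths
#'   (default `c(8, 12)`).
#' @param feature_dim Number of hash buckets (default `2^18`; collisions
#'   are accepted and additive).
#' @param alpha Additive smoothing constant (> 0, default 0.01).
#' @param fit_prior Use empirical class priors (default `TRUE`).
#' @param seed Integer seed recorded in the model and used to derive the
#'   default classification streams.
#' @return An `nbc_model`: list with the training parameters, `classes`
#'   (data.frame of species lineages), `log_prior` and `log_lik`
#'   (classes x buckets matrix of smoothed log-likelihoods).
#' @export
train_nbc <- function(db, k_range = c(8L, 12L), feature_dim = 2^18,
                      alpha = 0.01, fit_prior = TRUE, seed = 1L) {
  stopifnot(inherits(db, "reference_db"), length(k_range) == 2L)
  k_range <- as.integer(k_range)
  if (k_range[1] > k_range[2]) stop("kmin must be <= kmax", call. = FALSE)
  if (k_range[1] < 1L) stop("kmin must be >= 1", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  tax <- db$taxonomy
  if (anyNA(tax$species))
    stop("every reference record needs a species label to train on",
         call. = FALSE)
  species <- sort(unique(tax$species))
  classes <- tax[match(species, tax$species), TAX_RANKS, drop = FALSE]
  rownames(classes) <- NULL
  counts <- matrix(0, nrow = length(species), ncol = feature_dim)
  n_seqs <- integer(length(species))
  for (ci in seq_along(species)) {
    ids <- tax$seqid[tax$species == species[ci]]
    n_seqs[ci] <- length(ids)
    hs <- unlist(lapply(db$sequences[ids], kmer_hashes,
                        kmin = k_range[1], kmax = k_range[2],
                        dim = feature_dim))
    if (length(hs)) counts[ci, ] <- tabulate(hs, nbins = feature_dim)
  }
  log_lik <- log(counts + alpha) - log(rowSums(counts) + alpha * feature_dim)
  log_prior <- if (fit_prior) log(n_seqs / sum(n_seqs)) else
    rep(-log(length(species)), length(species))
  structure(list(k_range = k_range, feature_dim = feature_dim,
                 alpha = alpha, fit_prior = fit_prior, seed = as.integer(seed),
                 marker = db$marker, species = species, classes = classes,
                 n_seqs = n_seqs, log_prior = log_prior, log_lik = log_lik),
            class = "nbc_model")
}

#' @export
print.nbc_model <- function(x, ...) {
  cat(sprintf("nbc_model: %d species classes, k in [%d,%d], %d hash buckets, alpha=%g\n",
              length(x$species), x$k_range[1], x$k_range[2],
              x$feature_dim, x$alpha))
  invisible(x)
}

# species posteriors for one set of hashed k-mer indices
nbc_posterior <- function(model, idx) {
  z <- model$log_prior + as.vector(model$log_lik[, idx, drop = FALSE] %*%
                                     rep(1, length(idx)))
  z <- z - max(z)
  p <- exp(z)
  setNames(p / sum(p), model$species)
}

#' Classify ASVs with a trained naive Bayes model
#'
#' Computes species-level class support and predicts at the deepest rank
#' whose aggregate support reaches `prob_cutoff`: species first, then
#' (unless `backoff = FALSE`) genus and family by summing the support of
#' member species. If no rank qualifies the prediction is empty.
#'
#' Support is measured by `confidence`:
#' * `"bootstrap"` (default): the query's k-mers are resampled
#'   (`n_boot` draws of `boot_frac` of the k-mers, with replacement) and
#'   support is the fraction of bootstrap replicates won by the class
#'   (ties within a replicate broken at random). Genuine reference
#'   matches win every replicate; sequences with no consistent signal
#'   (e.g. random DNA) spread their wins and fall below the cutoff.
#' * `"posterior"`: the raw multinomial posterior probability. Raw
#'   posteriors of naive Bayes models are strongly overconfident on
#'   out-of-reference sequences, so this mode is mainly useful for
#'   studying exactly that failure mode.
#'
#' @param model An `nbc_model` from [train_nbc()].
#' @param asvs ASV table (or any data.frame with `asv_id` and
#'   `sequence`).
#' @param prob_cutoff Support cutoff in `[0, 1]` (default 0.97).
#' @param confidence Confidence measure, see above.
#' @param n_boot,boot_frac Bootstrap replicates and k-mer subsample
#'   fraction (defaults 100 and 1/8).
#' @param backoff Back off to genus/family when species support is below
#'   the cutoff (default `TRUE`); `FALSE` gives strict abstention.
#' @param seed Integer seed; per-ASV streams are derived from
#'   `(seed, asv_id)` so results do not depend on row order. Defaults to
#'   the model's training seed.
#' @return A predictions table (see [tophit_lca_classify()]).
#' @export
classify_nbc <- function(model, asvs, prob_cutoff = 0.97,
                         confidence = c("bootstrap", "posterior"),
                         n_boot = 100L, boot_frac = 0.125, backoff = TRUE,
                         seed = NULL) {
  stopifnot(inherits(model, "nbc_model"), is.data.frame(asvs),
            all(c("asv_id", "sequence") %in% names(asvs)))
  confidence <- match.arg(confidence)
  seed <- seed %||% model$seed
  name <- sprintf("nbc(k=%d-%d,cutoff=%.2f,%s)", model$k_range[1],
                  model$k_range[2], prob_cutoff, confidence)
  if (nrow(asvs) == 0L) return(empty_predictions())
  cls <- model$classes
  genus_key <- paste(cls$family, cls$genus)
  rows <- lapply(seq_len(nrow(asvs)), function(i) {
    idx <- kmer_hashes(asvs$sequence[i], model$k_range[1], model$k_range[2],
                       model$feature_dim)
    if (length(idx) == 0L)
      return(prediction_row(asvs$asv_id[i], NULL, NA_real_, name))
    support <- if (confidence == "posterior") nbc_posterior(model, idx) else
      with_rng(hash_seed(seed, asvs$asv_id[i], "nbc_boot"), {
        m <- length(idx)
        s <- max(1L, as.integer(round(m * boot_frac)))
        L <- model$log_lik[, idx, drop = FALSE]
        W <- matrix(vapply(seq_len(n_boot),
                           function(b) tabulate(sample.int(m, s, replace = TRUE), m),
                           numeric(m)),
                    nrow = m)
        scores <- L %*% W + model$log_prior       # classes x n_boot
        wins <- max.col(t(scores), ties.method = "random")
        setNames(tabulate(wins, nbins = length(model$species)) / n_boot,
                 model$species)
      })
    # species level
    if (max(support) >= prob_cutoff) {
      ci <- which.max(support)
      return(prediction_row(asvs$asv_id[i], row_to_lineage(cls[ci, ]),
                            unname(support[ci]), name))
    }
    if (backoff) {
      for (level in c("genus", "family")) {
        key <- if (level == "genus") genus_key else cls$family
        agg <- tapply(support, key, sum)
        if (max(agg) >= prob_cutoff) {
          members <- which(key == names(agg)[which.max(agg)])
          lin <- truncate_lineage(
            lca(lapply(members, function(j) row_to_lineage(cls[j, ]))), level)
          return(prediction_row(asvs$asv_id[i], lin,
                                unname(max(agg)), name))
        }
      }
    }
    prediction_row(asvs$asv_id[i], NULL, unname(max(support)), name)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hyperparameter optimisation for the naive Bayes classifier
#'
#' Stratified cross-validation over species: each species' sequences are
#' spread across `folds` folds; species with fewer sequences than folds
#' are held out of the CV with a warning (they still enter the final
#' model). Every grid point is scored by mean species-level F1 over the
#' folds (a held-out sequence counts TP when the predicted species
#' matches its label, FP when a different species is predicted, FN when
#' no species is predicted); the best point is refitted on the full
#' database. Ties prefer the smaller k-range width, then the larger
#' `alpha`.
#'
#' @param db A `reference_db`.
#' @param grid data.frame with columns `kmin`, `kmax`, `alpha` and
#'   optionally `fit_prior`.
#' @param folds Number of CV folds (>= 2, default 3).
#' @param feature_dim Hash buckets used for every grid point.
#' @param seed Integer seed (fold assignment and classification
#'   streams).
#' @param ... Further arguments passed to [classify_nbc()] during CV
#'   (e.g. `prob_cutoff`, `n_boot`).
#' @return List with `model` (the refitted best `nbc_model`) and
#'   `report` (the grid with a `mean_f1` column, in grid order).
#' @export
optimize_nbc <- function(db, grid, folds = 3L, feature_dim = 2^14, seed = 1L,
                         ...) {
  stopifnot(inherits(db, "reference_db"), is.data.frame(grid), nrow(grid) >= 1L,
            all(c("kmin", "kmax", "alpha") %in% names(grid)))
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (!"fit_prior" %in% names(grid)) grid$fit_prior <- TRUE
  tax <- db$taxonomy
  counts <- table(tax$species)
  cv_species <- names(counts)[counts >= folds]
  held_out <- setdiff(names(counts), cv_species)
  if (length(held_out))
    warning(length(held_out), " species with fewer than ", folds,
            " sequences held out of cross-validation: ",
            paste(held_out, collapse = ", "), call. = FALSE)
  if (length(cv_species) == 0L)
    stop("no species has enough sequences for ", folds, "-fold CV",
         call. = FALSE)
  fold_of <- with_rng(hash_seed(seed, "nbc_cv_folds"), {
    f <- setNames(integer(nrow(tax)), tax$seqid)
    for (sp in cv_species) {
      ids <- sample(tax$seqid[tax$species == sp])
      f[ids] <- rep_len(seq_len(folds), length(ids))
    }
    f
  })
  score_point <- function(g) {
    f1s <- numeric(folds)
    for (k in seq_len(folds)) {
      test_ids <- names(fold_of)[fold_of == k]
      train_ids <- setdiff(tax$seqid, test_ids)
      fit <- train_nbc(db_subset(db, train_ids),
                       k_range = c(g$kmin, g$kmax), feature_dim = feature_dim,
                       alpha = g$alpha, fit_prior = g$fit_prior,
                       seed = hash_seed(seed, "nbc_cv", k))
      queries <- data.frame(asv_id = test_ids,
                            sequence = unname(db$sequences[test_ids]),
                            stringsAsFactors = FALSE)
      pred <- classify_nbc(fit, queries, ...)
      truth_sp <- tax$species[match(test_ids, tax$seqid)]
      tp <- sum(!is.na(pred$species) & pred$species == truth_sp)
      fp <- sum(!is.na(pred$species) & pred$species != truth_sp)
      fn <- sum(is.na(pred$species))
      prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      f1s[k] <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
        2 * prec * rec / (prec + rec) else 0
    }
    mean(f1s)
  }
  grid$mean_f1 <- vapply(seq_len(nrow(grid)),
                         function(i) score_point(grid[i, ]), numeric(1))
  ord <- order(-grid$mean_f1, grid$kmax - grid$kmin, -grid$alpha)
  best <- grid[ord[1], ]
  model <- train_nbc(db, k_range = c(best$kmin, best$kmax),
                     feature_dim = feature_dim, alpha = best$alpha,
                     fit_prior = best$fit_prior, seed = seed)
  list(model = model, report = grid)
}
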