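# End-to-end benchmark orchestration: fixture/refdb -> exclusion -> PCR
# -> (reads) -> ASVs -> truth -> classify -> evaluate, over the full
# dataset x classifier x exclusion-plan grid. Execution is
# single-process and deterministic: cells run in sorted key order and
# every stage derives its own seed from the run seed, so identical
# configurations yield byte-identical outputs.

#' Build a benchmark run configuration
#'
#' @param outdir Output directory for the report bundle.
#' @param seed Master seed; every randomised stage derives a named
#'   stream from it.
#' @param fixture Named list of [fixture_spec()] arguments for the
#'   synthetic reference database (ignored when `refdb_fasta` is set).
#' @param refdb_fasta,refdb_lineage_tsv,marker Paths to a user-supplied
#'   reference database (FASTA + lineage TSV) instead of a fixture.
#' @param exclusion Named list: `fractions` (numeric vector),
#'   `replicates` (integer). The full database (fraction 0) is always
#'   evaluated in addition.
#' @param sim Named list of simulation parameters: `n_pairs`,
#'   `read_length`, `substitution_rate`, `base_quality`, `min_quality`,
#'   `simulate_reads` (logical: also emit FASTQ; ASVs always derive
#'   from dereplicated amplicons), `min_support`.
#' @param classifiers Character vector among `"tophit97"`, `"tophit100"`
#'   and `"nbc"`; may be empty (simulation and truth outputs only).
#' @param nbc Named list of naive Bayes parameters (`k_range`,
#'   `feature_dim`, `alpha`, `fit_prior`, `prob_cutoff`, `n_boot`).
#' @param eval_mode `"strict"` or `"lenient"`, see
#'   [score_predictions()].
#' @return A `run_config` list.
#' @export
run_config <- function(outdir = "ednabench_run", seed = 1L,
                       fixture = list(), refdb_fasta = NULL,
                       refdb_lineage_tsv = NULL, marker = "12S",
                       exclusion = list(fractions = c(0.3, 0.5, 0.7),
                                        replicates = 10L),
                       sim = list(), classifiers = c("tophit97", "tophit100"),
                       nbc = list(), eval_mode = "strict") {
  sim_defaults <- list(n_pairs = 500L, read_length = 130L,
                       substitution_rate = 0.001, base_quality = 35L,
                       min_quality = 0L, simulate_reads = FALSE,
                       min_support = 1L)
  nbc_defaults <- list(k_range = c(8L, 12L), feature_dim = 65536L,
                       alpha = 0.01, fit_prior = TRUE, prob_cutoff = 0.97,
                       n_boot = 100L)
  excl_defaults <- list(fractions = c(0.3, 0.5, 0.7), replicates = 10L)
  known <- c("tophit97", "tophit100", "nbc")
  if (!all(classifiers %in% known))
    stop("unknown classifier(s): ",
         paste(setdiff(classifiers, known), collapse = ", "), call. = FALSE)
  cfg <- list(
    outdir = outdir, seed = as.integer(seed), marker = marker,
    fixture = fixture,
    refdb_fasta = refdb_fasta, refdb_lineage_tsv = refdb_lineage_tsv,
    exclusion = utils::modifyList(excl_defaults, exclusion),
    sim = utils::modifyList(sim_defaults, sim),
    classifiers = as.character(classifiers),
    nbc = utils::modifyList(nbc_defaults, nbc),
    eval_mode = match.arg(eval_mode, c("strict", "lenient")))
  cfg$exclusion$replicates <- as.integer(cfg$exclusion$replicates)
  for (f in c("n_pairs", "read_length", "base_quality", "min_quality",
              "min_support"))
    cfg$sim[[f]] <- as.integer(cfg$sim[[f]])
  cfg$nbc$k_range <- as.integer(cfg$nbc$k_range)
  for (f in c("feature_dim", "n_boot")) cfg$nbc[[f]] <- as.integer(cfg$nbc[[f]])
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return A `run_config`; unknown keys raise an error. The
#'   serialisation round-trips: `write_run_config(read_run_config(p))`
#'   is byte-identical to a canonically written `p`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- c("outdir", "seed", "marker", "fixture", "refdb_fasta",
             "refdb_lineage_tsv", "exclusion", "sim", "classifiers", "nbc",
             "eval_mode")
  stray <- setdiff(names(x), known)
  if (length(stray))
    stop("unknown config key(s): ", paste(stray, collapse = ", "),
         call. = FALSE)
  do.call(run_config, x[intersect(known, names(x))])
}

#' Write a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}

benchmark_classifier <- function(name, db, cfg, cell_seed) {
  switch(name,
    tophit97 = function(asvs) tophit_lca_classify(asvs, db, min_identity = 0.97),
    tophit100 = function(asvs) tophit_lca_classify(asvs, db, min_identity = 1.0),
    nbc = {
      model <- train_nbc(db, k_range = cfg$nbc$k_range,
                         feature_dim = cfg$nbc$feature_dim,
                         alpha = cfg$nbc$alpha, fit_prior = cfg$nbc$fit_prior,
                         seed = cell_seed)
      function(asvs) classify_nbc(model, asvs,
                                  prob_cutoff = cfg$nbc$prob_cutoff,
                                  n_boot = cfg$nbc$n_boot, seed = cell_seed)
    },
    stop("unknown classifier: ", name, call. = FALSE))
}

#' Run a full benchmark
#'
#' Executes the whole pipeline described by a [run_config()]: builds or
#' loads the reference database, simulates the query community from the
#' full database (in-silico PCR, optional paired-end reads,
#' dereplicated ASVs, ground truth), then scores every configured
#' classifier against the full database and against every exclusion
#' plan. One metrics JSON is written per (classifier, plan) cell, plus
#' a combined `summary.tsv` and a `manifest.json` recording every seed
#' and parameter needed for exact re-execution. A failing cell is
#' logged and skipped; remaining cells still run.
#'
#' @param config A `run_config` (or a YAML path).
#' @return Invisibly, a list with `summary` (data.frame over cells),
#'   `truth`, `asvs`, `plans` and `failed` (character vector of failed
#'   cell keys).
#' @export
run_benchmark <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "cells"), showWarnings = FALSE)
  log_line <- function(stage, cell, msg)
    message(sprintf("[%s] %s %s", stage, cell, msg))

  # reference database
  if (!is.null(config$refdb_fasta)) {
    db <- read_reference_db(config$refdb_fasta, config$refdb_lineage_tsv,
                            config$marker)
    manifest_fixture <- NULL
    pr <- do.call(fixture_spec, config$fixture)$primer
  } else {
    fx_args <- config$fixture
    fx_args$seed <- fx_args$seed %||% hash_seed(config$seed, "fixture")
    config$fixture$seed <- fx_args$seed   # resolved seed into the manifest
    fx_args$marker <- config$marker
    spec <- do.call(fixture_spec, fx_args)
    fx <- make_toy_refdb(spec)
    db <- fx$db
    pr <- spec$primer
    manifest_fixture <- fx$manifest[c("mislabels", "ambiguous")]
    log_line("fixture", "-", sprintf("%d records, %d families",
                                     length(db$sequences),
                                     length(db_families(db))))
  }
  write_reference_db(db, file.path(outdir, "refdb.fasta"),
                     file.path(outdir, "lineage.tsv"))

  # query community from the full database
  amplicons <- amplify_db(db, pr)
  log_line("pcr", "-", sprintf("%d amplicons", nrow(amplicons)))
  write_amplicon_fasta(amplicons, file.path(outdir, "amplicons.fasta"))
  if (isTRUE(config$sim$simulate_reads)) {
    reads <- do.call(rbind, lapply(seq_len(nrow(amplicons)), function(i) {
      cbind(amplicon_id = amplicons$amplicon_id[i],
            simulate_reads(amplicons$sequence[i],
                           n_pairs = config$sim$n_pairs,
                           read_length = config$sim$read_length,
                           substitution_rate = config$sim$substitution_rate,
                           base_quality = config$sim$base_quality,
                           min_quality = config$sim$min_quality,
                           seed = hash_seed(config$seed, "reads", i)))
    }))
    write_fastq_pairs(reads, file.path(outdir, "reads"))
    log_line("simreads", "-", sprintf("%d pairs", nrow(reads)))
  }
  asvs <- derive_asvs(amplicons, mode = "dereplicate-amplicons",
                      min_support = config$sim$min_support)
  write_asvs(asvs, file.path(outdir, "asvs.fasta"),
             file.path(outdir, "asv_provenance.tsv"))
  truth <- assign_truth(asvs)
  write_truth_tsv(truth, file.path(outdir, "truth.tsv"))
  log_line("truth", "-", sprintf("%d ASVs, %d species-ambiguous",
                                 nrow(truth), sum(truth$ambiguous)))

  # exclusion plans: the full database plus the configured design
  plans <- c(list(plan_exclusion(db, 0, config$seed, 1L)),
             plan_exclusions(db, config$exclusion$fractions,
                             config$exclusion$replicates, config$seed))
  plan_key <- function(p) sprintf("f%02.0f_r%02d", p$fraction * 100, p$replicate)

  summary_rows <- list(); failed <- character(0)
  if (length(config$classifiers) > 0) {
    cells <- expand.grid(classifier = sort(config$classifiers),
                         plan = seq_along(plans), stringsAsFactors = FALSE)
    for (ci in seq_len(nrow(cells))) {
      cname <- cells$classifier[ci]
      plan <- plans[[cells$plan[ci]]]
      key <- paste(cname, plan_key(plan), sep = "_")
      res <- tryCatch({
        cell_db <- apply_exclusion(db, plan)
        cell_seed <- hash_seed(config$seed, "cell", key)
        clf <- benchmark_classifier(cname, cell_db, config, cell_seed)
        pred <- clf(asvs)
        sc <- score_predictions(truth, pred, mode = config$eval_mode)
        metrics <- compute_metrics(sc$counts)
        rich <- species_richness(pred, truth = truth)
        cell <- list(classifier = cname, fraction = plan$fraction,
                     replicate = plan$replicate,
                     excluded_families = plan$excluded,
                     counts = as.list(sc$counts),
                     metrics = as.list(metrics),
                     breakdown = as.list(hierarchical_breakdown(sc$verdicts)),
                     richness = as.list(rich))
        jsonlite::write_json(cell,
                             file.path(outdir, "cells", paste0(key, ".json")),
                             auto_unbox = TRUE, digits = NA, null = "null",
                             na = "null")
        cbind(data.frame(cell = key, classifier = cname,
                         fraction = plan$fraction, replicate = plan$replicate,
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(sc$counts)),
              as.data.frame(as.list(metrics), check.names = FALSE),
              rich)
      }, error = function(e) {
        log_line("cell", key, paste("FAILED:", conditionMessage(e)))
        NULL
      })
      if (is.null(res)) failed <- c(failed, key)
      else summary_rows[[key]] <- res
      log_line("evaluate", key, "done")
    }
  }
  summary <- if (length(summary_rows)) do.call(rbind, summary_rows) else
    data.frame()
  rownames(summary) <- NULL
  write.table(summary, file.path(outdir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  manifest <- list(config = unclass(config),
                   fixture = manifest_fixture,
                   plans = lapply(plans, unclass),
                   n_asvs = nrow(asvs), n_cells = length(summary_rows),
                   failed = failed)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(list(summary = summary, truth = truth, asvs = asvs,
                 plans = plans, failed = failed))
}
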