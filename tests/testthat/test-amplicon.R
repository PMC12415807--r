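toy_pr <- primer("t", "ACGTGACCTAGGCATTCG", "TCCGTAGGTGAACCTGCA",
                 max_mismatch = 0L, product_range = c(50L, 400L))

embed_template <- function(core, pr = toy_pr, flank = 15) {
  paste0(rand_seq(flank), pr$forward, core,
         as.character(Biostrings::reverseComplement(Biostrings::DNAString(pr$reverse))),
         rand_seq(flank))
}

test_that("amplify recovers an exactly embedded product with trimmed primers", {
  set.seed(11)
  core <- rand_seq(200)
  tmpl <- embed_template(core)
  amps <- amplify(tmpl, toy_pr)
  expect_equal(nrow(amps), 1)
  expect_equal(amps$sequence, core)
  expect_equal(amps$start, 15 + nchar(toy_pr$forward) + 1)
  expect_equal(amps$end, 15 + nchar(toy_pr$forward) + 200)
})

test_that("degenerate primer bases match compatible template bases", {
  set.seed(12)
  core <- rand_seq(100)
  # forward primer with R (A/G) over a template A
  pr <- primer("deg", "RCGTGACCTAGGCATTCG", "TCCGTAGGTGAACCTGCA",
               max_mismatch = 0L, product_range = c(50L, 400L))
  tmpl <- embed_template(core, toy_pr)  # template carries the A variant
  expect_equal(amplify(tmpl, pr)$sequence, core)
})

test_that("mismatch tolerance finds degraded primer sites", {
  set.seed(13)
  core <- rand_seq(120)
  tmpl <- embed_template(core)
  # one substitution inside the forward site
  pos <- 15 + 5
  bad <- paste0(substr(tmpl, 1, pos - 1),
                setdiff(c("A", "C", "G", "T"), substr(tmpl, pos, pos))[1],
                substr(tmpl, pos + 1, nchar(tmpl)))
  pr0 <- toy_pr
  expect_equal(nrow(amplify(bad, pr0)), 0)
  pr1 <- primer("t", pr0$forward, pr0$reverse, max_mismatch = 1L,
                product_range = pr0$product_range)
  expect_equal(amplify(bad, pr1)$sequence, core)
})

test_that("amplify agrees with the exhaustive window-scan oracle", {
  set.seed(14)
  pr <- primer("o", "ACGTRACCTAGG", "TCCGTAGGTGAC", max_mismatch = 2L,
               product_range = c(30L, 150L))
  for (rep in 1:100) {
    tmpl <- rand_seq(260)
    # plant a site pair in most templates so matches actually occur
    if (rep %% 3 != 0) {
      core <- rand_seq(sample(30:120, 1))
      tmpl <- paste0(substr(tmpl, 1, 20), "ACGTAACCTAGG", core,
                     oracle_revcomp("TCCGTAGGTGAC"),
                     substr(tmpl, 21, 80))
    }
    got <- sort(unique(amplify(tmpl, pr)$sequence))
    want <- oracle_amplify(tmpl, pr$forward, pr$reverse, pr$max_mismatch,
                           pr$product_range)
    expect_identical(got, want)
  }
})

test_that("amplify is strand-symmetric and monotone in mismatch tolerance", {
  set.seed(15)
  for (rep in 1:10) {
    core <- rand_seq(100)
    tmpl <- embed_template(core)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tmpl)))
    expect_setequal(amplify(tmpl, toy_pr)$sequence, amplify(rc, toy_pr)$sequence)
    pr2 <- primer("t", toy_pr$forward, toy_pr$reverse, max_mismatch = 3L,
                  product_range = toy_pr$product_range)
    expect_true(all(amplify(tmpl, toy_pr)$sequence %in%
                      amplify(tmpl, pr2)$sequence))
  }
})

test_that("select_representatives saturates, isolates and deduplicates", {
  set.seed(16)
  seqs <- c(a = rand_seq(80), b = rand_seq(80), c = rand_seq(80))
  expect_setequal(select_representatives(seqs, 5), names(seqs))
  # identical pair + one distant: n = 2 must take the distant one plus
  # exactly one of the twins (brute-force over all 2-subsets agrees)
  twin <- rand_seq(80); far <- rand_seq(80)
  trio <- c(A = twin, B = twin, C = far)
  got <- select_representatives(trio, 2, seed = 1)
  expect_true("C" %in% got)
  expect_length(intersect(got, c("A", "B")), 1)
  # n = 1 picks the sequence with maximal mean distance
  skew <- c(x = twin, y = twin, z = far)
  expect_equal(select_representatives(skew, 1, seed = 1), "z")
  expect_error(select_representatives(trio, 0), ">= 1")
})

test_that("error-free reads reconstruct both amplicon ends exactly", {
  set.seed(17)
  amp <- rand_seq(200)
  reads <- simulate_reads(amp, n_pairs = 10, read_length = 130,
                          substitution_rate = 0, seed = 4)
  expect_equal(nrow(reads), 10)
  expect_true(all(reads$read1 == substr(amp, 1, 130)))
  rc_tail <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(amp, 71, 200))))
  expect_true(all(reads$read2 == rc_tail))
  expect_true(all(nchar(reads$qual1) == 130))
})

test_that("read simulation defaults to 500 pairs per gene copy", {
  amp <- rand_seq(180)
  reads <- simulate_reads(amp, read_length = 130, substitution_rate = 0,
                          seed = 1)
  expect_equal(nrow(reads), 500)
})

test_that("substitution counts follow the configured rate", {
  set.seed(18)
  amp <- rand_seq(150)
  reads <- simulate_reads(amp, n_pairs = 34, read_length = 150,
                          substitution_rate = 0.01, seed = 9)
  nbases <- 34 * 150 * 2
  subs <- sum(vapply(seq_len(nrow(reads)), function(i) {
    sum(strsplit(reads$read1[i], "")[[1]] != strsplit(amp, "")[[1]][1:150]) +
      sum(strsplit(reads$read2[i], "")[[1]] !=
            strsplit(as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(amp))), "")[[1]][1:150])
  }, numeric(1)))
  # central 99% binomial interval around nbases * 0.01
  bounds <- qbinom(c(0.005, 0.995), nbases, 0.01)
  expect_gte(subs, bounds[1]); expect_lte(subs, bounds[2])
})

test_that("per-base substitution frequency converges at 1e5 bases (3 sigma)", {
  amp <- rand_seq(250)
  rate <- 0.02
  n_pairs <- 200  # 200 * 250 * 2 = 1e5 bases
  reads <- simulate_reads(amp, n_pairs = n_pairs, read_length = 250,
                          substitution_rate = rate, seed = 77)
  ref1 <- strsplit(amp, "")[[1]]
  ref2 <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(amp))), "")[[1]]
  subs <- sum(vapply(seq_len(n_pairs), function(i)
    sum(strsplit(reads$read1[i], "")[[1]] != ref1) +
      sum(strsplit(reads$read2[i], "")[[1]] != ref2), numeric(1)))
  n <- n_pairs * 250 * 2
  sigma <- sqrt(n * rate * (1 - rate))
  expect_lt(abs(subs - n * rate), 3 * sigma)
})

test_that("unattainable quality floors error; seeds reproduce reads", {
  amp <- rand_seq(100)
  expect_error(simulate_reads(amp, n_pairs = 5, read_length = 50,
                              substitution_rate = 0, base_quality = 20,
                              min_quality = 28, seed = 1),
               "min_quality")
  r1 <- simulate_reads(amp, n_pairs = 20, read_length = 60,
                       substitution_rate = 0.05, seed = 6)
  r2 <- simulate_reads(amp, n_pairs = 20, read_length = 60,
                       substitution_rate = 0.05, seed = 6)
  expect_identical(r1, r2)
})

test_that("derive_asvs dereplicates with provenance and support ordering", {
  prov <- function(sp) data.frame(class = "C", order = "O", family = "F",
                                  genus = "G", species = sp,
                                  stringsAsFactors = FALSE)
  amps <- data.frame(
    amplicon_id = sprintf("a%d", 1:4),
    sequence = c("ACGTACGT", "ACGTACGT", "ACGTACGT", "TTTTCCCC"),
    class = "C", order = "O", family = "F", genus = "G",
    species = c("X", "X", "X", "Y"), stringsAsFactors = FALSE)
  asvs <- derive_asvs(amps)
  expect_equal(nrow(asvs), 2)
  expect_equal(asvs$asv_id, c("ASV_1", "ASV_2"))     # by support
  expect_equal(asvs$support, c(3L, 1L))
  expect_equal(asvs$provenance[[1]]$species, rep("X", 3))
  # two species sharing a sequence collapse into one multi-species ASV
  amps2 <- amps
  amps2$species <- c("X", "Y", "X", "Y")
  amps2$sequence <- "ACGTACGT"
  asvs2 <- derive_asvs(amps2)
  expect_equal(nrow(asvs2), 1)
  expect_setequal(unique(asvs2$provenance[[1]]$species), c("X", "Y"))
  # min_support filters; support is conserved before filtering
  expect_equal(sum(derive_asvs(amps)$support), nrow(amps))
  expect_equal(nrow(derive_asvs(amps, min_support = 2)), 1)
})

test_that("intra-species gene variants yield one ASV per variant", {
  amps <- data.frame(
    amplicon_id = sprintf("a%d", 1:3),
    sequence = c("AAACCC", "AAACCG", "AAACGG"),
    class = "C", order = "O", family = "F", genus = "G",
    species = "X", stringsAsFactors = FALSE)
  asvs <- derive_asvs(amps)
  expect_equal(nrow(asvs), 3)   # variants inflate ASV count over species count
  truth <- assign_truth(asvs)
  expect_true(all(!truth$ambiguous))
})

test_that("merged-read dereplication reconstructs amplicons", {
  set.seed(19)
  amp <- rand_seq(180)
  reads <- simulate_reads(amp, n_pairs = 6, read_length = 130,
                          substitution_rate = 0, seed = 2)
  reads$class <- "C"; reads$order <- "O"; reads$family <- "F"
  reads$genus <- "G"; reads$species <- "X"
  asvs <- derive_asvs(reads, mode = "dereplicate-merged-reads")
  expect_equal(nrow(asvs), 1)
  expect_equal(asvs$sequence, amp)
  expect_equal(asvs$support, 6L)
})
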