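# Independent brute-force oracles used to validate the package's
# optimised implementations. These deliberately share no code with R/.

# ---- lineage path-intersection oracle -------------------------------------
# LCA as the longest common prefix of the rank-name paths.
oracle_lca <- function(lineages) {
  ranks <- c("class", "order", "family", "genus", "species")
  paths <- lapply(lineages, function(l) {
    v <- unclass(l)[ranks]
    v[cumsum(is.na(v)) > 0] <- NA  # truncate at first NA
    v
  })
  out <- rep(NA_character_, 5)
  for (i in 1:5) {
    vals <- vapply(paths, function(p) p[[i]], character(1))
    if (anyNA(vals) || length(unique(vals)) != 1) break
    out[i] <- vals[1]
  }
  do.call(lineage, as.list(out))
}

# ---- IUPAC window-scan amplification oracle -------------------------------
iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

iupac_compatible <- function(a, b) {
  length(intersect(iupac_sets[[a]], iupac_sets[[b]])) > 0
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# mismatch count of `pat` laid over `tmpl` at offset `pos` (1-based)
oracle_window_mismatches <- function(pat, tmpl, pos) {
  p <- strsplit(pat, "")[[1]]
  t <- strsplit(tmpl, "")[[1]][pos:(pos + length(p) - 1)]
  sum(!mapply(iupac_compatible, p, t))
}

oracle_sites <- function(pat, tmpl, max_mm) {
  k <- nchar(pat); n <- nchar(tmpl)
  if (n < k) return(integer(0))
  which(vapply(1:(n - k + 1),
               function(i) oracle_window_mismatches(pat, tmpl, i) <= max_mm,
               logical(1)))
}

# every qualifying primer-trimmed amplicon sequence over both strands
oracle_amplify <- function(template, fwd, rev, max_mm, bounds) {
  one_strand <- function(tmpl) {
    fs <- oracle_sites(fwd, tmpl, max_mm)
    rs <- oracle_sites(oracle_revcomp(rev), tmpl, max_mm)
    out <- character(0)
    for (f in fs) for (r in rs) {
      s <- f + nchar(fwd); e <- r - 1
      len <- e - s + 1
      if (len >= bounds[1] && len <= bounds[2])
        out <- c(out, substr(tmpl, s, e))
    }
    out
  }
  sort(unique(c(one_strand(template), one_strand(oracle_revcomp(template)))))
}

# ---- full-DP overlap alignment oracle -------------------------------------
# End-gap-free alignment, match +1 / mismatch -1 / gap -1 per column.
# Returns score plus identity/coverage from a diag>up>left traceback.
oracle_overlap_align <- function(query, subject) {
  q <- strsplit(query, "")[[1]]; s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  H <- matrix(0, n + 1, m + 1)   # free end gaps: first row/col zero
  for (i in 1:n) for (j in 1:m) {
    sub <- H[i, j] + if (q[i] == s[j]) 1 else -1
    H[i + 1, j + 1] <- max(sub, H[i, j + 1] - 1, H[i + 1, j] - 1)
  }
  # best end lies on the last row or the last column (free end gaps)
  score_row <- max(H[n + 1, ]); score_col <- max(H[, m + 1])
  best_score <- max(score_row, score_col)
  if (score_row >= score_col) {
    ei <- n + 1; ej <- which.max(H[n + 1, ])
  } else {
    ei <- which.max(H[, m + 1]); ej <- m + 1
  }
  # traceback, diag > up > left on ties
  i <- ei; j <- ej; matches <- 0; cols <- 0; qa <- 0
  while (i > 1 && j > 1) {
    sub <- H[i - 1, j - 1] + if (q[i - 1] == s[j - 1]) 1 else -1
    if (H[i, j] == sub) {
      matches <- matches + (q[i - 1] == s[j - 1]); cols <- cols + 1
      qa <- qa + 1; i <- i - 1; j <- j - 1
    } else if (H[i, j] == H[i - 1, j] - 1) {
      cols <- cols + 1; qa <- qa + 1; i <- i - 1
    } else {
      cols <- cols + 1; j <- j - 1
    }
  }
  list(score = best_score,
       identity = if (cols > 0) matches / cols else 0,
       coverage = qa / n)
}

# ---- misc helpers ----------------------------------------------------------
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rand_lineage_pool <- function(n_class = 2, n_order = 2, n_family = 2,
                              n_genus = 2, n_species = 2) {
  out <- list()
  for (ci in 1:n_class) for (oi in 1:n_order) for (fi in 1:n_family)
    for (gi in 1:n_genus) for (si in 1:n_species) {
      g <- sprintf("G%d%d%d%d", ci, oi, fi, gi)
      out[[length(out) + 1]] <- lineage(
        class = sprintf("C%d", ci), order = sprintf("O%d%d", ci, oi),
        family = sprintf("F%d%d%d", ci, oi, fi), genus = g,
        species = sprintf("%s sp%d", g, si))
    }
  out
}
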