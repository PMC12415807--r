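# Deterministic synthetic toy taxonomies and reference databases.
#
# Sequences are generated by mutating a single ancestral marker along
# the rank hierarchy (family -> genus -> species -> sequence copy) at
# configurable substitution rates. Every record embeds exact primer
# sites flanking the variable core, so in-silico PCR recovers one
# amplicon per record with known provenance. Mutations are
# substitutions only (no indels), keeping primer coordinates fixed and
# the amplify/truth bookkeeping exact. Mislabelled entries and
# cross-species identical amplicons can be planted and are listed in
# the manifest.

#' Default toy primer pair used by the fixture generator
#'
#' An invented, non-degenerate primer pair embedded verbatim in every
#' fixture record.
#'
#' @return A [primer()].
#' @export
toy_primer <- function() {
  primer("toy_marker",
         forward = "ACGTGACCTAGGCATTCG",
         reverse = "TCCGTAGGTGAACCTGCA",
         max_mismatch = 4L,
         product_range = c(50L, 400L))
}

#' Specify a synthetic reference database
#'
#' @param n_families Number of families.
#' @param genera_per_family Genera per family.
#' @param species_per_genus Species per genus.
#' @param seqs_per_species Sequence records (gene copies) per species.
#' @param core_length Length of the variable inter-primer core (bp).
#' @param flank_length Length of the flanks outside the primer sites.
#' @param divergence Named numeric vector of per-site substitution rates
#'   applied when descending the hierarchy: `family` (ancestor ->
#'   family), `genus`, `species` and `sequence` (within-species copy
#'   variation). All rates must lie in `[0, 0.75]`.
#' @param n_mislabels Number of planted mislabelled records: exact
#'   copies of a donor record labelled with a species from a different
#'   family (requires `seqs_per_species >= 2` so the donor family
#'   outnumbers the mislabel in its self-comparison conflict set, and
#'   `n_families >= n_mislabels + 1`).
#' @param n_ambiguous Number of planted cross-species identical amplicon
#'   pairs: the second species of a genus receives the first species'
#'   inter-primer cores verbatim (requires `species_per_genus >= 2`).
#' @param primer A [primer()] to embed (default [toy_primer()]).
#' @param marker Marker name recorded in the database.
#' @param seed Integer seed; generation is fully deterministic.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_families = 6L, genera_per_family = 2L,
                         species_per_genus = 2L, seqs_per_species = 2L,
                         core_length = 180L, flank_length = 20L,
                         divergence = c(family = 0.25, genus = 0.10,
                                        species = 0.05, sequence = 0.005),
                         n_mislabels = 0L, n_ambiguous = 0L,
                         primer = toy_primer(), marker = "12S", seed = 1L) {
  stopifnot(n_families >= 1, genera_per_family >= 1, species_per_genus >= 1,
            seqs_per_species >= 1, core_length >= 20, flank_length >= 0,
            n_mislabels >= 0, n_ambiguous >= 0, inherits(primer, "primer"))
  need <- c("family", "genus", "species", "sequence")
  if (!all(need %in% names(divergence)))
    stop("divergence must name rates for: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(divergence < 0) || any(divergence > 0.75))
    stop("divergence rates must lie in [0, 0.75]", call. = FALSE)
  if (n_mislabels > 0 && seqs_per_species < 2)
    stop("planting mislabels requires seqs_per_species >= 2 ",
         "(the donor family must outnumber the mislabelled copy)",
         call. = FALSE)
  if (n_mislabels > 0 && n_families < 2)
    stop("planting mislabels requires at least 2 families", call. = FALSE)
  if (n_mislabels > n_families)
    stop("at most one planted mislabel per donor family", call. = FALSE)
  if (n_ambiguous > 0 && species_per_genus < 2)
    stop("planting ambiguous pairs requires species_per_genus >= 2",
         call. = FALSE)
  if (n_ambiguous > n_families * genera_per_family)
    stop("at most one planted ambiguous pair per genus", call. = FALSE)
  structure(list(n_families = as.integer(n_families),
                 genera_per_family = as.integer(genera_per_family),
                 species_per_genus = as.integer(species_per_genus),
                 seqs_per_species = as.integer(seqs_per_species),
                 core_length = as.integer(core_length),
                 flank_length = as.integer(flank_length),
                 divergence = divergence[need],
                 n_mislabels = as.integer(n_mislabels),
                 n_ambiguous = as.integer(n_ambiguous),
                 primer = primer, marker = marker, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Mutate sequences by random substitutions
#'
#' Applies independent per-site substitutions at `rate` (the new base is
#' drawn uniformly from the three alternatives). Useful to emulate
#' unsequenced sister taxa: a query a few percent diverged from a
#' reference record whose own species is absent from the database - the
#' out-of-reference scenario where overconfident classifiers produce
#' false-positive species calls.
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @param rate Per-site substitution probability in `[0, 0.75]`.
#' @param seed Integer seed; deterministic given `seed`.
#' @return Named character vector of mutated sequences.
#' @export
mutate_dna <- function(sequences, rate, seed = 1L) {
  stopifnot(is.character(sequences), rate >= 0, rate <= 0.75)
  with_rng(hash_seed(seed, "mutate_dna"),
           vapply(sequences, mutate_seq, character(1), rate = rate,
                  mask = integer(0)))
}

# substitute bases at `rate` per site, never touching `mask` positions
mutate_seq <- function(seq, rate, mask) {
  if (rate == 0) return(seq)
  b <- strsplit(seq, "")[[1]]
  free <- setdiff(seq_along(b), mask)
  hit <- free[runif(length(free)) < rate]
  for (i in hit) b[i] <- sample(setdiff(DNA_BASES, b[i]), 1L)
  paste(b, collapse = "")
}

#' Generate a synthetic toy reference database
#'
#' See [fixture_spec()] for the generative model. Output is byte-stable:
#' identical specs (including seed) give identical databases and
#' manifests.
#'
#' @param spec A `fixture_spec`.
#' @return A list with `db` (a `reference_db`) and `manifest` (list with
#'   `mislabels` - data.frame of planted mislabelled record ids with
#'   their donor and labelled families - and `ambiguous` - data.frame of
#'   planted identical-amplicon species pairs).
#' @examples
#' fx <- make_toy_refdb(fixture_spec(n_families = 2, genera_per_family = 2,
#'                                   species_per_genus = 2,
#'                                   seqs_per_species = 1, seed = 7))
#' length(fx$db$sequences)  # 8 records
#' @export
make_toy_refdb <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  pr <- spec$primer
  flen <- nchar(pr$forward); rlen <- nchar(pr$reverse)
  fl <- spec$flank_length
  # layout: flank5 | F | core | revcomp(R) | flank3 ; primer positions masked
  core_start <- fl + flen + 1L
  core_end <- fl + flen + spec$core_length
  mask <- c(seq(fl + 1L, fl + flen), seq(core_end + 1L, core_end + rlen))
  total_len <- fl + flen + spec$core_length + rlen + fl
  with_rng(hash_seed(spec$seed, "fixture"), {
    ancestor <- paste0(random_dna(fl), pr$forward, random_dna(spec$core_length),
                       revcomp(pr$reverse), random_dna(fl))
    stopifnot(nchar(ancestor) == total_len)
    div <- spec$divergence
    records <- list(); lineage_rows <- list()
    orders <- ceiling(seq_len(spec$n_families) / 2)
    counter <- 0L
    for (fi in seq_len(spec$n_families)) {
      fam_name <- sprintf("Famil%02d", fi)
      fam_seq <- mutate_seq(ancestor, div["family"], mask)
      for (gi in seq_len(spec$genera_per_family)) {
        gen_name <- sprintf("Genus%02d%s", fi, LETTERS[gi])
        gen_seq <- mutate_seq(fam_seq, div["genus"], mask)
        for (si in seq_len(spec$species_per_genus)) {
          sp_name <- sprintf("%s speci%02d", gen_name, si)
          sp_seq <- mutate_seq(gen_seq, div["species"], mask)
          for (ri in seq_len(spec$seqs_per_species)) {
            counter <- counter + 1L
            sid <- sprintf("s%04d", counter)
            records[[sid]] <- mutate_seq(sp_seq, div["sequence"], mask)
            lineage_rows[[sid]] <- data.frame(
              seqid = sid, class = "ClassA",
              order = sprintf("Order%02d", orders[fi]),
              family = fam_name, genus = gen_name, species = sp_name,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    taxonomy <- do.call(rbind, lineage_rows)
    rownames(taxonomy) <- NULL
    seqs <- unlist(records)

    # plant cross-species identical amplicon pairs: in genus g of family
    # g (cycling), species 2 takes species 1's inter-primer cores
    ambiguous <- data.frame(genus = character(), species_a = character(),
                            species_b = character(), stringsAsFactors = FALSE)
    if (spec$n_ambiguous > 0) {
      genera <- unique(taxonomy$genus)
      for (ai in seq_len(spec$n_ambiguous)) {
        g <- genera[ai]
        sub <- taxonomy[taxonomy$genus == g, ]
        sps <- unique(sub$species)
        a_ids <- sub$seqid[sub$species == sps[1]]
        b_ids <- sub$seqid[sub$species == sps[2]]
        for (j in seq_along(b_ids)) {
          donor <- seqs[[a_ids[min(j, length(a_ids))]]]
          tgt <- seqs[[b_ids[j]]]
          substr(tgt, core_start, core_end) <-
            substr(donor, core_start, core_end)
          seqs[[b_ids[j]]] <- tgt
        }
        ambiguous <- rbind(ambiguous, data.frame(
          genus = g, species_a = sps[1], species_b = sps[2],
          stringsAsFactors = FALSE))
      }
    }

    # plant mislabels: an exact copy of a donor record from family i,
    # labelled as an existing species of family i+1
    mislabels <- data.frame(seqid = character(), donor_family = character(),
                            labelled_family = character(),
                            donor_species = character(),
                            labelled_species = character(),
                            stringsAsFactors = FALSE)
    if (spec$n_mislabels > 0) {
      fams <- sort(unique(taxonomy$family))
      for (mi in seq_len(spec$n_mislabels)) {
        donor_fam <- fams[mi]
        target_fam <- fams[mi %% length(fams) + 1L]
        donor_id <- taxonomy$seqid[taxonomy$family == donor_fam][1]
        target_row <- taxonomy[taxonomy$family == target_fam, ][1, ]
        mid <- sprintf("mislab%02d", mi)
        seqs[[mid]] <- seqs[[donor_id]]
        taxonomy <- rbind(taxonomy, within(target_row, seqid <- mid))
        mislabels <- rbind(mislabels, data.frame(
          seqid = mid, donor_family = donor_fam,
          labelled_family = target_fam,
          donor_species = taxonomy$species[taxonomy$seqid == donor_id],
          labelled_species = target_row$species,
          stringsAsFactors = FALSE))
      }
      rownames(taxonomy) <- NULL
    }

    tax_table <- taxonomy
    class(tax_table) <- c("taxonomy_table", "data.frame")
    list(db = reference_db(spec$marker, seqs, tax_table),
         manifest = list(spec = spec, mislabels = mislabels,
                         ambiguous = ambiguous))
  })
}

#' Fixture presets mirroring the benchmark's community archetypes
#'
#' * `"balanced"`: many divergent families, one record per species - a
#'   diverse community of well-separated taxa.
#' * `"similar"`: a single family of congeners with low divergence and
#'   planted identical-amplicon pairs - the hard, closely related case.
#' * `"realistic-like"`: a mixed community with intra-species sequence
#'   variants, which inflate ASV counts above the species count.
#'
#' @param preset Preset name.
#' @param seed Integer seed.
#' @return A `fixture_spec`.
#' @export
fixture_preset <- function(preset = c("balanced", "similar", "realistic-like"),
                           seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    balanced = fixture_spec(n_families = 8L, genera_per_family = 2L,
                            species_per_genus = 2L, seqs_per_species = 1L,
                            divergence = c(family = 0.30, genus = 0.12,
                                           species = 0.06, sequence = 0),
                            seed = seed),
    similar = fixture_spec(n_families = 1L, genera_per_family = 3L,
                           species_per_genus = 4L, seqs_per_species = 2L,
                           divergence = c(family = 0.10, genus = 0.04,
                                          species = 0.015, sequence = 0.003),
                           n_ambiguous = 2L, seed = seed),
    `realistic-like` = fixture_spec(n_families = 5L, genera_per_family = 2L,
                                    species_per_genus = 2L,
                                    seqs_per_species = 3L,
                                    divergence = c(family = 0.25,
                                                   genus = 0.10,
                                                   species = 0.05,
                                                   sequence = 0.01),
                                    n_ambiguous = 1L, seed = seed))
}
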