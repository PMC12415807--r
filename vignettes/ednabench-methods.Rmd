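---
title: "Benchmarking eDNA taxonomic classifiers with ednabench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking eDNA taxonomic classifiers with ednabench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednabench)
```

## The problem

Environmental DNA (eDNA) metabarcoding infers which species are present in
an environment by amplifying and sequencing a short mitochondrial marker
(12S or 16S rRNA, COI) from mixed-template DNA. The resulting amplicon
sequence variants (ASVs) are handed to a *taxonomic classifier*, which
matches them against a reference database. How much one can trust the
resulting species lists depends almost entirely on two things that are
invisible in real data: how the classifier behaves when the correct answer
is genuinely ambiguous, and how it behaves when the correct answer is *not
in the reference database at all*.

`ednabench` builds simulation benchmarks that make both failure modes
measurable. Because every query sequence is simulated from a known source,
the truth is known by construction; because reference databases can be
degraded deliberately (clade exclusion), classifier behaviour on
out-of-reference queries can be quantified rather than guessed.

## The benchmark loop

A full run (`run_benchmark()`) wires together:

1. **Reference curation** (`detect_mislabels()`): every record is aligned
   against all others with an end-gap-free aligner; subjects above 97%
   identity at full query coverage join a conflict set. If the lowest
   common ancestor (LCA) of the set is shallower than family, at least one
   member is mislabelled; the minority family in the set is flagged. Ties
   flag nothing and warn - deleting on a tie risks deleting correct data.
2. **Clade exclusion** (`plan_exclusions()`): whole families are removed
   at a configured fraction (default design: 30%, 50% and 70% of families,
   10 random replicates each, 30 exclusion databases). Excluding *whole*
   families emulates the common situation where entire clades are
   unsequenced, and guarantees the query's true species (and all its
   congeners) are absent.
3. **Community simulation**: `amplify()` performs in-silico PCR with
   degenerate (IUPAC) primers, allowing up to 4 substitutions per primer
   site and no indels (indels would make product coordinates ambiguous);
   `simulate_reads()` emits paired 130 bp reads at 500 pairs per gene copy
   under a flat-quality, uniform-substitution error model;
   `derive_asvs()` collapses identical sequences into ASVs carrying their
   full source provenance.
4. **Ground truth** (`assign_truth()`): an ASV whose provenance contains a
   single species gets a species-level label. When distinct species
   contributed *literally identical* amplicons there is no species-level
   truth: the label is the provenance LCA and the ASV is marked
   species-ambiguous. Truth is a function of the query community only -
   excluding families from the classifier's reference cannot move it.
5. **Classification**: two built-in classifiers span the two major
   families of tools, and `parse_external()` adapts third-party output
   (12-column tabular hits, or per-read taxon files) for scoring.
6. **Evaluation** (`score_predictions()`, `compute_metrics()`): at
   species level, TP = the predicted species matches the truth species;
   FP = any other species claim (including any species claim on a
   species-ambiguous ASV); TN = no species predicted where none was
   assignable; FN = no species predicted where one was. Accuracy,
   precision, recall, F1 and F0.5 follow; F0.5 weights precision over
   recall, matching the needs of invasive-species monitoring where false
   presences are costlier than false absences.

## The two built-in classifiers

**Top-hit + LCA** (`tophit_lca_classify()`): align the ASV (both
orientations) against every reference record, keep hits with identity at
or above the cutoff (97% lenient / 100% strict) at 100% query coverage,
and report the LCA of the retained hits' lineages. This is the classical
alignment-based strategy; the 100% variant answers only on exact matches.

**Hashed k-mer naive Bayes** (`train_nbc()` / `classify_nbc()`): counts of
all k-mers for k in 8..12 are hashed into 2^18 buckets (collisions
additive) and pooled per species into a multinomial model with additive
smoothing. Hashing is unsigned: signed hashing would produce negative
counts, which a multinomial likelihood cannot accept.
`optimize_nbc()` grid-searches k-range and smoothing via stratified
cross-validation on mean species-level F1.

### Why confidence is a bootstrap score

Raw naive Bayes posteriors are notoriously overconfident: log-likelihood
differences accumulate over hundreds of k-mers, so the softmax saturates
at 1.0 even for queries that resemble no class - on a toy-scale
vocabulary, a single chance shared k-mer shifts the log-odds by roughly
`log(1/alpha)`. A raw-posterior cutoff of 0.97 therefore cannot separate
"confident because right" from "confident because the model must pick
something", and random-DNA negative controls would receive species labels.

The default confidence is instead a bootstrap agreement score in the
spirit of the RDP/DADA2 naive Bayes wrappers: the query's k-mers are
resampled (100 draws of 1/8 of the k-mers) and confidence is the fraction
of replicates won by the top class. Genuine matches win every replicate
(confidence 1.0); random sequences spread their wins and abstain. The raw
posterior remains available (`confidence = "posterior"`) precisely because
its failure mode is one of the phenomena worth demonstrating.

Crucially, the bootstrap does *not* rescue the classifier from structured
out-of-reference queries: a query a few percent diverged from one
reference species wins every replicate for that species and produces a
confident false positive. The benchmark exploits this with its
"unsequenced sister species" construction (`mutate_dna()` at 1.5%
substitutions on a retained record): the stringent top-hit classifier
abstains on such queries, while the naive Bayes classifier confidently
names the wrong species - the characteristic false-positive behaviour of
probabilistic classifiers under incomplete references.

## The synthetic data generator

`make_toy_refdb()` grows a marker database by mutating one ancestral
sequence down the rank hierarchy (family -> genus -> species -> gene
copy) at configurable per-site substitution rates (defaults 25% / 10% /
5% / 0.5%), with exact primer sites embedded so every record amplifies.
Two kinds of structure can be planted, and are listed in the manifest:

* **mislabels** - an exact copy of a donor record labelled with a species
  from another family (requires at least two copies per species, so the
  donor family outvotes the single mislabelled copy in its conflict set);
* **ambiguous pairs** - a congener receives another species' inter-primer
  cores verbatim, producing cross-species identical amplicons and hence
  species-ambiguous ASVs.

Mutations are substitutions only. This keeps primer coordinates and
product lengths exact, which is what makes parameter-recovery tests
(planted mislabels and ambiguous pairs recovered *exactly*) possible. It
also means the generator does not emulate several properties of real
data: indels and length variation, compositional bias of mitochondrial
genomes, PCR chimeras and abundance bias, instrument-specific quality
profiles, or read-depth variation between taxa. Green tests therefore
demonstrate correctness of the benchmark machinery and the qualitative
classifier phenomena, not classifier performance on real communities -
the headline performance numbers of any real study depend on the real
reference databases and cannot be reproduced from synthetic data.

## Numerical and design choices

* **Alignment**: end-gap-free (overlap) alignment with unit costs
  (match +1, mismatch -1, gap -1), identity = matches / aligned columns
  (internal gaps count as mismatching columns), coverage = aligned query
  bases / query length. Validated against a quadratic DP oracle with
  traceback.
* **Exclusion rounding**: nearest integer, half away from zero, floor of
  one family whenever the fraction is positive.
* **Mislabel identity is strict** (`> 0.97`), classification identity is
  inclusive (`>= 0.97`); both configurable.
* **Randomness**: every randomised operation derives a private RNG stream
  from an explicit seed (hashed with stage and replicate tags) and
  restores the caller's RNG state; no function touches the global
  generator. This is what makes the full pipeline byte-reproducible.
* **Ambiguity boundary**: species-ambiguity is declared on *exact*
  sequence collision, the only boundary dereplication defines
  unambiguously. An ASV from two congeners 1 nt apart is two ASVs, each
  with species-level truth.
* **Ambiguous-ASV species calls score FP by default** ("strict"): where
  no species-level truth exists, any species claim is unfounded. A
  "lenient" mode (a claim matching one of the colliding sources counts
  TP) is available for sensitivity analysis.
* **Replicate aggregation** reports medians with min/max; undefined
  metrics (0/0) propagate as `NA` and are excluded with a count.
* **Problem sizes**: the shipped configurations use toy databases of
  6-10 families (24-51 records), 100-sequence negative controls, and
  1e5 simulated bases for error-rate calibration - large enough for the
  statistical checks (3-sigma binomial bands, chi-square uniformity at
  alpha 0.001) while keeping a full run in seconds.

## Worked example

```{r example, eval = FALSE}
fx <- make_toy_refdb(fixture_spec(seqs_per_species = 1, n_ambiguous = 2,
                                  seed = 7))
db <- fx$db
asvs <- derive_asvs(amplify_db(db, toy_primer()))
truth <- assign_truth(asvs)
pred <- tophit_lca_classify(asvs, db, min_identity = 0.97)
sc <- score_predictions(truth, pred)
compute_metrics(sc$counts)
hierarchical_breakdown(sc$verdicts)
```

On a complete reference with error-free amplicons this yields zero false
positives and recall 1 on unambiguous ASVs; the interesting numbers
appear once `exclude_families()` degrades the reference.

## Known limitations

* The built-in aligner computes no e-value model; e-value filtering
  applies only to external tabular hits (default threshold 1e-5).
* The read simulator's flat quality string makes the mean-quality filter
  a pass/fail property of the configuration rather than per-read
  stochastic rejection.
* `parse_external()` cannot compute query coverage from a bare 12-column
  hit table (the format has no query-length field); callers must supply
  query lengths to apply a coverage filter.
* Representative selection is a greedy max-min heuristic on k-mer Jaccard
  distance - a documented stand-in for phylogeny-guided selection, not a
  reproduction of it.
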