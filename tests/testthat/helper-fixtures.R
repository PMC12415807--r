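# Small hand-built fixtures shared across tests.

lin_str <- function(class, order, family, genus, species)
  paste(class, order, family, genus, species, sep = ";")

# reference_db from parallel vectors of ids, sequences, lineage strings
quick_db <- function(ids, seqs, lineages, marker = "12S") {
  tax <- build_taxonomy(data.frame(seqid = ids, lineage = lineages,
                                   stringsAsFactors = FALSE))
  reference_db(marker, setNames(seqs, ids), tax)
}

# a 10-family database with one record per family (for exclusion tests)
ten_family_db <- function() {
  ids <- sprintf("t%02d", 1:10)
  set.seed(99)
  seqs <- vapply(1:10, function(i) rand_seq(120), character(1))
  lineages <- vapply(1:10, function(i)
    lin_str("C1", sprintf("O%d", ceiling(i / 5)), sprintf("Fam%02d", i),
            sprintf("Gen%02d", i), sprintf("Gen%02d sp", i)), character(1))
  quick_db(ids, seqs, lineages)
}

# minimal ASV table from raw sequences + provenance lineage list
quick_asvs <- function(seqs, provenance) {
  df <- data.frame(asv_id = names(seqs), sequence = unname(seqs),
                   support = 1L, stringsAsFactors = FALSE)
  df$provenance <- provenance
  df
}

lutjanus_arg <- lineage("Actinopteri", "Perciformes", "Lutjanidae",
                        "Lutjanus", "Lutjanus argentimaculatus")
lutjanus_jocu <- lineage("Actinopteri", "Perciformes", "Lutjanidae",
                         "Lutjanus", "Lutjanus jocu")
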