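#!/usr/bin/env Rscript
# Stage 3: the note x concept dummy matrix.
#
# Builds the binary presence matrix (one row per note, one column per
# observed feature code, note labels inherited from patients), applies the
# minimum-4-distinct-patients column filter, and resolves the curated
# risk/protective term list against the observed codes. Writes the matrix
# as MTX + sidecar TSVs under results/data/.

suppressPackageStartupMessages(library(attemptnlp))

cohort <- read_corpus("results/data/corpus.jsonl")
lexicon <- build_default_lexicon()
curated <- default_curated_terms()

lines <- readLines("results/data/note_cuis.jsonl")
recs <- lapply(lines, jsonlite::fromJSON)
cui_sets <- lapply(recs, function(r) as.character(unlist(r$codes)))
names(cui_sets) <- vapply(recs, `[[`, "", "note_id")

fm_all <- build_note_matrix(cui_sets, cohort)
fm <- filter_min_patients(fm_all, 4)
write_feature_matrix(fm, "results/data/matrix")

cur <- resolve_curated(curated, cohort, lexicon, cui_sets = cui_sets)
writeLines(cur$codes, "results/data/curated_codes.txt")

cat(sprintf(paste0(
  "dummy matrix: %d notes x %d codes before filtering\n",
  "  codes in >= 4 distinct patients: %d\n",
  "  curated terms resolved to %d observed codes (%d terms unmatched)\n"),
  nrow(fm_all$rows), length(fm_all$codes), length(fm$codes),
  length(cur$codes), length(cur$unmatched)))
cat("wrote results/data/matrix.{mtx,_rows.tsv,_cols.tsv}, curated_codes.txt\n")
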