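#!/usr/bin/env Rscript
# Stage 5: final model and holdout evaluation.
#
# Re-runs feature selection on the full 80% training matrix, fits the final
# 300-tree forest, predicts every holdout note, aggregates note calls to
# patient classifications over the cutoff grid, and reports counts and
# metrics per cutoff plus the ROC over the grid's operating points. Writes
# results/cv_performance.csv, results/holdout_performance.csv,
# results/roc.{csv,png} and results/final_summary.json.

suppressPackageStartupMessages(library(attemptnlp))

SEED <- 20L
cohort <- read_corpus("results/data/corpus.jsonl")
fm <- read_feature_matrix("results/data/matrix")
curated_codes <- readLines("results/data/curated_codes.txt")
sel <- jsonlite::fromJSON("results/selection.json")
cv_summary <- utils::read.delim("results/cv_summary_raw.tsv")

split <- structure(list(training_patients = sel$training_patients,
                        holdout_patients = sel$holdout_patients,
                        seed = sel$seed), class = "split_assignment")

final <- finalize_and_evaluate(cohort, fm, intersect(curated_codes, fm$codes),
                               split, sel$selected_cutoff,
                               seed = SEED + 200L)
report_tables(cv_summary, final$holdout_table, final$roc, "results")

hl <- final$headline
jsonlite::write_json(
  list(selected_cutoff = sel$selected_cutoff,
       n_holdout = length(sel$holdout_patients),
       headline = as.list(hl), auc = final$roc$auc,
       n_final_features = length(final$features),
       model_fingerprint = final$model$training_fingerprint),
  "results/final_summary.json", auto_unbox = TRUE, pretty = TRUE)

cat(sprintf(paste0(
  "holdout evaluation (%d patients) at the %.0f%% cutoff:\n",
  "  sensitivity %.2f  specificity %.2f  PPV %.2f  NPV %.2f  accuracy %.2f\n",
  "  AUC over the cutoff grid: %.2f\n",
  "  final model features: %d\n"),
  length(sel$holdout_patients), 100 * sel$selected_cutoff,
  hl$sensitivity, hl$specificity, hl$ppv, hl$npv, hl$accuracy,
  final$roc$auc, length(final$features)))
cat("wrote results/{cv_performance,holdout_performance,roc}.csv, roc.png, final_summary.json\n")
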