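# attemptnlp

Classifying past-year suicide attempt among psychiatrically hospitalized
adolescents from the free text of their pre-admission electronic health
record (EHR) notes.

## The problem and the model

Adolescents admitted to psychiatric inpatient care often under-report
recent suicide attempts, while the preceding year of clinical
documentation — therapy notes, medication visits, emergency contacts —
records risk and protective context in unstructured text. The outcome
(any past-year attempt, dichotomized 0/1) exists only **per patient**;
the text exists only **per note**. `attemptnlp` implements the resulting
multiple-instance classification pipeline:

1. **Concept extraction** — dictionary longest-match tagging of note text
   into UMLS-style Concept Unique Identifiers (CUIs, `C` + 7 digits) with
   NegEx-style rule negation; a negated mention of `X` becomes the
   separate feature `X_neg` ("no suicide attempts" ≠ "suicide attempt").
2. **Dummy matrix** — a sparse binary note × CUI presence matrix; a code
   must occur in notes of ≥ 4 distinct patients to enter the model pool.
3. **Fold-wise feature selection** — per cross-validation fold, the 50
   codes with the largest mean decrease in Gini impurity from a 300-tree
   random forest, unioned with a curated list of 34 risk and 30
   protective clinical terms resolved to codes present in that fold's
   training notes.
4. **Note classification** — a 300-tree random forest over note rows,
   labels inherited from patients.
5. **Patient aggregation** — a patient is classified positive at cutoff
   *c* iff their proportion of positive notes is strictly greater than
   *c*, for *c* ∈ {0%, 10%, …, 100%}.
6. **Cutoff selection and holdout evaluation** — 5-fold cross-validation
   on the 80% training patients selects the operating cutoff
   (sensitivity floor 0.70, then maximal specificity); a final model is
   refit on all training patients and evaluated once on the 20% holdout:
   sensitivity, specificity, PPV, NPV, accuracy per cutoff, and the
   trapezoidal AUC over the grid's ROC operating points.

The original EHR data are protected; a synthetic-corpus generator
(`generate_cohort()`) reproduces the cohort's statistical shape — 37%
label prevalence, a right-skewed notes-per-patient distribution (median
≈ 70, mean ≈ 129, range 1–876), lexicon terms mentioned at
label-conditional rates, explicit negation phrases — so the entire
pipeline is testable offline. See `vignettes/pipeline-methods.Rmd` for
the full methods account.

## Worked example

```r
library(attemptnlp)

# a small synthetic cohort: 60 patients, reduced note volume
cfg <- generator_config(n_patients = 60, notes_meanlog = log(10),
                        notes_sdlog = 0.7, notes_max = 60, seed = 42)
cohort <- generate_cohort(cfg)
summarize_cohort(cohort)[c("n_patients", "n_notes", "prevalence")]
#> $n_patients
#> [1] 60
#> $n_notes
#> [1] 738
#> $prevalence
#> [1] 0.4833333

res <- run_pipeline(cohort, seed = 1)
res$selected_cutoff
#> [1] 0.7
round(subset(res$final$holdout_table,
             cutoff %in% c(0, 0.2, 0.5, res$selected_cutoff, 1)), 2)
#>    cutoff tn fn fp tp sensitivity specificity  ppv npv accuracy
#> 1     0.0  1  0  5  6           1        0.17 0.55 1.0     0.58
#> 3     0.2  4  0  2  6           1        0.67 0.75 1.0     0.83
#> 6     0.5  6  0  0  6           1        1.00 1.00 1.0     1.00
#> 8     0.7  6  0  0  6           1        1.00 1.00 1.0     1.00
#> 11    1.0  6  6  0  0           0        1.00 0.00 0.5     0.50
res$final$roc$auc
#> [1] 1
```

Reading the table: at cutoff 0% every patient with at least one positive
note is called positive (high sensitivity, poor specificity); raising the
cutoff trades sensitivity for specificity; at 100% the strict inequality
classifies nobody positive. On this strongly separated synthetic cohort
the holdout patients (12 here) are perfectly ranked (AUC 1.0) — real
clinical text is far noisier; the generator's default mention rates are
illustrative knobs, not clinical estimates.

## Analysis workflow

The `analysis/` scripts run the study-scale configuration (73 patients,
median ≈ 70 notes/patient) as a reproducible sequence, writing tables
under `results/`:

```sh
Rscript analysis/01_simulate.R    # synthetic corpus -> results/data/corpus.jsonl
Rscript analysis/02_extract.R     # note text -> feature codes (JSONL)
Rscript analysis/03_featurize.R   # dummy matrix (MTX) + curated resolution
Rscript analysis/04_train_cv.R    # 5-fold CV, per-fold features, cutoff choice
Rscript analysis/05_evaluate.R    # final model, holdout tables, ROC
```

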