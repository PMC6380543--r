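---
title: "Classifying past-year suicide attempt from clinical notes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying past-year suicide attempt from clinical notes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Adolescents admitted to inpatient psychiatric care often do not disclose a
recent suicide attempt, yet that history is among the strongest predictors
of future attempts. The year of clinical documentation that typically
precedes an index admission — outpatient psychotherapy notes, medication
visits, emergency contacts, collateral calls — encodes risk and protective
context in free text. `attemptnlp` implements a pipeline that classifies a
patient-level binary outcome (any past-year suicide attempt, as
self-reported on an anonymous survey) from that note-level text.

The statistical structure is a multiple-instance problem: supervision
exists only per patient, while the classifier operates per note. The
pipeline resolves it in the simplest defensible way — note rows inherit
their patient's label for training, and note-level predictions are
re-aggregated into a patient call through a proportion-of-notes threshold.

## Pipeline

1. **Concept extraction.** Each note is split into sentences (boundaries
   at `.`, `!`, `?` followed by whitespace, and at newlines), tokenized
   into lowercased alphanumeric runs, and scanned with a greedy
   leftmost-longest dictionary matcher over the lexicon's surface variants.
   A NegEx-style rule flags negated mentions: a trigger phrase (`no`,
   `not`, `denies`, `denied`, `without`, `negative for`) ending within the
   six tokens preceding a mention negates it unless a scope-breaking
   conjunction (`but`, `however`) intervenes. A negated mention of concept
   `X` becomes the distinct feature code `X_neg`. Industrial clinical NLP
   engines add part-of-speech tagging, shallow parsing, and named-entity
   resolution against the full UMLS; this package deliberately substitutes
   dictionary matching plus rule negation because the downstream model
   consumes only presence/absence of a fixed code set, and the substitution
   is exactly reproducible and testable against a brute-force oracle. The
   trigger list, scope window, and optional light stemming are exposed in
   `extraction_options()`; the defaults are the simplest rule set
   consistent with negated clinical documentation such as "no suicide
   attempts".

2. **Dummy matrix.** One binary row per note, one column per feature code
   observed anywhere in the corpus (`build_note_matrix()`); presence only,
   no counts. To curb overfitting, a code must appear in notes of at least
   four distinct patients to stay in the model pool
   (`filter_min_patients()`, distinct-patient counting, never note
   counting). This global filter is computed once on the full dataset; each
   cross-validation fold additionally restricts itself to codes that occur
   in its own training notes, in that order.

3. **Curated enrichment.** A clinician-style list of 34 risk and 30
   protective terms ships with the package (`default_curated_terms()`) and
   is fully user-replaceable. `resolve_curated()` maps each term to every
   lexicon concept containing it as a contiguous token subsequence
   (case-insensitive, exact tokens — fuzzy matching is deliberately out of
   scope) and keeps whichever observed forms (affirmed and/or `_neg`)
   actually occur in the corpus; unmatched terms are reported, not errors.
   Curated codes present in a fold's training notes are force-included in
   that fold's feature set.

4. **Fold-wise feature selection and training.** Patients are split 80/20
   (`split_train_holdout()`, patient-level so all of a patient's notes
   travel together; with 73 patients this gives 58 training and 15 holdout
   patients), and training patients are assigned to five folds with sizes
   differing by at most one (58 patients fold into 12, 12, 12, 11, 11).
   Per fold, a 300-tree random forest ranks the eligible codes by mean
   decrease in Gini impurity; the top 50 (ties broken by lexicographic
   code order, so ranking is deterministic) are unioned with the
   curated-present codes, and a fresh 300-tree forest is fit on those
   columns. Forest hyperparameters beyond tree count are the canonical
   random-forest defaults (sqrt(p) candidate features per split, unlimited
   depth). The forest engine is `ranger`, chosen for its speed on wide
   binary matrices and its built-in seeding; one test cross-checks its
   behavior against the classical `randomForest` implementation on a
   separable fixture.

5. **Patient aggregation.** A patient's score is the proportion of their
   notes classified positive; the patient is called positive at cutoff *c*
   iff that proportion is **strictly greater** than *c*, over the fixed
   grid 0%, 10%, ..., 100%. Strictness matters at both ends: a patient
   with zero positive notes is negative even at 0%, and nobody is positive
   at 100% — so sensitivity is non-increasing and specificity
   non-decreasing along the grid by construction.

6. **Cutoff selection and holdout evaluation.** Fold metrics are averaged
   per cutoff. The default policy selects, among cutoffs whose mean
   sensitivity clears a floor (0.70), the one with maximal mean
   specificity. When several cutoffs tie on specificity — common once
   specificity saturates at 1.0 on well-separated data — the tie resolves
   toward the candidate with maximal mean sensitivity, because the
   selection objective is to prioritize sensitivity without overly
   sacrificing specificity; only a remaining exact tie falls to the larger
   cutoff. If no cutoff clears the floor the policy falls back to Youden's
   index, and a manual override is available. The final model re-runs the
   identical selection procedure on the full 80% training matrix (the
   per-fold feature lists differ, so "the best model's features" is
   ambiguous; re-selection keeps the procedure uniform, and the union of
   fold lists is available via `final_features = "union"`). The holdout
   patients are then scored once: counts and the five metrics at every
   grid cutoff, headline metrics at the selected cutoff, and the ROC over
   the grid's operating points.

## Evaluation conventions

* **Metrics.** sensitivity = tp/(tp+fn), specificity = tn/(tn+fp),
  PPV = tp/(tp+fp), NPV = tn/(tn+fn), accuracy = (tp+tn)/n. Any 0/0 ratio
  is reported as 0.0 — this matches how all-negative classification rows
  print (0.00 sensitivity, 0.00 PPV) in per-cutoff tables. Full precision
  is kept internally; reports round to 2 decimals at write time.
* **ROC/AUC.** Each cutoff contributes the operating point
  (FPR, TPR); anchors (0,0) and (1,1) are appended and the trapezoid rule
  is applied after representing each distinct FPR by its maximum TPR. The
  envelope convention matters because the strict-threshold grid produces
  duplicate operating points (several cutoffs can yield identical
  confusion counts); connecting through the lower duplicate would
  under-integrate the attainable curve.
* **0-based half-open character offsets** for mentions, so
  `substring(text, start + 1, end)` always reproduces `matched_text`.

## The synthetic-corpus generator

The original electronic health records are protected and cannot ship, so
`generate_cohort()` produces corpora with the statistical structure the
analysis assumes, and every stage of the package is exercised against it:

* labels are independent Bernoulli draws at 37% prevalence (the observed
  rate in the 73-patient cohort the generator emulates);
* notes per patient follow a truncated log-normal (meanlog `log(70)`,
  sdlog 1.16, range 1–876), calibrated once so the rounded, truncated
  draw has median ≈ 70 and mean ≈ 129 — the pronounced mean/median gap
  reflects the right-skewed documentation volume of this population;
* note text is assembled from sentence templates whose concept slots are
  filled with lexicon surface terms sampled at label-conditional per-note
  rates (defaults: ten suicidality-cluster concepts at 0.30 for cases vs
  0.02 for controls; remaining concepts at a label-free 0.04). These rates
  are illustrative, configurable knobs — not estimates of any clinical
  population;
* mentions are wrapped in negation phrases with probability 0.10, and
  controls additionally receive negated-only documentation of signal
  concepts ("No suicide attempts.") at a per-note rate of 0.08, so the
  extractor's negation logic carries real signal;
* demographics are generated only to exercise corpus I/O; the model never
  sees them.

Identical configuration and seed give a byte-identical corpus.

What the generator does **not** emulate: realistic clinical prose (template
sentences only), within-patient topical correlation over time, provider
styles, misspellings, and section structure. Passing tests on synthetic
corpora therefore demonstrate that the machinery is correct and leak-free —
not that the model would attain any particular performance on real notes,
where concept rates are far noisier and the label-conditional separation is
much weaker.

## Determinism and numerical choices

Every stochastic step takes an explicit seed, and `run_pipeline()` derives
all stage seeds from one base seed; repeated runs are byte-reproducible
(corpus JSONL, report CSVs, summary JSON). Feature-importance ties break
lexicographically; the cutoff grid is built from exact decimal doubles so
grid membership tests behave; cutoff comparisons use a 1e-9 tolerance;
trained models carry an MD5 fingerprint of their serialized feature list
and forest, which the no-leakage test uses — perturbing holdout labels
must leave every training artifact's fingerprint unchanged.

Degenerate inputs are errors, not silent defaults: single-class training
folds (reported with the fold id), corpora with fewer than five patients,
empty cutoff tables, ROC computation without any actual negative, empty
confusion matrices. Patients with zero scored notes are excluded from
aggregation with a warning.

## Problem sizes in tests and scripts

The test suite exercises the full pipeline on simulated cohorts of 30–400
patients with a reduced note volume (log-normal median 8 notes/patient,
range 1–40) and a 30-concept lexicon; this keeps 20 end-to-end replicates
(ten strong-signal, ten null) to a few minutes while preserving the
multiple-instance geometry. The analysis scripts and the acceptance script
run the study-scale configuration (73 patients, median ≈ 70 notes per
patient, 64-concept lexicon). Signal recovery is asserted as holdout
sensitivity ≥ 0.80 at the CV-selected cutoff in at least 8 of 10 seeds;
null calibration as holdout AUC within [0.35, 0.65] in at least 8 of 10
seeds.

## Limitations

* Dictionary extraction cannot find concepts phrased outside the lexicon's
  variants, and the negation rule has no post-mention triggers by default.
* Label inheritance makes every note of a case patient a "positive" row,
  which is noisy supervision; the forest tolerates it, but note-level
  probabilities are not calibrated and should not be interpreted.
* The proportion-of-notes aggregation ignores note length, recency, and
  provider type.
* No alternative learners, no probability calibration, no temporal
  train/test splitting by note date: the pipeline classifies documented
  history, it does not forecast.
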