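#' @title Note-level random-forest pipeline with patient-level cutoff
#'   aggregation
#' @description The six-step procedure: (1) patient-level 80/20
#'   train/holdout split; (2) 5-fold cross-validation over training
#'   patients; (3) per-fold feature selection = top-50 codes by random
#'   forest mean decrease in Gini impurity, union curated codes present in
#'   that fold's training notes; (4) a 300-tree random forest on note-level
#'   rows with labels inherited from patients; (5) note predictions for the
#'   fold's test patients, aggregated per patient as the proportion of
#'   positive notes, classified positive at a cutoff `c` iff proportion
#'   strictly exceeds `c`, over the fixed grid 0%, 10%, ..., 100%;
#'   (6) cutoff selection from fold-averaged metrics, then a final model on
#'   the full training set evaluated once on the holdout patients.
#' @name model_pipeline
NULL

#' The fixed proportion-of-notes cutoff grid
#'
#' @return Numeric vector `c(0, 0.1, ..., 1)` (eleven values; exact decimal
#'   doubles, so `0.7 %in% cutoff_grid()` holds).
#' @export
cutoff_grid <- function() (0:10) / 10

#' Split patients into training and holdout sets
#'
#' Patient-level: all of a patient's notes travel together. The training
#' set has `round(fraction * n)` patients; the remainder is held out.
#'
#' @param corpus a `note_corpus` with at least 5 patients.
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed; the split is deterministic given the seed.
#' @param stratified if `TRUE`, split within label strata (default `FALSE`,
#'   plain random partition).
#' @return A `split_assignment`: list with `training_patients`,
#'   `holdout_patients`, `seed`.
#' @export
split_train_holdout <- function(corpus, fraction = 0.8, seed = 1L,
                                stratified = FALSE) {
  ids <- corpus$patients$patient_id
  n <- length(ids)
  if (n < 5) stop("need at least 5 patients to split, got ", n)
  set.seed(seed)
  if (stratified) {
    lab <- corpus$patients$attempt_label
    train <- character(0)
    for (g in unique(lab)) {
      gid <- sample(ids[lab == g])
      train <- c(train, gid[seq_len(round(fraction * length(gid)))])
    }
    # adjust to the exact overall size with a deterministic trim/top-up
    target <- round(fraction * n)
    pool <- sample(setdiff(ids, train))
    while (length(train) < target) {
      train <- c(train, pool[1]); pool <- pool[-1]
    }
    if (length(train) > target) train <- train[seq_len(target)]
  } else {
    shuffled <- sample(ids)
    train <- shuffled[seq_len(round(fraction * n))]
  }
  structure(list(training_patients = sort(train),
                 holdout_patients = sort(setdiff(ids, train)),
                 seed = as.integer(seed)),
            class = "split_assignment")
}

#' Assign training patients to cross-validation folds
#'
#' Fold sizes differ by at most one; with 58 training patients and k = 5
#' the sizes are 12, 12, 12, 11, 11. Each patient lands in exactly one
#' fold, so each serves as test data once and training data k - 1 times.
#'
#' @param split a `split_assignment`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A `fold_assignment`: named integer vector patient_id -> fold.
#' @export
assign_folds <- function(split, k = 5L, seed = 1L) {
  ids <- split$training_patients
  n <- length(ids)
  if (k > n) stop("k = ", k, " exceeds number of training patients (", n, ")")
  set.seed(seed)
  shuffled <- sample(ids)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- rep(seq_len(k), times = sizes)
  structure(stats::setNames(fold, shuffled)[order(shuffled)],
            class = "fold_assignment")
}

dense_x <- function(fm) {
  x <- as.matrix(fm$m)
  storage.mode(x) <- "double"
  colnames(x) <- fm$codes
  rownames(x) <- fm$rows$note_id
  x
}

#' Select features for one fold
#'
#' Fits a ranking forest (same settings as the final model: `n_trees`
#' trees) on all eligible columns of the fold's training matrix, ranks
#' codes by mean decrease in Gini impurity with ties broken by
#' lexicographic code order, keeps the top `top_k`, and unions them with
#' the curated codes present in the training matrix.
#'
#' @param fm_train `feature_matrix` restricted to the fold's training notes
#'   and to codes present in those notes.
#' @param curated_codes character vector of curated feature codes (e.g.
#'   `resolve_curated(...)$codes`).
#' @param top_k number of top-importance codes to keep (default 50).
#' @param seed integer seed for the ranking forest.
#' @param n_trees trees in the ranking forest (default 300).
#' @return Ordered character vector: top codes in importance order, then
#'   any additional curated codes in lexicographic order.
#' @export
select_features_fold <- function(fm_train, curated_codes = character(0),
                                 top_k = 50L, seed = 1L, n_trees = 300L) {
  p <- length(fm_train$codes)
  if (p == 0) stop("no eligible feature codes in training matrix")
  if (p < top_k) {
    warning(sprintf("only %d columns available (< top_k = %d); keeping all",
                    p, top_k))
  }
  if (p <= top_k) {
    top <- sort(fm_train$codes)
  } else {
    rf <- fit_ranger(fm_train, seed = seed, n_trees = n_trees,
                     importance = "impurity")
    gini <- rf$variable.importance[fm_train$codes]
    ord <- order(-gini, fm_train$codes)
    top <- fm_train$codes[ord][seq_len(top_k)]
  }
  extra <- sort(setdiff(intersect(curated_codes, fm_train$codes), top))
  c(top, extra)
}

fit_ranger <- function(fm, seed, n_trees, importance = "none") {
  y <- factor(fm$rows$note_label, levels = c(0L, 1L))
  ranger::ranger(x = dense_x(fm), y = y, num.trees = n_trees,
                 importance = importance, seed = seed, num.threads = 1,
                 respect.unordered.factors = "ignore")
}

#' Train the note-level classification forest
#'
#' A random forest of `n_trees` classification trees (canonical defaults:
#' sqrt(p) candidate features per split, unlimited depth) on note rows
#' whose labels are the inherited patient labels. Deterministic given the
#' seed.
#'
#' @param fm `feature_matrix` restricted to the selected features.
#' @param seed integer seed.
#' @param n_trees number of trees (default 300).
#' @param fold optional fold label used in degenerate-fold error messages.
#' @return An `attempt_model`: list with `feature_codes`, `forest`, `seed`,
#'   `n_trees`, `training_fingerprint`.
#' @export
train_forest <- function(fm, seed = 1L, n_trees = 300L, fold = NULL) {
  if (nrow(fm$rows) < 2) stop("need at least 2 training notes")
  if (length(unique(fm$rows$note_label)) < 2) {
    stop("single-class training notes",
         if (!is.null(fold)) paste0(" in fold ", fold) else "",
         ": cannot fit a classifier")
  }
  forest <- fit_ranger(fm, seed = seed, n_trees = n_trees)
  model <- structure(
    list(feature_codes = fm$codes, forest = forest, seed = as.integer(seed),
         n_trees = as.integer(n_trees)),
    class = "attempt_model")
  model$training_fingerprint <- model_fingerprint(model)
  model
}

#' Fingerprint of a trained model
#'
#' MD5 digest of the serialized feature list and fitted forest structure;
#' used to verify that holdout data never influences training artifacts.
#'
#' @param model an `attempt_model`.
#' @return Hex string.
#' @export
model_fingerprint <- function(model) {
  payload <- list(codes = model$feature_codes, seed = model$seed,
                  forest = model$forest$forest,
                  oob = model$forest$prediction.error)
  raw <- serialize(payload, NULL, version = 2)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(raw, tf)
  unname(tools::md5sum(tf))
}

#' Predict a binary class for each note
#'
#' Columns are aligned to the model's feature list: codes the model never
#' saw are dropped, codes missing from `fm` are imputed as all-zero. The
#' note call is the forest majority vote.
#'
#' @param model an `attempt_model`.
#' @param fm a `feature_matrix` for the notes to score.
#' @return Named integer vector (note_id -> 0/1).
#' @export
predict_notes <- function(model, fm) {
  if (nrow(fm$rows) == 0) return(stats::setNames(integer(0), character(0)))
  x <- matrix(0, nrow = nrow(fm$rows), ncol = length(model$feature_codes),
              dimnames = list(fm$rows$note_id, model$feature_codes))
  common <- intersect(model$feature_codes, fm$codes)
  if (length(common) > 0) {
    x[, common] <- as.matrix(fm$m[, match(common, fm$codes), drop = FALSE])
  }
  pr <- stats::predict(model$forest, data = x, num.threads = 1)$predictions
  stats::setNames(as.integer(as.character(pr)), fm$rows$note_id)
}

#' Aggregate note predictions to patient classifications
#'
#' Per patient: the proportion of their scored notes called positive; the
#' patient is classified positive at cutoff `c` iff that proportion is
#' strictly greater than `c`. The strict inequality means no patient is
#' positive at cutoff 100% and a patient with zero positive notes is
#' negative even at cutoff 0%.
#'
#' @param note_preds named integer vector (note_id -> 0/1).
#' @param corpus the `note_corpus` resolving notes to patients.
#' @param grid cutoff grid (default [cutoff_grid()]).
#' @param patients optional character vector of patients expected in scope;
#'   any of them with zero scored notes are excluded with a warning.
#' @return A `patient_predictions` object: data.frame with `patient_id`,
#'   `n_notes`, `n_positive_notes`, `proportion_positive`, plus a
#'   `classified` attribute (patients x cutoffs 0/1 matrix).
#' @export
aggregate_patient <- function(note_preds, corpus, grid = cutoff_grid(),
                              patients = NULL) {
  idx <- match(names(note_preds), corpus$notes$note_id)
  if (anyNA(idx)) {
    stop("predicted note(s) not in corpus: ",
         paste(names(note_preds)[is.na(idx)], collapse = ", "))
  }
  pat <- corpus$notes$patient_id[idx]
  ids <- sort(unique(pat))
  if (!is.null(patients)) {
    missing <- setdiff(patients, ids)
    if (length(missing) > 0) {
      warning("patient(s) with zero notes in scope excluded: ",
              paste(missing, collapse = ", "))
    }
    ids <- sort(intersect(patients, ids))
  }
  keep <- pat %in% ids
  pat <- pat[keep]; preds <- note_preds[keep]
  n_notes <- tabulate(factor(pat, levels = ids), nbins = length(ids))
  n_pos <- as.integer(rowsum(as.numeric(preds), pat)[ids, 1])
  prop <- n_pos / n_notes
  classified <- outer(prop, grid, FUN = ">") * 1L
  dimnames(classified) <- list(ids, format_cutoff(grid))
  out <- data.frame(patient_id = ids, n_notes = n_notes,
                    n_positive_notes = n_pos, proportion_positive = prop,
                    stringsAsFactors = FALSE)
  attr(out, "classified") <- classified
  attr(out, "grid") <- grid
  class(out) <- c("patient_predictions", "data.frame")
  out
}

format_cutoff <- function(grid) sprintf("%d%%", round(grid * 100))

#' Extract the per-cutoff classification matrix
#'
#' @param agg a `patient_predictions`.
#' @return Integer matrix patients x cutoffs.
#' @export
patient_classifications <- function(agg) attr(agg, "classified")

patient_labels <- function(corpus, ids) {
  stats::setNames(
    corpus$patients$attempt_label[match(ids, corpus$patients$patient_id)], ids)
}

score_cutoffs <- function(agg, labels, grid = cutoff_grid()) {
  cls <- patient_classifications(agg)
  out <- list()
  for (ci in seq_along(grid)) {
    preds <- stats::setNames(cls[, ci], rownames(cls))
    cm <- confusion(preds, labels[rownames(cls)])
    mr <- metrics(cm)
    out[[ci]] <- data.frame(cutoff = grid[ci], tn = cm$tn, fn = cm$fn,
                            fp = cm$fp, tp = cm$tp,
                            sensitivity = mr$sensitivity,
                            specificity = mr$specificity,
                            ppv = mr$ppv, npv = mr$npv,
                            accuracy = mr$accuracy)
  }
  do.call(rbind, out)
}

#' Five-fold cross-validation of the note classifier
#'
#' For each fold: restrict the (already patient-filtered) matrix to the
#' fold's training notes and to codes present in them, select features,
#' fit the forest, score the fold's test patients at every grid cutoff.
#' Fold metrics are then averaged per cutoff (with min and max) to support
#' cutoff selection.
#'
#' @param corpus a `note_corpus`.
#' @param fm the full `feature_matrix` (after [filter_min_patients()]).
#' @param curated_codes curated feature codes.
#' @param folds a `fold_assignment`.
#' @param grid cutoff grid.
#' @param seed integer base seed; fold f uses `seed + f` for selection and
#'   `seed + 100 + f` for the fitted forest.
#' @param top_k,n_trees selection and forest parameters.
#' @return A `cv_result`: list with `per_fold` (fold x cutoff metric rows),
#'   `summary` (11 rows: mean/min/max of each metric), `fold_features`
#'   (list of per-fold selected feature vectors).
#' @export
cross_validate <- function(corpus, fm, curated_codes, folds,
                           grid = cutoff_grid(), seed = 1L, top_k = 50L,
                           n_trees = 300L) {
  k <- max(folds)
  labels <- patient_labels(corpus, names(folds))
  per_fold <- list()
  fold_features <- vector("list", k)
  for (f in seq_len(k)) {
    test_pat <- names(folds)[folds == f]
    train_pat <- names(folds)[folds != f]
    train_notes <- fm$rows$note_id[fm$rows$patient_id %in% train_pat]
    test_notes <- fm$rows$note_id[fm$rows$patient_id %in% test_pat]
    fm_tr <- subset_notes(fm, train_notes, drop_empty_cols = TRUE)
    feats <- select_features_fold(fm_tr, curated_codes, top_k = top_k,
                                  seed = seed + f, n_trees = n_trees)
    fold_features[[f]] <- feats
    model <- tryCatch(
      train_forest(subset_codes(fm_tr, feats), seed = seed + 100L + f,
                   n_trees = n_trees, fold = f),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e),
                               call. = FALSE))
    preds <- predict_notes(model, subset_notes(fm, test_notes))
    agg <- aggregate_patient(preds, corpus, grid, patients = test_pat)
    sc <- score_cutoffs(agg, labels, grid)
    sc <- cbind(fold = f, sc)
    per_fold[[f]] <- sc
  }
  per_fold <- do.call(rbind, per_fold)
  metric_names <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
  summ <- data.frame(cutoff = grid)
  for (mn in metric_names) {
    v <- per_fold[[mn]]
    summ[[paste0("mean_", mn)]] <- as.numeric(
      tapply(v, per_fold$cutoff, mean)[as.character(grid)])
    summ[[paste0("min_", mn)]] <- as.numeric(
      tapply(v, per_fold$cutoff, min)[as.character(grid)])
    summ[[paste0("max_", mn)]] <- as.numeric(
      tapply(v, per_fold$cutoff, max)[as.character(grid)])
  }
  structure(list(per_fold = per_fold, summary = summ,
                 fold_features = fold_features),
            class = "cv_result")
}

#' Select the operating cutoff from cross-validation means
#'
#' Default policy: among cutoffs whose mean sensitivity is at least
#' `sens_floor`, pick the one with maximal mean specificity; specificity
#' ties (e.g. along a saturated-specificity plateau) resolve toward the
#' candidate with maximal mean sensitivity, consistent with the selection
#' objective of prioritizing sensitivity without overly sacrificing
#' specificity, and any remaining exact tie breaks toward the larger
#' cutoff. If no cutoff clears the floor, maximize Youden's index (mean
#' sensitivity + mean specificity - 1), ties toward the larger cutoff. A
#' manual `override` bypasses the policy.
#'
#' @param cv_summary the `summary` data.frame of a `cv_result` (or the
#'   `cv_result` itself).
#' @param sens_floor minimum acceptable mean sensitivity (default 0.70).
#' @param override optional cutoff value returned as-is.
#' @return The selected cutoff (proportion in `[0, 1]`).
#' @export
select_cutoff <- function(cv_summary, sens_floor = 0.70, override = NULL) {
  if (inherits(cv_summary, "cv_result")) cv_summary <- cv_summary$summary
  if (!is.null(override)) {
    if (override < 0 || override > 1) stop("override cutoff outside [0, 1]")
    return(override)
  }
  if (is.null(cv_summary) || nrow(cv_summary) == 0) stop("empty cutoff table")
  ok <- cv_summary$mean_sensitivity >= sens_floor
  if (any(ok)) {
    cand <- cv_summary[ok, , drop = FALSE]
    cand <- cand[cand$mean_specificity == max(cand$mean_specificity), ,
                 drop = FALSE]
    sel <- cand$cutoff[cand$mean_sensitivity == max(cand$mean_sensitivity)]
  } else {
    youden <- cv_summary$mean_sensitivity + cv_summary$mean_specificity - 1
    sel <- cv_summary$cutoff[youden == max(youden)]
  }
  max(sel)
}

#' Fit the final model and evaluate on the holdout set
#'
#' Re-runs the identical feature-selection procedure on the full training
#' matrix (default) or takes the union of the fold feature lists
#' (`final_features = "union"`), fits the final forest, predicts every
#' holdout note, aggregates to patients, and reports counts and metrics at
#' every grid cutoff plus headline metrics at the selected cutoff and the
#' trapezoidal AUC over the grid's operating points. The split and cutoff
#' must be fixed before holdout predictions are examined; nothing here
#' feeds back into training.
#'
#' @param corpus a `note_corpus`.
#' @param fm the full `feature_matrix` (after [filter_min_patients()]).
#' @param curated_codes curated feature codes.
#' @param split a `split_assignment`.
#' @param selected_cutoff cutoff fixed by [select_cutoff()].
#' @param grid cutoff grid.
#' @param seed integer seed (selection uses `seed`, final forest
#'   `seed + 1`).
#' @param top_k,n_trees selection and forest parameters.
#' @param final_features `"reselect"` (default) or `"union"`.
#' @param fold_features fold feature lists (required for `"union"`).
#' @return List with `holdout_table` (11 rows: counts + metrics),
#'   `headline` (metrics row at `selected_cutoff`), `roc` (a `roc_curve`),
#'   `model`, `patient_predictions`, `selected_cutoff`, `features`.
#' @export
finalize_and_evaluate <- function(corpus, fm, curated_codes, split,
                                  selected_cutoff, grid = cutoff_grid(),
                                  seed = 1L, top_k = 50L, n_trees = 300L,
                                  final_features = c("reselect", "union"),
                                  fold_features = NULL) {
  final_features <- match.arg(final_features)
  train_notes <- fm$rows$note_id[fm$rows$patient_id %in% split$training_patients]
  holdout_notes <- fm$rows$note_id[fm$rows$patient_id %in% split$holdout_patients]
  fm_tr <- subset_notes(fm, train_notes, drop_empty_cols = TRUE)
  if (final_features == "reselect") {
    feats <- select_features_fold(fm_tr, curated_codes, top_k = top_k,
                                  seed = seed, n_trees = n_trees)
  } else {
    if (is.null(fold_features)) stop("final_features = \"union\" needs fold_features")
    feats <- sort(intersect(unique(unlist(fold_features)), fm_tr$codes))
  }
  model <- train_forest(subset_codes(fm_tr, feats), seed = seed + 1L,
                        n_trees = n_trees)
  preds <- predict_notes(model, subset_notes(fm, holdout_notes))
  agg <- aggregate_patient(preds, corpus, grid,
                           patients = split$holdout_patients)
  labels <- patient_labels(corpus, agg$patient_id)
  tab <- score_cutoffs(agg, labels, grid)
  cms <- lapply(seq_along(grid), function(ci) {
    confusion_matrix(tp = tab$tp[ci], fp = tab$fp[ci],
                     tn = tab$tn[ci], fn = tab$fn[ci])
  })
  roc <- roc_auc(cms, grid)
  headline <- tab[abs(tab$cutoff - selected_cutoff) < 1e-9, , drop = FALSE]
  rownames(headline) <- NULL
  list(holdout_table = tab, headline = headline, roc = roc, model = model,
       patient_predictions = agg, selected_cutoff = selected_cutoff,
       features = feats)
}

#' Run the full pipeline on a corpus
#'
#' Extraction, matrix construction, the minimum-patients filter, curated
#' resolution, the 80/20 split, 5-fold cross-validation, cutoff selection,
#' and the final holdout evaluation, with all seeds derived from one base
#' seed.
#'
#' @param corpus a `note_corpus`.
#' @param lexicon a `cui_lexicon`.
#' @param curated a `curated_lexicon`.
#' @param seed integer base seed.
#' @param fraction,k,top_k,min_patients,n_trees,sens_floor pipeline
#'   constants (defaults 0.8, 5, 50, 4, 300, 0.70).
#' @param cutoff_override optional manual cutoff.
#' @param stratified stratified train/holdout split (default `FALSE`).
#' @param final_features `"reselect"` or `"union"`.
#' @param options an [extraction_options()].
#' @param grid cutoff grid.
#' @return A `pipeline_result`: list with `split`, `folds`, `cv`,
#'   `selected_cutoff`, `final`, `curated_resolution`, `matrix_dims`,
#'   `summary` (cohort summary).
#' @export
run_pipeline <- function(corpus, lexicon = build_default_lexicon(),
                         curated = default_curated_terms(), seed = 1L,
                         fraction = 0.8, k = 5L, top_k = 50L,
                         min_patients = 4L, n_trees = 300L,
                         sens_floor = 0.70, cutoff_override = NULL,
                         stratified = FALSE,
                         final_features = "reselect",
                         options = extraction_options(),
                         grid = cutoff_grid()) {
  seed <- as.integer(seed)
  cui_sets <- extract_corpus_cuis(corpus, lexicon, options)
  fm_all <- build_note_matrix(cui_sets, corpus)
  fm <- filter_min_patients(fm_all, min_patients)
  cur <- resolve_curated(curated, corpus, lexicon, cui_sets = cui_sets,
                         options = options)
  curated_codes <- intersect(cur$codes, fm$codes)
  split <- split_train_holdout(corpus, fraction, seed = seed + 1L,
                               stratified = stratified)
  folds <- assign_folds(split, k = k, seed = seed + 2L)
  cv <- cross_validate(corpus, fm, curated_codes, folds, grid = grid,
                       seed = seed + 10L, top_k = top_k, n_trees = n_trees)
  sel <- select_cutoff(cv$summary, sens_floor = sens_floor,
                       override = cutoff_override)
  final <- finalize_and_evaluate(corpus, fm, curated_codes, split, sel,
                                 grid = grid, seed = seed + 200L,
                                 top_k = top_k, n_trees = n_trees,
                                 final_features = final_features,
                                 fold_features = cv$fold_features)
  structure(list(split = split, folds = folds, cv = cv,
                 selected_cutoff = sel, final = final,
                 curated_resolution = cur,
                 matrix_dims = c(notes = nrow(fm$rows),
                                 codes_prefilter = length(fm_all$codes),
                                 codes = length(fm$codes)),
                 summary = summarize_cohort(corpus)),
            class = "pipeline_result")
}
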