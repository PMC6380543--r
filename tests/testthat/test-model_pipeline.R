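test_that("train/holdout split is patient-level with the specified sizes", {
  co <- label_corpus(73)
  sp <- split_train_holdout(co, 0.8, seed = 3)
  expect_equal(length(sp$training_patients), 58)
  expect_equal(length(sp$holdout_patients), 15)
  expect_equal(sort(c(sp$training_patients, sp$holdout_patients)),
               sort(co$patients$patient_id))

  sp10 <- split_train_holdout(label_corpus(10), 0.8, seed = 1)
  expect_equal(length(sp10$training_patients), 8)
  expect_equal(length(sp10$holdout_patients), 2)

  # deterministic given the seed
  expect_identical(split_train_holdout(co, 0.8, seed = 3), sp)
  expect_false(identical(split_train_holdout(co, 0.8, seed = 4), sp))

  expect_error(split_train_holdout(label_corpus(4)), "at least 5")
})

test_that("fold assignment partitions training patients with sizes differing by <= 1", {
  co <- label_corpus(73)
  sp <- split_train_holdout(co, 0.8, seed = 3)
  folds <- assign_folds(sp, k = 5, seed = 9)
  sizes <- as.integer(table(folds))
  expect_equal(sort(sizes), c(11L, 11L, 12L, 12L, 12L))
  expect_equal(sort(names(folds)), sort(sp$training_patients))
  expect_true(all(folds %in% 1:5))

  # 5 patients, 5 folds -> singletons
  sp5 <- split_train_holdout(label_corpus(7), 0.8, seed = 1)
  expect_equal(length(sp5$training_patients), 6)
  f5 <- assign_folds(sp5, k = 5, seed = 1)
  expect_equal(sort(as.integer(table(f5))), c(1L, 1L, 1L, 1L, 2L))

  expect_error(assign_folds(sp5, k = 10), "exceeds")
})

test_that("patient aggregation uses the strict proportion-greater-than rule", {
  pats <- data.frame(patient_id = "P1", attempt_label = 1L)
  notes <- data.frame(note_id = sprintf("N%02d", 1:10), patient_id = "P1",
                      timestamp = as.Date("2016-01-01") + 1:10, text = "")
  co <- note_corpus(pats, notes)
  preds <- stats::setNames(c(rep(1L, 3), rep(0L, 7)), notes$note_id)
  agg <- aggregate_patient(preds, co)
  expect_equal(agg$proportion_positive, 0.3)
  cls <- patient_classifications(agg)["P1", ]
  expect_equal(unname(cls[c("0%", "10%", "20%")]), c(1L, 1L, 1L))
  expect_true(all(cls[c("30%", "40%", "50%", "60%", "70%", "80%", "90%", "100%")] == 0L))

  # zero positive notes: negative everywhere (0 > 0 is false)
  agg0 <- aggregate_patient(stats::setNames(rep(0L, 10), notes$note_id), co)
  expect_true(all(patient_classifications(agg0) == 0L))

  # all positive: positive everywhere except 100% (1 > 1 is false)
  agg1 <- aggregate_patient(stats::setNames(rep(1L, 10), notes$note_id), co)
  cls1 <- patient_classifications(agg1)["P1", ]
  expect_true(all(cls1[1:10] == 1L))
  expect_equal(unname(cls1["100%"]), 0L)

  # classification is non-increasing in the cutoff for every patient
  set.seed(2)
  predsr <- stats::setNames(sample(0:1, 10, replace = TRUE), notes$note_id)
  clsr <- patient_classifications(aggregate_patient(predsr, co))
  expect_true(all(diff(as.integer(clsr[1, ])) <= 0))

  # expected patient with zero scored notes -> warning and exclusion
  expect_warning(
    aggregate_patient(preds[1:5], co, patients = c("P1", "P2")),
    "zero notes")
})

test_that("cutoff selection applies the sensitivity-floor / max-specificity policy", {
  cv <- published_cv_means()
  expect_equal(select_cutoff(cv, sens_floor = 0.70), 0.2)

  # a dominating cutoff wins under the default policy
  dom <- data.frame(cutoff = c(0.1, 0.2),
                    mean_sensitivity = c(0.9, 0.8),
                    mean_specificity = c(0.9, 0.5))
  expect_equal(select_cutoff(dom), 0.1)

  # no cutoff above the floor -> Youden fallback
  low <- data.frame(cutoff = c(0.1, 0.2, 0.3),
                    mean_sensitivity = c(0.6, 0.5, 0.2),
                    mean_specificity = c(0.5, 0.8, 0.9))
  expect_equal(select_cutoff(low, sens_floor = 0.70), 0.2)

  # specificity ties break toward the larger cutoff
  tie <- data.frame(cutoff = c(0.1, 0.2), mean_sensitivity = c(0.9, 0.9),
                    mean_specificity = c(0.7, 0.7))
  expect_equal(select_cutoff(tie), 0.2)

  expect_equal(select_cutoff(cv, override = 0.4), 0.4)
  expect_error(select_cutoff(cv[0, ]), "empty")
})

test_that("forest training is deterministic, errors on one-class folds, and separates a separable toy", {
  # feature exactly encodes the label
  sets <- c(
    stats::setNames(lapply(1:20, function(i) "C0000001"),
                    paste0("P", rep(1:4, 5), ".s", 1:20)),
    stats::setNames(lapply(1:20, function(i) character(0)),
                    paste0("P", rep(5:8, 5), ".n", 1:20)))
  labels <- stats::setNames(c(rep(1L, 4), rep(0L, 4)), paste0("P", 1:8))
  out <- fm_from_sets(sets, labels)
  model <- train_forest(out$fm, seed = 5)
  preds <- predict_notes(model, out$fm)
  expect_equal(unname(preds), out$fm$rows$note_label)

  # identical seed -> identical predictions and fingerprint
  model2 <- train_forest(out$fm, seed = 5)
  expect_identical(predict_notes(model2, out$fm), preds)
  expect_identical(model2$training_fingerprint, model$training_fingerprint)

  # one-class training data is a degenerate fold
  ones <- fm_from_sets(sets[1:20], labels[1:4])
  expect_error(train_forest(ones$fm, seed = 1, fold = 3), "fold 3")
})

test_that("an independent forest implementation agrees on the separable toy", {
  skip_if_not_installed("randomForest")
  sets <- c(
    stats::setNames(lapply(1:20, function(i) "C0000001"),
                    paste0("P", rep(1:4, 5), ".s", 1:20)),
    stats::setNames(lapply(1:20, function(i) character(0)),
                    paste0("P", rep(5:8, 5), ".n", 1:20)))
  labels <- stats::setNames(c(rep(1L, 4), rep(0L, 4)), paste0("P", 1:8))
  out <- fm_from_sets(sets, labels)
  x <- as.matrix(out$fm$m); colnames(x) <- out$fm$codes
  set.seed(1)
  rf <- randomForest::randomForest(x, factor(out$fm$rows$note_label),
                                   ntree = 300)
  ref <- as.integer(as.character(predict(rf, x)))
  model <- train_forest(out$fm, seed = 5)
  expect_equal(unname(predict_notes(model, out$fm)), ref)
})

test_that("prediction aligns columns by code name, not position", {
  set.seed(77)
  codes <- sprintf("C%07d", 1:12)
  pats <- paste0("P", 1:6)
  labels <- stats::setNames(rep(0:1, 3), pats)
  sets <- list()
  for (i in 1:40) {
    nm <- paste0(sample(pats, 1), ".", i)
    # make code presence label-dependent so predictions are non-trivial
    lab <- labels[sub("\\..*", "", nm)]
    p <- if (lab == 1) 0.5 else 0.1
    sets[[nm]] <- codes[stats::runif(12) < p]
  }
  out <- fm_from_sets(sets, labels)
  model <- train_forest(out$fm, seed = 2)
  base <- predict_notes(model, out$fm)
  perm <- subset_codes(out$fm, sample(out$fm$codes))
  expect_identical(predict_notes(model, perm), base)

  # unseen codes are dropped; missing codes impute to zero
  alien <- fm_from_sets(list(P1.z = "C9999999"), labels["P1"])
  pz <- predict_notes(model, alien$fm)
  expect_equal(names(pz), "P1.z")
  expect_true(pz %in% c(0L, 1L))

  # empty matrix -> empty map
  none <- subset_notes(out$fm, character(0))
  expect_equal(length(predict_notes(model, none)), 0)
})

test_that("fold feature selection takes top-k Gini codes union curated-present", {
  set.seed(101)
  codes <- sprintf("C%07d", 1:30)
  pats <- paste0("P", 1:10)
  labels <- stats::setNames(rep(0:1, 5), pats)
  sets <- list()
  for (i in 1:120) {
    nm <- paste0(sample(pats, 1), ".", i)
    lab <- labels[sub("\\..*", "", nm)]
    informative <- codes[1:5][stats::runif(5) < ifelse(lab == 1, 0.6, 0.05)]
    noise <- codes[6:30][stats::runif(25) < 0.10]
    sets[[nm]] <- c(informative, noise)
  }
  out <- fm_from_sets(sets, labels)
  feats <- select_features_fold(out$fm, curated_codes = character(0),
                                top_k = 10, seed = 4)
  expect_equal(length(feats), 10)
  expect_true(mean(codes[1:5] %in% feats) >= 0.8)  # signal codes rank high

  # curated codes present in training data are appended
  cur <- c(codes[25], "C9999999")  # second one absent
  feats2 <- select_features_fold(out$fm, curated_codes = cur, top_k = 10,
                                 seed = 4)
  expect_true(codes[25] %in% feats2)
  expect_false("C9999999" %in% feats2)
  expect_equal(feats2[1:10], feats)

  # top_k >= column count keeps everything, with a warning
  expect_warning(all_feats <- select_features_fold(out$fm, character(0),
                                                   top_k = 100, seed = 4),
                 "keeping all")
  expect_equal(sort(all_feats), sort(out$fm$codes))
  # determinism
  expect_identical(select_features_fold(out$fm, character(0), top_k = 10,
                                        seed = 4), feats)
})

test_that("cross-validation scores each training patient in exactly one test fold", {
  cfg <- pipeline_config(seed = 6, n_patients = 30)
  co <- generate_cohort(cfg)
  cs <- extract_corpus_cuis(co, cfg$lexicon)
  fm <- filter_min_patients(build_note_matrix(cs, co), 4)
  sp <- split_train_holdout(co, 0.8, seed = 1)
  folds <- assign_folds(sp, k = 5, seed = 2)
  cv <- cross_validate(co, fm, character(0), folds, seed = 3, top_k = 10,
                       n_trees = 100)
  expect_equal(nrow(cv$summary), 11)
  expect_equal(cv$summary$cutoff, cutoff_grid())
  expect_named(cv$summary,
               c("cutoff",
                 as.vector(outer(c("mean_", "min_", "max_"),
                                 c("sensitivity", "specificity", "ppv",
                                   "npv", "accuracy"), paste0))),
               ignore.order = TRUE)
  # 5 folds x 11 cutoffs
  expect_equal(nrow(cv$per_fold), 55)
  # every training patient is scored once: fold patient counts sum to 24
  expect_equal(sum(cv$per_fold$tn + cv$per_fold$fn + cv$per_fold$fp +
                   cv$per_fold$tp) / 11, 24)
  # mean sensitivity is non-increasing and mean specificity non-decreasing
  expect_true(all(diff(cv$summary$mean_sensitivity) <= 1e-12))
  expect_true(all(diff(cv$summary$mean_specificity) >= -1e-12))
})

test_that("the full pipeline recovers strong synthetic signal out of sample", {
  cfg <- pipeline_config(seed = 14, n_patients = 120)
  co <- generate_cohort(cfg)
  res <- run_pipeline(co, cfg$lexicon, default_curated_terms(), seed = 5)
  expect_gte(res$final$headline$sensitivity, 0.8)
  expect_gte(res$final$roc$auc, 0.9)
  # holdout table is the full grid with counts covering all holdout patients
  expect_equal(nrow(res$final$holdout_table), 11)
  n_holdout <- length(res$split$holdout_patients)
  expect_true(all(res$final$holdout_table$tn + res$final$holdout_table$fn +
                  res$final$holdout_table$fp + res$final$holdout_table$tp ==
                  n_holdout))
})

test_that("pipeline runs are bit-reproducible and blind to holdout labels", {
  cfg <- pipeline_config(seed = 23, n_patients = 40)
  co <- generate_cohort(cfg)
  cur <- default_curated_terms()
  r1 <- suppressWarnings(run_pipeline(co, cfg$lexicon, cur, seed = 8))
  r2 <- suppressWarnings(run_pipeline(co, cfg$lexicon, cur, seed = 8))
  expect_identical(r1$final$model$training_fingerprint,
                   r2$final$model$training_fingerprint)
  expect_identical(r1$final$holdout_table, r2$final$holdout_table)
  expect_identical(r1$selected_cutoff, r2$selected_cutoff)

  # flipping every holdout label changes no trained artifact
  co_flip <- co
  idx <- co_flip$patients$patient_id %in% r1$split$holdout_patients
  co_flip$patients$attempt_label[idx] <- 1L - co_flip$patients$attempt_label[idx]
  r3 <- suppressWarnings(run_pipeline(co_flip, cfg$lexicon, cur, seed = 8))
  expect_identical(r3$split, r1$split)
  expect_identical(r3$folds, r1$folds)
  expect_identical(r3$cv$summary, r1$cv$summary)
  expect_identical(r3$selected_cutoff, r1$selected_cutoff)
  expect_identical(r3$final$model$training_fingerprint,
                   r1$final$model$training_fingerprint)
})
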