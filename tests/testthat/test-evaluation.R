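test_that("confusion cross-tabulation matches hand counts and a brute-force tally", {
  preds <- stats::setNames(c(1, 1, 0, 0, 1), paste0("P", 1:5))
  labels <- stats::setNames(c(1, 0, 0, 1, 1), paste0("P", 1:5))
  cm <- confusion(preds, labels)
  expect_equal(cm$tp, 2); expect_equal(cm$fp, 1)
  expect_equal(cm$tn, 1); expect_equal(cm$fn, 1)

  # all correct -> no errors
  cm2 <- confusion(labels, labels)
  expect_equal(cm2$fp + cm2$fn, 0)

  # key mismatch errors with the symmetric difference
  expect_error(confusion(preds[1:4], labels), "P5")
  expect_error(confusion(preds, labels[1:4]), "P5")

  set.seed(3)
  for (rep in 1:10) {
    ids <- paste0("Q", 1:30)
    p <- stats::setNames(sample(0:1, 30, replace = TRUE), ids)
    l <- stats::setNames(sample(0:1, 30, replace = TRUE), sample(ids))
    cm3 <- confusion(p, l)
    tally <- table(pred = p[ids], lab = l[ids])
    expect_equal(cm3$tp, sum(p[ids] == 1 & l[ids] == 1))
    expect_equal(cm3$tn, sum(p[ids] == 0 & l[ids] == 0))
    expect_equal(cm3$tp + cm3$fp + cm3$tn + cm3$fn, 30)
  }
})

test_that("metrics follow the standard definitions with the 0/0 -> 0 convention", {
  m <- metrics(confusion_matrix(tp = 5, fn = 1, tn = 2, fp = 7))
  expect_equal(round(m$sensitivity, 2), 0.83)
  expect_equal(round(m$specificity, 2), 0.22)
  expect_equal(round(m$ppv, 2), 0.42)
  expect_equal(round(m$npv, 2), 0.67)
  expect_equal(round(m$accuracy, 2), 0.47)

  # no actual positives: sensitivity reported as 0.0 by convention
  m2 <- metrics(confusion_matrix(tp = 0, fn = 0, tn = 5, fp = 0))
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 1)
  expect_equal(m2$ppv, 0)

  expect_error(metrics(confusion_matrix(0, 0, 0, 0)), "empty")

  set.seed(9)
  for (rep in 1:20) {
    v <- sample(0:8, 4, replace = TRUE)
    if (sum(v) == 0) v[1] <- 1
    cm <- confusion_matrix(tp = v[1], fp = v[2], tn = v[3], fn = v[4])
    mm <- metrics(cm)
    expect_equal(mm$sensitivity,
                 if (v[1] + v[4] == 0) 0 else v[1] / (v[1] + v[4]))
    expect_equal(mm$accuracy, (v[1] + v[3]) / sum(v))
  }
})

test_that("ROC anchors and degenerate points behave canonically", {
  # chance: only the extreme points
  cm_all <- confusion_matrix(tp = 5, fp = 5, tn = 0, fn = 0)   # (1,1)
  cm_none <- confusion_matrix(tp = 0, fp = 0, tn = 5, fn = 5)  # (0,0)
  rc <- roc_auc(list(cm_none, cm_all))
  expect_equal(rc$auc, 0.5)

  # a perfect operating point drives AUC to 1
  cm_perfect <- confusion_matrix(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(roc_auc(list(cm_none, cm_perfect, cm_all))$auc, 1)

  expect_error(roc_auc(list(cm_all)), "at least 2")
  expect_error(roc_auc(list(confusion_matrix(tp = 1, fp = 0, tn = 0, fn = 1),
                            cm_all)),
               "no actual negatives")
})

test_that("ROC points are monotone along nested cutoff predictions", {
  set.seed(11)
  for (rep in 1:10) {
    prop <- stats::runif(40)
    lab <- sample(0:1, 40, replace = TRUE)
    if (sum(lab) == 0 || sum(lab) == 40) next
    cms <- lapply(cutoff_grid(), function(cc) {
      pred <- as.integer(prop > cc)
      confusion_matrix(tp = sum(pred & lab), fp = sum(pred & !lab),
                       tn = sum(!pred & !lab), fn = sum(!pred & lab))
    })
    fpr <- vapply(cms, function(cm) cm$fp / (cm$fp + cm$tn), 0)
    tpr <- vapply(cms, function(cm) metrics(cm)$sensitivity, 0)
    expect_true(all(diff(fpr) <= 1e-12))
    expect_true(all(diff(tpr) <= 1e-12))
    rc <- roc_auc(cms, cutoff_grid())
    expect_gte(rc$auc, 0); expect_lte(rc$auc, 1)
  }
})

test_that("AUC of label-independent patient scores hovers at chance over 10 seeds", {
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    prop <- stats::runif(500)
    lab <- stats::rbinom(500, 1, 0.37)
    cms <- lapply(cutoff_grid(), function(cc) {
      pred <- as.integer(prop > cc)
      confusion_matrix(tp = sum(pred & lab), fp = sum(pred & !lab),
                       tn = sum(!pred & !lab), fn = sum(!pred & lab))
    })
    roc_auc(cms)$auc
  }, 0)
  expect_true(all(aucs >= 0.4 & aucs <= 0.6))
})

test_that("report tables have the published schema and are self-consistent", {
  cv <- published_cv_means()
  for (mn in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    if (!paste0("mean_", mn) %in% names(cv)) cv[[paste0("mean_", mn)]] <- 0.5
    cv[[paste0("min_", mn)]] <- 0
    cv[[paste0("max_", mn)]] <- 1
  }
  ho <- published_holdout_counts()
  mets <- lapply(seq_len(nrow(ho)), function(i) {
    metrics(confusion_matrix(tp = ho$tp[i], fp = ho$fp[i], tn = ho$tn[i],
                             fn = ho$fn[i]))
  })
  for (mn in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    ho[[mn]] <- vapply(mets, `[[`, 0, mn)
  }
  cms <- lapply(seq_len(nrow(ho)), function(i) {
    confusion_matrix(tp = ho$tp[i], fp = ho$fp[i], tn = ho$tn[i], fn = ho$fn[i])
  })
  roc <- roc_auc(cms, ho$cutoff)
  dir1 <- withr::local_tempdir()
  paths <- report_tables(cv, ho, roc, dir1)
  hod <- utils::read.csv(file.path(dir1, "holdout_performance.csv"),
                         stringsAsFactors = FALSE)
  expect_equal(names(hod), c("cutoff", "tn", "fn", "fp", "tp", "sensitivity",
                             "specificity", "ppv", "npv", "accuracy"))
  expect_equal(nrow(hod), 11)
  # printed metric columns reproduce metrics() of the printed counts at 2 dp
  for (i in seq_len(nrow(hod))) {
    mm <- metrics(confusion_matrix(tp = hod$tp[i], fp = hod$fp[i],
                                   tn = hod$tn[i], fn = hod$fn[i]))
    expect_equal(hod$sensitivity[i], round(mm$sensitivity, 2))
    expect_equal(hod$accuracy[i], round(mm$accuracy, 2))
  }
  cvd <- utils::read.csv(file.path(dir1, "cv_performance.csv"))
  expect_equal(nrow(cvd), 11)
  expect_true(file.exists(file.path(dir1, "roc.csv")))
  expect_true(file.exists(file.path(dir1, "roc.png")))

  # re-running on the same inputs gives byte-identical CSVs
  dir2 <- withr::local_tempdir()
  report_tables(cv, ho, roc, dir2)
  for (f in c("cv_performance.csv", "holdout_performance.csv", "roc.csv")) {
    a <- file.path(dir1, f); b <- file.path(dir2, f)
    expect_identical(readBin(a, "raw", file.size(a)),
                     readBin(b, "raw", file.size(b)), label = f)
  }
})
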