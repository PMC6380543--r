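#' @title Diagnostic-test metrics, per-cutoff tables, and ROC/AUC
#' @description Patient-level confusion matrices, the five headline metrics
#'   (sensitivity, specificity, PPV, NPV, accuracy; any 0/0 ratio reported
#'   as 0.0), a ROC curve over the cutoff grid's operating points with
#'   trapezoidal AUC, and CSV/figure reporting.
#' @name evaluation
NULL

#' Construct a confusion matrix
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return A `confusion_matrix` list.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("negative confusion counts")
  structure(as.list(counts), class = "confusion_matrix")
}

#' Cross-tabulate patient predictions against labels
#'
#' @param preds named 0/1 vector (patient_id -> classification).
#' @param labels named 0/1 vector (patient_id -> actual outcome); the key
#'   sets must match exactly.
#' @return A `confusion_matrix`.
#' @export
confusion <- function(preds, labels) {
  extra <- setdiff(names(preds), names(labels))
  missing <- setdiff(names(labels), names(preds))
  if (length(extra) > 0 || length(missing) > 0) {
    stop("prediction/label key mismatch; only in preds: {",
         paste(extra, collapse = ", "), "}; only in labels: {",
         paste(missing, collapse = ", "), "}")
  }
  labels <- labels[names(preds)]
  confusion_matrix(tp = sum(preds == 1 & labels == 1),
                   fp = sum(preds == 1 & labels == 0),
                   tn = sum(preds == 0 & labels == 0),
                   fn = sum(preds == 0 & labels == 1))
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Metrics of a confusion matrix
#'
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), ppv = tp/(tp+fp),
#' npv = tn/(tn+fn), accuracy = (tp+tn)/total. Any 0/0 ratio is reported
#' as 0.0; full precision is kept internally and rounding to 2 decimals
#' happens only in written reports.
#'
#' @param cm a `confusion_matrix` with at least one scored patient.
#' @return List with the five metrics.
#' @export
metrics <- function(cm) {
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total == 0) stop("empty confusion matrix: no scored patients")
  list(sensitivity = safe_div(cm$tp, cm$tp + cm$fn),
       specificity = safe_div(cm$tn, cm$tn + cm$fp),
       ppv = safe_div(cm$tp, cm$tp + cm$fp),
       npv = safe_div(cm$tn, cm$tn + cm$fn),
       accuracy = (cm$tp + cm$tn) / total)
}

#' ROC curve and trapezoidal AUC over cutoff operating points
#'
#' Each confusion matrix contributes the operating point
#' (FPR = fp/(fp+tn), TPR = sensitivity); anchors (0,0) and (1,1) are
#' appended. For integration the points are sorted by FPR and each distinct
#' FPR is represented by its maximum TPR (the attainable ROC envelope along
#' the cutoff grid; duplicate FPRs therefore contribute zero width), then
#' the trapezoid rule is applied.
#'
#' @param cms list of `confusion_matrix` objects (>= 2 operating points).
#' @param cutoffs optional cutoff value per confusion matrix (for the
#'   returned point table).
#' @return A `roc_curve`: list with `points` (data.frame `fpr`, `tpr`,
#'   `cutoff`, anchors included with `NA` cutoff) and `auc`.
#' @export
roc_auc <- function(cms, cutoffs = NULL) {
  if (length(cms) < 2) stop("need at least 2 operating points")
  fpr <- vapply(cms, function(cm) {
    if (cm$fp + cm$tn == 0) {
      stop("FPR undefined: no actual negatives among scored patients")
    }
    cm$fp / (cm$fp + cm$tn)
  }, 0)
  tpr <- vapply(cms, function(cm) metrics(cm)$sensitivity, 0)
  if (is.null(cutoffs)) cutoffs <- rep(NA_real_, length(cms))
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                    cutoff = c(NA, cutoffs, NA))
  ord <- order(pts$fpr, pts$tpr)
  pts <- pts[ord, , drop = FALSE]
  rownames(pts) <- NULL
  env_tpr <- tapply(pts$tpr, pts$fpr, max)
  ux <- as.numeric(names(env_tpr))
  o <- order(ux)
  ux <- ux[o]; uy <- as.numeric(env_tpr)[o]
  auc <- sum(diff(ux) * (utils::head(uy, -1) + utils::tail(uy, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

fmt2 <- function(x) sprintf("%.2f", x)

#' Write cross-validation and holdout report tables plus the ROC figure
#'
#' Writes `cv_performance.csv` (one row per cutoff: mean and min-max of
#' each metric across folds), `holdout_performance.csv` (one row per
#' cutoff: confusion counts and metrics), `roc.csv`, and `roc.png` into
#' `rundir`. Metric values are formatted to 2 decimals; re-running with the
#' same inputs yields byte-identical CSVs.
#'
#' @param cv_summary the `summary` of a `cv_result` (or the `cv_result`).
#' @param holdout_table the 11-row holdout table from
#'   [finalize_and_evaluate()].
#' @param roc a `roc_curve`.
#' @param rundir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
report_tables <- function(cv_summary, holdout_table, roc, rundir) {
  if (inherits(cv_summary, "cv_result")) cv_summary <- cv_summary$summary
  dir.create(rundir, showWarnings = FALSE, recursive = TRUE)
  metric_names <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")

  cvout <- data.frame(cutoff = format_cutoff(cv_summary$cutoff))
  for (mn in metric_names) {
    cvout[[mn]] <- sprintf("%s (%s-%s)",
                           fmt2(cv_summary[[paste0("mean_", mn)]]),
                           fmt2(cv_summary[[paste0("min_", mn)]]),
                           fmt2(cv_summary[[paste0("max_", mn)]]))
  }
  cv_path <- file.path(rundir, "cv_performance.csv")
  utils::write.csv(cvout, cv_path, row.names = FALSE, quote = TRUE)

  ho <- data.frame(cutoff = format_cutoff(holdout_table$cutoff),
                   tn = holdout_table$tn, fn = holdout_table$fn,
                   fp = holdout_table$fp, tp = holdout_table$tp)
  for (mn in metric_names) ho[[mn]] <- fmt2(holdout_table[[mn]])
  ho_path <- file.path(rundir, "holdout_performance.csv")
  utils::write.csv(ho, ho_path, row.names = FALSE, quote = TRUE)

  rc <- data.frame(fpr = fmt2(roc$points$fpr), tpr = fmt2(roc$points$tpr),
                   cutoff = ifelse(is.na(roc$points$cutoff), "",
                                   format_cutoff(roc$points$cutoff)))
  roc_path <- file.path(rundir, "roc.csv")
  utils::write.csv(rc, roc_path, row.names = FALSE, quote = TRUE)

  png_path <- file.path(rundir, "roc.png")
  grDevices::png(png_path, width = 600, height = 600)
  graphics::plot(roc$points$fpr, roc$points$tpr, type = "b", pch = 19,
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate (1 - specificity)",
                 ylab = "True positive rate (sensitivity)",
                 main = sprintf("Holdout ROC over cutoff grid (AUC = %.2f)",
                                roc$auc))
  graphics::abline(0, 1, lty = 2, col = "grey50")
  grDevices::dev.off()

  invisible(c(cv_path, ho_path, roc_path, png_path))
}
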