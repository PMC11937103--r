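# Confusion-matrix metrics: precision, recall, F1, accuracy, MCC. Positive
# class is fixed to "converter" (label 1) and all reports state it.

#' 2x2 confusion counts
#'
#' @param y_true,y_pred equal-length vectors with values in `{0, 1}`; class 1
#'   (converter) is the positive class.
#' @return list of class `pd_confusion` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(y_true, y_pred) {
  assert_that(length(y_true) == length(y_pred), "length mismatch")
  assert_that(all(y_true %in% c(0, 1)) && all(y_pred %in% c(0, 1)),
              "labels must be in {0, 1}")
  structure(list(tp = sum(y_true == 1 & y_pred == 1),
                 fp = sum(y_true == 0 & y_pred == 1),
                 fn = sum(y_true == 1 & y_pred == 0),
                 tn = sum(y_true == 0 & y_pred == 0)),
            class = "pd_confusion")
}

# 0/0 ratios are defined as 0 with a warning (keeps batch evaluation total).
safe_div <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s: 0/0 defined as 0", what))
    return(0)
  }
  num / den
}

#' Metrics from a confusion matrix
#'
#' precision = tp/(tp+fp); recall = tp/(tp+fn); F1 = harmonic mean of the
#' two; accuracy = (tp+tn)/total; MCC = (tp*tn - fp*fn) /
#' sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)). Zero denominators yield 0 with a
#' warning.
#'
#' @param cm a `pd_confusion` (or list with tp/fp/fn/tn).
#' @param horizon_days optional horizon annotation.
#' @param n_censored_excluded optional count of censored subjects excluded.
#' @return list of class `pd_metric_report`.
#' @export
compute_metrics <- function(cm, horizon_days = NA_integer_,
                            n_censored_excluded = NA_integer_) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  assert_that(total > 0, "empty confusion matrix")
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  accuracy <- (tp + tn) / total
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    warning("MCC: 0/0 defined as 0")
    0
  } else (tp * tn - fp * fn) / mcc_den
  structure(list(precision = precision, recall = recall, f1 = f1,
                 accuracy = accuracy, mcc = mcc,
                 positive_class = "converter",
                 horizon_days = horizon_days,
                 n_censored_excluded = n_censored_excluded,
                 counts = list(tp = tp, fp = fp, fn = fn, tn = tn)),
            class = "pd_metric_report")
}

#' @export
print.pd_metric_report <- function(x, ...) {
  cat(sprintf(paste0("<pd_metric_report> positive class = %s",
                     if (!is.na(x$horizon_days)) ", horizon %d days" else "",
                     "\n"),
              x$positive_class, x$horizon_days))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f  accuracy %.4f  MCC %.4f\n",
              x$precision, x$recall, x$f1, x$accuracy, x$mcc))
  invisible(x)
}

#' Evaluate a predictions table against a labels table
#'
#' Joins on `subject_id` (must resolve uniquely), excludes and counts
#' subjects censored at the horizon, and returns the metric report; optionally
#' writes the report (JSON) and the confusion matrix (CSV) with run metadata.
#'
#' @param predictions data.frame with `subject_id`, `label_pred` (and
#'   optionally `horizon_days`).
#' @param labels data.frame with `subject_id`, `horizon_days`, `label`
#'   (censored rows absent, as written by [horizon_label_table()]).
#' @param horizon horizon in days to evaluate.
#' @param report_file optional JSON output path.
#' @param cm_file optional confusion-matrix CSV output path.
#' @param meta optional named list of run metadata (seed, config hash).
#' @return a `pd_metric_report`.
#' @export
evaluate_run <- function(predictions, labels, horizon,
                         report_file = NULL, cm_file = NULL, meta = list()) {
  lab <- labels[labels$horizon_days == horizon, , drop = FALSE]
  if ("horizon_days" %in% names(predictions))
    predictions <- predictions[is.na(predictions$horizon_days) |
                                 predictions$horizon_days == horizon, ,
                               drop = FALSE]
  assert_that(!anyDuplicated(predictions$subject_id),
              "duplicate subject_id in predictions")
  assert_that(!anyDuplicated(lab$subject_id),
              "duplicate subject_id in labels")
  unknown <- setdiff(predictions$subject_id, lab$subject_id)
  censored_ids <- unknown[unknown %in% labels$subject_id]
  truly_unknown <- setdiff(unknown, labels$subject_id)
  assert_that(length(truly_unknown) == 0,
              paste("unmatched subject ids:",
                    paste(truly_unknown, collapse = ", ")))
  keep <- predictions$subject_id %in% lab$subject_id
  m <- merge(predictions[keep, , drop = FALSE], lab, by = "subject_id")
  cm <- confusion(m$label, m$label_pred)
  rep <- compute_metrics(cm, horizon_days = horizon,
                         n_censored_excluded = length(censored_ids))
  if (!is.null(report_file)) {
    out <- c(rep[c("precision", "recall", "f1", "accuracy", "mcc",
                   "positive_class", "horizon_days",
                   "n_censored_excluded")],
             list(counts = rep$counts), meta)
    jsonlite::write_json(out, report_file, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(cm_file)) {
    utils::write.csv(data.frame(tp = cm$tp, fp = cm$fp, fn = cm$fn,
                                tn = cm$tn, horizon_days = horizon),
                     cm_file, row.names = FALSE)
  }
  rep
}
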