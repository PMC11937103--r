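test_that("confusion counts match a brute-force tally", {
  expect_equal(unclass(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)))[1:4],
               list(tp = 2L, fp = 0L, fn = 0L, tn = 2L), ignore_attr = TRUE)
  y <- c(1, 0, 1, 0)
  expect_equal(confusion(y, 1 - y)$tp, 0)
  expect_equal(confusion(y, 1 - y)$tn, 0)
  set.seed(3)
  yt <- sample(0:1, 50, replace = TRUE)
  yp <- sample(0:1, 50, replace = TRUE)
  cm <- confusion(yt, yp)
  tally <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in 1:50) {
    k <- if (yt[i] == 1 && yp[i] == 1) "tp" else if (yt[i] == 0 && yp[i] == 1)
      "fp" else if (yt[i] == 1) "fn" else "tn"
    tally[k] <- tally[k] + 1
  }
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               tally, ignore_attr = TRUE)
  expect_error(confusion(c(0, 1), c(1)), "length")
  expect_error(confusion(c(0, 2), c(1, 0)), "\\{0, 1\\}")
})

test_that("metric formulas reproduce hand-computed values", {
  perfect <- compute_metrics(list(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(unlist(perfect[c("precision", "recall", "f1", "accuracy",
                                "mcc")]),
               c(precision = 1, recall = 1, f1 = 1, accuracy = 1, mcc = 1))
  inverted <- compute_metrics(list(tp = 0, fp = 5, fn = 5, tn = 0))
  expect_equal(inverted$accuracy, 0)
  expect_equal(inverted$mcc, -1)
  m <- compute_metrics(list(tp = 45, fp = 5, fn = 10, tn = 40))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 45 / 55)
  expect_equal(m$f1, 2 * 0.9 * (45 / 55) / (0.9 + 45 / 55))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$mcc, (45 * 40 - 5 * 10) /
                 sqrt(50) / sqrt(55) / sqrt(45) / sqrt(50))
  expect_warning(compute_metrics(list(tp = 0, fp = 0, fn = 2, tn = 3)),
                 "0/0")
  expect_error(compute_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0)),
               "empty")
})

test_that("MCC and F1 stay within their bounds on an exhaustive grid", {
  for (tp in 0:6) for (fp in 0:6) for (fn in 0:6) for (tn in 0:6) {
    if (tp + fp + fn + tn == 0) next
    m <- suppressWarnings(compute_metrics(list(tp = tp, fp = fp,
                                               fn = fn, tn = tn)))
    expect_true(m$mcc >= -1 - 1e-12 && m$mcc <= 1 + 1e-12)
    if (tp + fp > 0 && tp + fn > 0 && tp > 0) {
      lo <- min(m$precision, m$recall); hi <- max(m$precision, m$recall)
      expect_true(m$f1 >= lo - 1e-12 && m$f1 <= hi + 1e-12)
    }
  }
})

test_that("swapping the positive class and predictions behaves symmetrically", {
  set.seed(4)
  for (i in 1:20) {
    cm <- as.list(setNames(sample(0:6, 4, replace = TRUE),
                           c("tp", "fp", "fn", "tn")))
    if (sum(unlist(cm)) == 0) next
    m <- suppressWarnings(compute_metrics(cm))
    # relabeling both truth and prediction (swap positive class) maps
    # tp<->tn, fp<->fn and must preserve MCC and accuracy
    sw <- list(tp = cm$tn, fp = cm$fn, fn = cm$fp, tn = cm$tp)
    ms <- suppressWarnings(compute_metrics(sw))
    expect_equal(ms$mcc, m$mcc, tolerance = 1e-12)
    expect_equal(ms$accuracy, m$accuracy, tolerance = 1e-12)
    # swapping truth with prediction transposes the matrix: fp<->fn,
    # so precision and recall exchange
    tr <- list(tp = cm$tp, fp = cm$fn, fn = cm$fp, tn = cm$tn)
    mt <- suppressWarnings(compute_metrics(tr))
    expect_equal(mt$precision, m$recall, tolerance = 1e-12)
    expect_equal(mt$recall, m$precision, tolerance = 1e-12)
  }
})

test_that("evaluate_run joins, censors, reports and writes artifacts", {
  labels <- data.frame(subject_id = c("A", "B", "D"),
                       horizon_days = 365L, label = c(1L, 0L, 1L))
  preds <- data.frame(subject_id = c("A", "B", "C", "D"),
                      horizon_days = 365L, label_pred = c(1L, 0L, 1L, 1L))
  # C is censored (present in the label table at another horizon)
  labels_all <- rbind(labels,
                      data.frame(subject_id = "C", horizon_days = 180L,
                                 label = 0L))
  dir <- withr::local_tempdir()
  rf <- file.path(dir, "report.json"); cf <- file.path(dir, "cm.csv")
  rep <- evaluate_run(preds, labels_all, 365L, report_file = rf,
                      cm_file = cf, meta = list(seed = 1))
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$n_censored_excluded, 1)
  expect_true(file.exists(rf) && file.exists(cf))
  js <- jsonlite::read_json(rf)
  expect_equal(js$accuracy, 1)
  expect_equal(js$positive_class, "converter")
  # unknown subject id fails loudly, naming the id
  preds2 <- rbind(preds, data.frame(subject_id = "ZZZ", horizon_days = 365L,
                                    label_pred = 0L))
  expect_error(evaluate_run(preds2, labels_all, 365L), "ZZZ")
})
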