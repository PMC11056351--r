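test_that("confusion matrix counts true-by-predicted pairs", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), c("a", "b"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2,
                                   dimnames = list(true = c("a", "b"),
                                                   predicted = c("a", "b"))))
  # perfect predictions give a diagonal matrix of class totals
  t3 <- rep(1:3, times = c(4, 2, 5))
  cmp <- confusion_matrix(t3, t3, letters[1:3])
  expect_equal(diag(unclass(cmp)), c(a = 4L, b = 2L, c = 5L))
  expect_equal(sum(unclass(cmp)) - sum(diag(unclass(cmp))), 0L)
  # row sums equal the true-class sample counts
  set.seed(60)
  tr <- sample(1:4, 100, TRUE); pr <- sample(1:4, 100, TRUE)
  cmr <- confusion_matrix(tr, pr, letters[1:4])
  expect_equal(unname(rowSums(unclass(cmr))), as.vector(table(factor(tr, 1:4))))
  expect_error(confusion_matrix(c(1, 5), c(1, 1), letters[1:3]), "out of range")
})

test_that("one-vs-rest counts decompose the confusion matrix", {
  cm <- matrix(c(5, 2, 1, 3), 2)   # rows true: [[5,1],[2,3]]
  counts <- one_vs_rest_counts(cm, 1)
  expect_equal(as.list(counts), list(TP = 5, FP = 2, FN = 1, TN = 3))
  # diagonal matrix: no false positives or negatives anywhere
  d <- diag(c(4, 6, 2))
  for (i in 1:3) {
    ci <- one_vs_rest_counts(d, i)
    expect_equal(ci$FP + ci$FN, 0)
    expect_equal(sum(unlist(ci)), 12)
  }
  # conservation for random matrices
  set.seed(61)
  r <- matrix(rpois(16, 5), 4)
  for (i in 1:4) expect_equal(sum(unlist(one_vs_rest_counts(r, i))), sum(r))
})

test_that("per-class metrics reproduce printed worked examples", {
  # recall from raw counts: 411 of 426 -> 96.48; 210 of 212 -> 99.06
  m1 <- class_metrics(tibble::tibble(TP = 411, FP = 0, FN = 15, TN = 0))
  expect_equal(scmix:::round2(m1$re), 96.48)
  m2 <- class_metrics(tibble::tibble(TP = 210, FP = 0, FN = 2, TN = 0))
  expect_equal(scmix:::round2(m2$re), 99.06)
  # all-correct counts give 100 everywhere
  m3 <- class_metrics(tibble::tibble(TP = 7, FP = 0, FN = 0, TN = 0))
  expect_equal(unlist(m3), c(acc = 100, pr = 100, re = 100, f1 = 100))
  # zero denominators report 0 and warn (once for precision, once for recall)
  w <- testthat::capture_warnings(
    m4 <- class_metrics(tibble::tibble(TP = 0, FP = 0, FN = 0, TN = 5)))
  expect_length(w, 2)
  expect_match(w, "zero denominator", all = TRUE)
  expect_equal(m4$pr, 0)
  expect_equal(m4$f1, 0)
})

test_that("macro averaging reproduces the printed table summaries", {
  # 4-class per-class accuracies -> macro 95.66
  acc4 <- c(92.88, 99.8, 98.47, 91.48)
  rows <- tibble::tibble(acc = acc4, pr = 0, re = 0, f1 = 0)
  expect_equal(scmix:::round2(macro_summary(rows)$acc), 95.66)
  # 5-class accuracies -> macro 98.68
  acc5 <- c(99.91, 99.27, 97.75, 98.21, 98.25)
  expect_equal(scmix:::round2(mean(acc5)), 98.68)
  # single class: macro equals that row
  one <- tibble::tibble(acc = 91.2, pr = 80.1, re = 70.5, f1 = 75)
  expect_equal(macro_summary(one), one)
  expect_error(macro_summary(one[0, ]), "at least one")
})

test_that("the report reproduces the 4-class recall column from raw counts", {
  # diagonal correct counts and per-class totals; off-diagonal errors spread
  # to the next class (recall depends only on the row)
  diag_counts <- c(523, 617, 582, 549)
  totals <- c(623, 620, 620, 624)
  cm <- diag(diag_counts)
  for (i in 1:4) cm[i, (i %% 4) + 1] <- cm[i, (i %% 4) + 1] + totals[i] - diag_counts[i]
  rep4 <- metrics_report(cm, c("EO", "L", "M", "N"))
  expect_equal(scmix:::round2(rep4$re[1:4]), c(83.95, 99.52, 93.87, 87.98))
  # identity confusion matrix: every metric is 100
  repi <- metrics_report(diag(c(3, 4, 5)))
  expect_true(all(abs(as.matrix(repi[, c("acc", "pr", "re", "f1")]) - 100) < 1e-9))
})

test_that("per-class recall and precision agree with an independent library", {
  skip_if_not_installed("caret")
  set.seed(62)
  for (rep in 1:5) {
    c_n <- sample(3:5, 1)
    cm <- matrix(rpois(c_n * c_n, 8) + 1, c_n)
    dimnames(cm) <- list(true = letters[1:c_n], predicted = letters[1:c_n])
    # caret expects rows = prediction, columns = reference
    oracle <- caret::confusionMatrix(as.table(t(cm)))
    by <- oracle$byClass
    rows <- metrics_report(cm)
    for (i in seq_len(c_n)) {
      expect_equal(rows$re[i] / 100, unname(by[i, "Sensitivity"]),
                   tolerance = 1e-10)
      expect_equal(rows$pr[i] / 100, unname(by[i, "Pos Pred Value"]),
                   tolerance = 1e-10)
    }
  }
})

test_that("macro and micro metrics coincide for identical class counts", {
  # symmetric confusion structure: every class has the same TP/FP/FN/TN
  cm <- matrix(2, 3, 3)
  diag(cm) <- 10
  rep3 <- metrics_report(cm)
  macro <- rep3[rep3$class == "MACRO", ]
  micro_pr <- sum(diag(cm)) / sum(cm) * 100  # pooled TP over pooled TP+FP
  expect_equal(macro$pr, micro_pr, tolerance = 1e-10)
  expect_equal(macro$re, micro_pr, tolerance = 1e-10)
})

test_that("one-vs-rest macro accuracy exceeds pooled accuracy with errors", {
  set.seed(63)
  for (rep in 1:5) {
    c_n <- sample(3:5, 1)
    cm <- diag(rpois(c_n, 50) + 20)
    cm[1, 2] <- 5  # guarantee off-diagonal mass
    cm <- cm + matrix(rpois(c_n * c_n, 2), c_n)
    rep_cm <- metrics_report(cm)
    macro_acc <- rep_cm$acc[rep_cm$class == "MACRO"]
    expect_gt(macro_acc, pooled_accuracy(cm))
  }
})

test_that("CSV and JSON report serializations agree field for field", {
  dir <- withr::local_tempdir()
  cm <- confusion_matrix(c(1, 1, 2, 2, 2), c(1, 2, 2, 2, 1), c("x", "y"))
  rep2 <- metrics_report(cm)
  paths <- write_report(rep2, cm, dir)
  csv <- utils::read.csv(paths["metrics_csv"])
  js <- jsonlite::fromJSON(paths["metrics_json"])
  expect_equal(csv$class, js$class)
  for (col in c("acc", "pr", "re", "f1"))
    expect_equal(csv[[col]], js[[col]], tolerance = 1e-12)
  ccsv <- utils::read.csv(paths["confusion_csv"], row.names = 1)
  expect_equal(unname(as.matrix(ccsv)), unname(unclass(cm)))
})
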