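# Confusion-matrix metrics against hand-computed oracles.

test_that("confusion matrices count actual-by-predicted pairs", {
  cm <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2)
  expect_equal(unclass(cm), matrix(c(1, 0, 1, 1), 2), ignore_attr = TRUE)

  perfect <- confusion_matrix(0:2, 0:2, 3)
  expect_equal(unclass(perfect), diag(3), ignore_attr = TRUE)

  expect_error(confusion_matrix(c(0, 3), c(0, 1), 2), "lie in")
})

test_that("one-vs-rest counts decompose the matrix and always sum to the
           total", {
  cm <- as_confusion(matrix(c(5, 1, 2, 7), 2, byrow = TRUE))
  bc <- binary_counts(cm, 0)
  expect_equal(bc, list(TP = 5, FP = 2, FN = 1, TN = 7))

  d <- as_confusion(diag(c(3, 4, 5)))
  for (i in 0:2) {
    bci <- binary_counts(d, i)
    expect_equal(bci$FP, 0)
    expect_equal(bci$FN, 0)
  }

  set.seed(11)
  for (r in 1:20) {
    m <- as_confusion(matrix(rpois(16, 5), 4))
    for (i in 0:3) {
      bci <- binary_counts(m, i)
      expect_equal(bci$TP + bci$FP + bci$FN + bci$TN, sum(m))
    }
  }
})

test_that("accuracy and misclassification are complementary percentages", {
  d <- as_confusion(diag(c(3, 4, 5)))
  expect_equal(accuracy(d), 100)
  expect_equal(misclassification(d), list(count = 0, rate = 0))

  # seven errors out of 545 test samples
  cm545 <- as_confusion(matrix(c(538, 7, 0, 0), 2, byrow = TRUE))
  expect_equal(misclassification(cm545)$count, 7)
  expect_equal(misclassification(cm545)$rate, 100 * 7 / 545)
  expect_equal(round(misclassification(cm545)$rate, 4), 1.2844)

  set.seed(12)
  for (r in 1:10) {
    m <- as_confusion(matrix(rpois(9, 10) + 1, 3))
    expect_equal(accuracy(m) + misclassification(m)$rate, 100)
  }
  expect_error(accuracy(as_confusion(matrix(0, 2, 2))), "empty")
})

test_that("per-class rates match hand arithmetic", {
  bc <- list(TP = 90, FP = 5, FN = 10, TN = 95)
  expect_equal(sensitivity(bc), 0.90)
  expect_equal(precision(bc), 90 / 95)
  expect_equal(round(precision(bc), 4), 0.9474)
  expect_equal(f1_score(bc), 2 * (90 / 95) * 0.9 / (90 / 95 + 0.9))
  expect_equal(round(f1_score(bc), 4), 0.9231)
  expect_equal(specificity(bc), 0.95)

  perfect <- list(TP = 10, FP = 0, FN = 0, TN = 30)
  expect_equal(c(sensitivity(perfect), specificity(perfect),
                 precision(perfect), f1_score(perfect)), rep(1, 4))

  degenerate <- list(TP = 0, FP = 0, FN = 0, TN = 10)
  expect_warning(s <- sensitivity(degenerate), "zero denominator")
  expect_equal(s, 0)
})

test_that("MCC matches the binary closed form and its bounds", {
  cm <- as_confusion(matrix(c(90, 10, 5, 95), 2, byrow = TRUE))
  expect_equal(mcc(cm), 8500 / sqrt(95 * 100 * 100 * 105))
  expect_equal(round(mcc(cm), 4), 0.8511)

  expect_equal(mcc(as_confusion(diag(c(5, 5, 5)))), 1)
  # all predictions in one class: zero denominator convention
  one_col <- as_confusion(matrix(c(10, 0, 10, 0), 2, byrow = TRUE))
  expect_equal(mcc(one_col), 0)
})

test_that("kappa matches hand arithmetic, and the printed variant differs", {
  cm <- as_confusion(matrix(c(20, 5, 10, 65), 2, byrow = TRUE))
  # Po = 0.85, Pe = (25*30 + 75*70) / 100^2 = 0.6
  expect_equal(kappa_score(cm), 0.625)
  expect_equal(kappa_score(cm, strict_printed = TRUE), 0.25 / 0.15)

  expect_equal(kappa_score(as_confusion(diag(c(4, 6)))), 1)
  # independent marginals: Po = Pe = 0.58
  indep <- as_confusion(matrix(c(9, 21, 21, 49), 2, byrow = TRUE))
  expect_equal(kappa_score(indep), 0)

  single <- as_confusion(matrix(c(7, 0, 0, 0), 2, byrow = TRUE))
  expect_error(kappa_score(single), "degenerate")
})

test_that("kappa and MCC are 1 exactly on diagonal matrices and below 1
           otherwise", {
  set.seed(13)
  for (r in 1:20) {
    m <- matrix(rpois(9, 6), 3)
    diag(m) <- diag(m) + 1            # ensure every class appears
    cm <- as_confusion(m)
    if (all(m[row(m) != col(m)] == 0)) {
      expect_equal(kappa_score(cm), 1)
      expect_equal(mcc(cm), 1)
    } else {
      expect_lt(kappa_score(cm), 1)
      expect_lt(mcc(cm), 1)
      expect_gte(mcc(cm), -1)
    }
  }
})

test_that("per-class rates are equivariant under class permutation", {
  set.seed(14)
  m <- matrix(rpois(9, 8) + 1, 3)
  perm <- c(3, 1, 2)
  rep1 <- metric_report(as_confusion(m))
  rep2 <- metric_report(as_confusion(m[perm, perm]))
  expect_equal(rep2$per_class$precision, rep1$per_class$precision[perm])
  expect_equal(rep2$per_class$f1, rep1$per_class$f1[perm])
  expect_equal(rep2$overall$accuracy, rep1$overall$accuracy)
  expect_equal(rep2$overall$mcc, rep1$overall$mcc)
  expect_equal(rep2$overall$kappa, rep1$overall$kappa)
})

test_that("fold-mean matrices average element-wise", {
  a <- as_confusion(matrix(c(1, 0, 0, 1), 2))
  b <- as_confusion(matrix(c(3, 0, 2, 1), 2))
  expect_equal(unclass(mean_confusion(list(a, a))), unclass(a),
               ignore_attr = TRUE)
  expect_equal(unclass(mean_confusion(list(a, b))),
               matrix(c(2, 0, 1, 1), 2), ignore_attr = TRUE)
  expect_error(mean_confusion(list()), "no matrices")
  expect_error(mean_confusion(list(a, as_confusion(diag(3)))), "shape")
})

test_that("confusion CSV and metric reports round-trip", {
  cm <- confusion_matrix(c(0, 0, 1, 2, 2), c(0, 1, 1, 2, 0), 3,
                         c("debris", "mucosa", "stroma"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(cm, path)
  expect_equal(readLines(path, n = 1),
               "\"Actual\\Predicted\",\"debris\",\"mucosa\",\"stroma\"")
  back <- read_confusion_csv(path)
  expect_equal(unclass(back), unclass(cm), ignore_attr = TRUE)

  rep <- metric_report(cm)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rep, jpath)
  js <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(js$overall$accuracy, rep$overall$accuracy)
  expect_equal(js$per_class$f1, rep$per_class$f1)

  td <- tidy(cm)
  expect_equal(sum(td$n), 5)
  expect_equal(glance(rep)$accuracy, accuracy(cm))
})
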