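test_that("confusion statistics reproduce the published cohort arithmetic", {
  # training cohort: 23 cases, 27 controls
  tr <- confusion_stats(confusion_matrix_counts(tp = 21, fp = 4,
                                                tn = 23, fn = 2))
  expect_equal(round(tr$sensitivity, 3), 0.913)
  expect_equal(round(tr$specificity, 3), 0.852)
  expect_equal(round(tr$accuracy, 3), 0.880)
  expect_equal(tr$mcc, 475 / (25 * sqrt(621)), tolerance = 1e-12)
  expect_equal(round(tr$mcc, 3), 0.762)
  # validation cohort: 48 cases, 53 controls
  va <- confusion_stats(confusion_matrix_counts(tp = 42, fp = 10,
                                                tn = 43, fn = 6))
  expect_equal(round(va$sensitivity, 3), 0.875)
  expect_equal(round(va$specificity, 3), 0.811)
  expect_equal(round(va$accuracy, 3), 0.842)
})

test_that("degenerate and perfect matrices are handled", {
  perfect <- confusion_stats(confusion_matrix_counts(10, 0, 15, 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$youden, 1)
  deg <- confusion_stats(confusion_matrix_counts(0, 0, 5, 5))
  expect_equal(deg$mcc, 0)
  expect_true(deg$mcc_degenerate)
  expect_error(confusion_matrix_counts(0, 0, 0, 0),
               class = "tepsig_error_confusion")
})

test_that("statistics agree with a brute-force recount from scored samples", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 40
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    scores <- rnorm(n)
    cutoff <- median(scores)
    st <- confusion_stats(confusion_matrix(scores > cutoff, y == 1))
    sens <- sum(scores > cutoff & y == 1) / sum(y == 1)
    spec <- sum(scores <= cutoff & y == 0) / sum(y == 0)
    expect_equal(st$sensitivity, sens)
    expect_equal(st$specificity, spec)
    expect_equal(st$accuracy, mean((scores > cutoff) == (y == 1)))
    expect_equal(st$youden, sens + spec - 1, tolerance = 1e-15)
  }
})

test_that("AUC equals Mann-Whitney pair counting, ties included", {
  pair_auc <- function(scores, y) {
    cases <- scores[y == 1]; ctrls <- scores[y == 0]
    cmp <- outer(cases, ctrls, function(a, b)
      (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(62)
  for (rep in 1:8) {
    n <- 30
    y <- rep(c(0, 1), each = n / 2)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # many ties
    roc <- roc_curve(scores, y)
    expect_equal(roc$auc, pair_auc(scores, y), tolerance = 1e-12)
    expect_equal(roc$points$fpr[1], 0)
    expect_equal(roc$points$tpr[1], 0)
    expect_equal(utils::tail(roc$points$fpr, 1), 1)
    expect_equal(utils::tail(roc$points$tpr, 1), 1)
    expect_true(all(diff(roc$points$fpr) >= 0))
  }
})

test_that("AUC is invariant under monotone score transforms and matches pROC", {
  set.seed(63)
  y <- rep(c(0, 1), each = 25)
  scores <- rnorm(50) + y
  roc <- roc_curve(scores, y)
  expect_equal(roc_curve(exp(scores), y)$auc, roc$auc, tolerance = 1e-12)
  expect_equal(roc_curve(rank(scores), y)$auc, roc$auc, tolerance = 1e-12)
  ref <- pROC::roc(y, scores, quiet = TRUE, direction = "<")
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  # perfectly ranked scores
  expect_equal(roc_curve(y + 0.001 * rnorm(50) * 0, y)$auc, 1)
})

test_that("bootstrap CI is deterministic, covers the point AUC, and tightens with n", {
  set.seed(64)
  y <- rep(c(0, 1), each = 20)
  scores <- rnorm(40) + 1.2 * y
  ci1 <- auc_ci(scores, y, n_boot = 300, seed = 9)
  ci2 <- auc_ci(scores, y, n_boot = 300, seed = 9)
  expect_identical(ci1, ci2)
  point <- roc_curve(scores, y)$auc
  expect_lte(ci1$ci_low, point)
  expect_gte(ci1$ci_high, point)
  # perfect separation: upper bound 1
  sep <- c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1))
  expect_equal(auc_ci(sep, y, n_boot = 100, seed = 1)$ci_high, 1)
  # larger cohorts give a narrower interval
  set.seed(65)
  y_big <- rep(c(0, 1), each = 200)
  s_big <- rnorm(400) + 1.2 * y_big
  ci_big <- auc_ci(s_big, y_big, n_boot = 300, seed = 9)
  expect_lt(ci_big$ci_high - ci_big$ci_low, ci1$ci_high - ci1$ci_low)
  expect_error(auc_ci(rnorm(6), rep(c(0, 1), 3), seed = 1),
               class = "tepsig_error_degenerate")
})

test_that("a full report is internally consistent and JSON-serializable", {
  set.seed(66)
  y <- rep(c(0, 1), each = 15)
  scores <- rnorm(30) + 2 * y
  rep_ <- classifier_report(scores, y, n_boot = 200, seed = 3)
  expect_equal(rep_$confusion$tp + rep_$confusion$fn, 15)
  expect_equal(rep_$confusion$tn + rep_$confusion$fp, 15)
  st <- confusion_stats(confusion_matrix_counts(rep_$confusion$tp,
                                                rep_$confusion$fp,
                                                rep_$confusion$tn,
                                                rep_$confusion$fn))
  expect_equal(rep_$mcc, st$mcc)
  expect_equal(rep_$youden, st$youden)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep_, path)
  back <- read_report(path)
  expect_equal(back$auc, rep_$auc, tolerance = 1e-12)
})
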