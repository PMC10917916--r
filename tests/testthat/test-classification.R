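# Classifier presets, cross-validated evaluation and the metric suite.

test_that("the five presets carry their canonical hidden widths", {
  expect_equal(buildClassifier("narrow")$hidden, 10L)
  expect_equal(buildClassifier("medium")$hidden, 25L)
  expect_equal(buildClassifier("wide")$hidden, 100L)
  expect_equal(buildClassifier("bilayered")$hidden, c(10L, 10L))
  expect_equal(buildClassifier("trilayered")$hidden, c(10L, 10L, 10L))
  expect_error(buildClassifier("huge"), "unknown classifier preset")
})

test_that("fitted classifiers emit normalized probabilities", {
  d <- shiftedGaussians(n = 60)
  clf <- fitClassifier(buildClassifier("bilayered", seed = 1), d$X, d$y)
  P <- predict(clf, d$X)
  expect_equal(dim(P), c(60L, 2L))
  expect_equal(rowSums(P), rep(1, 60), tolerance = 1e-9)
  cls <- predict(clf, d$X, type = "class")
  expect_s3_class(cls, "factor")
})

test_that("cross-validation separates well-separated clouds", {
  d <- shiftedGaussians(n = 200, shift = 4)
  rep_ <- crossvalEvaluate(d$X, d$y, preset = "narrow", folds = 10, seed = 1)
  expect_gte(metricValues(rep_)[["accuracy"]], 95)
  expect_false(is.na(metricValues(rep_)[["auc"]]))
})

test_that("label permutation drives accuracy to chance", {
  d <- shiftedGaussians(n = 200, shift = 4)
  set.seed(3)
  yPerm <- sample(d$y)
  rep_ <- crossvalEvaluate(d$X, yPerm, preset = "narrow", folds = 10,
                           seed = 1)
  acc <- metricValues(rep_)[["accuracy"]]
  expect_gte(acc, 40)
  expect_lte(acc, 60)
})

test_that("cross-validation is deterministic given the seed", {
  d <- shiftedGaussians(n = 80)
  r1 <- crossvalEvaluate(d$X, d$y, preset = "medium", folds = 5, seed = 9)
  r2 <- crossvalEvaluate(d$X, d$y, preset = "medium", folds = 5, seed = 9)
  expect_identical(metricValues(r1), metricValues(r2))
  expect_identical(confusionMatrix(r1), confusionMatrix(r2))
  expect_error(crossvalEvaluate(d$X[1:5, ], d$y[1:5], folds = 10),
               "fewer samples|at least")
})

test_that("metric suite matches reference formulas on anchor matrices", {
  # perfect classifier
  perf <- computeMetrics(matrix(c(50, 0, 0, 50), 2))
  m <- metricValues(perf)
  expect_equal(m[["accuracy"]], 100)
  expect_equal(m[["fnr"]], 0)
  expect_equal(m[["mcc"]], 100)
  expect_equal(m[["kappa"]], 100)
  # hand-checked confusion [[45, 5], [10, 40]] (rows = truth)
  cm <- matrix(c(45, 10, 5, 40), 2)
  m2 <- metricValues(computeMetrics(cm))
  expect_equal(m2[["accuracy"]], 85)
  expect_equal(m2[["sensitivity"]], 85)
  expect_equal(m2[["mcc"]], 70.4, tolerance = 0.05)
  expect_equal(m2[["kappa"]], 70, tolerance = 1e-9)
  # published-table consistency: sensitivity 95.25 pairs with FNR 4.75
  expect_equal(100 - 95.25, 4.75)
  expect_error(computeMetrics(matrix(0, 2, 2)), "positive total")
})

test_that("metrics respect symmetry and chance-correction properties", {
  set.seed(11)
  for (i in 1:20) {
    cm <- matrix(rpois(4, 20) + 1, 2)
    m <- metricValues(computeMetrics(cm))
    # FNR identity holds for any confusion matrix
    expect_equal(m[["fnr"]], 100 - m[["sensitivity"]])
    # label swap + transpose-consistent relabeling leaves accuracy,
    # kappa and |MCC| unchanged
    cmSwap <- cm[2:1, 2:1]
    ms <- metricValues(computeMetrics(cmSwap))
    expect_equal(ms[["accuracy"]], m[["accuracy"]])
    expect_equal(ms[["kappa"]], m[["kappa"]], tolerance = 1e-9)
    expect_equal(abs(ms[["mcc"]]), abs(m[["mcc"]]), tolerance = 1e-9)
    # kappa cannot exceed accuracy once accuracy is at or above chance
    if (m[["accuracy"]] >= 50) expect_lte(m[["kappa"]], m[["accuracy"]])
  }
})
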