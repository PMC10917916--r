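# Paired Student's t analysis: published-table anchors and reference
# agreement.

meNN <- c(94.3, 94.6, 94.3, 96.2)  # medium net across the four experiments
tiNN <- c(94.9, 93.4, 93.1, 96.1)  # trilayered net

test_that("the four-experiment accuracy table reproduces the printed statistics", {
  r <- pairedTTest(meNN, tiNN)
  expect_equal(r@diffs, c(0.6, 1.2, 1.2, 0.1))
  expect_equal(r@mean, 0.775)
  expect_equal(r@sd, 0.531)           # truncated at 3 decimals
  expect_equal(round(r@t, 3), 2.919)  # sqrt(N) * mean / sd
  expect_equal(r@dof, 3)
  expect_equal(round(r@interval, 3), c(-3.182, 3.182))
  expect_true(r@inside)
})

test_that("full-precision t agrees with the reference one-sample test", {
  r <- pairedTTest(meNN, tiNN, roundIntermediates = NULL)
  ref <- t.test(abs(meNN - tiNN), mu = 0)
  expect_equal(r@t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(r@interval,
               unname(c(-1, 1) * qt(0.975, 3)), tolerance = 1e-12)
})

test_that("the statistic is symmetric in the two classifiers", {
  r1 <- pairedTTest(meNN, tiNN)
  r2 <- pairedTTest(tiNN, meNN)
  expect_equal(r1@t, r2@t)
  expect_equal(r1@diffs, r2@diffs)
})

test_that("identical accuracies yield the degenerate zero statistic", {
  r <- pairedTTest(c(90, 91), c(90, 91))
  expect_true(r@degenerate)
  expect_equal(r@t, 0)
  expect_equal(r@mean, 0)
  expect_error(pairedTTest(1:3, 1:4), "equal length")
  expect_error(pairedTTest(1, 1), "at least 2")
})
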