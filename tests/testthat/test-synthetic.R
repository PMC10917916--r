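# Synthetic generators: shape/determinism contracts and statistical
# structure verified against simple independent oracles.

test_that("image generator honours counts, geometry and determinism", {
  a <- generateMammoImages(5, size = c(64, 64), effect = 0.9, seed = 1)
  expect_s4_class(a, "MammoImageSet")
  expect_equal(nImages(a), 10L)
  expect_equal(as.vector(table(imageLabels(a))), c(5L, 5L))
  expect_true(all(vapply(images(a), function(im)
    identical(dim(im), c(64L, 64L, 3L)), logical(1))))
  rng <- range(unlist(images(a)))
  expect_true(rng[1] >= 0 && rng[2] <= 1)
  b <- generateMammoImages(5, size = c(64, 64), effect = 0.9, seed = 1)
  expect_identical(images(a), images(b))
  expect_identical(lesionMasks(a), lesionMasks(b))
  expect_error(generateMammoImages(0), "positive")
  expect_error(generateMammoImages(2, size = c(32, 32)), "64")
  expect_error(generateMammoImages(2, effect = 1.5), "0, 1")
})

test_that("malignant lesions separate classes for a masked-mean thresholder", {
  iset <- generateMammoImages(100, size = c(64, 64), effect = 0.9, seed = 7)
  # oracle: mean intensity inside the image's lesion mask (central disk
  # fallback for images without a finding)
  H <- 64; W <- 64
  disk <- (row(matrix(0, H, W)) - H / 2)^2 +
    (col(matrix(0, H, W)) - W / 2)^2 <= (H / 4)^2
  stat <- vapply(seq_len(nImages(iset)), function(i) {
    m <- lesionMasks(iset)[[i]]
    if (!any(m)) m <- disk
    mean(images(iset)[[i]][, , 1][m])
  }, numeric(1))
  y <- imageLabels(iset)
  thr <- sort(stat)
  acc <- max(vapply(thr, function(t)
    mean((stat > t) == (y == "malignant")), numeric(1)))
  expect_gte(acc, 0.9)
})

test_that("malignant images carry a marked lesion; benign stay low contrast", {
  iset <- smallImageSet()
  mal <- imageLabels(iset) == "malignant"
  expect_true(all(vapply(lesionMasks(iset)[mal], any, logical(1))))
})

test_that("correlated pair generator plants the requested correlation", {
  p <- generateCorrelatedPair(200, 8, 8, r = 0.7, seed = 3)
  q <- generateCorrelatedPair(200, 8, 8, r = 0.7, seed = 3)
  expect_identical(p$F1, q$F1)
  expect_identical(p$F2, q$F2)
  expect_equal(nrow(p$F1), nrow(p$F2))

  # noise-free shared latent: classical CCA sees correlation ~ 1
  p1 <- generateCorrelatedPair(300, 4, 4, r = 1, seed = 2, noise = 1e-4)
  expect_gt(cancor(p1$F1, p1$F2)$cor[1], 0.99)
  # independent views stay low at n = 500
  p0 <- generateCorrelatedPair(500, 4, 4, r = 0, seed = 4)
  expect_lt(cancor(p0$F1, p0$F2)$cor[1], 0.2)
  expect_error(generateCorrelatedPair(100, 4, 4, r = 1.2), "0, 1")
  expect_error(generateCorrelatedPair(4, 4, 4, r = 0.5), "exceed 4")
})

test_that("planted canonical correlation is calibrated across seeds", {
  # classical-CCA oracle; low view dimension keeps the estimator's own
  # overfitting bias well below the tolerance
  for (r in c(0.3, 0.7, 1.0)) {
    est <- vapply(1:20, function(s) {
      p <- generateCorrelatedPair(500, 4, 4, r = r, seed = s)
      cancor(p$F1, p$F2)$cor[1]
    }, numeric(1))
    expect_lt(abs(mean(est) - r), 0.05)
  }
})

test_that("selection benchmark plants informative columns only where stated", {
  b <- generateSelectionBenchmark(300, 10, 90, seed = 1)
  expect_equal(ncol(b$X), 100L)
  expect_length(b$informativeIdx, 10L)
  # per-column two-sample t oracle
  tstat <- abs(vapply(seq_len(ncol(b$X)), function(j)
    t.test(b$X[b$y == "benign", j], b$X[b$y == "malignant", j])$statistic,
    numeric(1)))
  expect_gt(mean(tstat[b$informativeIdx]),
            mean(tstat[-b$informativeIdx]) + 2)
  expect_error(generateSelectionBenchmark(300, 0, 10), ">= 1")
  c2 <- generateSelectionBenchmark(300, 10, 90, seed = 1)
  expect_identical(b$X, c2$X)
  expect_identical(b$informativeIdx, c2$informativeIdx)
})
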