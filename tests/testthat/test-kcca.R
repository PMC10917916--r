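# Gaussian kernels, centering, the regularized kernel-CCA eigenproblem and
# entropy-weighted fusion.

test_that("Gaussian kernel has unit diagonal and the closed-form off-diagonal", {
  F <- rbind(c(0, 0), c(1, 1))
  K <- gaussianKernel(F, sigma = 1)$K
  expect_equal(diag(K), c(1, 1))
  expect_equal(K[1, 2], exp(-1), tolerance = 1e-12)
  # bandwidth limit: all entries -> 1
  Kbig <- gaussianKernel(matrix(rnorm(20), 10, 2), sigma = 1e6)$K
  expect_true(all(abs(Kbig - 1) < 1e-9))
  expect_error(gaussianKernel(F, sigma = -1), "> 0")
})

test_that("kernel centering annihilates means, constants, and is idempotent", {
  K <- gaussianKernel(matrix(rnorm(30), 15, 2))$K
  Kc <- centerKernel(K)
  expect_lt(max(abs(rowMeans(Kc))), 1e-10)
  expect_lt(max(abs(colMeans(Kc))), 1e-10)
  expect_equal(centerKernel(Kc), Kc, tolerance = 1e-10)
  expect_equal(centerKernel(matrix(1, 8, 8)), matrix(0, 8, 8))
})

test_that("identical kernels give canonical correlation 1", {
  K <- centerKernel(gaussianKernel(matrix(rnorm(40), 20, 2))$K)
  sol <- solveKCCA(K, K, reg = 1e-6)
  expect_equal(sol@rho, 1, tolerance = 1e-3)
})

test_that("linear-kernel hook matches classical CCA", {
  pair <- generateCorrelatedPair(40, 3, 3, r = 0.6, seed = 5, noise = 0.3)
  Ku <- centerKernel(tcrossprod(scale(pair$F1, scale = FALSE)))
  Kv <- centerKernel(tcrossprod(scale(pair$F2, scale = FALSE)))
  sol <- solveKCCA(Ku, Kv, reg = 1e-8)
  expect_equal(sol@rho, cancor(pair$F1, pair$F2)$cor[1], tolerance = 1e-3)
  # the solution satisfies the stated normalization
  expect_equal(sum((Ku %*% sol@xi)^2), 1, tolerance = 1e-6)
  expect_equal(sum((Kv %*% sol@eta)^2), 1, tolerance = 1e-6)
})

test_that("Gaussian kernel CCA recovers a planted correlation", {
  pair <- generateCorrelatedPair(300, 8, 8, r = 0.8, seed = 2)
  fused <- fuseFeatures(pair$F1, pair$F2, reg = 1e-3)
  expect_lt(abs(canonicalCorrelation(fused) - 0.8), 0.15)
  # independent views under stronger regularization stay low
  pair0 <- generateCorrelatedPair(300, 8, 8, r = 0, seed = 3)
  fused0 <- fuseFeatures(pair0$F1, pair0$F2, reg = 1e-1)
  expect_lt(canonicalCorrelation(fused0), 0.3)
})

test_that("rho is invariant to a common row permutation", {
  pair <- generateCorrelatedPair(60, 5, 5, r = 0.7, seed = 9)
  r1 <- canonicalCorrelation(fuseFeatures(pair$F1, pair$F2))
  set.seed(1); perm <- sample(60)
  r2 <- canonicalCorrelation(fuseFeatures(pair$F1[perm, ], pair$F2[perm, ]))
  expect_equal(r1, r2, tolerance = 1e-8)
})

test_that("histogram entropy hits its closed-form anchor cases", {
  expect_equal(shannonEntropy(rep(3.7, 50)), 0)
  # exactly uniform occupancy over 4 bins
  expect_equal(shannonEntropy(c(0.1, 0.35, 0.6, 0.85), bins = 4), 2)
  # balanced two-value column: one fair coin bit
  expect_equal(shannonEntropy(rep(c(0, 1), 20), bins = 2), 1)
  expect_error(shannonEntropy(rnorm(5), bins = 1), ">= 2")
})

test_that("fusion concatenates, weights by entropy, and keeps provenance", {
  pair <- generateCorrelatedPair(50, 3, 2, r = 0.5, seed = 4)
  fused <- fuseFeatures(pair$F1, pair$F2)
  expect_equal(dim(fusedValues(fused)), c(50L, 5L))
  expect_equal(fused@provenance$source, c(rep("F1", 3), rep("F2", 2)))
  expect_equal(fused@provenance$column, c(1:3, 1:2))
  expect_equal(nrow(fusedValues(fused)), nrow(pair$F1))

  # constant columns get weight zero and become zero columns
  F1 <- cbind(pair$F1, constant = 1)
  fused2 <- fuseFeatures(F1, pair$F2)
  expect_equal(entropyWeights(fused2)[4], 0, ignore_attr = TRUE)
  expect_true(all(fusedValues(fused2)[, 4] == 0))

  # minimal widths
  f11 <- fuseFeatures(pair$F1[, 1, drop = FALSE], pair$F2[, 1, drop = FALSE])
  expect_equal(ncol(fusedValues(f11)), 2L)
  expect_error(fuseFeatures(pair$F1[1:10, ], pair$F2), "same number of rows")
})
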