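# Quantum GNDO: operator-level hand anchors, stubbed-draw identities,
# bounds feasibility, and the wrapper selector contracts.

test_that("population initialization respects the box and seed", {
  pop <- initPopulation(6, 3, bounds = c(-2, 5), seed = 1)
  expect_equal(dim(pop$positions), c(6L, 3L))
  expect_true(all(pop$positions >= -2 & pop$positions <= 5))
  expect_identical(pop, initPopulation(6, 3, bounds = c(-2, 5), seed = 1))
  # degenerate box collapses every coordinate
  expect_true(all(initPopulation(4, 2, c(0, 0), seed = 1)$positions == 0))
  expect_error(initPopulation(3, 2), ">= 4")
})

test_that("penalty factor matches its closed forms and branch symmetry", {
  expect_equal(penaltyFactor(1, 0.37, 0.2, 0.9), 0)
  expect_equal(penaltyFactor(exp(-1), 0, 0.1, 0.5), 1)
  g1 <- 0.3; g2 <- 0.81
  expect_equal(penaltyFactor(g1, g2, 0.9, 0.1),
               -penaltyFactor(g1, g2, 0.1, 0.9))
  expect_error(penaltyFactor(0, 0.5, 0.1, 0.2), "0, 1")
})

test_that("local exploitation reproduces the scalar hand computation", {
  # population holding values 1 (candidate), 3 (best), 2 -> mean K = 2
  P <- matrix(c(1, 3, 2), 3, 1)
  f <- c(5, 1, 9)
  z <- localExploitation(P, f, j = 1, bounds = c(-10, 10), ct = 0.5)
  expect_equal(z, 2 + sqrt(2 / 3) * 0.5, tolerance = 1e-12)
  # ct = 0 lands exactly on the generalized mean
  expect_equal(localExploitation(P, f, 1, c(-10, 10), ct = 0), 2)
  # a collapsed population is a fixed point for any penalty
  Pc <- matrix(1.5, 4, 2)
  expect_equal(localExploitation(Pc, rep(1, 4), 2, c(-10, 10), ct = 7),
               c(1.5, 1.5))
})

test_that("global exploration honours the fitness-directed differences", {
  P <- matrix(c(0, 1, 2, 3, 4, 5, 6, 7), 4, 2)
  f <- c(0.1, 0.9, 0.5, 0.2)
  d0 <- list(l = c(2, 3, 4), rho = 0.7, g3 = 0, g4 = 0)
  expect_equal(globalExploration(P, f, 1, c(-10, 10), draws = d0), P[1, ])
  # f(Vj) < f(Vl1): v1 = Vj - Vl1
  d1 <- list(l = c(2, 3, 4), rho = 1, g3 = 1, g4 = 0)
  expect_equal(globalExploration(P, f, 1, c(-10, 10), draws = d1),
               P[1, ] + (P[1, ] - P[2, ]))
  # worse candidate: direction reverses
  d2 <- list(l = c(1, 3, 4), rho = 1, g3 = 1, g4 = 0)
  expect_equal(globalExploration(P, f, 2, c(-10, 10), draws = d2),
               P[2, ] + (P[1, ] - P[2, ]))
  expect_error(globalExploration(P[1:3, ], f[1:3], 1), "too small")
})

test_that("random exploration indices are distinct from the candidate", {
  set.seed(42)
  for (i in 1:1000) {
    l <- sample(setdiff(1:6, 3), 3)
    expect_false(3 %in% l)
    expect_equal(length(unique(l)), 3L)
  }
  # operator keeps positions inside the box under extreme stubbed draws
  P <- matrix(runif(8, 0, 1), 4, 2)
  f <- runif(4)
  for (i in 1:200) {
    d <- list(l = sample(2:4, 3), rho = runif(1), g3 = rnorm(1, sd = 50),
              g4 = rnorm(1, sd = 50))
    z <- globalExploration(P, f, 1, c(0, 1), draws = d)
    expect_true(all(z >= 0 & z <= 1))
  }
})

test_that("quantum update matches its scalar anchor and boundary cases", {
  # theta 0.5 blends pbest 1 and gbest 3 into attractor 2; jump = 2
  z <- quantumUpdate(vj = 0, pbest = 1, gbest = 3, Gbest = 2, beta = 1,
                     bounds = c(-10, 10),
                     draws = list(theta = 0.5, u = exp(-1), t = 0.3))
  expect_equal(z, 4)
  # t > 0.5 flips the sign of the jump
  zm <- quantumUpdate(0, 1, 3, 2, 1, c(-10, 10),
                      draws = list(theta = 0.5, u = exp(-1), t = 0.9))
  expect_equal(zm, 0)
  # u = 1: the log term vanishes
  expect_equal(quantumUpdate(0, 1, 3, 2, 1, c(-10, 10),
                             draws = list(theta = 0.5, u = 1, t = 0.3)), 2)
  # Vj = Gbest: distance term vanishes for any u
  expect_equal(quantumUpdate(2, 1, 3, 2, 5, c(-10, 10),
                             draws = list(theta = 0.5, u = 0.1, t = 0.3)), 2)
})

test_that("the continuous optimizer descends and records a monotone history", {
  r <- qgndoOptimize(function(x) sum((x - 1)^2), D = 3, n = 12, iters = 40,
                     bounds = c(-5, 5), seed = 3)
  expect_lt(r$cost, 1e-3)
  expect_true(all(diff(r$history) <= 1e-12))
  r2 <- qgndoOptimize(function(x) sum((x - 1)^2), D = 3, n = 12, iters = 40,
                      bounds = c(-5, 5), seed = 3)
  expect_identical(r$best, r2$best)
})

test_that("selection cost follows the error/sparsity trade-off formula", {
  b <- generateSelectionBenchmark(60, 4, 6, seed = 2)
  # empty mask is assigned the worst cost, not an error
  expect_equal(selectionFitness(rep(FALSE, 10), b$X, b$y)$cost, 1)
  # plug-in arithmetic: perfect accuracy, all columns
  expect_equal(0.99 * (1 - 1) + 0.01 * 1, 0.01)
  expect_equal(0.99 * (1 - 0) + 0.01 * (1 / 100), 0.9901)
  # the published operating point: accuracy 96.5%, 1572 of 4096 columns
  expect_equal(0.99 * (1 - 0.965) + 0.01 * (1572 / 4096), 0.0385,
               tolerance = 1e-3)
})

test_that("the selector is deterministic, monotone, and handles iters = 0", {
  b <- generateSelectionBenchmark(80, 3, 7, seed = 5)
  cfg <- list(n = 6, iters = 4, seed = 2,
              classifierCfg = list(preset = "narrow", maxit = 40))
  s1 <- selectFeatures(b$X, b$y, cfg)
  s2 <- selectFeatures(b$X, b$y, cfg)
  expect_identical(selectionMask(s1), selectionMask(s2))
  expect_identical(selectionHistory(s1), selectionHistory(s2))
  expect_true(all(diff(selectionHistory(s1)) <= 1e-12))
  expect_gte(sum(selectionMask(s1)), 1L)
  s0 <- selectFeatures(b$X, b$y, list(n = 6, iters = 0, seed = 2))
  expect_s4_class(s0, "SelectionResult")
  yOne <- factor(rep("benign", 80), levels = c("benign", "malignant"))
  expect_error(selectFeatures(b$X, yOne, cfg), "both classes")
})
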