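# Quantum-behaved generalized normal distribution optimization (Q-GNDO).
#
# GNDO alternates local exploitation - sampling around a generalized mean
# built from the candidate, the population best, and the population mean,
# with a generalized standard deviation and a log-cosine penalty factor -
# and global exploration mixing fitness-directed differences of three
# random individuals. The quantum mechanism adds a second move sampled
# around an attractor blending the personal and global bests, with a
# log-uniform jump scaled by the distance to the mean personal best and a
# contraction-expansion coefficient that shrinks linearly over iterations.
# Acceptance is greedy (a trial replaces its candidate only on strict
# improvement), so the best-cost trajectory is nonincreasing.

#' Initialize a Q-GNDO population
#'
#' Each coordinate is drawn uniformly inside the search box.
#'
#' @param n population size (`>= 4`; global exploration needs three distinct
#'   others).
#' @param D dimensionality.
#' @param bounds numeric `c(Zmin, Zmax)`.
#' @param seed integer seed.
#' @return list with `positions` (n x D matrix), `iteration = 0`.
#' @export
initPopulation <- function(n, D, bounds = c(0, 1), seed = 1L) {
  stopIfNot(n >= 4, "`n` must be >= 4")
  stopIfNot(D >= 1, "`D` must be >= 1")
  stopIfNot(length(bounds) == 2L && bounds[1] <= bounds[2], "bad bounds")
  withSeed(seed, {
    P <- matrix(bounds[1] + runif(n * D) * (bounds[2] - bounds[1]), n, D)
    list(positions = P, iteration = 0L, bounds = bounds)
  })
}

#' Penalty factor of the local-exploitation move
#'
#' `-log(g1) * cos(2 pi g2)` when `x <= y` and `-log(g1) * cos(2 pi g2 + pi)`
#' otherwise; the two branches are negatives of each other.
#'
#' @param gamma1 in `(0, 1]` (`0` is a log singularity).
#' @param gamma2,x,y numbers in `[0, 1]`.
#' @return numeric scalar.
#' @export
penaltyFactor <- function(gamma1, gamma2, x, y) {
  stopIfNot(gamma1 > 0 && gamma1 <= 1, "`gamma1` must lie in (0, 1]")
  if (x <= y) -log(gamma1) * cos(2 * pi * gamma2)
  else -log(gamma1) * cos(2 * pi * gamma2 + pi)
}

clampRows <- function(z, bounds) pmin(pmax(z, bounds[1]), bounds[2])

#' Local exploitation move
#'
#' Trial = generalized mean + generalized standard deviation x penalty
#' factor, where the mean blends the candidate, the best individual and the
#' population mean, and the deviation is the root mean square spread of the
#' three around that mean.
#'
#' @param positions n x D population matrix.
#' @param fitness length-n cost vector (lower is better).
#' @param j candidate index.
#' @param bounds search box.
#' @param ct optional penalty factor (drawn via [penaltyFactor()] from four
#'   uniforms when `NULL`).
#' @return trial position (length D), clamped into the box.
#' @export
localExploitation <- function(positions, fitness, j, bounds = c(0, 1),
                              ct = NULL) {
  vbest <- positions[which.min(fitness), ]
  K <- colMeans(positions)
  vj <- positions[j, ]
  delta <- (vj + vbest + K) / 3
  cj <- sqrt(((vj - delta)^2 + (vbest - delta)^2 + (K - delta)^2) / 3)
  if (is.null(ct))
    ct <- penaltyFactor(runif(1, .Machine$double.eps, 1), runif(1),
                        runif(1), runif(1))
  clampRows(delta + cj * ct, bounds)
}

#' Global exploration move
#'
#' Mixes two fitness-directed difference vectors built from three random
#' individuals distinct from the candidate: `v1` points from the worse to
#' the better of (candidate, l1) and `v2` likewise for (l2, l3); the trial is
#' `Vj + rho*|g3|*v1 + (1-rho)*|g4|*v2`.
#'
#' @inheritParams localExploitation
#' @param draws optional list overriding the random quantities (`l` =
#'   indices, `rho`, `g3`, `g4`) for stubbed tests.
#' @return trial position, clamped.
#' @export
globalExploration <- function(positions, fitness, j, bounds = c(0, 1),
                              draws = NULL) {
  n <- nrow(positions)
  stopIfNot(n >= 4, "population too small for global exploration")
  if (is.null(draws)) {
    l <- sample(setdiff(seq_len(n), j), 3L)
    rho <- runif(1); g3 <- rnorm(1); g4 <- rnorm(1)
  } else {
    l <- draws$l; rho <- draws$rho; g3 <- draws$g3; g4 <- draws$g4
  }
  vj <- positions[j, ]
  v1 <- if (fitness[j] < fitness[l[1]]) vj - positions[l[1], ]
        else positions[l[1], ] - vj
  v2 <- if (fitness[l[2]] < fitness[l[3]])
          positions[l[2], ] - positions[l[3], ]
        else positions[l[3], ] - positions[l[2], ]
  clampRows(vj + rho * abs(g3) * v1 + (1 - rho) * abs(g4) * v2, bounds)
}

#' Quantum update move
#'
#' Attractor `Omega = theta*pbest + (1-theta)*gbest`; the trial is
#' `Omega -/+ beta * |Gbest - Vj| * ln(1/u)` with the minus branch taken
#' when `t > 0.5`, where `Gbest` is the mean of the personal bests and
#' `beta` the contraction-expansion coefficient.
#'
#' @param vj current position of the candidate.
#' @param pbest personal best position of the candidate.
#' @param gbest global best position.
#' @param Gbest mean of all personal bests.
#' @param beta contraction-expansion coefficient.
#' @param bounds search box.
#' @param draws optional list overriding `theta`, `u`, `t`.
#' @return trial position, clamped.
#' @export
quantumUpdate <- function(vj, pbest, gbest, Gbest, beta = 1,
                          bounds = c(0, 1), draws = NULL) {
  if (is.null(draws)) {
    theta <- runif(1); u <- runif(1); tt <- runif(1)
  } else {
    theta <- draws$theta; u <- draws$u; tt <- draws$t
  }
  omega <- theta * pbest + (1 - theta) * gbest
  jump <- beta * abs(Gbest - vj) * log(1 / u)
  z <- if (tt > 0.5) omega - jump else omega + jump
  clampRows(z, bounds)
}

#' Minimize a function with quantum GNDO
#'
#' The hybrid loop: per candidate per iteration a GNDO move (fair coin
#' between local exploitation and global exploration) followed by a quantum
#' move, each accepted only on strict cost improvement.
#'
#' @param fn objective, `fn(x)` over length-`D` vectors (lower is better).
#' @param D dimensionality.
#' @param n population size.
#' @param iters iterations (`0` returns the best initial candidate).
#' @param bounds search box `c(Zmin, Zmax)`.
#' @param seed integer seed.
#' @param betaRange linear contraction-expansion schedule, start to end.
#' @return list with `best` (position), `cost`, `history` (best cost per
#'   iteration, nonincreasing), `fitnessRatio` diagnostic.
#' @examples
#' r <- qgndoOptimize(function(x) sum(x^2), D = 2, n = 20, iters = 50,
#'                    bounds = c(-10, 10), seed = 1)
#' r$cost
#' @export
qgndoOptimize <- function(fn, D, n = 30L, iters = 100L, bounds = c(-10, 10),
                          seed = 1L, betaRange = c(1, 0.5)) {
  pop <- initPopulation(n, D, bounds, seed)
  P <- pop$positions
  withSeed(deriveSeed(seed, "qgndo-loop"), {
    f <- apply(P, 1, fn)
    pbest <- P; pbestF <- f
    gi <- which.min(f)
    history <- numeric(iters)
    fratio <- numeric(iters)
    for (tau in seq_len(iters)) {
      beta <- if (iters > 1)
        betaRange[1] + (betaRange[2] - betaRange[1]) * (tau - 1) / (iters - 1)
      else betaRange[1]
      Gbest <- colMeans(pbest)
      for (j in seq_len(n)) {
        trial <- if (runif(1) < 0.5)
          localExploitation(P, f, j, bounds)
        else globalExploration(P, f, j, bounds)
        ft <- fn(trial)
        if (ft < f[j]) { P[j, ] <- trial; f[j] <- ft }
        trial <- quantumUpdate(P[j, ], pbest[j, ], pbest[which.min(pbestF), ],
                               Gbest, beta, bounds)
        ft <- fn(trial)
        if (ft < f[j]) { P[j, ] <- trial; f[j] <- ft }
        if (f[j] < pbestF[j]) { pbest[j, ] <- P[j, ]; pbestF[j] <- f[j] }
      }
      gi <- which.min(pbestF)
      history[tau] <- pbestF[gi]
      fratio[tau] <- mean(abs(pbestF[gi] / pmax(abs(f), 1e-300)))
    }
    if (iters == 0L) { history <- min(f); fratio <- NA_real_ }
    gi <- which.min(pbestF)
    list(best = pbest[gi, ], cost = pbestF[gi],
         history = if (iters > 0L) history else numeric(0),
         fitnessRatio = fratio)
  })
}

#' Wrapper-selection cost of a feature mask
#'
#' `cost = 0.99 * (1 - cvAccuracy) + 0.01 * (selected / D)`: classification
#' error of the wrapped classifier on the selected columns (cross-validated)
#' plus a small sparsity pressure. An empty mask is assigned the worst cost
#' 1 rather than an error, keeping the search total.
#'
#' @param mask logical vector over the columns of `X`.
#' @param X feature matrix.
#' @param y labels.
#' @param classifierCfg list: `preset`, `maxit`, `lambda` for the wrapped
#'   classifier.
#' @param folds cross-validation folds.
#' @param seed integer seed (fold assignment and classifier init).
#' @param foldAssign optional precomputed fold assignment.
#' @return list with `cost` and `accuracy`.
#' @export
selectionFitness <- function(mask, X, y,
                             classifierCfg = list(preset = "narrow",
                                                  maxit = 80L,
                                                  lambda = 1e-3),
                             folds = 3L, seed = 1L, foldAssign = NULL) {
  y <- labelsToFactor(y)
  D <- ncol(X)
  if (!any(mask)) return(list(cost = 1, accuracy = 0))
  if (is.null(foldAssign))
    foldAssign <- stratifiedFolds(y, folds, deriveSeed(seed, "fit-folds"))
  acc <- crossvalAccuracy(X[, mask, drop = FALSE], y, foldAssign,
                          preset = classifierCfg$preset %||% "narrow",
                          maxit = classifierCfg$maxit %||% 80L,
                          lambda = classifierCfg$lambda %||% 1e-3,
                          seed = seed)
  list(cost = 0.99 * (1 - acc) + 0.01 * (sum(mask) / D), accuracy = acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantum-GNDO wrapper feature selection
#'
#' Runs the hybrid Q-GNDO loop over continuous positions in `[0, 1]^D`,
#' binarizing each candidate at `threshold` and scoring it with
#' [selectionFitness()]. Identical masks are cached, and acceptance is
#' greedy, so the best-cost history is nonincreasing. Deterministic given
#' the seed.
#'
#' @param X feature matrix (N x D).
#' @param y labels (both classes must be present).
#' @param cfg list of controls: `n` (population, default 20), `iters`
#'   (default 30), `seed`, `classifierCfg`, `folds` (default 3), `bounds`
#'   (default `c(0, 1)`), `threshold` (default 0.5), `betaRange`.
#' @return a [SelectionResult-class].
#' @export
selectFeatures <- function(X, y, cfg = list()) {
  X <- asFeatureMatrix(X)
  y <- labelsToFactor(y)
  stopIfNot(nlevels(droplevels(y)) == 2L,
            "both classes must be present in `y`")
  n <- cfg$n %||% 20L
  iters <- cfg$iters %||% 30L
  seed <- cfg$seed %||% 1L
  folds <- cfg$folds %||% 3L
  bounds <- cfg$bounds %||% c(0, 1)
  threshold <- cfg$threshold %||% 0.5
  betaRange <- cfg$betaRange %||% c(1, 0.5)
  clfCfg <- cfg$classifierCfg %||% list(preset = "narrow", maxit = 80L,
                                        lambda = 1e-3)
  D <- ncol(X)
  foldAssign <- stratifiedFolds(y, folds, deriveSeed(seed, "sel-folds"))

  cache <- new.env(hash = TRUE, parent = emptyenv())
  evalMask <- function(z) {
    mask <- z > threshold
    key <- paste(as.integer(mask), collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    r <- selectionFitness(mask, X, y, clfCfg, folds = folds, seed = seed,
                          foldAssign = foldAssign)
    cache[[key]] <- r
    r
  }
  fn <- function(z) evalMask(z)$cost

  res <- qgndoOptimize(fn, D = D, n = n, iters = iters, bounds = bounds,
                       seed = seed, betaRange = betaRange)
  bestEval <- evalMask(res$best)
  mask <- res$best > threshold
  if (!any(mask)) mask[which.max(res$best)] <- TRUE  # degenerate guard
  new("SelectionResult", mask = as.logical(mask), cost = bestEval$cost,
      accuracy = bestEval$accuracy,
      history = if (length(res$history)) res$history else bestEval$cost,
      fitnessRatio = as.numeric(res$fitnessRatio), seed = as.integer(seed))
}
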