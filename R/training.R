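#' Hyperparameter record for network training
#'
#' Defaults are the Bayesian-optimization result used for the full-scale
#' models: learning rate 0.000241, momentum 0.776, 50 epochs, mini-batch 64,
#' SGD with momentum.
#'
#' @param learningRate positive learning rate.
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param epochs positive integer epoch count.
#' @param minibatch positive integer mini-batch size.
#' @param optimizer only `"sgdm"` is supported.
#' @return a named list of class `hyperParams`.
#' @export
hyperParams <- function(learningRate = 0.000241, momentum = 0.776,
                        epochs = 50L, minibatch = 64L, optimizer = "sgdm") {
  stopIfNot(learningRate >= 0, "`learningRate` must be >= 0")
  stopIfNot(momentum >= 0 && momentum < 1, "`momentum` must lie in [0, 1)")
  stopIfNot(epochs >= 1, "`epochs` must be a positive integer")
  stopIfNot(minibatch >= 1, "`minibatch` must be a positive integer")
  stopIfNot(identical(optimizer, "sgdm"), "only the 'sgdm' optimizer exists")
  structure(list(learningRate = learningRate, momentum = momentum,
                 epochs = as.integer(epochs),
                 minibatch = as.integer(minibatch), optimizer = optimizer),
            class = "hyperParams")
}

#' Stratified 50:50 train/test split
#'
#' Splits an image set so that each class contributes (to within one sample)
#' the requested fraction to the training partition. Deterministic given the
#' seed.
#'
#' @param imageSet a [MammoImageSet-class].
#' @param seed integer seed.
#' @param fraction training fraction (default 0.5, the protocol used
#'   throughout).
#' @return list with `trainIds`, `testIds`, `fraction`, `stratified`, `seed`.
#' @export
splitDataset <- function(imageSet, seed = 1L, fraction = 0.5) {
  y <- imageLabels(imageSet)
  counts <- table(y)
  stopIfNot(all(counts >= 2), "each class needs at least 2 images")
  withSeed(seed, {
    train <- integer(0)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      nTrain <- round(fraction * length(idx))
      train <- c(train, idx[seq_len(nTrain)])
    }
    train <- sort(train)
    list(trainIds = train,
         testIds = setdiff(seq_along(y), train),
         fraction = fraction, stratified = TRUE, seed = as.integer(seed))
  })
}

#' Subset an image set
#'
#' @param imageSet a [MammoImageSet-class].
#' @param ids integer indices to keep.
#' @return a [MammoImageSet-class].
#' @export
subsetImages <- function(imageSet, ids) {
  new("MammoImageSet",
      images = images(imageSet)[ids],
      labels = factor(as.character(imageLabels(imageSet)[ids]),
                      levels = c("benign", "malignant")),
      lesionMasks = if (length(lesionMasks(imageSet)))
        lesionMasks(imageSet)[ids] else list(),
      seed = imageSet@seed,
      params = c(imageSet@params, list(subset = ids)))
}

rotateCW <- function(m) t(m[nrow(m):1, , drop = FALSE])

applyImageOp <- function(im, op) {
  d <- dim(im)
  out <- switch(op,
    orig = im,
    hflip = im[, d[2]:1, , drop = FALSE],
    vflip = im[d[1]:1, , , drop = FALSE],
    rot90 = array(apply(im, 3, rotateCW), dim = d[c(2, 1, 3)]),
    rot180 = im[d[1]:1, d[2]:1, , drop = FALSE])
  out
}

applyMaskOp <- function(m, op) {
  switch(op,
    orig = m,
    hflip = m[, ncol(m):1, drop = FALSE],
    vflip = m[nrow(m):1, , drop = FALSE],
    rot90 = rotateCW(m),
    rot180 = m[nrow(m):1, ncol(m):1, drop = FALSE])
}

#' Geometric augmentation: flips and right-angle rotations
#'
#' Expands every source image into itself plus four label-preserving
#' variants (horizontal flip, vertical flip, 90 and 180 degree rotation),
#' the minimal "traditional" augmentation set; lesion masks are transformed
#' alongside. Provenance (source index and operation) is recorded in the
#' result's `params`.
#'
#' @param imageSet a [MammoImageSet-class]; images must be square for the
#'   90-degree rotation to preserve geometry.
#' @param seed kept for interface symmetry; the operation set is
#'   deterministic.
#' @return a [MammoImageSet-class] with `5 * nImages` images.
#' @export
augmentImages <- function(imageSet, seed = 1L) {
  stopIfNot(nImages(imageSet) >= 1L, "empty image set")
  d <- dim(images(imageSet)[[1L]])
  stopIfNot(d[1] == d[2],
            "right-angle rotations require square images")
  ops <- c("orig", "hflip", "vflip", "rot90", "rot180")
  imgs <- list(); masks <- list()
  lab <- character(0); src <- integer(0); opTag <- character(0)
  haveMasks <- length(lesionMasks(imageSet)) > 0L
  for (i in seq_len(nImages(imageSet))) {
    for (op in ops) {
      imgs[[length(imgs) + 1L]] <- applyImageOp(images(imageSet)[[i]], op)
      if (haveMasks)
        masks[[length(masks) + 1L]] <-
          applyMaskOp(lesionMasks(imageSet)[[i]], op)
      lab <- c(lab, as.character(imageLabels(imageSet)[i]))
      src <- c(src, i); opTag <- c(opTag, op)
    }
  }
  new("MammoImageSet", images = imgs,
      labels = factor(lab, levels = c("benign", "malignant")),
      lesionMasks = masks, seed = imageSet@seed,
      params = c(imageSet@params,
                 list(augmentation = data.frame(source = src, op = opTag))))
}

#' Train a network with SGD-momentum
#'
#' Mini-batch stochastic gradient descent with momentum on the softmax
#' cross-entropy loss. Batch-norm layers use batch statistics during
#' training and exponentially averaged running statistics at inference.
#' Per-epoch mean loss is recorded in the returned network's `history`.
#'
#' @param net a [Network-class].
#' @param trainSet a [MammoImageSet-class].
#' @param hp a [hyperParams()] record.
#' @param seed integer seed controlling shuffling (training is deterministic
#'   given net, data and seed).
#' @return the trained [Network-class].
#' @export
trainNetwork <- function(net, trainSet, hp = hyperParams(), seed = 1L) {
  stopIfNot(inherits(hp, "hyperParams"), "`hp` must come from hyperParams()")
  imgs <- images(trainSet)
  y <- as.integer(imageLabels(trainSet))
  n <- length(imgs)
  stopIfNot(n >= 1L, "empty training set")
  params <- net@params
  vel <- zeroLike(params)
  lossHist <- numeric(hp$epochs)
  withSeed(seed, {
    for (ep in seq_len(hp$epochs)) {
      ord <- sample(n)
      batchLoss <- c()
      for (s in split(ord, ceiling(seq_along(ord) / hp$minibatch))) {
        xb <- imagesToBatch(imgs[s], net@spec@inputShape)
        fw <- fwNode(net@spec@graph, params, xb, "train", NULL)
        params <- fw$par  # batch-norm running statistics
        probs <- softmaxRows(fw$out)
        li <- -log(pmax(probs[cbind(seq_along(s), y[s])], 1e-300))
        loss <- mean(li)
        if (!is.finite(loss))
          stop(errorCondition(
            sprintf("training diverged (non-finite loss at epoch %d)", ep),
            class = c("trainingFailure", "error", "condition")))
        batchLoss <- c(batchLoss, loss)
        Y <- matrix(0, length(s), 2L); Y[cbind(seq_along(s), y[s])] <- 1
        dlogits <- (probs - Y) / length(s)
        bw <- bwNode(net@spec@graph, params, fw$cache, dlogits, NULL)
        upd <- sgdUpdate(params, bw$grad, vel, hp$learningRate, hp$momentum)
        params <- upd$par; vel <- upd$vel
      }
      lossHist[ep] <- mean(batchLoss)
    }
    # Batch-norm recalibration: one forward pass over the training set sets
    # the running statistics to the exact average of batch statistics under
    # the final weights, so that inference-mode normalization matches what
    # training converged to (exponential averages lag badly for channels
    # with near-zero variance).
    k <- 0L
    for (s in split(seq_len(n), ceiling(seq_len(n) / hp$minibatch))) {
      k <- k + 1L
      xb <- imagesToBatch(imgs[s], net@spec@inputShape)
      fw <- fwNode(net@spec@graph, params, xb, "train", NULL, bnm = 1 / k,
                   keepCache = FALSE)
      params <- fw$par
    }
  })
  net@params <- params
  net@trained <- TRUE
  net@history <- list(loss = lossHist, hp = hp, seed = as.integer(seed))
  net
}

# Validation accuracy of a briefly trained network; the BO objective.
proxyObjective <- function(spec, trainSub, valSub, lr, momentum,
                           proxyEpochs, minibatch, seed) {
  net <- buildNetwork(spec, seed = seed)
  hp <- hyperParams(learningRate = lr, momentum = momentum,
                    epochs = proxyEpochs, minibatch = minibatch)
  net <- trainNetwork(net, trainSub, hp, seed = seed)
  probs <- predictNetwork(net, valSub)
  pred <- max.col(probs)
  mean(pred == as.integer(imageLabels(valSub)))
}

#' Bayesian optimization of learning rate and momentum
#'
#' Gaussian-process surrogate with expected improvement over the box
#' log10(lr) in `[-5, -2]`, momentum in `[0.5, 0.99]`. Each evaluation trains
#' the architecture for a few proxy epochs on a train split and scores
#' validation accuracy. Deterministic given the seed.
#'
#' @param netName architecture name or [NetworkSpec-class].
#' @param trainSet a [MammoImageSet-class].
#' @param valFraction fraction held out for validation (default 0.25).
#' @param budget total number of objective evaluations (`>= 1`).
#' @param seed integer seed.
#' @param proxyEpochs epochs per proxy training (default 2).
#' @param minibatch mini-batch size for proxy training (default 16).
#' @return a [hyperParams()] record of the best point found, with attributes
#'   `valAccuracy` (its objective value) and `trace` (the evaluation log).
#' @export
bayesOptimize <- function(netName, trainSet, valFraction = 0.25, budget = 8L,
                          seed = 1L, proxyEpochs = 2L, minibatch = 16L) {
  stopIfNot(budget >= 1, "`budget` must be >= 1")
  stopIfNot(nImages(trainSet) >= 4L, "training set too small")
  spec <- if (is(netName, "NetworkSpec")) netName else networkSpec(netName)
  sp <- splitDataset(trainSet, seed = deriveSeed(seed, "bo-split"),
                     fraction = 1 - valFraction)
  trainSub <- subsetImages(trainSet, sp$trainIds)
  valSub <- subsetImages(trainSet, sp$testIds)

  lo <- c(-5, 0.5); hi <- c(-2, 0.99)  # log10(lr), momentum
  evalPoint <- function(z, k) {  # z in [0,1]^2
    p <- lo + z * (hi - lo)
    proxyObjective(spec, trainSub, valSub, lr = 10^p[1], momentum = p[2],
                   proxyEpochs = proxyEpochs, minibatch = minibatch,
                   seed = deriveSeed(seed, paste0("bo-eval-", k)))
  }

  withSeed(seed, {
    nInit <- min(budget, 4L)
    Z <- lhs::randomLHS(nInit, 2L)
    acc <- vapply(seq_len(nInit), function(i) evalPoint(Z[i, ], i),
                  numeric(1))
    k <- nInit
    while (k < budget) {
      cand <- matrix(runif(500 * 2), ncol = 2)
      ei <- expectedImprovement(Z, -acc, cand)
      znew <- cand[which.max(ei), ]
      k <- k + 1L
      Z <- rbind(Z, znew)
      acc <- c(acc, evalPoint(znew, k))
    }
    best <- which.max(acc)
    p <- lo + Z[best, ] * (hi - lo)
    hp <- hyperParams(learningRate = 10^p[1], momentum = p[2])
    attr(hp, "valAccuracy") <- acc[best]
    attr(hp, "trace") <- data.frame(log10lr = lo[1] + Z[, 1] * (hi - lo)[1],
                                    momentum = lo[2] + Z[, 2] * (hi - lo)[2],
                                    valAccuracy = acc,
                                    bestSoFar = cummax(acc))
    hp
  })
}

# GP posterior + expected improvement for minimization of y at candidates.
expectedImprovement <- function(X, y, cand, lengthscale = 0.3) {
  n <- nrow(X)
  sf2 <- max(stats::var(y), 1e-12)
  k <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sf2 * exp(-0.5 * pmax(d2, 0) / lengthscale^2)
  }
  K <- k(X, X) + diag(1e-6 * sf2 + 1e-10, n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y - mean(y)))
  Ks <- k(cand, X)
  mu <- mean(y) + Ks %*% alpha
  v <- forwardsolve(t(L), t(Ks))
  s2 <- pmax(sf2 - colSums(v^2), 1e-12)
  s <- sqrt(s2)
  fbest <- min(y)
  imp <- fbest - mu
  zz <- imp / s
  as.vector(imp * stats::pnorm(zz) + s * stats::dnorm(zz))
}
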