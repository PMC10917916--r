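# Shallow fully connected classifier presets and the evaluation suite.
# The five presets mirror the point-and-click neural-network family these
# names come from: "narrow"/"medium"/"wide" are single hidden layers of
# width 10/25/100, "bilayered"/"trilayered" stack two/three hidden layers
# of width 10. All use ReLU hidden activations and a two-way softmax head,
# and are fitted full-batch with a quasi-Newton optimizer (L-BFGS) under a
# small ridge penalty.

presetHidden <- function(preset) {
  switch(preset,
    narrow = 10L, medium = 25L, wide = 100L,
    bilayered = c(10L, 10L), trilayered = c(10L, 10L, 10L),
    stop("unknown classifier preset: ", preset, call. = FALSE))
}

#' Build a shallow neural-network classifier
#'
#' @param preset one of `"narrow"`, `"medium"`, `"wide"`, `"bilayered"`,
#'   `"trilayered"`.
#' @param seed integer seed for deterministic initialization.
#' @param maxit L-BFGS iteration cap (full-batch fitting).
#' @param lambda ridge penalty on the weights.
#' @return an unfitted classifier object (class `mlpClassifier`).
#' @export
buildClassifier <- function(preset = "narrow", seed = 1L, maxit = 150L,
                            lambda = 1e-4) {
  structure(list(preset = preset, hidden = presetHidden(preset),
                 seed = as.integer(seed), maxit = as.integer(maxit),
                 lambda = lambda, theta = NULL, sizes = NULL,
                 center = NULL, scale = NULL),
            class = "mlpClassifier")
}

#' Fit a shallow classifier
#'
#' Standardizes the features with training statistics, then minimizes the
#' ridge-penalized softmax cross-entropy with L-BFGS-B from a He-normal
#' start.
#'
#' @param clf an `mlpClassifier` from [buildClassifier()].
#' @param X numeric feature matrix (rows = samples).
#' @param y factor with levels benign, malignant.
#' @return the fitted classifier.
#' @export
fitClassifier <- function(clf, X, y) {
  X <- as.matrix(X)
  y <- labelsToFactor(y)
  stopIfNot(nrow(X) == length(y), "X rows and labels differ")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  sizes <- as.integer(c(ncol(X), clf$hidden, 2L))
  theta0 <- withSeed(clf$seed, {
    unlist(lapply(seq_len(length(sizes) - 1L), function(l) {
      c(rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
        numeric(sizes[l + 1L]))
    }))
  })
  yi <- as.integer(y) - 1L
  fn <- function(th) .mlpLossGrad(th, Xs, yi, sizes, clf$lambda)$loss
  gr <- function(th) .mlpLossGrad(th, Xs, yi, sizes, clf$lambda)$grad
  opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = clf$maxit))
  clf$theta <- opt$par; clf$sizes <- sizes
  clf$center <- ctr; clf$scale <- scl
  clf
}

#' @export
predict.mlpClassifier <- function(object, newdata, type = c("prob", "class"),
                                  ...) {
  type <- match.arg(type)
  stopIfNot(!is.null(object$theta), "classifier has not been fitted")
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$center, "-"),
              2, object$scale, "/")
  P <- .mlpPredict(object$theta, Xs, object$sizes)
  colnames(P) <- c("benign", "malignant")
  if (type == "prob") return(P)
  factor(c("benign", "malignant")[max.col(P)],
         levels = c("benign", "malignant"))
}

#' Confusion-matrix metric suite
#'
#' Computes the full performance panel from a 2x2 confusion matrix
#' (rows = truth, columns = prediction, order benign then malignant):
#' accuracy, macro-averaged sensitivity and precision, F1 (harmonic mean of
#' the macro averages), FNR (`100 - sensitivity` by construction), G-measure
#' (`sqrt(precision * sensitivity)`), Matthews correlation and Cohen's
#' kappa - all on the percent scale - plus the rank-statistic AUC when
#' held-out scores are supplied.
#'
#' @param confusion 2x2 nonnegative integer matrix with a positive total.
#' @param scores optional numeric vector of malignant-class scores for AUC.
#' @param labels optional truth factor aligned with `scores`.
#' @return a [MetricsReport-class].
#' @examples
#' computeMetrics(matrix(c(45, 10, 5, 40), 2))
#' @export
computeMetrics <- function(confusion, scores = NULL, labels = NULL) {
  cm <- matrix(as.numeric(confusion), 2L, 2L)
  stopIfNot(all(cm >= 0) && sum(cm) >= 1,
            "confusion must be nonnegative with a positive total")
  dimnames(cm) <- list(truth = c("benign", "malignant"),
                       pred = c("benign", "malignant"))
  total <- sum(cm)
  acc <- sum(diag(cm)) / total
  recall <- diag(cm) / pmax(rowSums(cm), 1e-300)
  prec <- diag(cm) / pmax(colSums(cm), 1e-300)
  sens <- mean(recall)
  precision <- mean(prec)
  f1 <- if (precision + sens > 0)
    2 * precision * sens / (precision + sens) else 0
  g <- sqrt(precision * sens)
  tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]; tp <- cm[2, 2]
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  auc <- NA_real_
  if (!is.null(scores) && !is.null(labels)) {
    labels <- labelsToFactor(labels)
    if (nlevels(droplevels(labels)) == 2L)
      auc <- as.numeric(pROC::auc(pROC::roc(
        response = labels, predictor = as.numeric(scores),
        levels = c("benign", "malignant"), direction = "<", quiet = TRUE)))
  }
  metrics <- c(accuracy = 100 * acc, sensitivity = 100 * sens,
               precision = 100 * precision, f1 = 100 * f1,
               fnr = 100 - 100 * sens, g_measure = 100 * g,
               mcc = 100 * mcc, kappa = 100 * kappa, auc = auc)
  stopifnot(abs(metrics["fnr"] - (100 - metrics["sensitivity"])) < 1e-9)
  new("MetricsReport", confusion = matrix(as.integer(round(confusion)), 2L,
                                          2L, dimnames = dimnames(cm)),
      metrics = metrics)
}

#' Stratified k-fold cross-validated evaluation
#'
#' Fits the chosen classifier preset on each training fold and pools the
#' out-of-fold predictions into a single confusion matrix from which the
#' metric suite (and the AUC of the pooled malignant-class scores) is
#' computed. Deterministic given the seed.
#'
#' @param X feature matrix.
#' @param y labels (benign/malignant).
#' @param preset classifier preset name (see [buildClassifier()]).
#' @param folds number of folds (default 10).
#' @param seed integer seed.
#' @param maxit,lambda classifier fitting controls.
#' @return a [MetricsReport-class].
#' @export
crossvalEvaluate <- function(X, y, preset = "narrow", folds = 10L, seed = 1L,
                             maxit = 150L, lambda = 1e-4) {
  X <- as.matrix(X)
  y <- labelsToFactor(y)
  stopIfNot(folds >= 2, "`folds` must be >= 2")
  stopIfNot(nrow(X) >= folds, "fewer samples than folds")
  stopIfNot(all(table(y) >= folds),
            "each class needs at least `folds` samples for stratification")
  fa <- stratifiedFolds(y, folds, deriveSeed(seed, "cv-folds"))
  pred <- factor(rep(NA_character_, length(y)),
                 levels = c("benign", "malignant"))
  score <- numeric(length(y))
  for (k in seq_len(folds)) {
    tr <- fa != k
    clf <- buildClassifier(preset, seed = deriveSeed(seed, paste0("cv", k)),
                           maxit = maxit, lambda = lambda)
    clf <- fitClassifier(clf, X[tr, , drop = FALSE], y[tr])
    P <- predict(clf, X[!tr, , drop = FALSE])
    pred[!tr] <- factor(c("benign", "malignant")[max.col(P)],
                        levels = c("benign", "malignant"))
    score[!tr] <- P[, "malignant"]
  }
  cm <- table(truth = y, pred = pred)
  computeMetrics(as.matrix(cm), scores = score, labels = y)
}

# Pooled out-of-fold accuracy only - the cheap path used inside the
# wrapper-selection fitness.
crossvalAccuracy <- function(X, y, foldAssign, preset = "narrow",
                             maxit = 80L, lambda = 1e-3, seed = 1L) {
  correct <- 0L
  for (k in sort(unique(foldAssign))) {
    tr <- foldAssign != k
    clf <- buildClassifier(preset, seed = deriveSeed(seed, paste0("wf", k)),
                           maxit = maxit, lambda = lambda)
    clf <- fitClassifier(clf, X[tr, , drop = FALSE], y[tr])
    P <- predict(clf, X[!tr, , drop = FALSE])
    correct <- correct + sum(max.col(P) == as.integer(y[!tr]))
  }
  correct / length(y)
}
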