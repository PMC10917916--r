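# Gaussian-kernel canonical correlation analysis with entropy-based feature
# weighting. The kernel-CCA solution on the two deep-feature views is a
# fusion-quality diagnostic (its dual coefficients live in N-dimensional
# sample space); the fused matrix itself is the entropy-weighted horizontal
# concatenation of the two views, which is what preserves the published
# N x (p1 + p2) output width.

#' Gaussian (RBF) kernel matrix
#'
#' `K[i, j] = exp(-||fi - fj||^2 / (2 sigma^2))` over the rows of `F`;
#' symmetric with unit diagonal.
#'
#' @param F numeric matrix (rows = samples).
#' @param sigma positive bandwidth; `NULL` selects the median pairwise
#'   distance heuristic.
#' @return list with `K` (N x N matrix) and `sigma` (the bandwidth used).
#' @export
gaussianKernel <- function(F, sigma = NULL) {
  F <- as.matrix(F)
  stopIfNot(nrow(F) >= 2, "need at least 2 rows")
  sq <- rowSums(F^2)
  d2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(F), 0)
  if (is.null(sigma)) {
    med <- stats::median(sqrt(d2[upper.tri(d2)]))
    sigma <- if (is.finite(med) && med > 0) med else 1
  }
  stopIfNot(is.numeric(sigma) && sigma > 0, "`sigma` must be > 0")
  K <- exp(-d2 / (2 * sigma^2))
  K <- (K + t(K)) / 2
  diag(K) <- 1
  list(K = K, sigma = sigma)
}

#' Center a kernel matrix
#'
#' Double centering `K' = H K H` with `H = I - (1/N) 11'`; row and column
#' means of the result vanish. Centering is idempotent.
#'
#' @param K symmetric kernel matrix.
#' @return centered kernel matrix.
#' @export
centerKernel <- function(K) {
  K <- as.matrix(K)
  stopIfNot(nrow(K) == ncol(K), "`K` must be square")
  rm <- rowMeans(K)
  K - outer(rm, rep(1, ncol(K))) - outer(rep(1, nrow(K)), colMeans(K)) +
    mean(K)
}

#' Solve the regularized kernel-CCA generalized eigenproblem
#'
#' Finds the leading canonical pair maximizing `xi' Ku Kv eta` subject to
#' `xi' Ku Ku xi = eta' Kv Kv eta = 1`. Ridge regularization follows the
#' standard convention of replacing the constraint blocks `K^2` with
#' `(K + (N reg / 2) I)^2`, which keeps the problem solvable (a centered
#' kernel is always rank deficient) and controls the spurious perfect
#' correlations a full-rank Gaussian kernel would otherwise produce. The
#' correlation is computed as the leading singular value of
#' `Ru^-1 Ku Kv Rv^-1`, clipped into `[0, 1]`; the sign of `xi` is fixed so
#' its largest-magnitude entry is positive.
#'
#' @param Ku,Kv centered kernel matrices of equal size.
#' @param reg ridge parameter `>= 0` (default 1e-3).
#' @return a [KccaSolution-class].
#' @export
solveKCCA <- function(Ku, Kv, reg = 1e-3) {
  Ku <- as.matrix(Ku); Kv <- as.matrix(Kv)
  stopIfNot(all(dim(Ku) == dim(Kv)) && nrow(Ku) == ncol(Ku),
            "`Ku` and `Kv` must be square matrices of equal size")
  stopIfNot(reg >= 0, "`reg` must be >= 0")
  N <- nrow(Ku)
  kap <- N * reg / 2
  Ru <- Ku + diag(kap, N)
  Rv <- Kv + diag(kap, N)
  B <- tryCatch(
    solve(Ru, Ku) %*% t(solve(Rv, Kv)),
    error = function(e) stop(errorCondition(
      paste0("kernel-CCA system is singular; use reg > 0 (",
             conditionMessage(e), ")"),
      class = c("numericalFailure", "error", "condition"))))
  sv <- svd(B)
  rho <- min(max(sv$d[1], 0), 1)
  # xi from the left singular vector: s_u = Ru xi
  xi <- tryCatch(solve(Ru, sv$u[, 1]), error = function(e) stop(
    errorCondition("singular constraint block; use reg > 0",
                   class = c("numericalFailure", "error", "condition"))))
  eta <- solve(Rv, sv$v[, 1])
  nu <- sqrt(sum((Ku %*% xi)^2))
  nv <- sqrt(sum((Kv %*% eta)^2))
  if (nu > 0) xi <- xi / nu
  if (nv > 0) eta <- eta / nv
  if (xi[which.max(abs(xi))] < 0) { xi <- -xi; eta <- -eta }
  new("KccaSolution", xi = as.numeric(xi), eta = as.numeric(eta),
      rho = rho, reg = reg)
}

#' Histogram Shannon entropy of a feature column
#'
#' Entropy in bits over `bins` equal-width bins spanning the column range.
#' A constant column has a single occupied bin and entropy 0.
#'
#' @param column numeric vector.
#' @param bins number of bins (`>= 2`); default 256, matching 8-bit
#'   intensity resolution.
#' @return nonnegative entropy in bits.
#' @export
shannonEntropy <- function(column, bins = 256L) {
  stopIfNot(bins >= 2, "`bins` must be >= 2")
  stopIfNot(all(is.finite(column)), "column must be finite")
  r <- range(column)
  if (r[2] - r[1] < .Machine$double.eps * max(1, abs(r[1]))) return(0)
  cuts <- seq(r[1], r[2], length.out = bins + 1L)
  counts <- tabulate(findInterval(column, cuts, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  p <- counts[counts > 0] / length(column)
  -sum(p * log2(p))
}

#' Kernel-CCA + entropy feature fusion
#'
#' Computes Gaussian kernels on the two views, solves the regularized
#' kernel CCA (recording the first canonical correlation as a
#' fusion-quality diagnostic), horizontally concatenates the two feature
#' matrices, and rescales each column by its normalized histogram entropy
#' `w_c = H_c / max_c H_c`, down-weighting near-constant, low-information
#' columns. Fusing two `N x 2048` views yields the `N x 4096` fused matrix.
#'
#' @param F1,F2 feature matrices with equal row counts and aligned rows.
#' @param sigma Gaussian bandwidth (`NULL` = per-view median heuristic).
#' @param reg kernel-CCA ridge parameter.
#' @param bins entropy histogram bins.
#' @return a [FusedFeatures-class].
#' @examples
#' pair <- generateCorrelatedPair(60, 5, 4, r = 0.8, seed = 1)
#' fused <- fuseFeatures(pair$F1, pair$F2)
#' dim(fusedValues(fused))
#' @export
fuseFeatures <- function(F1, F2, sigma = NULL, reg = 1e-3, bins = 256L) {
  F1 <- asFeatureMatrix(F1, "a"); F2 <- asFeatureMatrix(F2, "b")
  stopIfNot(nrow(F1) == nrow(F2),
            "`F1` and `F2` must have the same number of rows")
  k1 <- gaussianKernel(F1, sigma)
  k2 <- gaussianKernel(F2, sigma)
  sol <- solveKCCA(centerKernel(k1$K), centerKernel(k2$K), reg = reg)
  values <- cbind(F1, F2)
  H <- apply(values, 2, shannonEntropy, bins = bins)
  w <- if (max(H) > 0) H / max(H) else rep(0, length(H))
  values <- sweep(values, 2, w, "*")
  prov <- data.frame(
    source = rep(c("F1", "F2"), c(ncol(F1), ncol(F2))),
    column = c(seq_len(ncol(F1)), seq_len(ncol(F2))))
  new("FusedFeatures", values = values, weights = as.numeric(w),
      provenance = prov, kcca = sol, sigma = c(k1$sigma, k2$sigma))
}
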