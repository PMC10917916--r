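#' Paired Student's t analysis of two classifiers' accuracies
#'
#' Computes per-experiment absolute accuracy differences `|a_i - b_i|`,
#' their mean and sample standard deviation (denominator `N - 1`), and the
#' statistic `t = sqrt(N) * mean / sd` - the one-sample t on the
#' differences - then compares it with the two-sided critical interval of
#' the t distribution at `pLevel` with `N - 1` degrees of freedom.
#'
#' When `roundIntermediates` is set, the mean and standard deviation are
#' truncated toward zero at that many decimals before forming `t`, which
#' reproduces arithmetic done on printed three-decimal tables (a printed
#' s.d. of 0.531 is the truncation of 0.5315...; rounding half-up would give
#' 0.532 and a different `t`).
#'
#' @param a,b numeric accuracy vectors (percent) of the two classifiers,
#'   equal length `>= 2`.
#' @param labels optional experiment names.
#' @param pLevel two-sided significance level for the critical interval.
#' @param roundIntermediates integer number of decimals at which the mean
#'   and standard deviation are truncated before forming `t`; `NULL`
#'   disables (full precision, the reference one-sample t).
#' @return a [TTestResult-class]. With all differences zero, `t = 0` and the
#'   `degenerate` flag is set.
#' @examples
#' pairedTTest(a = c(94.3, 94.6, 94.3, 96.2),
#'             b = c(94.9, 93.4, 93.1, 96.1))
#' @export
pairedTTest <- function(a, b, labels = NULL, pLevel = 0.05,
                        roundIntermediates = 3L) {
  stopIfNot(length(a) == length(b), "`a` and `b` must have equal length")
  stopIfNot(length(a) >= 2, "need at least 2 paired experiments")
  stopIfNot(pLevel > 0 && pLevel < 1, "`pLevel` must lie in (0, 1)")
  diffs <- abs(a - b)
  if (!is.null(labels)) names(diffs) <- labels
  N <- length(diffs)
  mu <- mean(diffs)
  sigma <- sqrt(sum((diffs - mu)^2) / (N - 1))
  degenerate <- all(diffs == 0)
  if (!is.null(roundIntermediates)) {
    mu <- truncAt(mu, roundIntermediates)
    sigma <- truncAt(sigma, roundIntermediates)
  }
  tval <- if (degenerate || sigma == 0) 0 else sqrt(N) * mu / sigma
  crit <- qt(1 - pLevel / 2, df = N - 1)
  interval <- c(-crit, crit)
  new("TTestResult", diffs = as.numeric(diffs), mean = mu, sd = sigma,
      t = tval, dof = N - 1, interval = interval, pLevel = pLevel,
      inside = (tval > interval[1] && tval < interval[2]),
      degenerate = degenerate)
}
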