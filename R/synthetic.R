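#' Generate a synthetic two-class mammogram-like image set
#'
#' Emulates a benign/malignant mammogram collection at a chosen geometry.
#' Backgrounds are low-frequency Gaussian random fields plus pixel noise
#' (mammogram-like smooth intensity gradients). Malignant images contain 1-3
#' high-contrast anisotropic Gaussian blobs (mass-like lesions) whose contrast
#' scales with `effect`; benign images contain only background texture plus,
#' with probability 1/2, a single low-contrast smooth blob whose contrast does
#' not depend on `effect`. Per-image lesion masks mark blob pixels (within the
#' 2-sigma contour of any inserted blob).
#'
#' @param nPerClass images per class (positive integer).
#' @param size `c(H, W)` with `H, W >= 64`. Default `c(227, 227)`, the input
#'   geometry of the bottleneck-residual networks.
#' @param effect class separability in `[0, 1]`; scales malignant lesion
#'   contrast.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param channels 1 (grayscale) or 3 (gray channel replicated, as the
#'   networks expect 227 x 227 x 3 input). Default 3.
#' @return a [MammoImageSet-class].
#' @examples
#' iset <- generateMammoImages(5, size = c(64, 64), effect = 0.9, seed = 1)
#' iset
#' @export
generateMammoImages <- function(nPerClass, size = c(227L, 227L),
                                effect = 0.9, seed = 1L, channels = 3L) {
  stopIfNot(is.numeric(nPerClass) && length(nPerClass) == 1L &&
              nPerClass >= 1 && nPerClass == round(nPerClass),
            "`nPerClass` must be a positive integer")
  stopIfNot(length(size) == 2L && all(size >= 64),
            "`size` must be c(H, W) with H, W >= 64")
  stopIfNot(is.numeric(effect) && effect >= 0 && effect <= 1,
            "`effect` must lie in [0, 1]")
  stopIfNot(channels %in% c(1L, 3L), "`channels` must be 1 or 3")
  H <- as.integer(size[1]); W <- as.integer(size[2])

  withSeed(seed, {
    n <- 2L * as.integer(nPerClass)
    labels <- factor(rep(c("benign", "malignant"), each = nPerClass),
                     levels = c("benign", "malignant"))
    imgs <- vector("list", n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      bg <- makeBackground(H, W)
      if (labels[i] == "malignant") {
        amp <- 0.2 + 0.5 * effect
        nb <- sample(1:3, 1L)
        lesion <- makeLesionField(H, W, nBlobs = nb, amplitude = amp,
                                  eccMin = 0.35)
      } else if (runif(1) < 0.5) {
        # occasional benign finding: single smooth, near-isotropic,
        # low-contrast blob
        lesion <- makeLesionField(H, W, nBlobs = 1L, amplitude = 0.06,
                                  eccMin = 0.85)
      } else {
        lesion <- list(field = matrix(0, H, W), mask = matrix(FALSE, H, W))
      }
      img <- pmin(pmax(bg + lesion$field, 0), 1)
      if (channels == 3L) img <- array(rep(img, 3L), dim = c(H, W, 3L))
      else img <- array(img, dim = c(H, W, 1L))
      imgs[[i]] <- img
      masks[[i]] <- lesion$mask
    }
    new("MammoImageSet", images = imgs, labels = labels, lesionMasks = masks,
        seed = as.integer(seed),
        params = list(nPerClass = as.integer(nPerClass), size = c(H, W),
                      effect = effect, channels = as.integer(channels)))
  })
}

# Low-frequency Gaussian random field background plus pixel noise.
makeBackground <- function(H, W) {
  coarse <- matrix(rnorm(12 * 12), 12, 12)
  field <- bilinearResize(coarse, H, W)
  0.35 + 0.12 * field + matrix(rnorm(H * W, sd = 0.03), H, W)
}

# Sum of anisotropic Gaussian blobs; returns intensity field and 2-sigma mask.
makeLesionField <- function(H, W, nBlobs, amplitude, eccMin) {
  field <- matrix(0, H, W)
  mask <- matrix(FALSE, H, W)
  ys <- matrix(seq_len(H), H, W)
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (b in seq_len(nBlobs)) {
    cy <- runif(1, 0.3, 0.7) * H
    cx <- runif(1, 0.3, 0.7) * W
    s1 <- runif(1, 0.05, 0.10) * min(H, W)
    s2 <- s1 * runif(1, eccMin, 1)
    th <- runif(1, 0, pi)
    amp <- amplitude / nBlobs * runif(1, 0.85, 1.15)
    dy <- ys - cy; dx <- xs - cx
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    q <- (u / s1)^2 + (v / s2)^2
    field <- field + amp * exp(-q / 2)
    mask <- mask | (q <= 4)  # within 2 sigma
  }
  list(field = field, mask = mask)
}

#' Generate a pair of feature matrices with a planted canonical correlation
#'
#' Builds `F1 = u a1' + noise * E1` and `F2 = v a2' + noise * E2` where `u`
#' and `v` share a latent factor so that the population first canonical
#' correlation between the two views equals `r` (the latent correlation is
#' inflated by `1 + noise^2` to cancel the attenuation from the independent
#' column noise).
#'
#' @param n sample count (`> 4`).
#' @param p1,p2 column counts of the two views.
#' @param r target first canonical correlation in `[0, 1]`.
#' @param seed integer seed.
#' @param noise standard deviation of independent per-column noise
#'   (default 0.05).
#' @return list with elements `F1`, `F2` (matrices with matching rownames),
#'   `latentCorr` and `seed`.
#' @examples
#' pair <- generateCorrelatedPair(200, 8, 8, r = 0.7, seed = 3)
#' stats::cancor(pair$F1, pair$F2)$cor[1]
#' @export
generateCorrelatedPair <- function(n, p1, p2, r, seed = 1L, noise = 0.05) {
  stopIfNot(is.numeric(n) && n > 4, "`n` must exceed 4")
  stopIfNot(is.numeric(r) && length(r) == 1L && r >= 0 && r <= 1,
            "`r` must lie in [0, 1]")
  stopIfNot(p1 >= 1 && p2 >= 1, "`p1` and `p2` must be >= 1")
  withSeed(seed, {
    z <- rnorm(n)
    rr <- min(1, r * (1 + noise^2))
    u <- sqrt(rr) * z + sqrt(1 - rr) * rnorm(n)
    v <- sqrt(rr) * z + sqrt(1 - rr) * rnorm(n)
    a1 <- rnorm(p1); a1 <- a1 / sqrt(sum(a1^2))
    a2 <- rnorm(p2); a2 <- a2 / sqrt(sum(a2^2))
    F1 <- u %o% a1 + noise * matrix(rnorm(n * p1), n, p1)
    F2 <- v %o% a2 + noise * matrix(rnorm(n * p2), n, p2)
    rownames(F1) <- rownames(F2) <- sprintf("s%04d", seq_len(n))
    colnames(F1) <- sprintf("u%03d", seq_len(p1))
    colnames(F2) <- sprintf("v%03d", seq_len(p2))
    list(F1 = F1, F2 = F2, latentCorr = r, seed = as.integer(seed))
  })
}

#' Generate a feature-selection benchmark with known informative columns
#'
#' Informative columns are class-shifted Gaussians (means `+/- shift/2` by
#' class, unit variance); noise columns are standard Gaussians independent of
#' the labels by construction.
#'
#' @param n sample count.
#' @param pInf number of informative columns (`>= 1`).
#' @param pNoise number of pure-noise columns.
#' @param shift between-class mean shift of informative columns. The default
#'   1.2 gives a per-column AUC of about 0.80 - a strong single radiomic
#'   feature, so that subsets of informative columns separate the classes
#'   well while no single noise column does.
#' @param seed integer seed.
#' @return list with `X` (n x (pInf + pNoise) matrix), `y` (factor),
#'   `informativeIdx` (integer vector of column indices), `seed`.
#' @export
generateSelectionBenchmark <- function(n, pInf, pNoise, shift = 1.2,
                                       seed = 1L) {
  stopIfNot(is.numeric(pInf) && pInf >= 1, "`pInf` must be >= 1")
  stopIfNot(pNoise >= 0, "`pNoise` must be >= 0")
  stopIfNot(n >= 8, "`n` must be >= 8")
  withSeed(seed, {
    p <- as.integer(pInf + pNoise)
    y <- factor(sample(rep(c("benign", "malignant"), length.out = n)),
                levels = c("benign", "malignant"))
    X <- matrix(rnorm(n * p), n, p)
    informative <- sort(sample(seq_len(p), pInf))
    sgn <- ifelse(y == "malignant", shift / 2, -shift / 2)
    for (j in informative) X[, j] <- X[, j] + sgn
    X <- asFeatureMatrix(X)
    list(X = X, y = y, informativeIdx = informative,
         seed = as.integer(seed))
  })
}
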