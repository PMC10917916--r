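# Internal helpers: seeded evaluation, seed derivation, resizing, checks.

# Evaluate expr under a local RNG state; the caller's RNG is untouched.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed from a global seed and a stage tag.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Bilinear resize of a 2-D matrix to (H, W); used for Grad-CAM upsampling
# and for loading images of nonstandard size.
bilinearResize <- function(m, H, W) {
  h0 <- nrow(m); w0 <- ncol(m)
  if (h0 == H && w0 == W) return(m)
  # map output pixel centers into input coordinates
  ys <- (seq_len(H) - 0.5) * h0 / H + 0.5
  xs <- (seq_len(W) - 0.5) * w0 / W + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h0); y1 <- pmin(y0 + 1, h0)
  x0 <- pmin(pmax(floor(xs), 1), w0); x1 <- pmin(x0 + 1, w0)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE] * ((1 - fy) %o% (1 - fx)) +
       m[y1, x0, drop = FALSE] * (fy %o% (1 - fx)) +
       m[y0, x1, drop = FALSE] * ((1 - fy) %o% fx) +
       m[y1, x1, drop = FALSE] * (fy %o% fx)
  a
}

# Truncate toward zero at `digits` decimals (printed-table arithmetic).
truncAt <- function(x, digits) trunc(x * 10^digits) / 10^digits

# Coerce a numeric matrix into the package's feature-matrix convention:
# rownames = sample ids, colnames = feature ids.
asFeatureMatrix <- function(x, prefix = "f") {
  x <- as.matrix(x)
  stopIfNot(all(is.finite(x)), "feature matrix entries must be finite")
  if (is.null(rownames(x))) rownames(x) <- sprintf("s%04d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("%s%04d", prefix,
                                                   seq_len(ncol(x)))
  x
}

# Stratified fold assignment, deterministic given seed.
stratifiedFolds <- function(y, folds, seed) {
  withSeed(seed, {
    assign <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assign
  })
}

labelsToFactor <- function(labels) {
  f <- factor(as.character(labels), levels = c("benign", "malignant"))
  stopIfNot(!anyNA(f), "labels must be 'benign' or 'malignant'")
  f
}
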