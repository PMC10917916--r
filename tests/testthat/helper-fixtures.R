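# Shared fixtures, built once per test run and cached in an environment.
# All fixtures are generated in code under fixed seeds; nothing is stored on
# disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Small lesion image set at 64 x 64 (generator precondition: >= 64).
smallImageSet <- function() {
  fixture("smallImageSet",
          function() generateMammoImages(12, size = c(64, 64), effect = 0.9,
                                         seed = 101))
}

# A tiny bottleneck-residual net trained to separate the small image set.
trainedTinyNet <- function() {
  fixture("trainedTinyNet", function() {
    iset <- generateMammoImages(30, size = c(64, 64), effect = 0.9,
                                seed = 11)
    net <- buildNetwork(tinyBottleneckSpec(c(64, 64, 3)), seed = 2)
    hp <- hyperParams(learningRate = 0.01, momentum = 0.9, epochs = 12,
                      minibatch = 10)
    list(net = trainNetwork(net, iset, hp, seed = 3), iset = iset)
  })
}

# Two shifted-Gaussian clouds, the separable-features oracle for the
# classifier suite: class means 4 sd apart along every coordinate.
shiftedGaussians <- function(n = 200, p = 4, shift = 4, seed = 5) {
  set.seed(seed)
  y <- factor(rep(c("benign", "malignant"), each = n / 2),
              levels = c("benign", "malignant"))
  X <- matrix(rnorm(n * p), n, p) +
    ifelse(y == "malignant", shift / 2, -shift / 2)
  list(X = X, y = y)
}
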