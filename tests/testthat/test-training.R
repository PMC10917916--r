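# Splitting, augmentation, SGD training and Bayesian hyperparameter search.

test_that("stratified split halves each class and is reproducible", {
  iset <- generateMammoImages(10, size = c(64, 64), seed = 3)
  sp <- splitDataset(iset, seed = 1)
  y <- imageLabels(iset)
  expect_equal(as.vector(table(y[sp$trainIds])), c(10L, 10L) / 2 * 1L)
  expect_setequal(c(sp$trainIds, sp$testIds), seq_len(20))
  expect_identical(sp, splitDataset(iset, seed = 1))
  expect_false(identical(sp$trainIds, splitDataset(iset, seed = 2)$trainIds))
})

test_that("odd class sizes split to within one sample of 50%", {
  iset <- generateMammoImages(11, size = c(64, 64), seed = 4)
  sp <- splitDataset(iset, seed = 1)
  y <- imageLabels(iset)
  perClass <- table(y[sp$trainIds])
  expect_true(all(perClass %in% c(5L, 6L)))
})

test_that("augmentation produces the four classical variants per image", {
  iset <- subsetImages(smallImageSet(), c(1:5, 13:17))
  aug <- augmentImages(iset)
  expect_equal(nImages(aug), 50L)
  prov <- aug@params$augmentation
  expect_equal(as.character(imageLabels(aug)),
               as.character(imageLabels(iset))[prov$source])
  # flips are involutions; rot180 is rot90 twice
  im <- images(iset)[[1]]
  expect_identical(mammofuse:::applyImageOp(
    mammofuse:::applyImageOp(im, "hflip"), "hflip"), im)
  expect_identical(mammofuse:::applyImageOp(
    mammofuse:::applyImageOp(im, "vflip"), "vflip"), im)
  expect_equal(mammofuse:::applyImageOp(
    mammofuse:::applyImageOp(im, "rot90"), "rot90"),
    mammofuse:::applyImageOp(im, "rot180"))
  # masks transformed alongside images
  expect_equal(sum(lesionMasks(aug)[[2]]), sum(lesionMasks(iset)[[1]]))
})

test_that("zero learning rate leaves learnable weights untouched", {
  iset <- subsetImages(smallImageSet(), c(1:4, 13:16))
  net <- buildNetwork(tinyBottleneckSpec(c(64, 64, 3)), seed = 1)
  # full-batch so every epoch sees identical batch statistics
  hp <- hyperParams(learningRate = 0, epochs = 2, minibatch = 8)
  tr <- trainNetwork(net, iset, hp, seed = 1)
  # compare learnable leaves (running statistics are recalibrated by design)
  strip <- function(p) {
    if (is.null(p)) return(NULL)
    if (!is.null(names(p)) && "rmean" %in% names(p))
      return(p[c("gamma", "beta")])
    if (is.list(p)) return(lapply(p, strip))
    p
  }
  expect_identical(strip(tr@params), strip(net@params))
  expect_equal(tr@history$loss[1], tr@history$loss[2])
})

test_that("training reduces loss and reaches high accuracy on separable data", {
  tt <- trainedTinyNet()
  loss <- tt$net@history$loss
  expect_lt(loss[length(loss)], loss[1])
  p <- predictNetwork(tt$net, tt$iset)
  acc <- mean(max.col(p) == as.integer(imageLabels(tt$iset)))
  expect_gte(acc, 0.9)
})

test_that("training is deterministic given a seed", {
  iset <- subsetImages(smallImageSet(), c(1:4, 13:16))
  hp <- hyperParams(learningRate = 0.01, momentum = 0.9, epochs = 2,
                    minibatch = 4)
  f <- function() {
    net <- buildNetwork(tinyBottleneckSpec(c(64, 64, 3)), seed = 2)
    trainNetwork(net, iset, hp, seed = 5)@history$loss
  }
  expect_identical(f(), f())
})

test_that("Bayesian optimization respects its budget and search box", {
  iset <- generateMammoImages(8, size = c(64, 64), effect = 0.9, seed = 21)
  spec <- tinyBottleneckSpec(c(64, 64, 3), stem = 4, width = 8,
                             gapChannels = 16)
  hp1 <- bayesOptimize(spec, iset, budget = 1, seed = 1, proxyEpochs = 1,
                       minibatch = 4)
  expect_equal(nrow(attr(hp1, "trace")), 1L)
  hp <- bayesOptimize(spec, iset, budget = 5, seed = 1, proxyEpochs = 2,
                      minibatch = 4)
  tr <- attr(hp, "trace")
  expect_equal(nrow(tr), 5L)
  expect_true(all(hp$learningRate >= 1e-5 & hp$learningRate <= 1e-2))
  expect_true(all(hp$momentum >= 0.5 & hp$momentum <= 0.99))
  # best-so-far objective is monotone nondecreasing (accuracy scale)
  expect_true(all(diff(tr$bestSoFar) >= 0))
  # beats the random-guessing baseline on separable data
  expect_gte(attr(hp, "valAccuracy"), 0.5)
})

test_that("hyperparameter defaults and validation follow the protocol", {
  hp <- hyperParams()
  expect_equal(hp$learningRate, 0.000241)
  expect_equal(hp$momentum, 0.776)
  expect_equal(hp$epochs, 50L)
  expect_equal(hp$minibatch, 64L)
  expect_error(hyperParams(momentum = 1), "0, 1")
  expect_error(hyperParams(optimizer = "adam"), "sgdm")
})
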