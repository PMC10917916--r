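# Architecture construction, parameter accounting, forward contracts,
# feature extraction and Grad-CAM.

test_that("unit parameter counts match closed-form arithmetic", {
  cnt <- mammofuse:::countNodeParams
  # dense 2048 -> 2 with bias
  expect_equal(cnt(mammofuse:::denseNode(2048L, 2L)), 4098)
  # conv 3x3, 3 -> 32 with bias
  expect_equal(cnt(mammofuse:::convNode(3L, 3L, 32L)), 896)
  # grouped conv splits input channels across filter groups
  expect_equal(cnt(mammofuse:::convNode(3L, 4L, 6L, groups = 2L)),
               3 * 3 * 2 * 6 + 6)
})

test_that("network construction is deterministic and seed moves weights only", {
  s <- tinyBottleneckSpec(c(64, 64, 3))
  n1 <- buildNetwork(s, seed = 4)
  n2 <- buildNetwork(s, seed = 4)
  n3 <- buildNetwork(s, seed = 5)
  expect_identical(n1@params, n2@params)
  expect_false(identical(n1@params, n3@params))
  expect_identical(countParameters(n1), countParameters(n3))
  expect_error(buildNetwork("five_block"), "unknown architecture")
})

test_that("forward pass emits normalized two-class probabilities", {
  net <- buildNetwork(tinyBottleneckSpec(c(64, 64, 3)), seed = 1)
  iset <- smallImageSet()
  p <- predictNetwork(net, subsetImages(iset, 1:3))
  expect_equal(dim(p), c(3L, 2L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
})

test_that("feature extraction is batch invariant with stable row order", {
  net <- buildNetwork(tinyBottleneckSpec(c(64, 64, 3)), seed = 1)
  iset <- subsetImages(smallImageSet(), 1:6)
  F1 <- extractFeatures(net, iset, batch = 1)
  F2 <- extractFeatures(net, iset, batch = 4)
  expect_equal(dim(F1), c(6L, 32L))
  expect_lt(max(abs(F1 - F2)), 1e-10)
  # identical image repeated gives identical rows
  two <- list(images(iset)[[1]], images(iset)[[1]])
  Fr <- extractFeatures(net, two)
  expect_equal(Fr[1, ], Fr[2, ], ignore_attr = TRUE)
  expect_error(extractFeatures(net, list()), "empty")
})

test_that("analytic gradients agree with finite differences through the stack", {
  spec <- tinyBottleneckSpec(c(16, 16, 3), stem = 4, width = 4,
                             gapChannels = 6)
  net <- buildNetwork(spec, seed = 7)
  set.seed(9)
  x <- array(runif(16 * 16 * 3 * 3), c(16, 16, 3, 3))
  yidx <- c(1, 2, 1)
  lossOf <- function(params) {
    fw <- mammofuse:::fwNode(net@spec@graph, params, x, "train", NULL)
    p <- mammofuse:::softmaxRows(fw$out)
    -mean(log(p[cbind(1:3, yidx)]))
  }
  fw <- mammofuse:::fwNode(net@spec@graph, net@params, x, "train", NULL)
  p <- mammofuse:::softmaxRows(fw$out)
  Y <- matrix(0, 3, 2); Y[cbind(1:3, yidx)] <- 1
  bw <- mammofuse:::bwNode(net@spec@graph, net@params, fw$cache,
                           (p - Y) / 3, NULL)
  cases <- list(  # (path into the param tree, field, flat index)
    list(c(1), "W", 3),                         # stem conv kernel
    list(c(4, NA, 1, 1), "gamma", 2),           # batchnorm scale in branch
    list(c(4, NA, 1, 5), "W", 9),               # strided 3x3 bottleneck conv
    list(c(9), "W", 10))                        # dense head
  getLeaf <- function(tree, path) {
    for (k in path) tree <- if (is.na(k)) tree$branches else tree[[k]]
    tree
  }
  for (cs in cases) {
    g <- getLeaf(bw$grad, cs[[1]])[[cs[[2]]]][cs[[3]]]
    eps <- 1e-5
    perturb <- function(d) {
      pp <- net@params
      # walk down, modify leaf, rebuild (paths are short)
      modify <- function(tree, path) {
        if (length(path) == 0) {
          tree[[cs[[2]]]][cs[[3]]] <- tree[[cs[[2]]]][cs[[3]]] + d
          return(tree)
        }
        k <- path[1]
        if (is.na(k)) tree$branches <- modify(tree$branches, path[-1])
        else tree[[k]] <- modify(tree[[k]], path[-1])
        tree
      }
      lossOf(modify(pp, cs[[1]]))
    }
    fd <- (perturb(eps) - perturb(-eps)) / (2 * eps)
    expect_equal(g, fd, tolerance = 1e-5)
  }
})

test_that("architecture descriptions round-trip through JSON", {
  spec <- tinyBottleneckSpec(c(64, 64, 3))
  path <- file.path(withr::local_tempdir(), "spec.json")
  writeNetworkSpec(spec, path)
  back <- readNetworkSpec(path)
  expect_equal(back@name, spec@name)
  expect_equal(back@inputShape, spec@inputShape)
  expect_equal(countParameters(back), countParameters(spec))
  net <- buildNetwork(back, seed = 3)
  p <- predictNetwork(net, images(smallImageSet())[1:2])
  expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6)
})

test_that("Grad-CAM returns a normalized map and survives degenerate input", {
  net <- buildNetwork(tinyBottleneckSpec(c(64, 64, 3)), seed = 1)
  img <- images(smallImageSet())[[1]]
  cam <- gradCAM(net, img, "malignant")
  expect_equal(dim(cam), c(64L, 64L))
  expect_true(all(cam >= 0 & cam <= 1))
  zero <- array(0, c(64, 64, 3))
  camZ <- gradCAM(net, zero, 2)
  expect_false(anyNA(camZ))
  expect_error(gradCAM(net, img, 3), "invalid target class")
})

test_that("Grad-CAM of a trained net concentrates on the lesion", {
  tt <- trainedTinyNet()
  mal <- which(imageLabels(tt$iset) == "malignant")
  diffs <- vapply(head(mal, 20), function(i) {
    cam <- gradCAM(tt$net, images(tt$iset)[[i]], "malignant")
    m <- lesionMasks(tt$iset)[[i]]
    mean(cam[m]) - mean(cam[!m])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
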