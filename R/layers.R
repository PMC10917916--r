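# Layer-graph machinery. A network is a nested graph of nodes:
#   layer nodes : conv, bn, relu, maxpool, gap, dense
#   seq         : ordered list of nodes
#   parallelAdd : branches evaluated on the same input and summed, plus a
#                 skip path ("identity" or a projection node) added on top -
#                 the residual/bottleneck building block.
# Activations are (H, W, C, B) arrays; the dense head works on B x C
# matrices produced by gap. Softmax is applied outside the graph.

convNode <- function(k, cin, cout, stride = 1L, pad = "same", groups = 1L) {
  stopIfNot(cout >= 1 && k >= 1 && stride >= 1, "bad conv geometry")
  stopIfNot(cin %% groups == 0 && cout %% groups == 0,
            "channels must be divisible by groups")
  list(type = "conv", k = as.integer(k), cin = as.integer(cin),
       cout = as.integer(cout), stride = as.integer(stride), pad = pad,
       groups = as.integer(groups))
}
bnNode <- function(c) list(type = "bn", c = as.integer(c))
reluNode <- function() list(type = "relu")
maxpoolNode <- function(k = 3L, stride = 1L, pad = "same")
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = pad)
gapNode <- function() list(type = "gap")
denseNode <- function(cin, cout) {
  stopIfNot(cout >= 1, "dense depth must be >= 1")
  list(type = "dense", cin = as.integer(cin), cout = as.integer(cout))
}
seqNode <- function(...) list(type = "seq", nodes = list(...))
parallelAddNode <- function(branches, skip = "identity")
  list(type = "parallelAdd", branches = branches, skip = skip)

# Bottleneck block: batchnorm before each conv (as in the architecture
# narrative), 1x1 reduce -> 3x3 (optionally strided) -> 1x1 expand, with a
# projection skip when shape changes. `twoConv` drops the final 1x1 (the
# first block of both networks).
bottleneckBranch <- function(cin, mid, cout, stride3 = 1L, twoConv = FALSE) {
  nodes <- list(bnNode(cin), convNode(1L, cin, mid), reluNode(),
                bnNode(mid), convNode(3L, mid, mid, stride = stride3),
                reluNode())
  if (!twoConv)
    nodes <- c(nodes, list(bnNode(mid), convNode(1L, mid, cout), reluNode()))
  do.call(seqNode, nodes)
}

bottleneckGroup <- function(cin, mid, cout, stride3 = 1L, nBranches = 1L,
                            twoConv = FALSE) {
  branches <- replicate(nBranches,
                        bottleneckBranch(cin, mid, cout, stride3, twoConv),
                        simplify = FALSE)
  skip <- if (cin == cout && stride3 == 1L) "identity"
          else convNode(1L, cin, cout, stride = stride3)
  parallelAddNode(branches, skip)
}

# -- parameter initialization -------------------------------------------------

initNode <- function(node) {
  switch(node$type,
    conv = {
      fanIn <- node$k^2 * node$cin / node$groups
      list(W = matrix(rnorm(fanIn * node$cout, sd = sqrt(2 / fanIn)),
                      fanIn, node$cout),
           b = numeric(node$cout))
    },
    bn = list(gamma = rep(1, node$c), beta = numeric(node$c),
              rmean = numeric(node$c), rvar = rep(1, node$c)),
    dense = list(W = matrix(rnorm(node$cin * node$cout,
                                  sd = sqrt(1 / node$cin)),
                            node$cin, node$cout),
                 b = numeric(node$cout)),
    seq = lapply(node$nodes, initNode),
    parallelAdd = list(
      branches = lapply(node$branches, initNode),
      skip = if (identical(node$skip, "identity")) NULL
             else initNode(node$skip)),
    NULL)
}

countNodeParams <- function(node) {
  switch(node$type,
    conv = node$k^2 * (node$cin / node$groups) * node$cout + node$cout,
    bn = 2 * node$c,
    dense = node$cin * node$cout + node$cout,
    seq = sum(vapply(node$nodes, countNodeParams, numeric(1))),
    parallelAdd = sum(vapply(node$branches, countNodeParams, numeric(1))) +
      (if (identical(node$skip, "identity")) 0
       else countNodeParams(node$skip)),
    0)
}

# -- forward ------------------------------------------------------------------

bnStats <- function(x) {
  d <- dim(x); C <- d[3]; B <- d[4]
  Xm <- matrix(x, nrow = d[1] * d[2])
  ch <- rep(seq_len(C), B)
  m <- d[1] * d[2] * B
  mu <- as.vector(rowsum(matrix(colSums(Xm)), ch)) / m
  ex2 <- as.vector(rowsum(matrix(colSums(Xm^2)), ch)) / m
  list(mu = mu, var = pmax(ex2 - mu^2, 0), ch = ch, m = m)
}

fwNode <- function(node, par, x, mode, env, bnm = 0.1, keepCache = TRUE) {
  switch(node$type,
    conv = {
      y <- .conv2dForward(x, par$W, par$b, node$k, node$stride,
                          identical(node$pad, "same"), node$groups)
      list(out = y, cache = if (keepCache) list(x = x), par = par)
    },
    bn = {
      d <- dim(x); eps <- 1e-3
      if (mode == "train") {
        st <- bnStats(x)
        mu <- st$mu; v <- st$var
        par$rmean <- (1 - bnm) * par$rmean + bnm * mu
        par$rvar <- (1 - bnm) * par$rvar + bnm * v
      } else { mu <- par$rmean; v <- par$rvar }
      invstd <- 1 / sqrt(v + eps)
      ch <- rep(seq_len(d[3]), d[4])
      Xm <- matrix(x, nrow = d[1] * d[2])
      xhat <- sweep(Xm, 2, mu[ch], "-")
      xhat <- sweep(xhat, 2, invstd[ch], "*")
      y <- sweep(xhat, 2, par$gamma[ch], "*")
      y <- sweep(y, 2, par$beta[ch], "+")
      dim(y) <- d
      list(out = y,
           cache = if (keepCache)
             list(xhat = xhat, invstd = invstd, ch = ch, d = d,
                  train = (mode == "train")),
           par = par)
    },
    relu = {
      if (!keepCache) return(list(out = pmax(x, 0), cache = NULL,
                                  par = par))
      pos <- x > 0
      list(out = x * pos, cache = list(pos = pos), par = par)
    },
    maxpool = {
      r <- .maxpoolForward(x, node$k, node$stride,
                           identical(node$pad, "same"))
      list(out = r$y,
           cache = if (keepCache) list(argmax = r$argmax, xdim = dim(x)),
           par = par)
    },
    gap = {
      d <- dim(x)
      y <- t(matrix(colMeans(matrix(x, nrow = d[1] * d[2])), d[3], d[4]))
      if (!is.null(env)) env$gapOut <- y
      list(out = y, cache = if (keepCache) list(x = x, d = d), par = par)
    },
    dense = {
      y <- x %*% par$W + matrix(par$b, nrow(x), length(par$b), byrow = TRUE)
      list(out = y, cache = if (keepCache) list(x = x), par = par)
    },
    seq = {
      caches <- vector("list", length(node$nodes))
      for (i in seq_along(node$nodes)) {
        r <- fwNode(node$nodes[[i]], par[[i]], x, mode, env, bnm,
                    keepCache)
        x <- r$out
        caches[i] <- list(r$cache)
        par[i] <- list(r$par)  # [[<- would drop NULL entries
      }
      list(out = x, cache = caches, par = par)
    },
    parallelAdd = {
      bc <- vector("list", length(node$branches))
      out <- NULL
      for (i in seq_along(node$branches)) {
        r <- fwNode(node$branches[[i]], par$branches[[i]], x, mode, env,
                    bnm, keepCache)
        bc[[i]] <- r$cache; par$branches[[i]] <- r$par
        out <- if (is.null(out)) r$out else out + r$out
      }
      if (identical(node$skip, "identity")) {
        out <- out + x
        sc <- NULL
      } else {
        r <- fwNode(node$skip, par$skip, x, mode, env, bnm, keepCache)
        sc <- r$cache; par$skip <- r$par
        out <- out + r$out
      }
      list(out = out, cache = list(branches = bc, skip = sc), par = par)
    },
    stop("unknown node type: ", node$type))
}

# -- backward -----------------------------------------------------------------

bwNode <- function(node, par, cache, dy, env) {
  switch(node$type,
    conv = {
      r <- .conv2dBackward(cache$x, par$W, dy, node$k, node$stride,
                           identical(node$pad, "same"), node$groups)
      list(dx = r$dx, grad = list(W = r$dw, b = r$db))
    },
    bn = {
      d <- cache$d; ch <- cache$ch
      Dm <- matrix(dy, nrow = d[1] * d[2])
      dgamma <- as.vector(rowsum(matrix(colSums(Dm * cache$xhat)), ch))
      dbeta <- as.vector(rowsum(matrix(colSums(Dm)), ch))
      dxhat <- sweep(Dm, 2, par$gamma[ch], "*")
      if (cache$train) {
        m <- d[1] * d[2] * d[4]
        s1 <- as.vector(rowsum(matrix(colSums(dxhat)), ch))
        s2 <- as.vector(rowsum(matrix(colSums(dxhat * cache$xhat)), ch))
        dx <- dxhat -
          sweep(cache$xhat, 2, (s2 / m)[ch], "*") -
          matrix((s1 / m)[ch], nrow(Dm), ncol(Dm), byrow = TRUE)
        dx <- sweep(dx, 2, cache$invstd[ch], "*")
      } else {
        dx <- sweep(dxhat, 2, cache$invstd[ch], "*")
      }
      dim(dx) <- d
      list(dx = dx, grad = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dy * cache$pos, grad = NULL),
    maxpool = list(dx = .maxpoolBackward(dy, cache$argmax,
                                         as.integer(cache$xdim)),
                   grad = NULL),
    gap = {
      d <- cache$d
      hw <- d[1] * d[2]
      if (!is.null(env)) { env$gapGradIn <- dy; env$gapActIn <- cache$x }
      dx <- matrix(rep(as.vector(t(dy)) / hw, each = hw), nrow = hw)
      dim(dx) <- d
      if (!is.null(env)) env$camGrad <- dx
      list(dx = dx, grad = NULL)
    },
    dense = list(dx = dy %*% t(par$W),
                 grad = list(W = crossprod(cache$x, dy), b = colSums(dy))),
    seq = {
      grads <- vector("list", length(node$nodes))
      for (i in rev(seq_along(node$nodes))) {
        r <- bwNode(node$nodes[[i]], par[[i]], cache[[i]], dy, env)
        dy <- r$dx
        grads[i] <- list(r$grad)  # keep NULL gradients as placeholders
      }
      list(dx = dy, grad = grads)
    },
    parallelAdd = {
      grads <- list(branches = vector("list", length(node$branches)),
                    skip = NULL)
      dx <- NULL
      for (i in seq_along(node$branches)) {
        r <- bwNode(node$branches[[i]], par$branches[[i]],
                    cache$branches[[i]], dy, env)
        grads$branches[i] <- list(r$grad)
        dx <- if (is.null(dx)) r$dx else dx + r$dx
      }
      if (identical(node$skip, "identity")) {
        dx <- dx + dy
      } else {
        r <- bwNode(node$skip, par$skip, cache$skip, dy, env)
        grads$skip <- r$grad
        dx <- dx + r$dx
      }
      list(dx = dx, grad = grads)
    },
    stop("unknown node type: ", node$type))
}

# -- SGD-momentum update ------------------------------------------------------

zeroLike <- function(par) {
  if (is.null(par)) return(NULL)
  if (is.list(par)) return(lapply(par, zeroLike))
  par * 0
}

learnableFields <- c("W", "b", "gamma", "beta")

sgdUpdate <- function(par, grad, vel, lr, momentum) {
  if (is.null(grad)) return(list(par = par, vel = vel))
  if (!is.null(names(par)) && any(names(par) %in% learnableFields)) {
    for (f in intersect(names(grad), learnableFields)) {
      vel[[f]] <- momentum * vel[[f]] - lr * grad[[f]]
      par[[f]] <- par[[f]] + vel[[f]]
    }
    return(list(par = par, vel = vel))
  }
  for (i in seq_along(grad)) {
    if (is.null(grad[[i]])) next
    r <- sgdUpdate(par[[i]], grad[[i]], vel[[i]], lr, momentum)
    par[[i]] <- r$par; vel[[i]] <- r$vel
  }
  list(par = par, vel = vel)
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
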