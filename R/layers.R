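# Layer-level forward and backward passes. Feature maps are (H, W, C, B)
# arrays; dense activations are (units, B) matrices. Each layer is a plain
# list: name, type, params (trainable arrays), state (non-trainable, BN
# moving statistics) and cfg. Backward passes return the gradient with
# respect to the layer input plus per-parameter gradients, enabling both
# training and class-activation mapping from arbitrary tap points.

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

heInit <- function(dims, fanIn) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fanIn)), dim = dims)
}

# spatial mean per channel: (H, W, C, B) -> (C, B)
gapCB <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

# broadcast a (C, B) matrix over the spatial dimensions of an (H, W, C, B) map
bcChan <- function(v, hw) rep(as.vector(v), each = hw)

sigmoid <- function(z) 1 / (1 + exp(-z))

reluF <- function(x) { x[x < 0] <- 0; x }

# ---- batch normalization (shared by bn layers and the residual block) ----

# per-channel sums of an (H, W, C, B) array, via one reshape
chanSums <- function(x, d) {
  rowSums(matrix(colSums(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

# per-channel broadcast: length H*W*C vector that recycles exactly over the
# batch dimension in elementwise ops with an (H, W, C, B) array
chanVec <- function(v, hw) rep(v, each = hw)

bnForward <- function(x, gamma, beta, movMean, movVar, training) {
  d <- dim(x)
  hw <- d[1] * d[2]
  n <- hw * d[4]
  if (training) {
    mu <- chanSums(x, d) / n
    va <- chanSums(x * x, d) / n - mu^2
    movMean <- BN_MOMENTUM * movMean + (1 - BN_MOMENTUM) * mu
    movVar <- BN_MOMENTUM * movVar + (1 - BN_MOMENTUM) * va
  } else {
    mu <- movMean
    va <- movVar
  }
  invsd <- 1 / sqrt(va + BN_EPS)
  xhat <- (x - chanVec(mu, hw)) * chanVec(invsd, hw)
  dim(xhat) <- d
  y <- xhat * chanVec(gamma, hw) + chanVec(beta, hw)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invsd = invsd, d = d),
       movMean = movMean, movVar = movVar)
}

bnBackward <- function(dy, cache, gamma, training) {
  d <- cache$d
  hw <- d[1] * d[2]
  xhat <- cache$xhat
  dxhat <- dy * chanVec(gamma, hw)
  dgamma <- chanSums(dy * xhat, d)
  dbeta <- chanSums(dy, d)
  if (!training) {
    dx <- dxhat * chanVec(cache$invsd, hw)
    dim(dx) <- d
    return(list(dx = dx, dgamma = dgamma, dbeta = dbeta))
  }
  n <- hw * d[4]
  m1 <- chanSums(dxhat, d) / n
  m2 <- chanSums(dxhat * xhat, d) / n
  dx <- chanVec(cache$invsd, hw) *
    (dxhat - chanVec(m1, hw) - xhat * chanVec(m2, hw))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- attention modules ----

seForward <- function(x, W1, b1, W2, b2) {
  d <- dim(x)
  g <- gapCB(x)                       # C x B
  z <- W1 %*% g + b1                  # Cr x B
  a <- reluF(z)
  s <- sigmoid(W2 %*% a + b2)         # C x B
  y <- x * bcChan(s, d[1] * d[2])
  dim(y) <- d
  list(y = y, cache = list(x = x, g = g, z = z, a = a, s = s, d = d))
}

seBackward <- function(dy, cache, W1, W2) {
  d <- cache$d
  hw <- d[1] * d[2]
  s <- cache$s
  ds <- matrix(colSums(matrix(dy * cache$x, hw, d[3] * d[4])), d[3], d[4])
  dt2 <- ds * s * (1 - s)
  dW2 <- dt2 %*% t(cache$a)
  db2 <- rowSums(dt2)
  da <- t(W2) %*% dt2
  dz <- da * (cache$z > 0)
  dW1 <- dz %*% t(cache$g)
  db1 <- rowSums(dz)
  dg <- t(W1) %*% dz
  dx <- dy * bcChan(s, hw) + bcChan(dg / hw, hw)
  dim(dx) <- d
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

gcForward <- function(x, Wg, bg) {
  d <- dim(x)
  g <- gapCB(x)
  sg <- sigmoid(Wg %*% g + bg)        # C x B
  s <- 1 + sg
  y <- x * bcChan(s, d[1] * d[2])
  dim(y) <- d
  list(y = y, cache = list(x = x, g = g, sg = sg, d = d))
}

gcBackward <- function(dy, cache, Wg) {
  d <- cache$d
  hw <- d[1] * d[2]
  s <- 1 + cache$sg
  ds <- matrix(colSums(matrix(dy * cache$x, hw, d[3] * d[4])), d[3], d[4])
  dt <- ds * cache$sg * (1 - cache$sg)
  dWg <- dt %*% t(cache$g)
  dbg <- rowSums(dt)
  dg <- t(Wg) %*% dt
  dx <- dy * bcChan(s, hw) + bcChan(dg / hw, hw)
  dim(dx) <- d
  list(dx = dx, dWg = dWg, dbg = dbg)
}

# ---- layer dispatch ----

layerForward <- function(layer, x, training = FALSE) {
  p <- layer$params
  switch(layer$type,
    conv = {
      y <- .cpp_conv2d_forward(x, dim(x), p$k, dim(p$k), p$b)
      list(y = y, cache = list(x = x), layer = layer)
    },
    dwconv = {
      y <- .cpp_dwconv_forward(x, dim(x), p$k, dim(p$k), p$b)
      list(y = y, cache = list(x = x), layer = layer)
    },
    bn = {
      r <- bnForward(x, p$gamma, p$beta, layer$state$movMean,
                     layer$state$movVar, training)
      if (training) {
        layer$state$movMean <- r$movMean
        layer$state$movVar <- r$movVar
      }
      list(y = r$y, cache = r$cache, layer = layer)
    },
    relu = {
      y <- reluF(x)
      list(y = y, cache = list(mask = x > 0), layer = layer)
    },
    maxpool = {
      r <- .cpp_maxpool_forward(x, dim(x))
      list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)), layer = layer)
    },
    se = {
      r <- seForward(x, p$W1, p$b1, p$W2, p$b2)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    gc = {
      r <- gcForward(x, p$Wg, p$bg)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    resblock = {
      u1 <- .cpp_conv2d_forward(x, dim(x), p$k1, dim(p$k1), p$cb1)
      b1 <- bnForward(u1, p$g1, p$be1, layer$state$m1, layer$state$v1, training)
      r1 <- reluF(b1$y)
      u2 <- .cpp_conv2d_forward(r1, dim(r1), p$k2, dim(p$k2), p$cb2)
      b2 <- bnForward(u2, p$g2, p$be2, layer$state$m2, layer$state$v2, training)
      sk <- .cpp_conv2d_forward(x, dim(x), p$ks, dim(p$ks), p$cbs)
      bs <- bnForward(sk, p$gs, p$bes, layer$state$ms, layer$state$vs, training)
      if (training) {
        layer$state$m1 <- b1$movMean; layer$state$v1 <- b1$movVar
        layer$state$m2 <- b2$movMean; layer$state$v2 <- b2$movVar
        layer$state$ms <- bs$movMean; layer$state$vs <- bs$movVar
      }
      y <- b2$y + bs$y  # no activation after the addition
      list(y = y,
           cache = list(x = x, r1 = r1, b1 = b1$cache, b2 = b2$cache,
                        bs = bs$cache, mask1 = b1$y > 0),
           layer = layer)
    },
    gap = {
      list(y = gapCB(x), cache = list(d = dim(x)), layer = layer)
    },
    dense = {
      y <- p$W %*% x + p$b
      list(y = y, cache = list(x = x), layer = layer)
    },
    dropout = {
      if (training && layer$cfg$rate > 0) {
        keep <- 1 - layer$cfg$rate
        mask <- (stats::runif(length(x)) < keep) / keep
        dim(mask) <- dim(x)
        list(y = x * mask, cache = list(mask = mask), layer = layer)
      } else {
        list(y = x, cache = list(mask = NULL), layer = layer)
      }
    },
    softmax = {
      z <- x - matrix(apply(x, 2, max), nrow(x), ncol(x), byrow = TRUE)
      e <- exp(z)
      pr <- e / matrix(colSums(e), nrow(x), ncol(x), byrow = TRUE)
      list(y = pr, cache = NULL, layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

layerBackward <- function(layer, cache, dy, training = FALSE) {
  p <- layer$params
  switch(layer$type,
    conv = {
      r <- .cpp_conv2d_backward(cache$x, dim(cache$x), p$k, dim(p$k), dy)
      list(dx = r$dx, grads = list(k = r$dk, b = r$db))
    },
    dwconv = {
      r <- .cpp_dwconv_backward(cache$x, dim(cache$x), p$k, dim(p$k), dy)
      list(dx = r$dx, grads = list(k = r$dk, b = r$db))
    },
    bn = {
      r <- bnBackward(dy, cache, p$gamma, training)
      list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
    },
    relu = {
      list(dx = dy * cache$mask, grads = list())
    },
    maxpool = {
      list(dx = .cpp_maxpool_backward(dy, cache$idx, cache$xdim), grads = list())
    },
    se = {
      r <- seBackward(dy, cache, p$W1, p$W2)
      list(dx = r$dx,
           grads = list(W1 = r$dW1, b1 = r$db1, W2 = r$dW2, b2 = r$db2))
    },
    gc = {
      r <- gcBackward(dy, cache, p$Wg)
      list(dx = r$dx, grads = list(Wg = r$dWg, bg = r$dbg))
    },
    resblock = {
      # main path: dy -> bn2 -> conv2 -> relu -> bn1 -> conv1
      rb2 <- bnBackward(dy, cache$b2, p$g2, training)
      rc2 <- .cpp_conv2d_backward(cache$r1, dim(cache$r1), p$k2, dim(p$k2),
                                  rb2$dx)
      dr1 <- rc2$dx * cache$mask1
      rb1 <- bnBackward(dr1, cache$b1, p$g1, training)
      rc1 <- .cpp_conv2d_backward(cache$x, dim(cache$x), p$k1, dim(p$k1),
                                  rb1$dx)
      # skip path: dy -> bn_s -> conv_s
      rbs <- bnBackward(dy, cache$bs, p$gs, training)
      rcs <- .cpp_conv2d_backward(cache$x, dim(cache$x), p$ks, dim(p$ks),
                                  rbs$dx)
      list(dx = rc1$dx + rcs$dx,
           grads = list(k1 = rc1$dk, cb1 = rc1$db, g1 = rb1$dgamma,
                        be1 = rb1$dbeta, k2 = rc2$dk, cb2 = rc2$db,
                        g2 = rb2$dgamma, be2 = rb2$dbeta, ks = rcs$dk,
                        cbs = rcs$db, gs = rbs$dgamma, bes = rbs$dbeta))
    },
    gap = {
      d <- cache$d
      hw <- d[1] * d[2]
      dx <- bcChan(dy / hw, hw)
      dim(dx) <- d
      list(dx = dx, grads = list())
    },
    dense = {
      list(dx = t(p$W) %*% dy,
           grads = list(W = dy %*% t(cache$x), b = rowSums(dy)))
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = list())
      else list(dx = dy * cache$mask, grads = list())
    },
    stop("no backward pass for layer type: ", layer$type)
  )
}
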