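## Internal minimal convolutional network: valid convolutions via im2col,
## 2x2 downsampling, fully connected layers, softmax + cross-entropy, SGD
## with momentum. Batches are stored as N x (H*W*C) matrices in column-major
## spatial order (row fastest, then column, then channel).

# Index matrix P x Q mapping output position p (row-fastest) and kernel
# offset q (kernel-row fastest, then kernel-col, then channel) to linear
# indices of an H x W x C grid.
im2colIndex <- function(h, w, c, k) {
  oh <- h - k + 1L; ow <- w - k + 1L
  pi <- rep(seq_len(oh), times = ow)
  pj <- rep(seq_len(ow), each = oh)
  off <- expand.grid(di = 0:(k - 1L), dj = 0:(k - 1L), ch = seq_len(c))
  P <- oh * ow; Q <- nrow(off)
  idx <- matrix(0L, P, Q)
  for (q in seq_len(Q)) {
    idx[, q] <- (pi + off$di[q]) + h * (pj + off$dj[q] - 1L) +
      h * w * (off$ch[q] - 1L)
  }
  idx
}

# Index matrix (P2*C) x s^2 for non-overlapping s x s pooling windows.
poolIndex <- function(h, w, c, s = 2L) {
  oh <- h %/% s; ow <- w %/% s
  pos <- expand.grid(i = seq_len(oh), j = seq_len(ow), ch = seq_len(c))
  P <- nrow(pos)
  idx <- matrix(0L, P, s * s)
  q <- 0L
  for (dj in 0:(s - 1L)) for (di in 0:(s - 1L)) {
    q <- q + 1L
    idx[, q] <- ((pos$i - 1L) * s + 1L + di) + h * ((pos$j - 1L) * s + dj) +
      h * w * (pos$ch - 1L)
  }
  idx
}

# Static geometry of the network for a given input patch/channel count.
netGeometry <- function(config, channels) {
  k <- config@kernelSize
  h <- config@patchSize; w <- config@patchSize; c <- channels
  convs <- list()
  for (i in seq_along(config@convChannels)) {
    oh <- h - k + 1L; ow <- w - k + 1L
    cout <- config@convChannels[i]
    ph <- oh %/% 2L; pw <- ow %/% 2L
    convs[[i]] <- list(
      inDim = c(h, w, c), convDim = c(oh, ow, cout), poolDim = c(ph, pw, cout),
      idx = im2colIndex(h, w, c, k),
      pidx = poolIndex(oh, ow, cout, 2L))
    h <- ph; w <- pw; c <- cout
  }
  list(convs = convs, flat = h * w * c)
}

netInit <- function(config, channels) {
  geom <- netGeometry(config, channels)
  k <- config@kernelSize
  params <- list(conv = list(), geom = geom)
  cin <- channels
  for (i in seq_along(config@convChannels)) {
    cout <- config@convChannels[i]
    fanIn <- k * k * cin
    params$conv[[i]] <- list(
      W = matrix(rnorm(fanIn * cout, 0, sqrt(2 / fanIn)), fanIn, cout),
      b = numeric(cout))
    cin <- cout
  }
  params$fc1 <- list(
    W = matrix(rnorm(geom$flat * config@fcUnits, 0, sqrt(2 / geom$flat)),
               geom$flat, config@fcUnits),
    b = numeric(config@fcUnits))
  params$fc2 <- list(
    W = matrix(rnorm(config@fcUnits * config@nClasses, 0, sqrt(2 / config@fcUnits)),
               config@fcUnits, config@nClasses),
    b = numeric(config@nClasses))
  params
}

netActivate <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else softplus(z)
}

netActivateGrad <- function(z, activation) {
  if (activation == "relu") (z > 0) * 1 else 1 / (1 + exp(-z))
}

# Forward pass. X: N x (P*P*C). Returns softmax probabilities and, when
# `cache` is TRUE, the intermediates needed for backprop.
netForward <- function(params, config, X, cache = FALSE) {
  geom <- params$geom
  N <- nrow(X)
  caches <- list()
  for (i in seq_along(geom$convs)) {
    g <- geom$convs[[i]]
    P <- nrow(g$idx); Q <- ncol(g$idx)
    A <- X[, as.vector(g$idx), drop = FALSE]
    dim(A) <- c(N * P, Q)
    Z <- A %*% params$conv[[i]]$W
    Z <- sweep(Z, 2L, params$conv[[i]]$b, "+")
    H <- netActivate(Z, config@activation)
    dim(H) <- c(N, P * ncol(Z))            # N x (conv spatial * cout)
    # pooling
    P2 <- nrow(g$pidx)
    Ap <- H[, as.vector(g$pidx), drop = FALSE]
    dim(Ap) <- c(N * P2, 4L)
    if (config@pool == "max") {
      arg <- max.col(Ap, ties.method = "first")
      Y <- Ap[cbind(seq_len(N * P2), arg)]
    } else {
      arg <- NULL
      Y <- rowMeans(Ap)
    }
    dim(Y) <- c(N, P2)
    if (cache) caches[[i]] <- list(Xin = X, Acol = A, Z = Z, arg = arg, Ncells = N * P2)
    X <- Y
  }
  Z1 <- sweep(X %*% params$fc1$W, 2L, params$fc1$b, "+")
  H1 <- netActivate(Z1, config@activation)
  Z2 <- sweep(H1 %*% params$fc2$W, 2L, params$fc2$b, "+")
  m <- apply(Z2, 1L, max)
  E <- exp(Z2 - m)
  probs <- E / rowSums(E)
  if (!cache) return(list(probs = probs))
  list(probs = probs, caches = caches, flatIn = X, Z1 = Z1, H1 = H1)
}

# Backward pass; returns gradients with the same structure as params.
netBackward <- function(params, config, fwd, Y1hot) {
  geom <- params$geom
  N <- nrow(Y1hot)
  grads <- list(conv = vector("list", length(geom$convs)))
  dZ2 <- (fwd$probs - Y1hot) / N
  grads$fc2 <- list(W = crossprod(fwd$H1, dZ2), b = colSums(dZ2))
  dH1 <- dZ2 %*% t(params$fc2$W)
  dZ1 <- dH1 * netActivateGrad(fwd$Z1, config@activation)
  grads$fc1 <- list(W = crossprod(fwd$flatIn, dZ1), b = colSums(dZ1))
  dX <- dZ1 %*% t(params$fc1$W)            # N x flat
  for (i in rev(seq_along(geom$convs))) {
    g <- geom$convs[[i]]
    cc <- fwd$caches[[i]]
    P2 <- nrow(g$pidx)
    # un-pool: dX is N x P2 -> gradient on the activated conv output H
    convCells <- prod(g$convDim)
    dH <- matrix(0, N, convCells)
    dXmat <- dX
    dim(dXmat) <- c(N, P2)
    if (config@pool == "max") {
      ARG <- cc$arg
      dim(ARG) <- c(N, P2)
      for (j in 1:4) {
        sel <- (ARG == j) * dXmat
        cols <- g$pidx[, j]
        dH[, cols] <- dH[, cols] + sel
      }
    } else {
      for (j in 1:4) {
        cols <- g$pidx[, j]
        dH[, cols] <- dH[, cols] + dXmat / 4
      }
    }
    # through the activation to the pre-activation conv output
    P <- nrow(g$idx)
    cout <- g$convDim[3L]
    dHmat <- dH
    dim(dHmat) <- c(N * P, cout)
    dZ <- dHmat * netActivateGrad(cc$Z, config@activation)
    grads$conv[[i]] <- list(W = crossprod(cc$Acol, dZ), b = colSums(dZ))
    # propagate to the layer input unless this is the first layer
    if (i > 1L) {
      dA <- dZ %*% t(params$conv[[i]]$W)   # (N*P) x Q
      Q <- ncol(g$idx)
      dim(dA) <- c(N, P, Q)
      dXin <- matrix(0, N, prod(g$inDim))
      for (q in seq_len(Q)) {
        cols <- g$idx[, q]
        dXin[, cols] <- dXin[, cols] + dA[, , q]
      }
      dX <- dXin
    }
  }
  grads
}

netUpdate <- function(params, grads, vel, lr, momentum = 0.9) {
  upd <- function(p, g, v) {
    v$W <- momentum * v$W - lr * g$W
    v$b <- momentum * v$b - lr * g$b
    p$W <- p$W + v$W
    p$b <- p$b + v$b
    list(p = p, v = v)
  }
  for (i in seq_along(params$conv)) {
    r <- upd(params$conv[[i]], grads$conv[[i]], vel$conv[[i]])
    params$conv[[i]] <- r$p; vel$conv[[i]] <- r$v
  }
  for (nm in c("fc1", "fc2")) {
    r <- upd(params[[nm]], grads[[nm]], vel[[nm]])
    params[[nm]] <- r$p; vel[[nm]] <- r$v
  }
  list(params = params, vel = vel)
}

netZeroVel <- function(params) {
  zero <- function(p) list(W = p$W * 0, b = p$b * 0)
  list(conv = lapply(params$conv, zero), fc1 = zero(params$fc1),
       fc2 = zero(params$fc2))
}

# One SGD epoch over pre-extracted patches; returns params, velocity and
# the mean cross-entropy.
netEpoch <- function(params, vel, config, X, y1hot, order) {
  N <- nrow(X)
  bs <- config@batchSize
  lossSum <- 0
  nb <- 0L
  for (start in seq(1L, N, by = bs)) {
    rows <- order[start:min(start + bs - 1L, N)]
    fwd <- netForward(params, config, X[rows, , drop = FALSE], cache = TRUE)
    Yb <- y1hot[rows, , drop = FALSE]
    lossSum <- lossSum + -mean(log(pmax(rowSums(fwd$probs * Yb), 1e-12))) *
      length(rows)
    grads <- netBackward(params, config, fwd, Yb)
    r <- netUpdate(params, grads, vel, config@learningRate)
    params <- r$params; vel <- r$vel
    nb <- nb + 1L
  }
  list(params = params, vel = vel, loss = lossSum / N)
}

## Patch extraction ----------------------------------------------------------

# Reflect-pad each channel of an H x W x C stack by `pad`.
padStack <- function(stack, pad) {
  h <- dim(stack)[1L]; w <- dim(stack)[2L]; C <- dim(stack)[3L]
  ri <- reflectIndex(seq.int(1L - pad, h + pad), h)
  ci <- reflectIndex(seq.int(1L - pad, w + pad), w)
  stack[ri, ci, , drop = FALSE]
}

# Extract P x P x C patches centered on the given (row, col) pixels of an
# H x W x C stack, as an N x (P*P*C) matrix (reflect padding at borders).
extractPatches <- function(stack, rows, cols, patchSize) {
  pad <- (patchSize - 1L) %/% 2L
  padded <- padStack(stack, pad)
  H2 <- dim(padded)[1L]; W2 <- dim(padded)[2L]; C <- dim(padded)[3L]
  # top-left corner of each patch in padded coordinates
  base <- rows + H2 * (cols - 1L)
  offs <- as.vector(outer(0:(patchSize - 1L),
                          H2 * (0:(patchSize - 1L)), "+"))
  offs <- as.vector(outer(offs, H2 * W2 * (0:(C - 1L)), "+"))
  idx <- outer(as.integer(base), as.integer(offs), "+")
  out <- padded[idx]
  dim(out) <- c(length(base), length(offs))
  out
}
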