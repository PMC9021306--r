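# Internal 1-D CNN machinery: convolution via shifted matrix products,
# max pooling, batch normalization, dense layers, and Adam. Everything is
# plain matrix algebra so training is deterministic on one CPU for a
# fixed seed.
#
# An activation tensor with n samples, L time steps and C channels is
# stored as an (n*L) x C matrix whose row index is r = i + (l-1)*n
# (sample index i varying fastest). Shifting the time step by one is then
# a row shift by n, which lets the same-padded convolution with kernel
# length k be computed as k shifted matrix products without any array
# reshaping; rows falling outside the signal are the zero padding.

.conv_forward <- function(X, W, b, k, n, nL) {
  C <- ncol(X)
  f <- ncol(W)
  p <- (k - 1L) %/% 2L
  Z <- matrix(rep(b, each = nL), nL, f)
  for (o in seq_len(k)) {
    Wo <- W[(o - 1L) * C + seq_len(C), , drop = FALSE]
    d <- o - p - 1L
    if (d == 0L) {
      Z <- Z + X %*% Wo
    } else if (d < 0L) {
      rows_z <- (-d * n + 1L):nL
      Z[rows_z, ] <- Z[rows_z, , drop = FALSE] +
        X[seq_len(nL + d * n), , drop = FALSE] %*% Wo
    } else {
      rows_z <- seq_len(nL - d * n)
      Z[rows_z, ] <- Z[rows_z, , drop = FALSE] +
        X[(d * n + 1L):nL, , drop = FALSE] %*% Wo
    }
  }
  Z
}

.conv_backward <- function(X, dZ, W, k, n, nL) {
  C <- ncol(X)
  f <- ncol(dZ)
  p <- (k - 1L) %/% 2L
  dW <- matrix(0, k * C, f)
  dX <- matrix(0, nL, C)
  for (o in seq_len(k)) {
    d <- o - p - 1L
    if (d == 0L) {
      rows_x <- rows_z <- seq_len(nL)
    } else if (d < 0L) {
      rows_x <- seq_len(nL + d * n)
      rows_z <- (-d * n + 1L):nL
    } else {
      rows_x <- (d * n + 1L):nL
      rows_z <- seq_len(nL - d * n)
    }
    Wo <- W[(o - 1L) * C + seq_len(C), , drop = FALSE]
    dW[(o - 1L) * C + seq_len(C), ] <-
      crossprod(X[rows_x, , drop = FALSE], dZ[rows_z, , drop = FALSE])
    dX[rows_x, ] <- dX[rows_x, , drop = FALSE] +
      dZ[rows_z, , drop = FALSE] %*% t(Wo)
  }
  list(dW = dW, dX = dX)
}

# Row indices of the odd / even time steps feeding a pool of size 2.
.pool_rows <- function(n, L) {
  L2 <- L %/% 2L
  i1 <- as.integer(outer(seq_len(n), (seq(1L, 2L * L2, by = 2L) - 1L) * n,
                         `+`))
  list(i1 = i1, i2 = i1 + n, L2 = L2)
}

.bn_forward <- function(x, ly, training, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x * x) - mu * mu
    v[v < 0] <- 0
  } else {
    mu <- ly$running_mean
    v <- ly$running_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, inv, `*`)
  y <- sweep(sweep(xhat, 2, ly$gamma, `*`), 2, ly$beta, `+`)
  list(y = y, xhat = xhat, inv = inv, mu = mu, v = v)
}

.bn_backward <- function(dy, cache, gamma) {
  n <- nrow(dy)
  f <- ncol(dy)
  dxhat <- sweep(dy, 2, gamma, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(dxhat - matrix(s1 / n, n, f, byrow = TRUE) -
                cache$xhat * matrix(s2 / n, n, f, byrow = TRUE),
              2, cache$inv, `*`)
  list(dx = dx, dgamma = colSums(dy * cache$xhat), dbeta = colSums(dy))
}

.nn_forward <- function(net, x, baseline = NULL, training = FALSE) {
  cfg <- net$config
  n_conv <- length(cfg$filters_eff)
  caches <- vector("list", n_conv)
  d <- dim(x)
  n <- d[1]
  L <- d[2]
  X <- matrix(x, n * L, d[3])      # (i,l) rows, channel columns
  for (u in seq_len(n_conv)) {
    ly <- net$layers[[u]]
    nL <- n * L
    Z <- .conv_forward(X, ly$W, ly$b, cfg$kernel_len, n, nL)
    mask <- Z > 0
    A <- Z * mask
    pr <- .pool_rows(n, L)
    a1 <- A[pr$i1, , drop = FALSE]
    a2 <- A[pr$i2, , drop = FALSE]
    pmask <- a1 >= a2                # ties route to the first slot
    caches[[u]] <- list(X = X, relu_mask = mask, pr = pr, pmask = pmask,
                        n = n, L = L)
    X <- pmax(a1, a2)
    L <- pr$L2
  }
  # flatten (n*L x C) -> (n x L*C); the shared linear layout makes this a
  # relabelling of dimensions, not a data rearrangement
  C_last <- ncol(X)
  flat <- X
  dim(flat) <- c(n, L * C_last)
  if (cfg$use_baseline_bgl) {
    if (is.null(baseline))
      stop("paired model requires a baseline glucose per sample")
    flat <- cbind(flat, baseline * cfg$baseline_scale)
  }
  bnl <- net$layers[[n_conv + 1L]]
  bn <- .bn_forward(flat, bnl, training)
  d1 <- net$layers[[n_conv + 2L]]
  h_pre <- bn$y %*% d1$W + matrix(d1$b, n, length(d1$b), byrow = TRUE)
  hmask <- h_pre > 0
  h <- h_pre * hmask
  d2 <- net$layers[[n_conv + 3L]]
  pred <- drop(h %*% d2$W) + d2$b
  list(pred = pred, caches = caches, flat_dim = c(n, L, C_last),
       bn = bn, h = h, hmask = hmask)
}

.nn_backward <- function(net, fw, dpred) {
  cfg <- net$config
  n_conv <- length(cfg$filters_eff)
  grads <- vector("list", length(net$layers))
  dp <- matrix(dpred, ncol = 1)

  d2 <- net$layers[[n_conv + 3L]]
  grads[[n_conv + 3L]] <- list(W = crossprod(fw$h, dp), b = sum(dpred))
  dh <- (dp %*% t(d2$W)) * fw$hmask

  d1 <- net$layers[[n_conv + 2L]]
  grads[[n_conv + 2L]] <- list(W = crossprod(fw$bn$y, dh), b = colSums(dh))
  dbny <- dh %*% t(d1$W)

  bnl <- net$layers[[n_conv + 1L]]
  bnb <- .bn_backward(dbny, fw$bn, bnl$gamma)
  grads[[n_conv + 1L]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
  dflat <- bnb$dx
  if (cfg$use_baseline_bgl) dflat <- dflat[, -ncol(dflat), drop = FALSE]
  fd <- fw$flat_dim
  dX <- dflat
  dim(dX) <- c(fd[1] * fd[2], fd[3])

  for (u in rev(seq_len(n_conv))) {
    cache <- fw$caches[[u]]
    n <- cache$n
    L <- cache$L
    nL <- n * L
    dA <- matrix(0, nL, ncol(cache$relu_mask))
    dA[cache$pr$i1, ] <- dX * cache$pmask
    dA[cache$pr$i2, ] <- dX * !cache$pmask
    dZ <- dA * cache$relu_mask
    ly <- net$layers[[u]]
    cb <- .conv_backward(cache$X, dZ, ly$W, cfg$kernel_len, n, nL)
    grads[[u]] <- list(W = cb$dW, b = colSums(dZ))
    dX <- cb$dX
  }
  grads
}

.adam_step <- function(net, grads, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  net$t <- net$t + 1L
  bc1 <- 1 - beta1^net$t
  bc2 <- 1 - beta2^net$t
  for (u in seq_along(grads)) {
    for (p in names(grads[[u]])) {
      g <- grads[[u]][[p]]
      st <- net$opt[[u]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      net$opt[[u]][[p]] <- st
      net$layers[[u]][[p]] <- net$layers[[u]][[p]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  net
}
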