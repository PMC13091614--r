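# Minimal feed-forward network backend for the "nn" model family.
#
# Three hidden layers (sizes configurable), Leaky ReLU hidden activations,
# softmax output, Adam optimizer on (optionally class-weighted) categorical
# cross-entropy. Pure matrix R: no external backend required, fully
# reproducible under a seed.

LEAKY_SLOPE <- 0.01

.leaky <- function(z) ifelse(z > 0, z, LEAKY_SLOPE * z)
.leaky_grad <- function(z) ifelse(z > 0, 1, LEAKY_SLOPE)

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.mlp_init <- function(d_in, hidden, d_out, seed) {
  set.seed(seed)
  sizes <- c(d_in, hidden, d_out)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    # He initialization, appropriate for (leaky) ReLU layers
    list(W = matrix(rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
                    sizes[l], sizes[l + 1L]),
         b = rep(0, sizes[l + 1L]))
  })
}

.mlp_forward <- function(layers, X) {
  L <- length(layers)
  Z <- vector("list", L); A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    A[[l + 1L]] <- if (l < L) .leaky(Z[[l]]) else .softmax(Z[[l]])
  }
  list(Z = Z, A = A)
}

.mlp_train <- function(X, y, hidden = c(50L, 100L, 50L), lr = 0.01,
                       epochs = 50L, batch_size = 256L, weights = NULL,
                       seed = 1L) {
  n <- nrow(X); d <- ncol(X); K <- max(y) + 1L
  if (is.null(weights)) weights <- rep(1, n)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y + 1L)] <- 1
  layers <- .mlp_init(d, hidden, K, seed)
  L <- length(layers)
  # Adam state
  m <- lapply(layers, function(p) list(W = p$W * 0, b = p$b * 0))
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L

  for (ep in seq_len(epochs)) {
    set.seed(seed + ep)
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1L, n)]
      Xb <- X[ix, , drop = FALSE]; Yb <- Y[ix, , drop = FALSE]
      wb <- weights[ix] / sum(weights[ix])
      fw <- .mlp_forward(layers, Xb)
      # weighted cross-entropy gradient at the softmax layer
      delta <- (fw$A[[L + 1L]] - Yb) * wb
      t <- t + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(fw$A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(layers[[l]]$W)) * .leaky_grad(fw$Z[[l - 1L]])
        m[[l]]$W <- b1 * m[[l]]$W + (1 - b1) * gW
        m[[l]]$b <- b1 * m[[l]]$b + (1 - b1) * gb
        v[[l]]$W <- b2 * v[[l]]$W + (1 - b2) * gW^2
        v[[l]]$b <- b2 * v[[l]]$b + (1 - b2) * gb^2
        mhW <- m[[l]]$W / (1 - b1^t); mhb <- m[[l]]$b / (1 - b1^t)
        vhW <- v[[l]]$W / (1 - b2^t); vhb <- v[[l]]$b / (1 - b2^t)
        layers[[l]]$W <- layers[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
        layers[[l]]$b <- layers[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
      }
    }
  }
  list(layers = layers, hidden = hidden)
}

.mlp_predict <- function(fit, X) {
  fw <- .mlp_forward(fit$layers, X)
  fw$A[[length(fit$layers) + 1L]]
}
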