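# Minimal dense feed-forward regressor (three fully connected layers:
# input -> hidden1 -> hidden2 -> output, ReLU activations, Adam on MSE).
# Kept deliberately small: dense matrix algebra is all these shapes need.

mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  layers <- vector("list", length(sizes) - 1)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    # He initialization for the ReLU layers
    layers[[l]] <- list(
      W = matrix(rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                 nrow = fan_in),
      b = rep(0, sizes[l + 1])
    )
  }
  layers
}

mlp_forward <- function(layers, X) {
  acts <- list(X)
  n_layers <- length(layers)
  H <- X
  for (l in seq_len(n_layers)) {
    Z <- sweep(H %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    H <- if (l < n_layers) pmax(Z, 0) else Z
    acts[[l + 1]] <- H
  }
  list(out = H, acts = acts)
}

mlp_train <- function(X, Y, hidden = c(64L, 32L), lr = 1e-3, epochs = 20L,
                      batch_size = 256L, seed = 1L) {
  withr_seed(seed, {
    layers <- mlp_init(ncol(X), hidden, ncol(Y))
    mom <- lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                           mb = l$b * 0, vb = l$b * 0))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0
    n <- nrow(X)
    for (epoch in seq_len(epochs)) {
      perm <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        fw <- mlp_forward(layers, Xb)
        grad_out <- 2 * (fw$out - Yb) / (nrow(Xb) * ncol(Yb))  # d MSE
        t_step <- t_step + 1
        delta <- grad_out
        for (l in rev(seq_along(layers))) {
          A_prev <- fw$acts[[l]]
          gW <- crossprod(A_prev, delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(layers[[l]]$W)) * (fw$acts[[l]] > 0)
          }
          m <- mom[[l]]
          m$mW <- beta1 * m$mW + (1 - beta1) * gW
          m$vW <- beta2 * m$vW + (1 - beta2) * gW^2
          m$mb <- beta1 * m$mb + (1 - beta1) * gb
          m$vb <- beta2 * m$vb + (1 - beta2) * gb^2
          mom[[l]] <- m
          corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
          layers[[l]]$W <- layers[[l]]$W -
            lr * (m$mW / corr1) / (sqrt(m$vW / corr2) + eps)
          layers[[l]]$b <- layers[[l]]$b -
            lr * (m$mb / corr1) / (sqrt(m$vb / corr2) + eps)
        }
      }
    }
    layers
  })
}

mlp_predict <- function(layers, X) mlp_forward(layers, X)$out
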