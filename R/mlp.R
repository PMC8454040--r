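# Small fully-connected binary classifier used by the voting ensemble:
# hidden layers with rectified-linear activations, one sigmoid output unit,
# class-weighted cross-entropy loss, minibatch Adam, inputs standardized with
# training-set statistics. Written with plain matrix algebra so training is
# deterministic given the seed.

mlpInit <- function(inputDim, hidden, seed) {
  sizes <- c(inputDim, hidden, 1L)
  withSeed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fanIn <- sizes[l]
      list(W = matrix(stats::rnorm(fanIn * sizes[l + 1L], sd = sqrt(2 / fanIn)),
                      fanIn, sizes[l + 1L]),
           b = rep(0, sizes[l + 1L]))
    })
  })
}

mlpStandardize <- function(model, X)
  sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")

# Forward pass; returns activations per layer when `keep` (for backprop).
# `X` must already be standardized when `model` is a bare layer list.
mlpLayersForward <- function(layers, X, keep = FALSE) {
  A <- X
  acts <- if (keep) list(A) else NULL
  nl <- length(layers)
  for (l in seq_len(nl)) {
    Z <- sweep(A %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    A <- if (l < nl) pmax(Z, 0) else 1 / (1 + exp(-Z))
    if (keep) acts[[l + 1L]] <- A
  }
  if (keep) list(prob = as.numeric(A), acts = acts) else as.numeric(A)
}

mlpPredict <- function(model, X)
  mlpLayersForward(model$layers, mlpStandardize(model, X))

# Train one network. `posWeight` scales the loss of label-1 examples
# (set to nNeg/nPos to balance an imbalanced dataset).
mlpTrain <- function(X, y, hidden = c(64L, 32L, 8L), epochs = 100L,
                     batchSize = 128L, lr = 1e-3, posWeight = 1,
                     seed = 1L) {
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  layers <- mlpInit(ncol(X), hidden, seed)
  nl <- length(layers)
  mW <- lapply(layers, function(l) l$W * 0); vW <- mW
  mB <- lapply(layers, function(l) l$b * 0); vB <- mB
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  n <- nrow(Xs)
  w <- ifelse(y == 1, posWeight, 1)
  withSeed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1L, n)]
        fw <- mlpLayersForward(layers, Xs[idx, , drop = FALSE], keep = TRUE)
        # weighted gradient of sigmoid + cross-entropy
        delta <- matrix(w[idx] * (fw$prob - y[idx]), ncol = 1L) / sum(w[idx])
        t <- t + 1L
        for (l in rev(seq_len(nl))) {
          A <- fw$acts[[l]]
          gW <- crossprod(A, delta)
          gB <- colSums(delta)
          if (l > 1L)
            delta <- (delta %*% t(layers[[l]]$W)) * (fw$acts[[l]] > 0)
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
          mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gB
          vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gB^2
          corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
          layers[[l]]$W <- layers[[l]]$W -
            lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
          layers[[l]]$b <- layers[[l]]$b -
            lr * (mB[[l]] / corr1) / (sqrt(vB[[l]] / corr2) + eps)
        }
      }
    }
  })
  list(layers = layers, center = center, scale = scale)
}
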