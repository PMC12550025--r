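# Minimal dense-network toolkit: Glorot-initialized linear layers, ReLU,
# block softmax, and Adam. Forward passes cache what the hand-written
# backward passes need. Everything operates on row-major batches
# (one sample per row).

nn_linear_init <- function(rng, nin, nout) {
  sd <- sqrt(2 / (nin + nout))
  list(W = matrix(rng$rnorm(nin * nout, 0, sd), nin, nout),
       b = numeric(nout))
}

nn_linear_fwd <- function(p, X) {
  sweep(X %*% p$W, 2, p$b, `+`)
}

# Returns gradients for the layer and the input.
nn_linear_bwd <- function(p, X, dY) {
  list(dW = crossprod(X, dY), db = colSums(dY), dX = tcrossprod(dY, p$W))
}

nn_relu <- function(X) (X > 0) * X
nn_relu_bwd <- function(X, dY) (X > 0) * dY

# Softmax over blocks of `block` consecutive columns (each block is one
# categorical fiber). X is n x (nblocks*block).
nn_block_softmax <- function(X, block) {
  n <- nrow(X); nb <- ncol(X) / block
  out <- X
  for (b in seq_len(nb)) {
    cols <- ((b - 1L) * block + 1L):(b * block)
    sl <- X[, cols, drop = FALSE]
    sl <- exp(sl - apply(sl, 1, max))
    out[, cols] <- sl / rowSums(sl)
  }
  out
}

# Backward of y = block_softmax(x) given upstream dY and the forward
# output P: dX = P * (dY - rowSums(dY * P)) per block.
nn_block_softmax_bwd <- function(P, dY, block) {
  n <- nrow(P); nb <- ncol(P) / block
  dX <- dY
  for (b in seq_len(nb)) {
    cols <- ((b - 1L) * block + 1L):(b * block)
    Pb <- P[, cols, drop = FALSE]; dYb <- dY[, cols, drop = FALSE]
    dX[, cols] <- Pb * (dYb - rowSums(dYb * Pb))
  }
  dX
}

# Weighted categorical cross-entropy over column blocks with one-hot
# truth. Returns mean-per-sample loss and the gradient wrt logits.
# `w` is a per-channel weight applied through the true channel.
nn_block_ce <- function(logits, truth, block, w = NULL) {
  n <- nrow(logits)
  P <- nn_block_softmax(logits, block)
  eps <- 1e-12
  nb <- ncol(logits) / block
  if (is.null(w)) w <- rep(1, block)
  # weight of each fiber = w[true channel]
  fib_w <- matrix(0, n, nb)
  for (b in seq_len(nb)) {
    cols <- ((b - 1L) * block + 1L):(b * block)
    fib_w[, b] <- truth[, cols, drop = FALSE] %*% w
  }
  loss <- 0
  dlog <- matrix(0, n, ncol(logits))
  for (b in seq_len(nb)) {
    cols <- ((b - 1L) * block + 1L):(b * block)
    Pb <- P[, cols, drop = FALSE]; Tb <- truth[, cols, drop = FALSE]
    loss <- loss + sum(-fib_w[, b] * log(rowSums(Pb * Tb) + eps))
    dlog[, cols] <- fib_w[, b] * (Pb - Tb)
  }
  list(loss = loss / n, dlogits = dlog / n, probs = P)
}

## ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0),
         how = "list", classes = "ANY")
}

# params and grads share the same nested structure.
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    if (is.list(p)) {
      out <- mapply(upd, p, g, s, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), s = lapply(out, `[[`, "s")))
    }
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- s$m / (1 - beta1^t)
    vh <- s$v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
  }
  out <- mapply(upd, params, grads, state, SIMPLIFY = FALSE)
  list(params = lapply(out, `[[`, "p"), state = lapply(out, `[[`, "s"))
}

# Elementwise addition of two identically shaped nested gradient lists.
grad_add <- function(a, b) {
  if (is.list(a)) return(mapply(grad_add, a, b, SIMPLIFY = FALSE))
  a + b
}

grad_zero_like <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}
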