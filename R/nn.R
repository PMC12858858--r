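# Feed-forward scorer and AdamW optimizer, implemented with BLAS-backed
# matrix operations. The network maps a d-dimensional cell embedding through
# three ReLU hidden layers of width 256 to G softplus-activated gene scores,
# so every instance-level prediction is non-negative.

nn_init <- function(d, G, hidden = 256, n_hidden = 3, seed = 0,
                    out_mean = NULL) {
  set.seed(derive_seed(seed, "init"))
  dims <- c(d, rep(hidden, n_hidden), G)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1L)) {
    bound <- 1 / sqrt(dims[l])
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -bound, bound),
                     dims[l], dims[l + 1L])
    b[[l]] <- stats::runif(dims[l + 1L], -bound, bound)
  }
  # start the softplus output at the per-gene mean target so the network only
  # has to learn deviations; softplus^{-1}(m) = log(expm1(m))
  if (!is.null(out_mean)) {
    m <- pmax(out_mean, 1e-4)
    b[[length(b)]] <- ifelse(m > 30, m, log(expm1(m)))
  }
  list(W = W, b = b, dims = dims)
}

# Forward pass; returns the softplus output and, when `cache` is TRUE, the
# intermediate activations needed for backprop.
nn_forward <- function(net, X, cache = FALSE) {
  L <- length(net$W)
  H <- X
  Hs <- if (cache) vector("list", L) else NULL
  Zs <- if (cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    if (cache) Hs[[l]] <- H
    Z <- sweep(H %*% net$W[[l]], 2, net$b[[l]], "+")
    if (l < L) H <- relu(Z) else H <- softplus(Z)
    if (cache) Zs[[l]] <- Z
  }
  if (cache) list(P = H, Hs = Hs, Zs = Zs) else H
}

# Backward pass from the gradient of the loss w.r.t. the softplus output.
nn_backward <- function(net, fwd, dP) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dP * sigmoid(fwd$Zs[[L]])          # softplus'(z) = sigmoid(z)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$Hs[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- tcrossprod(delta, net$W[[l]])
      delta <- delta * (fwd$Zs[[l - 1L]] > 0)  # ReLU gate
    }
  }
  list(W = gW, b = gb)
}

# AdamW over a flat named list of numeric arrays: decoupled weight decay on
# weight matrices (not biases / dispersion), bias-corrected first and second
# moments.
adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0.01, decay_mask = NULL) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    step <- (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
    wd <- if (is.null(decay_mask) || isTRUE(decay_mask[[k]])) weight_decay else 0
    params[[k]] <- params[[k]] - lr * step - lr * wd * params[[k]]
  }
  list(params = params, state = state)
}

# Flatten / unflatten the network (+ optional log-dispersion) for the optimizer.
nn_flatten <- function(net, log_alpha = NULL) {
  p <- list()
  for (l in seq_along(net$W)) {
    p[[paste0("W", l)]] <- net$W[[l]]
    p[[paste0("b", l)]] <- net$b[[l]]
  }
  if (!is.null(log_alpha)) p$log_alpha <- log_alpha
  p
}

nn_unflatten <- function(params, net) {
  for (l in seq_along(net$W)) {
    net$W[[l]] <- params[[paste0("W", l)]]
    net$b[[l]] <- params[[paste0("b", l)]]
  }
  net
}
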