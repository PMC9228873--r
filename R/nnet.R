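## Minimal dense-network machinery: Glorot initialisation, forward pass with
## inverted dropout, explicit backward pass, and an Adam optimiser.  Only the
## pieces the adversarial autoencoder needs; all state is plain R lists so
## that "frozen" sub-networks can be asserted bit-identical across steps.

act_fun <- function(name) {
  switch(name,
    sigmoid = function(z) 1 / (1 + exp(-z)),
    tanh = tanh,
    relu = function(z) pmax(z, 0),
    linear = identity,
    stop_bad("unknown activation '%s'", name))
}

## derivative expressed through the activation output a (cheaper than
## recomputing from z for sigmoid/tanh)
act_grad <- function(name, a) {
  switch(name,
    sigmoid = a * (1 - a),
    tanh = 1 - a^2,
    relu = (a > 0) * 1,
    linear = array(1, dim(a)),
    stop_bad("unknown activation '%s'", name))
}

## sizes: c(n_in, hidden..., n_out); hidden_act applied to all but the last
## layer, out_act to the last.
mlp_init <- function(sizes, hidden_act, out_act) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    limit <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -limit, limit),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  acts <- c(rep(hidden_act, L - 1L), out_act)
  list(sizes = sizes, W = W, b = b, acts = acts)
}

## forward pass; dropout (inverted) applied to hidden activations when
## training = TRUE and rate > 0.  Returns output plus caches for backward.
mlp_forward <- function(net, X, dropout = 0, training = FALSE) {
  L <- length(net$W)
  a <- X
  a_list <- vector("list", L + 1L)
  mask_list <- vector("list", L)
  a_list[[1L]] <- a
  for (l in seq_len(L)) {
    z <- a %*% net$W[[l]]
    z <- sweep(z, 2L, net$b[[l]], `+`)
    a <- act_fun(net$acts[l])(z)
    if (training && dropout > 0 && l < L) {
      mask <- matrix(stats::rbinom(length(a), 1L, 1 - dropout) / (1 - dropout),
                     nrow(a), ncol(a))
      a <- a * mask
      mask_list[[l]] <- mask
    }
    a_list[[l + 1L]] <- a
  }
  list(out = a, a = a_list, masks = mask_list)
}

## backward pass from dL/dz at the output layer (pre-activation gradient).
## Returns weight/bias gradients and dL/dinput.
mlp_backward <- function(net, cache, dz_out) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  dz <- dz_out
  for (l in L:1) {
    gW[[l]] <- crossprod(cache$a[[l]], dz)
    gb[[l]] <- colSums(dz)
    if (l > 1L) {
      da <- tcrossprod(dz, net$W[[l]])
      if (!is.null(cache$masks[[l - 1L]])) da <- da * cache$masks[[l - 1L]]
      dz <- da * act_grad(net$acts[l - 1L], cache$a[[l]])
    } else {
      d_input <- tcrossprod(dz, net$W[[1L]])
    }
  }
  list(W = gW, b = gb, input = d_input)
}

adam_init <- function(net) {
  zeros <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  }
  list(mW = lapply(net$W, zeros), vW = lapply(net$W, zeros),
       mb = lapply(net$b, zeros), vb = lapply(net$b, zeros), t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}
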