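# Minimal dense-network machinery used by the compressors and the mixture
# density head. Parameters are nested lists of matrices so the Adam updater
# can walk them generically; all gradients are hand-derived (tanh hidden
# layers, linear outputs).

# widths: c(in, h1, ..., out); last layer linear unless out_activation.
.mlp_init <- function(widths, out_activation = FALSE) {
  n_layer <- length(widths) - 1L
  W <- vector("list", n_layer)
  b <- vector("list", n_layer)
  for (l in seq_len(n_layer)) {
    s <- 1 / sqrt(widths[l]) # fan-in-scaled uniform init
    W[[l]] <- matrix(runif(widths[l] * widths[l + 1L], -s, s),
                     widths[l], widths[l + 1L])
    b[[l]] <- runif(widths[l + 1L], -s, s)
  }
  list(W = W, b = b, widths = widths, out_activation = out_activation)
}

# Returns list(out, cache); cache holds post-activation values per layer.
.mlp_forward <- function(mlp, X) {
  n_layer <- length(mlp$W)
  acts <- vector("list", n_layer + 1L)
  acts[[1L]] <- X
  H <- X
  for (l in seq_len(n_layer)) {
    H <- H %*% mlp$W[[l]] + rep(mlp$b[[l]], each = nrow(H))
    if (l < n_layer || mlp$out_activation) H <- tanh(H)
    acts[[l + 1L]] <- H
  }
  list(out = H, acts = acts)
}

# dOut: gradient wrt the MLP output. Returns grads (same shape as params)
# and dX (gradient wrt the input).
.mlp_backward <- function(mlp, cache, dOut) {
  n_layer <- length(mlp$W)
  gW <- vector("list", n_layer)
  gb <- vector("list", n_layer)
  delta <- dOut
  for (l in rev(seq_len(n_layer))) {
    if (l < n_layer || mlp$out_activation)
      delta <- delta * (1 - cache$acts[[l + 1L]]^2) # tanh'
    gW[[l]] <- crossprod(cache$acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    delta <- delta %*% t(mlp$W[[l]])
  }
  list(W = gW, b = gb, dX = delta)
}

# --- generic Adam over nested lists of numeric arrays -----------------------

.adam_init <- function(params) {
  zeros <- function(x) {
    if (is.list(x)) lapply(x, zeros)
    else if (is.numeric(x)) x * 0
    else x
  }
  list(m = zeros(params), v = zeros(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        if (!is.numeric(p[[i]]) && !is.list(p[[i]])) next
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

# Numeric-only view of nested parameter lists (for gradient checks/coef).
.flatten_params <- function(params) {
  out <- c()
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else if (is.numeric(x)) out <<- c(out, as.numeric(x))
    invisible(NULL)
  }
  walk(params)
  out
}

.count_params <- function(params) length(.flatten_params(params))
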