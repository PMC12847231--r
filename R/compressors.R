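#' Compressor architecture specification
#'
#' Describes one of the three trainable compressor families that map a data
#' payload to `q` learned summaries:
#' * `"set_mlp"`: a multilayer perceptron applied to each row of an
#'   `n x d` payload independently, followed by mean-pooling over rows. The
#'   output is permutation invariant and the parameter count is independent
#'   of the sample size `n`.
#' * `"tabular_mlp"`: a plain MLP on a fixed-length candidate-statistic
#'   vector (no pooling).
#' * `"gin"`: a graph isomorphism network on a tree payload. Each layer
#'   updates node features via
#'   \eqn{h'_v = \mathrm{MLP}\big((1 + \epsilon) h_v + \sum_{u \in N(v)} h_u\big)}
#'   with constant all-ones input features. Each layer's update is a
#'   two-layer MLP with `mlp_hidden` hidden units; the last layer's MLP
#'   ends in the output width `q` and node features are mean-pooled over
#'   the graph as the final operation.
#'
#' Hidden activations are `tanh` throughout; final outputs are linear.
#'
#' @param kind one of `"set_mlp"`, `"tabular_mlp"`, `"gin"`.
#' @param input_dim payload row width `d` (set), candidate count `c`
#'   (tabular); ignored for `"gin"` (node features are scalar ones).
#' @param hidden hidden-layer widths of the per-row/tabular MLP
#'   (default 16, 16).
#' @param output_dim number of learned summaries `q`.
#' @param gin_epsilon GIN self-weight \eqn{\epsilon} (default 0).
#' @param gin_layers number of message-passing layers (default 2).
#' @param mlp_hidden hidden width inside each GIN-layer MLP (default 8).
#' @param feature_dim node-feature width between GIN layers (default 8).
#' @return An object of class `"compressor_config"`.
#' @export
compressor_config <- function(kind = c("set_mlp", "tabular_mlp", "gin"),
                              input_dim = 1L, hidden = c(16L, 16L),
                              output_dim = 1L, gin_epsilon = 0,
                              gin_layers = 2L, mlp_hidden = 8L,
                              feature_dim = 8L) {
  kind <- match.arg(kind)
  output_dim <- .check_count(output_dim, "output_dim")
  if (any(hidden < 1L)) .stopf("hidden widths must be positive")
  structure(list(kind = kind, input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden), output_dim = output_dim,
                 gin_epsilon = gin_epsilon,
                 gin_layers = .check_count(gin_layers, "gin_layers"),
                 mlp_hidden = .check_count(mlp_hidden, "mlp_hidden"),
                 feature_dim = .check_count(feature_dim, "feature_dim")),
            class = "compressor_config")
}

# Initialize trainable state; consumes the current RNG stream.
.compressor_init <- function(config) {
  mlps <- switch(config$kind,
    set_mlp = ,
    tabular_mlp = list(
      .mlp_init(c(config$input_dim, config$hidden, config$output_dim))),
    gin = lapply(seq_len(config$gin_layers), function(l) {
      d_in <- if (l == 1L) 1L else config$feature_dim
      d_out <- if (l == config$gin_layers) config$output_dim
               else config$feature_dim
      # intermediate layers end in tanh so stacked layers stay nonlinear
      .mlp_init(c(d_in, config$mlp_hidden, d_out),
                out_activation = l < config$gin_layers)
    })
  )
  structure(list(config = config, mlps = mlps), class = "compressor_state")
}

#' @export
print.compressor_state <- function(x, ...) {
  n_par <- .count_params(.compressor_params(x))
  cat(sprintf("%s compressor: q = %d summaries, %d trainable parameters\n",
              x$config$kind, x$config$output_dim, n_par))
  invisible(x)
}

.compressor_params <- function(state) {
  lapply(state$mlps, function(m) list(W = m$W, b = m$b))
}

.compressor_set_params <- function(state, params) {
  for (i in seq_along(params)) {
    state$mlps[[i]]$W <- params[[i]]$W
    state$mlps[[i]]$b <- params[[i]]$b
  }
  state
}

# --- set / tabular MLPs -----------------------------------------------------

# Zflat: (B*n) x d with rows of example i contiguous; returns B x q.
.set_forward <- function(state, Zflat, n, B) {
  f <- .mlp_forward(state$mlps[[1L]], Zflat)
  groups <- rep(seq_len(B), each = n)
  t_out <- rowsum(f$out, groups, reorder = FALSE) / n
  list(t = t_out, cache = f, n = n, B = B)
}

.set_backward <- function(state, cache, dT) {
  dRows <- dT[rep(seq_len(cache$B), each = cache$n), , drop = FALSE] / cache$n
  bw <- .mlp_backward(state$mlps[[1L]], cache$cache, dRows)
  list(list(W = bw$W, b = bw$b))
}

.tabular_forward <- function(state, V) {
  f <- .mlp_forward(state$mlps[[1L]], V)
  list(t = f$out, cache = f)
}

.tabular_backward <- function(state, cache, dT) {
  bw <- .mlp_backward(state$mlps[[1L]], cache$cache, dT)
  list(list(W = bw$W, b = bw$b))
}

# --- GIN --------------------------------------------------------------------

# Pack a list of trees into one block graph with 1-based node ids.
.gin_batch <- function(trees) {
  sizes <- vapply(trees, function(tr) tr$n_nodes, integer(1L))
  offsets <- c(0L, cumsum(sizes))
  e <- do.call(rbind, lapply(seq_along(trees), function(i) {
    trees[[i]]$edges + 1L + offsets[i]
  }))
  list(e1 = e[, 1L], e2 = e[, 2L],
       graph_id = rep(seq_along(trees), sizes),
       sizes = sizes, N = sum(sizes), B = length(trees))
}

# Sum of neighbor features for every node (undirected edges).
.neighbor_sum <- function(H, batch) {
  vals <- rbind(H[batch$e2, , drop = FALSE], H[batch$e1, , drop = FALSE])
  r <- rowsum(vals, c(batch$e1, batch$e2))
  out <- matrix(0, batch$N, ncol(H))
  out[as.integer(rownames(r)), ] <- r
  out
}

.gin_forward <- function(state, batch) {
  eps <- state$config$gin_epsilon
  L <- state$config$gin_layers
  H <- matrix(1, batch$N, 1L)
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    S <- (1 + eps) * H + .neighbor_sum(H, batch)
    f <- .mlp_forward(state$mlps[[l]], S)
    caches[[l]] <- f
    H <- f$out
  }
  t_out <- rowsum(H, batch$graph_id, reorder = FALSE) /
    batch$sizes
  list(t = t_out, caches = caches)
}

.gin_backward <- function(state, batch, cache, dT) {
  eps <- state$config$gin_epsilon
  L <- state$config$gin_layers
  dH <- (dT / batch$sizes)[batch$graph_id, , drop = FALSE]
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    bw <- .mlp_backward(state$mlps[[l]], cache$caches[[l]], dH)
    grads[[l]] <- list(W = bw$W, b = bw$b)
    if (l > 1L) dH <- (1 + eps) * bw$dX + .neighbor_sum(bw$dX, batch)
  }
  grads
}

# Dispatch on payload kind; payloads is the batch slice in table layout.
.compressor_forward_batch <- function(state, payloads) {
  switch(state$config$kind,
    set_mlp = {
      dims <- dim(payloads) # B x n x d
      Zflat <- matrix(aperm(payloads, c(2L, 1L, 3L)),
                      nrow = dims[1L] * dims[2L], ncol = dims[3L])
      .set_forward(state, Zflat, dims[2L], dims[1L])
    },
    tabular_mlp = .tabular_forward(state, payloads),
    gin = {
      batch <- if (is.list(payloads) && !is.null(payloads$graph_id))
        payloads else .gin_batch(payloads)
      out <- .gin_forward(state, batch)
      out$batch <- batch
      out
    })
}

.compressor_backward_batch <- function(state, cache, dT) {
  switch(state$config$kind,
    set_mlp = .set_backward(state, cache, dT),
    tabular_mlp = .tabular_backward(state, cache, dT),
    gin = .gin_backward(state, cache$batch, cache, dT))
}

# --- public single-payload forward passes -----------------------------------

#' Evaluate a set compressor on one data matrix
#'
#' @param state a `compressor_state` of kind `"set_mlp"` (e.g. from a fitted
#'   [fit_mdn_compressor()] model via `$compressor`).
#' @param z numeric `n x d` matrix.
#' @return Length-`q` numeric vector of summaries; permutation invariant in
#'   the rows of `z`.
#' @export
set_compressor_forward <- function(state, z) {
  if (state$config$kind != "set_mlp") .stopf("`state` is not a set_mlp")
  if (!is.matrix(z) || ncol(z) != state$config$input_dim)
    .stopf("`z` must be a matrix with %d columns", state$config$input_dim)
  out <- .set_forward(state, z, nrow(z), 1L)
  as.numeric(out$t)
}

#' Evaluate a tabular compressor on one candidate-statistic vector
#'
#' @param state a `compressor_state` of kind `"tabular_mlp"`.
#' @param v numeric vector of length `input_dim`.
#' @return Length-`q` numeric vector of summaries.
#' @export
tabular_compressor_forward <- function(state, v) {
  if (state$config$kind != "tabular_mlp")
    .stopf("`state` is not a tabular_mlp")
  if (length(v) != state$config$input_dim)
    .stopf("`v` must have length %d", state$config$input_dim)
  out <- .tabular_forward(state, matrix(v, nrow = 1L))
  as.numeric(out$t)
}

#' Evaluate a graph isomorphism network on one tree
#'
#' @param state a `compressor_state` of kind `"gin"`.
#' @param tree a [grown_tree()].
#' @return Length-`q` numeric vector of summaries; invariant to node
#'   relabeling.
#' @export
gin_forward <- function(state, tree) {
  if (state$config$kind != "gin") .stopf("`state` is not a gin")
  if (!inherits(tree, "grown_tree")) .stopf("`tree` must be a grown_tree")
  out <- .gin_forward(state, .gin_batch(list(tree)))
  as.numeric(out$t)
}
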