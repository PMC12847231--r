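#' Optimization schedule for neural compressors
#'
#' Mini-batch Adam with a validation-plateau schedule: the learning rate is
#' multiplied by `lr_decay` if the validation loss has not improved for
#' `decay_patience` consecutive epochs, and training stops after
#' `stop_patience` epochs without improvement. The returned model always
#' carries the parameters with the best validation loss.
#'
#' @param batch_size examples per mini-batch.
#' @param lr initial learning rate (default 1e-2).
#' @param lr_decay multiplicative decay factor (default 0.1).
#' @param decay_patience epochs without improvement before decaying.
#' @param stop_patience epochs without improvement before stopping; must be
#'   at least `decay_patience`.
#' @param max_epochs hard cap on epochs.
#' @param verbose print one line per epoch?
#' @return An object of class `"train_control"`.
#' @export
train_control <- function(batch_size = 512L, lr = 1e-2, lr_decay = 0.1,
                          decay_patience = 10L, stop_patience = 20L,
                          max_epochs = 100L, verbose = FALSE) {
  decay_patience <- .check_count(decay_patience, "decay_patience")
  stop_patience <- .check_count(stop_patience, "stop_patience")
  if (stop_patience < decay_patience)
    .stopf("`stop_patience` must be >= `decay_patience`")
  structure(list(batch_size = .check_count(batch_size, "batch_size"),
                 lr = .check_positive(lr, "lr"), lr_decay = lr_decay,
                 decay_patience = decay_patience,
                 stop_patience = stop_patience,
                 max_epochs = .check_count(max_epochs, "max_epochs"),
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

.payload_batch <- function(table, idx) {
  switch(payload_kind(table),
    matrix = table$payloads[idx, , , drop = FALSE],
    vector = table$payloads[idx, , drop = FALSE],
    tree = .gin_batch(table$payloads[idx])
  )
}

# One forward+loss (+ gradients when `backward`) pass over a batch.
# `A` is the positive-definite weight of the quadratic loss (NULL: identity).
.net_batch <- function(comp, head, payloads, theta, backward = TRUE,
                       A = NULL) {
  fwd <- .compressor_forward_batch(comp, payloads)
  if (!is.null(head)) {
    hf <- .head_forward(head, fwd$t)
    ls <- .mdn_loss(head, hf, theta)
    loss <- mean(ls$nlp)
    if (!backward) return(list(loss = loss))
    hb <- .head_backward(head, hf, ls$d_eta, ls$d_loc, ls$d_scale)
    comp_grads <- .compressor_backward_batch(comp, fwd, hb$dT)
    list(loss = loss, grads = list(comp = comp_grads, head = hb$grads))
  } else {
    diff <- theta - fwd$t
    wdiff <- if (is.null(A)) diff else diff %*% A
    loss <- mean(rowSums(diff * wdiff))
    if (!backward) return(list(loss = loss))
    dT <- -2 * wdiff / nrow(theta)
    comp_grads <- .compressor_backward_batch(comp, fwd, dT)
    list(loss = loss, grads = list(comp = comp_grads))
  }
}

# Validation loss, chunked so tree batches stay small.
.net_eval <- function(comp, head, table, chunk = 5000L, A = NULL) {
  m <- n_draws(table)
  total <- 0
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    out <- .net_batch(comp, head, .payload_batch(table, idx),
                      table$params[idx, , drop = FALSE], backward = FALSE,
                      A = A)
    total <- total + out$loss * length(idx)
  }
  total / m
}

# Shared training engine. head_cfg = NULL trains on the quadratic
# posterior-mean loss; otherwise on the Monte Carlo EPE (mixture NLP).
.train_network <- function(train, val, comp_cfg, head_cfg, control,
                           A = NULL) {
  if (n_draws(train) < 1L || n_draws(val) < 1L)
    .stopf("training and validation tables must be non-empty")
  if (payload_kind(train) != payload_kind(val))
    .stopf("train and validation payload kinds differ")
  p <- ncol(train$params)
  comp <- .compressor_init(comp_cfg)
  head <- if (!is.null(head_cfg))
    .mdn_head_init(head_cfg, comp_cfg$output_dim, p)
  params <- list(comp = .compressor_params(comp),
                 head = if (!is.null(head)) .head_params(head))
  if (is.null(head)) params$head <- NULL
  adam <- .adam_init(params)
  m <- n_draws(train)
  bs <- min(control$batch_size, m)
  # trees: fix the batch membership once (graph packing is precomputed),
  # shuffle the batch order each epoch; arrays are resliced every epoch.
  tree_kind <- payload_kind(train) == "tree"
  if (tree_kind) {
    ord <- sample.int(m)
    split_idx <- split(ord, ceiling(seq_along(ord) / bs))
    tree_batches <- lapply(split_idx, function(ix)
      .payload_batch(train, ix))
  }
  lr <- control$lr
  history <- vector("list", control$max_epochs)
  best_val <- Inf
  best_params <- params
  since_improve <- 0L
  epochs_run <- 0L
  for (epoch in seq_len(control$max_epochs)) {
    if (tree_kind) {
      batch_order <- sample.int(length(split_idx))
    } else {
      ord <- sample.int(m)
      split_idx <- split(ord, ceiling(seq_along(ord) / bs))
      batch_order <- seq_along(split_idx)
    }
    train_loss <- 0
    for (bi in batch_order) {
      idx <- split_idx[[bi]]
      payloads <- if (tree_kind) tree_batches[[bi]]
                  else .payload_batch(train, idx)
      out <- .net_batch(comp, head, payloads,
                        train$params[idx, , drop = FALSE], A = A)
      if (!is.finite(out$loss))
        .stopf("non-finite training loss at epoch %d", epoch)
      train_loss <- train_loss + out$loss * length(idx)
      step <- .adam_step(params, out$grads, adam, lr)
      params <- step$params
      adam <- step$state
      comp <- .compressor_set_params(comp, params$comp)
      if (!is.null(head)) head <- .head_set_params(head, params$head)
    }
    train_loss <- train_loss / m
    val_loss <- .net_eval(comp, head, val, A = A)
    epochs_run <- epoch
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss, lr = lr)
    if (control$verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.1e",
                      epoch, train_loss, val_loss, lr))
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss
      best_params <- params
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= control$stop_patience) break
      if (since_improve %% control$decay_patience == 0L)
        lr <- lr * control$lr_decay
    }
  }
  comp <- .compressor_set_params(comp, best_params$comp)
  if (!is.null(head)) head <- .head_set_params(head, best_params$head)
  list(compressor = comp, head = head,
       history = do.call(rbind, history[seq_len(epochs_run)]),
       best_val = best_val, epochs = epochs_run)
}

.default_compressor <- function(table, q) {
  switch(payload_kind(table),
    matrix = compressor_config("set_mlp", input_dim = dim(table$payloads)[3L],
                               output_dim = q),
    vector = compressor_config("tabular_mlp", input_dim = ncol(table$payloads),
                               output_dim = q),
    tree = compressor_config("gin", output_dim = q)
  )
}

#' Fit an EPE-minimizing mixture-density compressor
#'
#' Trains a compressor and a conditional mixture-density head end-to-end by
#' minimizing the Monte Carlo estimate of the expected posterior entropy
#' (the mean negative log mixture density of the true parameters given the
#' compressed summaries; see [epe_estimate()]). The bottleneck forces all
#' information used by the density head through the `q = p` learned
#' summaries, which are then used as ABC summary statistics.
#'
#' @param train,val training and validation [reference_table()]s from the
#'   same model.
#' @param compressor a [compressor_config()]; defaults to the architecture
#'   matching the payload kind (set MLP for matrix payloads, tabular MLP
#'   for vector payloads, GIN for trees) with `q` equal to the parameter
#'   dimension.
#' @param mdn an [mdn_config()]; defaults to a Gaussian mixture with
#'   `k = 2` components for matrix payloads and `k = 10` for trees.
#' @param control a [train_control()].
#' @return An object of class `"epe_mdn"` with components `compressor`
#'   (a `compressor_state`), `head`, `history` (per-epoch losses), and
#'   `best_val`. Methods: [predict.epe_mdn()], [simulate.epe_mdn()],
#'   `print`, `summary`, `plot`, `coef`.
#' @seealso [extract_summaries()], [rejection_sample()]
#' @export
fit_mdn_compressor <- function(train, val, compressor = NULL, mdn = NULL,
                               control = train_control()) {
  p <- ncol(train$params)
  if (is.null(compressor)) compressor <- .default_compressor(train, p)
  if (is.null(mdn))
    mdn <- mdn_config("gaussian",
                      k = if (payload_kind(train) == "tree") 10L else 2L)
  fit <- .train_network(train, val, compressor, mdn, control)
  structure(list(compressor = fit$compressor, head = fit$head,
                 history = fit$history, best_val = fit$best_val,
                 epochs = fit$epochs, p = p,
                 compressor_config = compressor, mdn_config = mdn),
            class = "epe_mdn")
}

#' Fit a nonlinear posterior-mean compressor
#'
#' Trains the same compressor architectures as [fit_mdn_compressor()] but
#' on the quadratic Bayes-risk loss
#' \eqn{m^{-1} \sum_i \|\theta_i - t(z_i)\|^2} (identity weight matrix),
#' whose minimizer is the posterior mean. The network output (one summary
#' per parameter) is used directly as the ABC summary. For models whose
#' posterior mean is uninformative (multimodal, symmetric posteriors) this
#' collapses to a constant and the downstream posterior reverts to the
#' prior.
#'
#' @inheritParams fit_mdn_compressor
#' @param A optional `p x p` symmetric positive-definite weight matrix of
#'   the quadratic loss (default: identity). Ordinary least squares is
#'   invariant to `A`, but the shared nonlinear trunk is not.
#' @return An object of class `"posterior_mean_net"`; `predict()` returns
#'   the estimated posterior means / summaries.
#' @export
fit_posterior_mean_net <- function(train, val, compressor = NULL,
                                   control = train_control(), A = NULL) {
  p <- ncol(train$params)
  if (is.null(compressor)) compressor <- .default_compressor(train, p)
  if (compressor$output_dim != p)
    .stopf("posterior-mean networks need output_dim equal to the %d parameter(s)", p)
  if (!is.null(A)) {
    if (!is.matrix(A) || any(dim(A) != p) || any(abs(A - t(A)) > 1e-12) ||
        any(eigen(A, symmetric = TRUE, only.values = TRUE)$values <= 0))
      .stopf("`A` must be a %d x %d symmetric positive-definite matrix",
             p, p)
  }
  fit <- .train_network(train, val, compressor, NULL, control, A = A)
  structure(list(compressor = fit$compressor, history = fit$history,
                 best_val = fit$best_val, epochs = fit$epochs, p = p,
                 compressor_config = compressor),
            class = "posterior_mean_net")
}

#' Extract learned summaries for a whole reference table
#'
#' Runs the (trained) compressor deterministically over every payload of a
#' table and returns the `m x q` summary matrix.
#'
#' @param object an `epe_mdn`, `posterior_mean_net`, or `compressor_state`.
#' @param table a [reference_table()] whose payload kind matches the
#'   compressor.
#' @param chunk payloads per forward pass (bounds memory for large tables).
#' @return Numeric `m x q` matrix of summaries.
#' @export
extract_summaries <- function(object, table, chunk = 5000L) {
  comp <- if (inherits(object, "compressor_state")) object
          else object$compressor
  expected <- switch(comp$config$kind, set_mlp = "matrix",
                     tabular_mlp = "vector", gin = "tree")
  if (payload_kind(table) != expected)
    .stopf("compressor kind %s expects %s payloads, table has %s payloads",
           comp$config$kind, expected, payload_kind(table))
  m <- n_draws(table)
  out <- matrix(0, m, comp$config$output_dim)
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    fwd <- .compressor_forward_batch(comp, .payload_batch(table, idx))
    out[idx, ] <- fwd$t
  }
  out
}

# Summaries for a single payload of any supported kind.
.compress_one <- function(comp, payload) {
  switch(comp$config$kind,
    set_mlp = set_compressor_forward(comp, payload),
    tabular_mlp = tabular_compressor_forward(comp, payload),
    gin = gin_forward(comp, payload))
}

#' Predict from a fitted mixture-density compressor
#'
#' @param object an `epe_mdn` fit.
#' @param newdata a [reference_table()], a single payload (`n x d` matrix,
#'   candidate vector, or [grown_tree()]), or, with
#'   `from = "summaries"`, a numeric matrix of already-extracted summaries.
#' @param type `"summaries"` returns the compressed summaries;
#'   `"mixture"` returns a list of [mixture_params()] (the conditional
#'   posterior estimate per example).
#' @param from whether `newdata` holds payloads or summaries.
#' @param ... unused.
#' @return See `type`.
#' @export
predict.epe_mdn <- function(object, newdata,
                            type = c("summaries", "mixture"),
                            from = c("payloads", "summaries"), ...) {
  type <- match.arg(type)
  from <- match.arg(from)
  if (from == "summaries") {
    t_mat <- if (is.vector(newdata)) matrix(newdata, nrow = 1L) else newdata
  } else if (inherits(newdata, "reference_table")) {
    t_mat <- extract_summaries(object, newdata)
  } else {
    t_mat <- matrix(.compress_one(object$compressor, newdata), nrow = 1L)
  }
  if (type == "summaries") return(t_mat)
  fwd <- .head_forward(object$head, t_mat)
  .head_outputs_to_mixtures(object$head, fwd)
}

#' Draw posterior samples from a fitted mixture-density compressor
#'
#' Compresses `newdata` to summaries, evaluates the mixture head, and
#' draws `nsim` ancestral samples from the estimated conditional posterior.
#'
#' @param object an `epe_mdn` fit.
#' @param nsim draws per example.
#' @param seed optional seed passed to [set.seed()].
#' @param newdata single payload or [reference_table()].
#' @param ... unused.
#' @return For a single payload, an `nsim x p` matrix; for a table, a list
#'   of such matrices.
#' @export
simulate.epe_mdn <- function(object, nsim = 1000L, seed = NULL, newdata,
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  mix <- predict(object, newdata, type = "mixture")
  out <- lapply(mix, mdn_sample, s = nsim)
  if (length(out) == 1L) out[[1L]] else out
}

#' @export
print.epe_mdn <- function(x, ...) {
  cat(sprintf(
    "EPE-minimizing MDN compression (%s + %s mixture, k = %d)\n",
    x$compressor_config$kind, x$mdn_config$family, x$mdn_config$k))
  cat(sprintf("  summaries: q = %d; trained %d epochs; best validation EPE %.4f nats\n",
              x$compressor_config$output_dim, x$epochs, x$best_val))
  invisible(x)
}

#' @export
summary.epe_mdn <- function(object, ...) {
  print(object)
  n_par <- .count_params(.compressor_params(object$compressor)) +
    .count_params(.head_params(object$head))
  cat(sprintf("  %d trainable parameters (compressor + head)\n", n_par))
  cat(sprintf("  final learning rate %.1e\n",
              tail(object$history$lr, 1L)))
  invisible(object)
}

#' @export
coef.epe_mdn <- function(object, ...) {
  c(compressor = .flatten_params(.compressor_params(object$compressor)),
    head = .flatten_params(.head_params(object$head)))
}

#' @export
plot.epe_mdn <- function(x, ...) .plot_history(x$history, "EPE loss (nats)")

#' @export
print.posterior_mean_net <- function(x, ...) {
  cat(sprintf(
    "Posterior-mean compressor (%s, quadratic loss)\n  trained %d epochs; best validation loss %.4f\n",
    x$compressor_config$kind, x$epochs, x$best_val))
  invisible(x)
}

#' Predict posterior-mean summaries
#'
#' @param object a `posterior_mean_net` fit.
#' @param newdata a [reference_table()] or single payload.
#' @param ... unused.
#' @return Numeric matrix of summaries (estimated posterior means).
#' @export
predict.posterior_mean_net <- function(object, newdata, ...) {
  if (inherits(newdata, "reference_table"))
    extract_summaries(object, newdata)
  else matrix(.compress_one(object$compressor, newdata), nrow = 1L)
}

#' @export
plot.posterior_mean_net <- function(x, ...)
  .plot_history(x$history, "quadratic loss")

.plot_history <- function(history, ylab) {
  graphics::plot(history$epoch, history$train_loss, type = "l",
                 xlab = "epoch", ylab = ylab,
                 ylim = range(history$train_loss, history$val_loss))
  graphics::lines(history$epoch, history$val_loss, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   bty = "n")
  invisible(history)
}
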