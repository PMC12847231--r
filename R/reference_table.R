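#' Reference tables of joint prior-predictive draws
#'
#' A reference table holds `m` joint draws \eqn{(\theta_i, z_i)} from the
#' prior predictive distribution of a generative model, optionally together
#' with an `m x q` matrix of summary statistics \eqn{t(z_i)}. It is the
#' central container of the package: simulators produce reference tables,
#' compressors fill in their `summaries` block, and the rejection-ABC engine
#' treats the training table as the pool of candidate posterior samples.
#'
#' Three payload kinds are supported: `"matrix"` payloads (each draw is an
#' `n x d` data matrix, stored as an `m x n x d` array), `"vector"` payloads
#' (each draw is a length-`c` vector of candidate statistics, stored as an
#' `m x c` matrix), and `"tree"` payloads (each draw is a [grown_tree()]).
#'
#' @param params numeric `m x p` matrix of parameter draws (a vector is
#'   treated as `m x 1`).
#' @param payloads an `m x n x d` array, an `m x c` matrix, or a list of
#'   `m` tree objects.
#' @param summaries optional numeric `m x q` matrix of summaries.
#' @param split one of `"train"`, `"validation"`, `"test"`.
#' @param model optional model name for bookkeeping.
#'
#' @return An object of class `"reference_table"`.
#' @seealso [simulate_benchmark()], [simulate_gamma_toy()], [simulate_tree()]
#' @export
reference_table <- function(params, payloads, summaries = NULL,
                            split = c("train", "validation", "test"),
                            model = NULL) {
  split <- match.arg(split)
  if (is.vector(params)) params <- matrix(params, ncol = 1L)
  if (!is.matrix(params) || !is.numeric(params))
    .stopf("`params` must be a numeric matrix")
  m <- nrow(params)
  if (is.array(payloads) && length(dim(payloads)) == 3L) {
    kind <- "matrix"
    if (dim(payloads)[1L] != m)
      .stopf("payload array has %d slices but params has %d rows",
             dim(payloads)[1L], m)
  } else if (is.matrix(payloads)) {
    kind <- "vector"
    if (nrow(payloads) != m)
      .stopf("payload matrix has %d rows but params has %d rows",
             nrow(payloads), m)
  } else if (is.list(payloads)) {
    kind <- "tree"
    if (length(payloads) != m)
      .stopf("payload list has %d elements but params has %d rows",
             length(payloads), m)
  } else {
    .stopf("unsupported payload type")
  }
  if (!is.null(summaries)) {
    if (is.vector(summaries)) summaries <- matrix(summaries, ncol = 1L)
    if (nrow(summaries) != m)
      .stopf("`summaries` has %d rows but params has %d rows",
             nrow(summaries), m)
    if (any(!is.finite(summaries)))
      .stopf("`summaries` must be finite")
  }
  structure(
    list(params = params, payloads = payloads, summaries = summaries,
         split = split, model = model),
    payload_kind = kind,
    class = "reference_table"
  )
}

#' @export
print.reference_table <- function(x, ...) {
  kind <- payload_kind(x)
  dims <- switch(kind,
    matrix = sprintf("%d x %d matrices", dim(x$payloads)[2L],
                     dim(x$payloads)[3L]),
    vector = sprintf("length-%d vectors", ncol(x$payloads)),
    tree = sprintf("trees (%d nodes)",
                   if (length(x$payloads)) x$payloads[[1L]]$n_nodes else 0L)
  )
  cat(sprintf(
    "Reference table (%s split%s): m = %d draws, p = %d parameter(s)\n",
    x$split, if (is.null(x$model)) "" else paste0(", model ", x$model),
    nrow(x$params), ncol(x$params)))
  cat(sprintf("  payloads:  %s\n", dims))
  if (is.null(x$summaries)) cat("  summaries: none\n")
  else cat(sprintf("  summaries: q = %d\n", ncol(x$summaries)))
  invisible(x)
}

#' Number of draws in a reference table
#' @param table a [reference_table()].
#' @return Integer number of joint draws `m`.
#' @export
n_draws <- function(table) nrow(table$params)

#' Payload kind of a reference table
#' @param table a [reference_table()].
#' @return `"matrix"`, `"vector"`, or `"tree"`.
#' @export
payload_kind <- function(table) attr(table, "payload_kind")

#' Extract one payload from a reference table
#' @param table a [reference_table()].
#' @param i draw index.
#' @return An `n x d` matrix, a numeric vector, or a tree, depending on the
#'   payload kind.
#' @export
get_payload <- function(table, i) {
  switch(payload_kind(table),
    matrix = {
      d <- dim(table$payloads)
      matrix(table$payloads[i, , ], nrow = d[2L], ncol = d[3L])
    },
    vector = table$payloads[i, ],
    tree = table$payloads[[i]]
  )
}

#' Subset a reference table by draw indices
#' @param table a [reference_table()].
#' @param idx integer vector of draw indices.
#' @param split optional new split label.
#' @return A [reference_table()] containing the selected draws.
#' @export
subset_table <- function(table, idx, split = table$split) {
  payloads <- switch(payload_kind(table),
    matrix = table$payloads[idx, , , drop = FALSE],
    vector = table$payloads[idx, , drop = FALSE],
    tree = table$payloads[idx]
  )
  reference_table(table$params[idx, , drop = FALSE], payloads,
                  summaries = if (!is.null(table$summaries))
                    table$summaries[idx, , drop = FALSE],
                  split = split, model = table$model)
}
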