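#' Standardization moments of a summary matrix
#'
#' Per-column mean and standard deviation, intended to be computed on the
#' training split only and then applied to all splits, so that the ABC
#' distance weighs every summary equally.
#'
#' @param summaries numeric `m x q` matrix.
#' @return List with `mean` and `sd` vectors (class `"summary_moments"`).
#' @export
summary_moments <- function(summaries) {
  if (is.vector(summaries)) summaries <- matrix(summaries, ncol = 1L)
  mu <- colMeans(summaries)
  sdev <- apply(summaries, 2L, stats::sd)
  zero <- which(sdev == 0 | !is.finite(sdev))
  if (length(zero)) {
    nm <- colnames(summaries)[zero] %||% as.character(zero)
    .stopf("summary column(s) %s have zero standard deviation",
           paste(nm, collapse = ", "))
  }
  structure(list(mean = mu, sd = sdev), class = "summary_moments")
}

#' Standardize summaries with given moments
#'
#' @param summaries numeric `m x q` matrix or length-`q` vector.
#' @param moments a [summary_moments()] object (from the training split).
#' @return Standardized matrix (vectors become `1 x q`).
#' @export
standardize <- function(summaries, moments) {
  if (is.vector(summaries))
    summaries <- matrix(summaries, ncol = length(moments$mean))
  sweep(sweep(summaries, 2L, moments$mean), 2L, moments$sd, "/")
}

#' Accepted posterior samples
#'
#' @param theta `s x p` matrix of accepted (or drawn) parameters.
#' @param provenance `"abc"`, `"mdn"`, `"quadrature"`, or `"prior"`.
#' @param distances accepted distances, sorted non-decreasing (abc only).
#' @param indices accepted reference-table row indices (abc only).
#' @return An object of class `"posterior_samples"`.
#' @export
posterior_samples <- function(theta,
                              provenance = c("abc", "mdn", "quadrature",
                                             "prior"),
                              distances = NULL, indices = NULL) {
  provenance <- match.arg(provenance)
  if (is.vector(theta)) theta <- matrix(theta, ncol = 1L)
  if (!is.null(distances) && is.unsorted(distances))
    .stopf("`distances` must be sorted non-decreasing")
  structure(list(theta = theta, provenance = provenance,
                 distances = distances, indices = indices),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("%d posterior samples (%s), p = %d\n", nrow(x$theta),
              x$provenance, ncol(x$theta)))
  invisible(x)
}

#' Rejection ABC against a reference table
#'
#' Accepts the `s` parameter rows of the reference table whose standardized
#' summaries have the smallest Euclidean distance to the observed
#' standardized summaries (acceptance by count rather than by a tolerance
#' \eqn{\epsilon}; the accepted fraction `s / m` is recorded). Distance
#' ties are broken by ascending row index, making the accepted set
#' deterministic given the table.
#'
#' @param observed_t length-`q` vector of observed summaries (on the
#'   original scale).
#' @param table a [reference_table()] whose `summaries` block is filled, or
#'   a plain `m x q` summary matrix if `params` is supplied.
#' @param s number of accepted samples.
#' @param moments standardization moments; default computed from the table
#'   summaries (the table is the training split).
#' @param params optional `m x p` matrix when `table` is a plain matrix.
#' @return A [posterior_samples()] object with provenance `"abc"`.
#' @export
rejection_sample <- function(observed_t, table, s, moments = NULL,
                             params = NULL) {
  if (inherits(table, "reference_table")) {
    if (is.null(table$summaries)) .stopf("table has no summaries")
    summaries <- table$summaries
    params <- table$params
  } else {
    summaries <- table
    if (is.null(params)) .stopf("`params` required with a summary matrix")
  }
  s <- .check_count(s, "s")
  m <- nrow(summaries)
  if (s > m) .stopf("cannot accept s = %d of m = %d rows", s, m)
  if (is.null(moments)) moments <- summary_moments(summaries)
  std <- standardize(summaries, moments)
  obs <- as.numeric(standardize(observed_t, moments))
  d2 <- rep(0, m)
  for (j in seq_len(ncol(std))) d2 <- d2 + (std[, j] - obs[j])^2
  ord <- order(d2)[seq_len(s)] # ties broken by row index
  posterior_samples(params[ord, , drop = FALSE], "abc",
                    distances = sqrt(d2[ord]), indices = ord)
}

#' Greedy minimum-entropy subset selection
#'
#' Implements entropy-based subset selection for one observed dataset:
#' starting from the empty set (scored by the entropy of the prior draws in
#' the table), the candidate whose inclusion yields the lowest
#' nearest-neighbor entropy of the ABC posterior is added greedily until no
#' candidate lowers the current score. Because the conditional posterior
#' entropy of a dataset can exceed the prior entropy, the selection can
#' legitimately return an empty set, discarding even a sufficient
#' statistic.
#'
#' @param observed_t named length-`c` vector of observed candidate
#'   summaries.
#' @param table a [reference_table()] whose summaries hold the same `c`
#'   candidates (matching column order).
#' @param s accepted samples per ABC run.
#' @param k_nn neighbor order for the entropy estimator.
#' @param moments standardization moments (default from the table).
#' @param on_duplicates passed to the entropy estimator.
#' @return List with `selected` (integer indices into the candidates,
#'   possibly empty), `names`, `cpe` (the achieved entropy), and
#'   `prior_entropy` (the empty-set score).
#' @export
min_cpe_select <- function(observed_t, table, s, k_nn = 4L, moments = NULL,
                           on_duplicates = c("jitter", "error")) {
  on_duplicates <- match.arg(on_duplicates)
  if (is.null(table$summaries)) .stopf("table has no candidate summaries")
  c_dim <- ncol(table$summaries)
  if (length(observed_t) != c_dim)
    .stopf("`observed_t` must have %d entries", c_dim)
  if (is.null(moments)) moments <- summary_moments(table$summaries)
  score <- function(cols) {
    sub_moments <- structure(list(mean = moments$mean[cols],
                                  sd = moments$sd[cols]),
                             class = "summary_moments")
    ps <- rejection_sample(observed_t[cols],
                           table$summaries[, cols, drop = FALSE], s,
                           moments = sub_moments, params = table$params)
    cpe_of_abc_posterior(ps, k = k_nn, on_duplicates = on_duplicates)
  }
  prior_entropy <- .kl_entropy(table$params, k_nn, on_duplicates)
  selected <- integer(0)
  best <- prior_entropy
  remaining <- seq_len(c_dim)
  repeat {
    scores <- vapply(remaining, function(j) score(c(selected, j)),
                     numeric(1L))
    if (!length(scores) || min(scores) >= best) break
    take <- remaining[which.min(scores)]
    selected <- c(selected, take)
    remaining <- setdiff(remaining, take)
    best <- min(scores)
  }
  list(selected = selected,
       names = (colnames(table$summaries) %||%
                  paste0("c", seq_len(c_dim)))[selected],
       cpe = best, prior_entropy = prior_entropy)
}
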