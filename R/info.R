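#' Closed-form gamma differential entropy
#'
#' \eqn{H = \alpha - \ln\beta + \ln\Gamma(\alpha) + (1 - \alpha)\psi(\alpha)}
#' in nats, for a gamma distribution with shape \eqn{\alpha} and rate
#' \eqn{\beta}.
#'
#' @param shape,rate gamma parameters (positive; vectorized).
#' @return Differential entropy in nats.
#' @examples
#' gamma_entropy(1.5, 1) # prior entropy of the conjugate toy, about 1.36
#' @export
gamma_entropy <- function(shape, rate) {
  if (any(shape <= 0) || any(rate <= 0))
    .stopf("`shape` and `rate` must be positive")
  shape - log(rate) + lgamma(shape) + (1 - shape) * digamma(shape)
}

#' Closed-form normal differential entropy
#'
#' \eqn{H = \frac12 \ln(2\pi e \sigma^2)} in nats.
#'
#' @param sd standard deviation (positive; vectorized).
#' @return Differential entropy in nats.
#' @examples
#' normal_entropy(1) # about 1.42
#' @export
normal_entropy <- function(sd) {
  if (any(sd <= 0)) .stopf("`sd` must be positive")
  0.5 * log(2 * pi * exp(1) * sd^2)
}

#' Closed-form uniform differential entropy
#'
#' \eqn{H = \ln(hi - lo)} in nats.
#'
#' @param lo,hi support bounds with `lo < hi`.
#' @return Differential entropy in nats.
#' @export
uniform_entropy <- function(lo, hi) {
  if (any(hi <= lo)) .stopf("`lo` must be below `hi`")
  log(hi - lo)
}

.info_estimate <- function(value, estimator, m = 0L, k = NA_integer_) {
  structure(list(value = value, estimator = estimator, m = as.integer(m),
                 k = k), class = "info_estimate")
}

#' @export
print.info_estimate <- function(x, ...) {
  extra <- switch(x$estimator,
    knn = sprintf(" (m = %d, k = %d)", x$m, x$k),
    monte_carlo = sprintf(" (m = %d)", x$m),
    "")
  cat(sprintf("%s estimate: %.4f nats%s\n", x$estimator, x$value, extra))
  invisible(x)
}

#' @export
as.numeric.info_estimate <- function(x, ...) x$value

# Kozachenko-Leonenko estimator on a plain matrix; returns a scalar.
.kl_entropy <- function(x, k, on_duplicates = c("error", "jitter")) {
  on_duplicates <- match.arg(on_duplicates)
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  m <- nrow(x); d <- ncol(x)
  if (m <= k) .stopf("need more samples (m = %d) than neighbors (k = %d)", m, k)
  eps <- .knn_distances(x, k)[, k]
  if (any(eps == 0)) {
    if (on_duplicates == "error")
      .stopf(paste0("duplicate points give zero nearest-neighbor distance; ",
                    "set on_duplicates = \"jitter\" to break ties"))
    scale <- pmax(apply(x, 2L, stats::sd), 1e-8)
    x <- x + matrix(rnorm(m * d, sd = 1e-10), m, d) *
      rep(scale, each = m)
    eps <- .knn_distances(x, k)[, k]
  }
  log_cd <- (d / 2) * log(pi) - lgamma(d / 2 + 1)
  digamma(m) - digamma(k) + log_cd + d * mean(log(eps))
}

#' Nearest-neighbor entropy estimate
#'
#' Kozachenko-Leonenko estimator of differential entropy,
#' \deqn{\hat H = \psi(m) - \psi(k) + \ln c_d + \frac{d}{m} \sum_i \ln \epsilon_i,}
#' where \eqn{\epsilon_i} is the Euclidean distance from sample `i` to its
#' `k`-th nearest neighbor and \eqn{c_d} the volume of the unit `d`-ball.
#'
#' @param x numeric `m x d` matrix of samples (a vector is `m x 1`).
#' @param k neighbor order (default 4).
#' @param on_duplicates `"error"` to fail on coincident points, `"jitter"`
#'   to add noise at 1e-10 of the per-column scale.
#' @return An `info_estimate` (value in nats); use `$value` or
#'   `as.numeric()`.
#' @export
knn_entropy <- function(x, k = 4L, on_duplicates = c("error", "jitter")) {
  k <- .check_count(k, "k")
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  .info_estimate(.kl_entropy(x, k, on_duplicates), "knn", nrow(x), k)
}

#' Nearest-neighbor mutual information estimate
#'
#' Estimates \eqn{I\{x, y\} = H(x) + H(y) - H(x, y)} with the
#' Kozachenko-Leonenko entropy estimator applied to each block and to the
#' joint sample with a shared neighbor order, which makes the estimate
#' exactly symmetric in its arguments.
#'
#' @param x,y numeric matrices (or vectors) with matching row counts.
#' @param k neighbor order.
#' @param clip truncate small negative estimates at zero?
#' @param on_duplicates passed to [knn_entropy()].
#' @return An `info_estimate` in nats.
#' @export
knn_mutual_information <- function(x, y, k = 4L, clip = TRUE,
                                   on_duplicates = c("error", "jitter")) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (is.vector(y)) y <- matrix(y, ncol = 1L)
  if (nrow(x) != nrow(y)) .stopf("`x` and `y` must have matching rows")
  on_duplicates <- match.arg(on_duplicates)
  mi <- .kl_entropy(x, k, on_duplicates) + .kl_entropy(y, k, on_duplicates) -
    .kl_entropy(cbind(x, y), k, on_duplicates)
  if (clip) mi <- max(mi, 0)
  .info_estimate(mi, "knn", nrow(x), k)
}

#' Monte Carlo estimate of the expected posterior entropy
#'
#' Given `m` joint draws \eqn{(\theta_i, t_i)} from the prior predictive
#' distribution and a conditional log-density \eqn{\log \hat f(\theta | t)},
#' returns \deqn{\hat{\mathcal H} = -m^{-1} \sum_i \log \hat f(\theta_i | t_i),}
#' the quantity minimized when training the mixture-density compressor: the
#' training loss of [fit_mdn_compressor()] evaluated on the same draws is
#' exactly this estimate.
#'
#' @param log_density function of two arguments `(theta, t)`. With
#'   `vectorized = FALSE` (default) it is called once per draw with a
#'   parameter row vector and a summary row vector; with
#'   `vectorized = TRUE` it is called once with the full matrices and must
#'   return `m` log-densities.
#' @param params numeric `m x p` matrix of parameter draws.
#' @param summaries numeric `m x q` matrix of matching summaries.
#' @param vectorized see `log_density`.
#' @return An `info_estimate` with estimator `"monte_carlo"`.
#' @export
epe_estimate <- function(log_density, params, summaries, vectorized = FALSE) {
  if (is.vector(params)) params <- matrix(params, ncol = 1L)
  if (is.vector(summaries)) summaries <- matrix(summaries, ncol = 1L)
  if (nrow(params) != nrow(summaries))
    .stopf("`params` and `summaries` must have matching rows")
  m <- nrow(params)
  if (vectorized) {
    lp <- log_density(params, summaries)
  } else {
    lp <- vapply(seq_len(m),
                 function(i) log_density(params[i, ], summaries[i, ]),
                 numeric(1L))
  }
  bad <- which(!is.finite(lp))
  if (length(bad))
    .stopf("log density is not finite at draw %d", bad[1L])
  .info_estimate(-mean(lp), "monte_carlo", m)
}

#' Conditional posterior entropy of accepted ABC samples
#'
#' Applies the nearest-neighbor entropy estimator to the parameter rows of
#' a set of accepted posterior samples; this is the quantity minimized by
#' entropy-based subset selection ([min_cpe_select()]).
#'
#' @param samples a [posterior_samples] object or an `s x p` matrix.
#' @param k neighbor order.
#' @param on_duplicates passed to [knn_entropy()].
#' @return Scalar entropy in nats.
#' @export
cpe_of_abc_posterior <- function(samples, k = 4L,
                                 on_duplicates = c("error", "jitter")) {
  theta <- if (inherits(samples, "posterior_samples")) samples$theta
           else samples
  .kl_entropy(theta, .check_count(k, "k"), match.arg(on_duplicates))
}
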