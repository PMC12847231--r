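#' Scott's-rule bandwidths
#'
#' Per-dimension Gaussian kernel bandwidth
#' \eqn{h_d = \hat\sigma_d \, s^{-1/(p + 4)}}, where `s` is the sample
#' count and `p` the dimension.
#'
#' @param samples numeric `s x p` matrix (vector allowed).
#' @return Length-`p` vector of bandwidths.
#' @export
scott_bandwidth <- function(samples) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  s <- nrow(samples); p <- ncol(samples)
  apply(samples, 2L, stats::sd) * s^(-1 / (p + 4))
}

#' Negative log probability under a (reflected) kernel density estimate
#'
#' Evaluates \eqn{-\log[s^{-1} \sum_i K_h(\tilde\theta_i - \theta)]} with a
#' diagonal-bandwidth Gaussian product kernel and Scott's rule. For bounded
#' parameters, each sample additionally contributes its reflections
#' \eqn{2\,lo - \tilde\theta} and \eqn{2\,hi - \tilde\theta} at every
#' finite boundary (single reflection per boundary), the standard boundary
#' bias correction that stops mass leaking out of the support.
#'
#' @param samples posterior draws: `s x p` matrix, vector, or
#'   [posterior_samples()].
#' @param theta_true length-`p` vector at which to evaluate.
#' @param lo,hi optional support bounds (scalar or length-`p`; `NA` or
#'   infinite entries disable reflection for that side).
#' @param bandwidth optional bandwidth override (length-`p`).
#' @return Scalar NLP in nats.
#' @export
nlp_kde <- function(samples, theta_true, lo = NULL, hi = NULL,
                    bandwidth = NULL) {
  if (inherits(samples, "posterior_samples")) samples <- samples$theta
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  s <- nrow(samples); p <- ncol(samples)
  if (s < 2L) .stopf("need at least two samples")
  h <- bandwidth %||% scott_bandwidth(samples)
  if (any(h <= 0) || any(!is.finite(h)))
    .stopf("kernel bandwidth is zero; samples have no spread")
  lo <- rep(if (is.null(lo)) -Inf else lo, length.out = p)
  hi <- rep(if (is.null(hi)) Inf else hi, length.out = p)
  lo[is.na(lo)] <- -Inf; hi[is.na(hi)] <- Inf
  dens <- matrix(0, s, p)
  for (d in seq_len(p)) {
    kd <- dnorm(theta_true[d] - samples[, d], sd = h[d])
    if (is.finite(lo[d]))
      kd <- kd + dnorm(theta_true[d] - (2 * lo[d] - samples[, d]), sd = h[d])
    if (is.finite(hi[d]))
      kd <- kd + dnorm(theta_true[d] - (2 * hi[d] - samples[, d]), sd = h[d])
    dens[, d] <- kd
  }
  f_hat <- mean(apply(dens, 1L, prod))
  if (f_hat <= 0) return(Inf)
  -log(f_hat)
}

#' Root mean integrated squared error of posterior samples
#'
#' \deqn{\mathrm{RMISE} = \Big[s^{-1} \sum_{i=1}^s
#'   \|\tilde\theta_i - \theta\|^2\Big]^{1/2}.}
#' A concentration metric: suitable for unimodal posteriors, misleading for
#' multimodal ones (a point mass between two modes can score better than
#' the true posterior).
#'
#' @param samples `s x p` matrix, vector, or [posterior_samples()].
#' @param theta_true length-`p` vector of true parameters.
#' @return Non-negative scalar.
#' @export
rmise <- function(samples, theta_true) {
  if (inherits(samples, "posterior_samples")) samples <- samples$theta
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  sqrt(mean(rowSums(sweep(samples, 2L, theta_true)^2)))
}

#' Deterministic quadrature posterior on a one-dimensional grid
#'
#' Normalizes an unnormalized log posterior evaluated on a grid by the
#' trapezoid rule (after max-log subtraction to avoid underflow) and
#' equips it with an inverse-CDF sampler. Exact up to grid resolution for
#' one-dimensional parameters; used as the likelihood-based gold standard.
#'
#' @param grid increasing numeric grid covering the effective support.
#' @param log_unnorm unnormalized log posterior values on the grid.
#' @return An object of class `"grid_posterior"` with `grid`, `density`
#'   (integrating to one), and `cdf`.
#' @export
grid_posterior <- function(grid, log_unnorm) {
  if (length(grid) != length(log_unnorm)) .stopf("lengths differ")
  if (is.unsorted(grid, strictly = TRUE)) .stopf("`grid` must be increasing")
  lu <- log_unnorm - max(log_unnorm)
  u <- exp(lu)
  dx <- diff(grid)
  cell <- dx * (u[-1L] + u[-length(u)]) / 2
  z <- sum(cell)
  density <- u / z
  cdf <- c(0, cumsum(cell)) / z
  structure(list(grid = grid, density = density, cdf = cdf),
            class = "grid_posterior")
}

#' @export
print.grid_posterior <- function(x, ...) {
  cat(sprintf("Quadrature posterior on [%g, %g] (%d grid points)\n",
              min(x$grid), max(x$grid), length(x$grid)))
  invisible(x)
}

#' Draw samples from a quadrature posterior
#'
#' Inverse-CDF sampling with linear interpolation between grid points.
#'
#' @param gp a [grid_posterior()].
#' @param s number of draws.
#' @return A [posterior_samples()] object with provenance `"quadrature"`.
#' @export
grid_posterior_sample <- function(gp, s) {
  s <- .check_count(s, "s")
  u <- runif(s)
  theta <- approx(gp$cdf, gp$grid, xout = u, ties = "ordered",
                  rule = 2L)$y
  posterior_samples(theta, "quadrature")
}

# Log likelihood of the tanh-mixture benchmark for a grid of thetas and one
# payload's informative column.
.benchmark_loglik <- function(theta_grid, z1) {
  th <- tanh(theta_grid)
  sdv <- sqrt(pmax(1 - th^2, 1e-300))
  out <- numeric(length(theta_grid))
  for (g in seq_along(theta_grid)) {
    a <- dnorm(z1, mean = th[g], sd = sdv[g], log = TRUE)
    b <- dnorm(z1, mean = -th[g], sd = sdv[g], log = TRUE)
    mx <- pmax(a, b)
    out[g] <- sum(mx + log(0.5 * exp(a - mx) + 0.5 * exp(b - mx)))
  }
  out
}

#' Exact posterior of the benchmark model by quadrature
#'
#' The benchmark likelihood is tractable, so the true posterior of the
#' scalar parameter is computed by deterministic quadrature: the
#' unnormalized log posterior (standard-normal log prior plus the
#' tanh-mixture log likelihood of the informative first column; the
#' distractor column is independent of the parameter and drops out) is
#' evaluated on a grid and normalized by the trapezoid rule.
#'
#' @param z `n x 2` benchmark payload.
#' @param grid evaluation grid (default 2049 points on `[-6, 6]`, well
#'   beyond the effective standard-normal prior support).
#' @return A [grid_posterior()].
#' @export
benchmark_true_posterior <- function(z, grid = seq(-6, 6,
                                                   length.out = 2049L)) {
  if (!is.matrix(z) || ncol(z) != 2L)
    .stopf("`z` must be an n x 2 benchmark payload")
  log_unnorm <- dnorm(grid, log = TRUE) + .benchmark_loglik(grid, z[, 1L])
  grid_posterior(grid, log_unnorm)
}

#' Aggregate a per-example metric
#'
#' @param values numeric vector of per-example metric values (at least 2).
#' @return Named vector with the mean and the standard error
#'   \eqn{\mathrm{sd}/\sqrt{m}}.
#' @export
aggregate_metric <- function(values) {
  if (length(values) < 2L) .stopf("need at least two examples")
  c(mean = mean(values), se = stats::sd(values) / sqrt(length(values)))
}

#' Assemble a metric report
#'
#' One row per (method, metric) with test-set mean and standard error, the
#' layout used for tabulating method comparisons.
#'
#' @param method method label.
#' @param experiment experiment label.
#' @param nlp,rmise numeric vectors of per-example metric values.
#' @return A `data.frame` of class `"metric_report"` with columns
#'   `method`, `experiment`, `metric`, `mean`, `se`.
#' @export
metric_report <- function(method, experiment, nlp, rmise = NULL) {
  rows <- list(data.frame(method = method, experiment = experiment,
                          metric = "nlp",
                          mean = aggregate_metric(nlp)[["mean"]],
                          se = aggregate_metric(nlp)[["se"]]))
  if (!is.null(rmise))
    rows <- c(rows, list(data.frame(method = method, experiment = experiment,
                                    metric = "rmise",
                                    mean = aggregate_metric(rmise)[["mean"]],
                                    se = aggregate_metric(rmise)[["se"]])))
  out <- do.call(rbind, rows)
  class(out) <- c("metric_report", "data.frame")
  out
}
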