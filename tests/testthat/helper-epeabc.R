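# Shared test utilities.

# Perturb the i-th scalar (in flattening order) of a nested parameter list.
perturb_param <- function(params, i, eps) {
  cnt <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    if (is.numeric(x)) {
      k <- length(x)
      if (i > cnt && i <= cnt + k) x[i - cnt] <- x[i - cnt] + eps
      cnt <<- cnt + k
    }
    x
  }
  walk(params)
}

# Central-difference gradient at selected coordinates.
numeric_gradient <- function(loss_fn, params, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    (loss_fn(perturb_param(params, i, eps)) -
       loss_fn(perturb_param(params, i, -eps))) / (2 * eps)
  }, numeric(1L))
}

# Kolmogorov-Smirnov distance against a CDF without ks.test's tie warnings.
ks_distance <- function(samples, cdf) {
  x <- sort(samples)
  n <- length(x)
  u <- cdf(x)
  max(abs(u - seq_len(n) / n), abs(u - (seq_len(n) - 1L) / n))
}

# Loss of a fitted (or raw) compressor+head on a whole table via the
# internal batch engine; used to cross-check against epe_estimate.
net_loss_on_table <- function(fit, table) {
  epeabc:::.net_eval(fit$compressor, fit$head, table)
}
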