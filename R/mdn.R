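#' Mixture-density head specification
#'
#' The conditional density head placed on top of a compressor. Given the
#' `q` learned summaries `t`, three independent two-layer MLPs (one hidden
#' layer of `hidden` units, then a linear output) produce the mixture
#' logits \eqn{\eta(t)}, the component locations \eqn{\mu(t)} and
#' log-scales \eqn{\kappa(t)} (Gaussian family), or the component log-shape
#' pairs (scaled-beta family). The estimated posterior for the Gaussian
#' family is
#' \deqn{\hat f(\theta \mid t) = \sum_{j=1}^k \mathrm{softmax}_j(\eta(t))\,
#'   \mathrm{Normal}(\theta \mid \mu_j(t), e^{2 \kappa_j(t)}),}
#' so \eqn{\kappa} parameterizes the log standard deviation. Scaled-beta
#' components live on the box `(lo, hi)` per parameter dimension.
#'
#' @param family `"gaussian"` or `"scaled_beta"`.
#' @param k number of mixture components.
#' @param lo,hi support bounds (scalars or length-`p` vectors), required
#'   for `"scaled_beta"`.
#' @param hidden hidden width of each head MLP (default 16).
#' @return An object of class `"mdn_config"`.
#' @export
mdn_config <- function(family = c("gaussian", "scaled_beta"), k = 2L,
                       lo = NULL, hi = NULL, hidden = 16L) {
  family <- match.arg(family)
  k <- .check_count(k, "k")
  if (family == "scaled_beta") {
    if (is.null(lo) || is.null(hi) || any(hi <= lo))
      .stopf("scaled_beta components need bounds with lo < hi")
  }
  structure(list(family = family, k = k, lo = lo, hi = hi,
                 hidden = .check_count(hidden, "hidden")),
            class = "mdn_config")
}

# Trainable head state. p: parameter dimension, q: summary dimension.
.mdn_head_init <- function(config, q, p) {
  k <- config$k
  mlps <- list(
    eta = .mlp_init(c(q, config$hidden, k)),
    loc = .mlp_init(c(q, config$hidden, k * p)), # mu | log-shape alpha
    scale = .mlp_init(c(q, config$hidden, k * p)) # kappa | log-shape beta
  )
  structure(list(config = config, mlps = mlps, p = p, q = q),
            class = "mdn_head_state")
}

.head_params <- function(head) lapply(head$mlps, function(m) list(W = m$W, b = m$b))

.head_set_params <- function(head, params) {
  for (nm in names(params)) {
    head$mlps[[nm]]$W <- params[[nm]]$W
    head$mlps[[nm]]$b <- params[[nm]]$b
  }
  head
}

# Forward through the three head MLPs. t_mat: B x q.
.head_forward <- function(head, t_mat) {
  f_eta <- .mlp_forward(head$mlps$eta, t_mat)
  f_loc <- .mlp_forward(head$mlps$loc, t_mat)
  f_scale <- .mlp_forward(head$mlps$scale, t_mat)
  list(eta = f_eta$out, loc = f_loc$out, scale = f_scale$out,
       caches = list(eta = f_eta, loc = f_loc, scale = f_scale))
}

.rowlse <- function(x) {
  mx <- apply(x, 1L, max)
  mx + log(rowSums(exp(x - mx)))
}

# Negative-log-probability loss and its gradients wrt the head outputs.
# theta: B x p. Returns list(nlp = per-example -log f, d_eta, d_loc,
# d_scale) with gradients of mean(nlp).
.mdn_loss <- function(head, fwd, theta) {
  cfg <- head$config
  k <- cfg$k; p <- head$p; B <- nrow(theta)
  eta <- fwd$eta
  logw <- eta - .rowlse(eta)
  if (cfg$family == "gaussian") {
    # per-component log density, summed over parameter dims
    logphi <- matrix(0, B, k)
    d_loc <- matrix(0, B, k * p)
    d_scale <- matrix(0, B, k * p)
    mu <- fwd$loc; kap <- fwd$scale
    for (j in seq_len(k)) {
      cols <- ((j - 1L) * p + 1L):(j * p)
      diff <- theta - mu[, cols, drop = FALSE]
      inv_var <- exp(-2 * kap[, cols, drop = FALSE])
      logphi[, j] <- rowSums(-kap[, cols, drop = FALSE] -
                               0.5 * log(2 * pi) - 0.5 * diff^2 * inv_var)
      d_loc[, cols] <- -diff * inv_var     # d(-logphi_j)/dmu, pre-resp
      d_scale[, cols] <- 1 - diff^2 * inv_var # d(-logphi_j)/dkappa
    }
  } else {
    lo <- rep(cfg$lo, length.out = p); hi <- rep(cfg$hi, length.out = p)
    width <- hi - lo
    x <- sweep(sweep(theta, 2L, lo), 2L, width, "/")
    x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
    logphi <- matrix(0, B, k)
    d_loc <- matrix(0, B, k * p)
    d_scale <- matrix(0, B, k * p)
    lx <- log(x); l1x <- log1p(-x)
    for (j in seq_len(k)) {
      cols <- ((j - 1L) * p + 1L):(j * p)
      alpha <- exp(fwd$loc[, cols, drop = FALSE])
      beta <- exp(fwd$scale[, cols, drop = FALSE])
      logphi[, j] <- rowSums((alpha - 1) * lx + (beta - 1) * l1x -
                               lbeta(alpha, beta) -
                               rep(log(width), each = B))
      dab <- digamma(alpha + beta)
      d_loc[, cols] <- -alpha * (lx - digamma(alpha) + dab)
      d_scale[, cols] <- -beta * (l1x - digamma(beta) + dab)
    }
  }
  logjoint <- logw + logphi
  logf <- .rowlse(logjoint)
  r <- exp(logjoint - logf) # responsibilities, B x k
  w <- exp(logw)
  scale_g <- 1 / B
  d_eta <- (w - r) * scale_g
  rep_r <- r[, rep(seq_len(k), each = p), drop = FALSE]
  list(nlp = -logf,
       d_eta = d_eta,
       d_loc = d_loc * rep_r * scale_g,
       d_scale = d_scale * rep_r * scale_g)
}

# Backprop the three head gradients; returns list(grads, dT).
.head_backward <- function(head, fwd, d_eta, d_loc, d_scale) {
  bw_eta <- .mlp_backward(head$mlps$eta, fwd$caches$eta, d_eta)
  bw_loc <- .mlp_backward(head$mlps$loc, fwd$caches$loc, d_loc)
  bw_scale <- .mlp_backward(head$mlps$scale, fwd$caches$scale, d_scale)
  list(grads = list(eta = list(W = bw_eta$W, b = bw_eta$b),
                    loc = list(W = bw_loc$W, b = bw_loc$b),
                    scale = list(W = bw_scale$W, b = bw_scale$b)),
       dT = bw_eta$dX + bw_loc$dX + bw_scale$dX)
}

# --- mixture parameter objects ---------------------------------------------

#' Per-example mixture parameters
#'
#' Container for the conditional mixture returned by an MDN head for a
#' single example.
#'
#' @param family `"gaussian"` or `"scaled_beta"`.
#' @param logits length-`k` mixture logits \eqn{\eta}.
#' @param locations `k x p` matrix: Gaussian means or beta log-shape
#'   \eqn{\log\alpha}.
#' @param log_scales `k x p` matrix: Gaussian log standard deviations
#'   \eqn{\kappa} or beta log-shape \eqn{\log\beta}.
#' @param lo,hi support bounds (scaled-beta only).
#' @return An object of class `"mixture_params"`.
#' @export
mixture_params <- function(family = c("gaussian", "scaled_beta"), logits,
                           locations, log_scales, lo = NULL, hi = NULL) {
  family <- match.arg(family)
  if (is.vector(locations)) locations <- matrix(locations, ncol = 1L)
  if (is.vector(log_scales)) log_scales <- matrix(log_scales, ncol = 1L)
  k <- length(logits)
  if (nrow(locations) != k || nrow(log_scales) != k ||
      any(dim(locations) != dim(log_scales)))
    .stopf("locations and log_scales must be k x p with k = length(logits)")
  structure(list(family = family, logits = as.numeric(logits),
                 locations = locations, log_scales = log_scales,
                 lo = lo, hi = hi), class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("%s mixture, k = %d components, p = %d dimension(s)\n",
              x$family, length(x$logits), ncol(x$locations)))
  w <- exp(x$logits - max(x$logits))
  cat("  weights:", paste(sprintf("%.3f", w / sum(w)), collapse = " "), "\n")
  invisible(x)
}

#' Log density of a scaled-beta component
#'
#' Density of `lo + (hi - lo) * Beta(alpha, beta)` evaluated in log space;
#' returns `-Inf` outside `(lo, hi)`.
#'
#' @param shape1,shape2 beta shapes (positive).
#' @param lo,hi support bounds.
#' @param theta evaluation points.
#' @return Log densities.
#' @export
scaled_beta_log_prob <- function(shape1, shape2, lo, hi, theta) {
  if (any(shape1 <= 0) || any(shape2 <= 0)) .stopf("shapes must be positive")
  if (any(hi <= lo)) .stopf("need lo < hi")
  x <- (theta - lo) / (hi - lo)
  out <- rep(-Inf, length(x))
  ok <- x > 0 & x < 1
  out[ok] <- stats::dbeta(x[ok], shape1, shape2, log = TRUE) - log(hi - lo)
  out
}

#' Log density of a conditional mixture
#'
#' Evaluates \eqn{\log \hat f(\theta \mid t)} for a [mixture_params()]
#' object via a numerically stable log-sum-exp over components. For the
#' scaled-beta family, values outside the support give `-Inf`.
#'
#' @param params_out a [mixture_params()] object.
#' @param theta length-`p` vector or `s x p` matrix of evaluation points.
#' @return Log density (vector of length `s`).
#' @export
mdn_log_prob <- function(params_out, theta) {
  if (!inherits(params_out, "mixture_params"))
    .stopf("`params_out` must be a mixture_params object")
  p <- ncol(params_out$locations)
  if (is.vector(theta)) theta <- matrix(theta, ncol = p)
  k <- length(params_out$logits)
  logw <- params_out$logits - max(params_out$logits)
  logw <- logw - log(sum(exp(logw)))
  comp <- matrix(0, nrow(theta), k)
  for (j in seq_len(k)) {
    if (params_out$family == "gaussian") {
      lp <- dnorm(theta,
                  mean = rep(params_out$locations[j, ], each = nrow(theta)),
                  sd = rep(exp(params_out$log_scales[j, ]),
                           each = nrow(theta)), log = TRUE)
    } else {
      lp <- matrix(0, nrow(theta), p)
      for (d in seq_len(p)) {
        lo <- rep(params_out$lo, length.out = p)[d]
        hi <- rep(params_out$hi, length.out = p)[d]
        lp[, d] <- scaled_beta_log_prob(exp(params_out$locations[j, d]),
                                        exp(params_out$log_scales[j, d]),
                                        lo, hi, theta[, d])
      }
    }
    comp[, j] <- logw[j] + rowSums(matrix(lp, nrow(theta), p))
  }
  .rowlse(comp)
}

#' Draw samples from a conditional mixture
#'
#' Ancestral sampling: a component is drawn from the softmax of the logits,
#' then a draw is taken from that component.
#'
#' @param params_out a [mixture_params()] object.
#' @param s number of draws.
#' @return `s x p` matrix of samples.
#' @export
mdn_sample <- function(params_out, s) {
  s <- .check_count(s, "s")
  p <- ncol(params_out$locations)
  w <- exp(params_out$logits - max(params_out$logits))
  w <- w / sum(w)
  j <- sample.int(length(w), s, replace = TRUE, prob = w)
  out <- matrix(0, s, p)
  for (d in seq_len(p)) {
    if (params_out$family == "gaussian") {
      out[, d] <- rnorm(s, params_out$locations[j, d],
                        exp(params_out$log_scales[j, d]))
    } else {
      lo <- rep(params_out$lo, length.out = p)[d]
      hi <- rep(params_out$hi, length.out = p)[d]
      out[, d] <- lo + (hi - lo) *
        rbeta(s, exp(params_out$locations[j, d]),
              exp(params_out$log_scales[j, d]))
    }
  }
  out
}

# Split B x (k, k*p, k*p) head outputs into one mixture_params per row.
.head_outputs_to_mixtures <- function(head, fwd_or_mat) {
  cfg <- head$config; k <- cfg$k; p <- head$p
  eta <- fwd_or_mat$eta; loc <- fwd_or_mat$loc; sc <- fwd_or_mat$scale
  lapply(seq_len(nrow(eta)), function(i) {
    mixture_params(cfg$family, eta[i, ],
                   matrix(loc[i, ], k, p, byrow = TRUE),
                   matrix(sc[i, ], k, p, byrow = TRUE),
                   lo = cfg$lo, hi = cfg$hi)
  })
}
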