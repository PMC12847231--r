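#' Linear posterior-mean summaries
#'
#' Ordinary least squares regression of the parameters on candidate
#' summaries (semi-automatic ABC). The fitted linear predictor estimates
#' the posterior mean and is used as one summary per parameter. Candidates
#' are standardized internally; a rank-deficient design is flagged and the
#' minimum-norm solution is used.
#'
#' @param candidates numeric `m x c` matrix of candidate statistics.
#' @param params numeric `m x p` parameter matrix (vector allowed).
#' @return An object of class `"linear_summaries"` with `coefficients`
#'   (`(c + 1) x p`, intercept first, on the standardized candidate scale)
#'   and a `predict()` method.
#' @export
fit_linear_posterior_mean <- function(candidates, params) {
  if (is.vector(params)) params <- matrix(params, ncol = 1L)
  if (!is.matrix(candidates)) candidates <- as.matrix(candidates)
  m <- nrow(candidates); c_dim <- ncol(candidates)
  if (m != nrow(params)) .stopf("row counts differ")
  if (m <= c_dim + 1L) .stopf("need more draws than candidates")
  moments <- summary_moments(candidates)
  X <- cbind(1, standardize(candidates, moments))
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1L]
  rank <- sum(sv$d > tol)
  rank_deficient <- rank < ncol(X)
  if (rank_deficient)
    warning("rank-deficient design; using the minimum-norm solution",
            call. = FALSE)
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  coefficients <- sv$v %*% (dinv * crossprod(sv$u, params))
  rownames(coefficients) <- c("(Intercept)",
                              colnames(candidates) %||%
                                paste0("c", seq_len(c_dim)))
  structure(list(coefficients = coefficients, moments = moments,
                 rank_deficient = rank_deficient, p = ncol(params)),
            class = "linear_summaries")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.linear_summaries <- function(x, ...) {
  cat(sprintf("Linear posterior-mean summaries: %d candidates -> %d summar%s\n",
              nrow(x$coefficients) - 1L, x$p, if (x$p == 1L) "y" else "ies"))
  if (x$rank_deficient) cat("  (rank-deficient design, minimum-norm fit)\n")
  invisible(x)
}

#' @export
coef.linear_summaries <- function(object, ...) object$coefficients

#' @export
predict.linear_summaries <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  cbind(1, standardize(newdata, object$moments)) %*% object$coefficients
}

#' Partial least squares summaries
#'
#' Supervised projection of candidate statistics onto `r` latent
#' directions maximizing covariance with the parameters. The latent scores
#' (not the parameter predictions) are used as summaries. The component
#' count is chosen by `folds`-fold cross-validation of the parameter
#' prediction error. The decomposition is delegated to
#' \code{mixOmics::pls}; this function adds standardization, CV component
#' selection, and a plain projection-matrix interface.
#'
#' @param candidates numeric `m x c` matrix.
#' @param params numeric `m x p` matrix (vector allowed).
#' @param max_components maximum latent dimension (default `c`).
#' @param folds number of CV folds (default 5).
#' @return An object of class `"pls_summaries"` with `projection`
#'   (`c x r` matrix applied to standardized candidates), `ncomp = r`, and
#'   the per-component CV mean squared errors.
#' @export
fit_pls <- function(candidates, params, max_components = NULL, folds = 5L) {
  if (!requireNamespace("mixOmics", quietly = TRUE))
    .stopf("fit_pls requires the mixOmics package")
  if (is.vector(params)) params <- matrix(params, ncol = 1L)
  if (!is.matrix(candidates)) candidates <- as.matrix(candidates)
  c_dim <- ncol(candidates)
  m <- nrow(candidates)
  if (is.null(max_components)) max_components <- c_dim
  if (max_components > c_dim)
    .stopf("`max_components` cannot exceed the %d candidates", c_dim)
  folds <- .check_count(folds, "folds", min = 2L)
  moments <- summary_moments(candidates)
  X <- standardize(candidates, moments)
  colnames(X) <- paste0("x", seq_len(c_dim)) # mixOmics matches by name
  fold_id <- rep_len(seq_len(folds), m)[sample.int(m)]
  cv_mse <- numeric(max_components)
  sq_err <- matrix(0, folds, max_components)
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    fit <- mixOmics::pls(X[!hold, , drop = FALSE],
                         params[!hold, , drop = FALSE],
                         ncomp = max_components, mode = "regression",
                         scale = FALSE)
    pred <- predict(fit, X[hold, , drop = FALSE])$predict
    for (r in seq_len(max_components)) {
      sq_err[f, r] <- sum((params[hold, , drop = FALSE] -
                             pred[, , r])^2)
    }
  }
  cv_mse <- colSums(sq_err) / m
  # parsimonious selection: the smallest component count whose CV error is
  # within 1% of the response variance of the minimum. A plain argmin
  # always inflates the count on (near-)noiseless responses, where extra
  # components only chase finite-sample covariance jitter.
  tol <- 0.01 * sum(apply(params, 2L, stats::var))
  ncomp <- which(cv_mse <= min(cv_mse) + tol)[1L]
  fit <- mixOmics::pls(X, params, ncomp = ncomp, mode = "regression",
                       scale = FALSE)
  W <- fit$loadings$X # weights
  P <- fit$mat.c      # X loadings
  projection <- W %*% solve(crossprod(P, W))
  rownames(projection) <- colnames(candidates) %||%
    paste0("c", seq_len(c_dim))
  structure(list(projection = projection, ncomp = ncomp, cv_mse = cv_mse,
                 moments = moments), class = "pls_summaries")
}

#' @export
print.pls_summaries <- function(x, ...) {
  cat(sprintf("PLS summaries: %d candidates -> %d latent component(s)\n",
              nrow(x$projection), x$ncomp))
  cat("  CV MSE by component count:",
      paste(sprintf("%.4f", x$cv_mse), collapse = " "), "\n")
  invisible(x)
}

#' @export
predict.pls_summaries <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  standardize(newdata, object$moments) %*% object$projection
}
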