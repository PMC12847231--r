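test_that("exact linear relationships are recovered to machine precision", {
  set.seed(501)
  x <- matrix(rnorm(600), 200, 3)
  theta <- 3 * x[, 1L] - 2
  fit <- fit_linear_posterior_mean(x, theta)
  expect_equal(as.numeric(predict(fit, x)), theta, tolerance = 1e-10)
  # coefficient on the first (standardized) candidate is 3 * sd(x1)
  expect_equal(unname(fit$coefficients[2L, 1L]), 3 * sd(x[, 1L]),
               tolerance = 1e-10)
  expect_lt(max(abs(fit$coefficients[3:4, 1L])), 1e-10)
})

test_that("least-squares residuals are orthogonal to the design", {
  set.seed(502)
  x <- matrix(rnorm(1000), 250, 4)
  theta <- x[, 2L] - 0.5 * x[, 4L] + rnorm(250)
  fit <- fit_linear_posterior_mean(x, theta)
  resid <- theta - as.numeric(predict(fit, x))
  xs <- standardize(x, fit$moments)
  expect_lt(max(abs(crossprod(cbind(1, xs), resid))), 1e-8)
})

test_that("rank-deficient designs are flagged and fall back to minimum norm", {
  set.seed(503)
  x <- matrix(rnorm(300), 100, 3)
  x <- cbind(x, x[, 1L]) # duplicated column
  theta <- x[, 1L] + rnorm(100, sd = 0.1)
  expect_warning(fit <- fit_linear_posterior_mean(x, theta),
                 "rank-deficient")
  # minimum-norm solution splits the weight across the duplicates
  expect_equal(unname(fit$coefficients[2L, 1L]),
               unname(fit$coefficients[5L, 1L]))
  expect_equal(as.numeric(predict(fit, x)),
               as.numeric(cbind(1, standardize(x, fit$moments)) %*%
                            fit$coefficients))
})

test_that("gamma-toy regression slope on the second moment is negative", {
  set.seed(504)
  tab <- simulate_gamma_toy(1.5, 1, 4, 2e4)
  fit <- fit_linear_posterior_mean(tab$summaries, tab$params)
  # posterior mean (a + n/2) / (b + n t / 2) decreases in t
  expect_lt(fit$coefficients[2L, 1L], 0)
})

test_that("PLS selects one component for noiseless linear responses", {
  skip_if_not_installed("mixOmics")
  set.seed(505)
  x <- matrix(rnorm(1500), 500, 3)
  theta <- 2 * x[, 1L] - x[, 2L]
  fit <- fit_pls(x, theta)
  expect_equal(fit$ncomp, 1L)
  expect_equal(dim(fit$projection), c(3L, 1L))
  # the single latent score predicts theta up to scale
  scores <- predict(fit, x)
  expect_gt(abs(cor(scores[, 1L], theta)), 0.999)
})

test_that("PLS latent scores are uncorrelated and projection is consistent", {
  skip_if_not_installed("mixOmics")
  set.seed(506)
  x <- matrix(rnorm(4000), 500, 8)
  theta <- x[, 1L] + 0.5 * x[, 2L]^2 + rnorm(500, sd = 0.5)
  fit <- fit_pls(x, theta, max_components = 4L)
  scores <- predict(fit, x)
  if (ncol(scores) > 1L) {
    cors <- cor(scores)
    expect_lt(max(abs(cors[upper.tri(cors)])), 1e-6)
  }
  expect_equal(nrow(fit$projection), 8L)
  expect_error(fit_pls(x, theta, max_components = 9L), "cannot exceed")
})

test_that("nonlinear posterior-mean network learns the conjugate map", {
  set.seed(507)
  train <- simulate_gamma_toy(1.5, 1, 4, 2e4)
  val <- simulate_gamma_toy(1.5, 1, 4, 2e3, split = "validation")
  fit <- fit_posterior_mean_net(train, val,
                                control = train_control(batch_size = 512L,
                                                        max_epochs = 20L))
  test <- simulate_gamma_toy(1.5, 1, 4, 2000, split = "test")
  pred <- predict(fit, test)[, 1L]
  closed_form <- (1.5 + 2) / (1 + 2 * test$summaries[, 1L])
  # the learned map tracks the closed-form posterior mean; exact rank
  # agreement is unattainable because mean-pooling is the final operation
  # (the output is additive over observations while the conjugate
  # posterior mean is not), so the bound reflects that architectural bias
  expect_gt(cor(pred, closed_form, method = "spearman"), 0.94)
})

test_that("posterior-mean output collapses to zero for the reflected toy", {
  set.seed(508)
  train <- simulate_reflected_gamma_toy(1.5, 1, 4, 1e4)
  val <- simulate_reflected_gamma_toy(1.5, 1, 4, 1e3, split = "validation")
  fit <- fit_posterior_mean_net(train, val,
                                control = train_control(batch_size = 512L,
                                                        max_epochs = 10L))
  test <- simulate_reflected_gamma_toy(1.5, 1, 4, 500, split = "test")
  pred <- predict(fit, test)[, 1L]
  # the posterior mean is identically zero, so the best achievable
  # quadratic loss is E[theta^2] = a (a + 1) / b^2 = 3.75
  expect_lt(mean(abs(pred)), 0.25 * sd(train$params))
  expect_equal(fit$best_val, 3.75, tolerance = 0.15)
})

test_that("weighted quadratic loss matches its definition and gradients", {
  set.seed(509)
  m <- 12L
  params_mat <- matrix(rnorm(m * 2), m, 2)
  cand <- matrix(rnorm(m * 5), m, 5)
  A <- crossprod(matrix(rnorm(4), 2, 2)) + diag(2) # SPD
  comp <- epeabc:::.compressor_init(
    compressor_config("tabular_mlp", input_dim = 5L, output_dim = 2L))
  out <- epeabc:::.net_batch(comp, NULL, cand, params_mat, A = A)
  # loss agrees with the explicit quadratic form
  t_hat <- epeabc:::.compressor_forward_batch(comp, cand)$t
  expect_equal(out$loss, mean(vapply(seq_len(m), function(i) {
    d <- params_mat[i, ] - t_hat[i, ]
    as.numeric(d %*% A %*% d)
  }, numeric(1L))))
  # gradients agree with central differences
  params <- list(comp = epeabc:::.compressor_params(comp))
  loss_fn <- function(p) {
    epeabc:::.net_batch(epeabc:::.compressor_set_params(comp, p$comp),
                        NULL, cand, params_mat, backward = FALSE,
                        A = A)$loss
  }
  analytic <- epeabc:::.flatten_params(out$grads)
  idx <- sort(sample(length(analytic), 15L))
  expect_equal(analytic[idx], numeric_gradient(loss_fn, params, idx),
               tolerance = 1e-6)
  # invalid weights are rejected
  train <- reference_table(params_mat, cand)
  expect_error(fit_posterior_mean_net(train, train,
                                      A = matrix(1:4, 2, 2)),
               "positive-definite")
})
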