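test_that("mixture log density matches closed forms", {
  mp <- mixture_params("gaussian", logits = 0, locations = 0,
                       log_scales = 0)
  expect_equal(mdn_log_prob(mp, 0), -0.5 * log(2 * pi))
  # identical components collapse to a single component for any logits
  mp2 <- mixture_params("gaussian", logits = c(3, -1),
                        locations = c(0.5, 0.5), log_scales = c(0.2, 0.2))
  mp1 <- mixture_params("gaussian", logits = 0, locations = 0.5,
                        log_scales = 0.2)
  th <- seq(-2, 2, by = 0.5)
  expect_equal(mdn_log_prob(mp2, matrix(th)), mdn_log_prob(mp1, matrix(th)))
})

test_that("mixture densities are normalized", {
  set.seed(401)
  for (rep in 1:5) {
    k <- sample(1:4, 1)
    mp <- mixture_params("gaussian", logits = rnorm(k),
                         locations = rnorm(k), log_scales = rnorm(k, 0, 0.5))
    total <- stats::integrate(function(x)
      exp(mdn_log_prob(mp, matrix(x))), -Inf, Inf)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  mp <- mixture_params("scaled_beta", logits = c(0, 1),
                       locations = log(c(2, 3)), log_scales = log(c(4, 1.5)),
                       lo = 0, hi = 10)
  total <- stats::integrate(function(x) exp(mdn_log_prob(mp, matrix(x))),
                            0, 10)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("scaled-beta log density matches hand values and boundaries", {
  # flat Beta(1, 1) rescaled to (0, 10) has density 0.1
  expect_equal(scaled_beta_log_prob(1, 1, 0, 10, 3.7), log(0.1))
  # Beta(2, 2) density at 1/2 is 6 * 0.5 * 0.5 = 1.5
  expect_equal(scaled_beta_log_prob(2, 2, 0, 1, 0.5), log(1.5))
  expect_equal(scaled_beta_log_prob(2, 2, 0, 1, 0), -Inf)
  expect_equal(scaled_beta_log_prob(2, 2, 0, 1, 1.2), -Inf)
  expect_error(scaled_beta_log_prob(-1, 2, 0, 1, 0.5), "positive")
})

test_that("ancestral sampling reproduces the mixture", {
  set.seed(402)
  mp <- mixture_params("gaussian", logits = 0, locations = 0,
                       log_scales = 0)
  x <- mdn_sample(mp, 1e5)
  expect_equal(mean(x), 0, tolerance = 0.02)
  expect_equal(var(as.numeric(x)), 1, tolerance = 0.02)
  # degenerate logits put all draws in the first component
  mp <- mixture_params("gaussian", logits = c(50, -50),
                       locations = c(10, -10), log_scales = c(-3, -3))
  expect_true(all(mdn_sample(mp, 1000) > 9))
  # flat scaled beta has mean at the middle of the support
  mp <- mixture_params("scaled_beta", logits = 0, locations = log(1),
                       log_scales = log(1), lo = 0, hi = 10)
  expect_equal(mean(mdn_sample(mp, 1e5)), 5, tolerance = 0.05)
})

test_that("training loss is exactly the Monte Carlo EPE of the fit", {
  set.seed(403)
  train <- simulate_gamma_toy(1.5, 1, 4, 512)
  val <- simulate_gamma_toy(1.5, 1, 4, 128, split = "validation")
  fit <- fit_mdn_compressor(train, val,
                            control = train_control(batch_size = 256L,
                                                    max_epochs = 2L))
  # loss computed by the training engine on the training table
  engine_loss <- net_loss_on_table(fit, train)
  # the same quantity assembled from public pieces: compress, evaluate the
  # mixture head, take the mean negative log density at the true parameters
  t_mat <- extract_summaries(fit, train)
  fitted_log_density <- function(theta, t) {
    mix <- predict(fit, t, from = "summaries", type = "mixture")
    vapply(seq_along(mix), function(i) mdn_log_prob(mix[[i]], theta[i, ]),
           numeric(1L))
  }
  epe <- epe_estimate(fitted_log_density, train$params, t_mat,
                      vectorized = TRUE)
  expect_equal(engine_loss, epe$value, tolerance = 1e-12)
})

test_that("fitted MDN objects expose coherent methods", {
  set.seed(404)
  train <- simulate_gamma_toy(1.5, 1, 4, 400)
  val <- simulate_gamma_toy(1.5, 1, 4, 100, split = "validation")
  fit <- fit_mdn_compressor(train, val,
                            control = train_control(batch_size = 200L,
                                                    max_epochs = 3L))
  expect_s3_class(fit, "epe_mdn")
  expect_output(print(fit), "MDN compression")
  expect_equal(nrow(fit$history), fit$epochs)
  t_mat <- predict(fit, train)
  expect_equal(dim(t_mat), c(400L, 1L))
  # deterministic forward pass
  expect_equal(predict(fit, train), t_mat)
  mix <- predict(fit, get_payload(train, 1L), type = "mixture")
  expect_s3_class(mix[[1L]], "mixture_params")
  draws <- simulate(fit, nsim = 50L, seed = 1, newdata = get_payload(train, 1L))
  expect_equal(dim(draws), c(50L, 1L))
  expect_length(coef(fit), epeabc:::.count_params(
    epeabc:::.compressor_params(fit$compressor)) +
      epeabc:::.count_params(epeabc:::.head_params(fit$head)))
})

test_that("seeded training is reproducible", {
  run <- function() {
    set.seed(405)
    train <- simulate_gamma_toy(1.5, 1, 4, 300)
    val <- simulate_gamma_toy(1.5, 1, 4, 100, split = "validation")
    fit <- fit_mdn_compressor(train, val,
                              control = train_control(batch_size = 150L,
                                                      max_epochs = 3L))
    coef(fit)
  }
  expect_identical(run(), run())
})
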