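test_that("gamma-toy report reproduces the closed-form anchors", {
  set.seed(801)
  r <- run_gamma_toy(m = 2e4)
  expect_equal(r$prior_entropy, 1.36, tolerance = 0.005)
  expect_equal(r$cpe_at_ref, 1.47, tolerance = 0.005)
  expect_equal(r$epe, 0.87, tolerance = 0.03)
  expect_lt(abs(r$frac_cpe_increase - 0.30), 0.02)
})

test_that("piecewise MI table swaps with the prior labels", {
  set.seed(802)
  mi <- run_piecewise(m = 5000, n = 100)
  expect_equal(dim(mi), c(2L, 2L))
  # the log-variance summary is informative only for the left prior, the
  # mean only for the right prior
  expect_gt(mi["centre_-1", "log_var"], 0.5)
  expect_gt(mi["centre_+1", "mean"], 0.8)
  expect_lt(mi["centre_-1", "mean"], 0.1)
  expect_lt(mi["centre_+1", "log_var"], 0.1)
})

test_that("candidate-summary tables round-trip through CSV", {
  set.seed(803)
  m <- 10L
  params <- matrix(runif(2 * m, 0, 10), m, 2)
  cand <- matrix(rnorm(7 * m), m, 7)
  colnames(params) <- c("mutation", "recombination")
  colnames(cand) <- paste0("s", 1:7)
  tab <- reference_table(params, cand, summaries = cand)
  path <- tempfile(fileext = ".csv")
  write_candidate_summary_table(tab, path)
  tab2 <- load_candidate_summary_table(path)
  expect_equal(n_draws(tab2), m)
  expect_equal(payload_kind(tab2), "vector")
  expect_equal(unname(tab2$params), unname(params))
  expect_equal(unname(tab2$payloads), unname(cand))
  # wrong column count is reported with the found headers
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1:3, b = 1:3), bad, row.names = FALSE)
  expect_error(load_candidate_summary_table(bad), "found 2: a, b")
  # out-of-support parameters trigger a warning
  params_bad <- params; params_bad[1L, 1L] <- 12
  tab3 <- reference_table(params_bad, cand)
  write_candidate_summary_table(tab3, path)
  expect_warning(load_candidate_summary_table(path), "outside")
})

test_that("trees round-trip through edge-list CSV", {
  set.seed(804)
  tree <- simulate_tree(1.2, 40)
  path <- tempfile(fileext = ".csv")
  write_tree_csv(tree, path)
  expect_equal(readLines(path, n = 1L), "\"source\",\"target\"")
  tree2 <- read_tree_csv(path)
  expect_equal(tree2$edges, tree$edges)
  expect_equal(tree2$n_nodes, tree$n_nodes)
})

test_that("experiment runners wire methods end to end at tiny scale", {
  set.seed(805)
  out <- run_benchmark(train_m = 2000L, val_m = 300L, test_m = 40L,
                       s = 100L,
                       methods = c("prior", "expert", "linear_regression",
                                   "quadrature"),
                       control = train_control(max_epochs = 2L))
  expect_s3_class(out$report, "metric_report")
  expect_setequal(unique(out$report$method),
                  c("prior", "expert", "linear_regression", "quadrature"))
  expect_true(all(is.finite(out$report$mean)))
  # the informed quadrature posterior beats the prior baseline
  nlp <- with(out$report, setNames(mean[metric == "nlp"],
                                   method[metric == "nlp"]))
  expect_lt(nlp[["quadrature"]], nlp[["prior"]])
})

test_that("scaled-down sizes are applied consistently", {
  sz <- epeabc:::.scale_sizes(0.01, 1e6, 1e4, 1e3, 1000)
  expect_equal(sz$train_m, 10000L)
  expect_equal(sz$val_m, 200L)  # floor applies
  expect_equal(sz$test_m, 50L)
  expect_equal(sz$s, 50L)
})

test_that("JSON checkpoints round-trip trained models exactly", {
  set.seed(806)
  train <- simulate_gamma_toy(1.5, 1, 4, 300)
  val <- simulate_gamma_toy(1.5, 1, 4, 100, split = "validation")
  fit <- fit_mdn_compressor(train, val,
                            control = train_control(batch_size = 150L,
                                                    max_epochs = 2L))
  path <- tempfile(fileext = ".json")
  save_checkpoint(fit, path)
  fit2 <- load_checkpoint(path)
  expect_equal(predict(fit2, train), predict(fit, train))
  mix1 <- predict(fit, get_payload(train, 5L), type = "mixture")[[1L]]
  mix2 <- predict(fit2, get_payload(train, 5L), type = "mixture")[[1L]]
  expect_equal(mdn_log_prob(mix2, 1.2), mdn_log_prob(mix1, 1.2))

  pm <- fit_posterior_mean_net(train, val,
                               control = train_control(batch_size = 150L,
                                                       max_epochs = 2L))
  save_checkpoint(pm, path)
  pm2 <- load_checkpoint(path)
  expect_equal(predict(pm2, train), predict(pm, train))
})
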