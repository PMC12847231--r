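test_that("set compressor is invariant to row order and duplication", {
  set.seed(301)
  cfg <- compressor_config("set_mlp", input_dim = 2L, output_dim = 1L)
  state <- epeabc:::.compressor_init(cfg)
  for (rep in 1:20) {
    z <- matrix(rnorm(20), 10, 2)
    t1 <- set_compressor_forward(state, z)
    expect_equal(set_compressor_forward(state, z[sample(10), ]), t1)
    expect_equal(set_compressor_forward(state, rbind(z, z)), t1)
  }
  expect_error(set_compressor_forward(state, matrix(0, 4, 3)), "2 columns")
})

test_that("zero weights give zero (set) or constant (gin) outputs", {
  cfg <- compressor_config("set_mlp", input_dim = 2L, output_dim = 1L)
  state <- epeabc:::.compressor_init(cfg)
  zero <- rapply(epeabc:::.compressor_params(state), function(x) x * 0,
                 how = "replace")
  state <- epeabc:::.compressor_set_params(state, zero)
  expect_equal(set_compressor_forward(state, matrix(rnorm(20), 10, 2)), 0)

  set.seed(302)
  gcfg <- compressor_config("gin", output_dim = 1L)
  gstate <- epeabc:::.compressor_init(gcfg)
  gzero <- rapply(epeabc:::.compressor_params(gstate), function(x) x * 0,
                  how = "replace")
  gstate <- epeabc:::.compressor_set_params(gstate, gzero)
  out_path <- gin_forward(gstate, simulate_tree(0, 10))
  out_star <- gin_forward(gstate, simulate_tree(10, 25))
  expect_equal(out_path, out_star) # constant regardless of the tree
})

test_that("tabular compressor is a pure deterministic map", {
  set.seed(303)
  cfg <- compressor_config("tabular_mlp", input_dim = 7L, output_dim = 2L)
  state <- epeabc:::.compressor_init(cfg)
  v <- rnorm(7)
  expect_equal(tabular_compressor_forward(state, v),
               tabular_compressor_forward(state, v))
  expect_length(tabular_compressor_forward(state, v), 2L)
  expect_error(tabular_compressor_forward(state, rnorm(5)), "length 7")
})

test_that("GIN output is invariant to node relabeling", {
  set.seed(304)
  cfg <- compressor_config("gin", output_dim = 1L)
  state <- epeabc:::.compressor_init(cfg)
  for (rep in 1:20) {
    tree <- simulate_tree(runif(1, 0, 2), 30)
    perm <- sample(0:29)
    relabeled <- grown_tree(30, matrix(perm[tree$edges + 1L], ncol = 2L))
    expect_equal(gin_forward(state, tree), gin_forward(state, relabeled))
  }
})

test_that("GIN distinguishes path from star", {
  set.seed(305)
  cfg <- compressor_config("gin", output_dim = 1L)
  state <- epeabc:::.compressor_init(cfg)
  path <- grown_tree(4, rbind(c(0, 1), c(1, 2), c(2, 3)))
  star <- grown_tree(4, rbind(c(0, 1), c(0, 2), c(0, 3)))
  expect_false(isTRUE(all.equal(gin_forward(state, path),
                                gin_forward(state, star))))
})

test_that("compressor parameter count does not grow with sample size", {
  cfg <- compressor_config("set_mlp", input_dim = 2L, output_dim = 1L)
  state <- epeabc:::.compressor_init(cfg)
  n_par <- epeabc:::.count_params(epeabc:::.compressor_params(state))
  expect_equal(n_par, (2 * 16 + 16) + (16 * 16 + 16) + (16 + 1))
  # forward works for any n with the same parameters
  expect_length(set_compressor_forward(state, matrix(rnorm(6), 3, 2)), 1L)
  expect_length(set_compressor_forward(state, matrix(rnorm(60), 30, 2)), 1L)
})

test_that("mean-pooled summaries concentrate as the sample size grows", {
  set.seed(306)
  cfg <- compressor_config("set_mlp", input_dim = 2L, output_dim = 1L)
  state <- epeabc:::.compressor_init(cfg)
  theta <- 0.7
  th <- tanh(theta)
  draw_t <- function(n) {
    u <- sample(c(-1, 1), n, replace = TRUE)
    z <- cbind(u * th + rnorm(n) * sqrt(1 - th^2), rnorm(n))
    set_compressor_forward(state, z)
  }
  v10 <- var(replicate(300, draw_t(10L)))
  v100 <- var(replicate(300, draw_t(100L)))
  # variance of a mean of i.i.d. row features shrinks like 1/n
  expect_lt(v100, v10 / 5)
})

test_that("backpropagated gradients match numeric differentiation", {
  set.seed(307)
  tab <- simulate_benchmark(5, 6)
  comp <- epeabc:::.compressor_init(
    compressor_config("set_mlp", input_dim = 2L, output_dim = 1L))
  head <- epeabc:::.mdn_head_init(mdn_config("gaussian", k = 2L), 1L, 1L)
  params <- list(comp = epeabc:::.compressor_params(comp),
                 head = epeabc:::.head_params(head))
  loss_fn <- function(p) {
    epeabc:::.net_batch(epeabc:::.compressor_set_params(comp, p$comp),
                        epeabc:::.head_set_params(head, p$head),
                        tab$payloads, tab$params, backward = FALSE)$loss
  }
  out <- epeabc:::.net_batch(comp, head, tab$payloads, tab$params)
  analytic <- epeabc:::.flatten_params(out$grads)
  idx <- sort(sample(length(analytic), 20L))
  expect_equal(analytic[idx], numeric_gradient(loss_fn, params, idx),
               tolerance = 1e-6)

  # GIN + quadratic loss path
  trees <- simulate_tree_table(12, 5)
  gcomp <- epeabc:::.compressor_init(compressor_config("gin",
                                                       output_dim = 1L))
  gparams <- list(comp = epeabc:::.compressor_params(gcomp))
  batch <- epeabc:::.gin_batch(trees$payloads)
  gloss <- function(p) {
    epeabc:::.net_batch(epeabc:::.compressor_set_params(gcomp, p$comp),
                        NULL, batch, trees$params, backward = FALSE)$loss
  }
  gout <- epeabc:::.net_batch(gcomp, NULL, batch, trees$params)
  ganalytic <- epeabc:::.flatten_params(gout$grads)
  gidx <- sort(sample(length(ganalytic), 20L))
  expect_equal(ganalytic[gidx], numeric_gradient(gloss, gparams, gidx),
               tolerance = 1e-6)
})
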