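test_that("second moment and conjugate posterior match hand computations", {
  expect_equal(second_moment(c(1, 1, 1, 1)), 1)
  expect_equal(second_moment(c(0, 0)), 0)
  expect_equal(second_moment(c(1, -1, 2, 0)), 1.5) # (1 + 1 + 4 + 0) / 4
  expect_error(second_moment(numeric(0)), "at least one")

  post <- gamma_posterior(1.5, 1, 4, 0.3)
  expect_equal(post$shape, 3.5)
  expect_equal(post$rate, 1.6)
  post0 <- gamma_posterior(2, 3, 0, 99)
  expect_equal(post0$shape, 2) # no data: posterior = prior
  expect_equal(post0$rate, 3)
  expect_equal(gamma_posterior(2, 2, 10, 1), list(shape = 7, rate = 7))
  expect_error(gamma_posterior(1.5, 1, 4, -0.1), "non-negative")
  expect_error(gamma_posterior(-1, 1, 4, 0.3), "positive")
})

test_that("gamma toy simulator obeys the generative model", {
  set.seed(101)
  tab <- simulate_gamma_toy(1.5, 1, 4, 2e4)
  expect_s3_class(tab, "reference_table")
  expect_equal(payload_kind(tab), "matrix")
  expect_equal(dim(tab$payloads), c(2e4L, 4L, 1L))
  expect_true(all(tab$params > 0))
  expect_equal(mean(tab$params), 1.5, tolerance = 0.02) # gamma mean a/b
  # stored summary is the second moment of each payload
  i <- c(1L, 7L, 1234L)
  expect_equal(tab$summaries[i, 1L],
               vapply(i, function(j) second_moment(get_payload(tab, j)),
                      numeric(1L)))
  # at fixed theta = 1 the second moment converges to 1
  set.seed(102)
  y <- rnorm(2e5)
  expect_equal(second_moment(y), 1, tolerance = 0.01)
  expect_error(simulate_gamma_toy(0, 1, 4, 10), "positive")
})

test_that("posterior mean recovers the parameter for large n", {
  set.seed(103)
  tab <- simulate_gamma_toy(1.5, 1, 1e4, 1L)
  post <- gamma_posterior(1.5, 1, 1e4, tab$summaries[1L, 1L])
  expect_equal(post$shape / post$rate, tab$params[1L, 1L],
               tolerance = 0.05)
})

test_that("reflected-gamma toy splits sign and magnitude independently", {
  set.seed(104)
  tab <- simulate_reflected_gamma_toy(1.5, 1, 4, 5e4)
  th <- tab$params[, 1L]
  expect_equal(mean(th), 0, tolerance = 0.02)       # symmetric prior
  expect_equal(mean(abs(th)), 1.5, tolerance = 0.03) # |theta| ~ Gamma(a, b)
  expect_lt(abs(mean(th > 0) - 0.5), 0.01)
})

test_that("piecewise model is continuous at the transition", {
  set.seed(105)
  # theta < 0: zero-mean with variance exp(theta); theta >= 0: mean theta
  tab <- simulate_piecewise(-1, 0.25, 2000, 50)
  neg <- tab$params[, 1L] < 0
  y <- tab$payloads[, , 1L]
  v <- apply(y, 1L, var)
  expect_equal(v[neg], exp(tab$params[neg, 1L]), tolerance = 0.15)
  tab2 <- simulate_piecewise(1, 0.25, 2000, 50)
  pos <- tab2$params[, 1L] >= 0
  ybar <- rowMeans(tab2$payloads[, , 1L])
  expect_equal(ybar[pos], tab2$params[pos, 1L], tolerance = 0.15)
})

test_that("benchmark payload entries have zero mean and unit variance for any theta", {
  set.seed(106)
  tab <- simulate_benchmark(10, 2e4)
  z1 <- as.numeric(tab$payloads[, , 1L])
  expect_equal(mean(z1), 0, tolerance = 0.01)
  expect_equal(mean(z1^2), 1, tolerance = 0.01)   # unit-variance mixture
  expect_equal(mean(z1^3), 0, tolerance = 0.05)   # odd moments vanish
  # conditional on theta near zero the column is standard normal
  sub <- abs(tab$params[, 1L]) < 0.05
  expect_equal(var(as.numeric(tab$payloads[sub, , 1L])), 1,
               tolerance = 0.05)
  # distractor column is standard normal independent of theta
  z2 <- rowMeans(tab$payloads[, , 2L])
  expect_lt(abs(cor(z2, tab$params[, 1L])), 0.03)
})

test_that("benchmark candidate moments match hand computations", {
  z <- matrix(1, 5, 2)
  expect_equal(benchmark_candidate_summaries(z), rep(1, 6))
  expect_equal(benchmark_candidate_summaries(matrix(0, 3, 2)), rep(0, 6))
  z <- cbind(c(1, -1), c(2, 0))
  expect_equal(benchmark_candidate_summaries(z),
               c(1, 1, 1, 2, 8, 32))
  expect_error(benchmark_candidate_summaries(matrix(0, 3, 3)),
               "two columns")
  # table-level helper agrees with the single-payload version
  set.seed(107)
  tab <- simulate_benchmark(10, 20)
  cand <- candidate_summaries(tab)$summaries
  expect_equal(cand[3L, ],
               benchmark_candidate_summaries(get_payload(tab, 3L)),
               ignore_attr = TRUE)
})

test_that("tree simulator produces valid trees with the stated kernel", {
  set.seed(108)
  tr <- simulate_tree(0.5, 2)
  expect_equal(tr$edges, matrix(c(0L, 1L), 1L)) # only possible attachment
  tr <- simulate_tree(1, 200)
  expect_equal(nrow(tr$edges), 199L)
  expect_equal(sum(tree_degrees(tr)), 2L * 199L)
  expect_silent(grown_tree(tr$n_nodes, tr$edges)) # connected and acyclic
  expect_error(simulate_tree(1, 1), ">= 2")
  expect_error(grown_tree(4, rbind(c(0, 1), c(0, 1), c(2, 3))), "cycle")

  # theta = 0: uniform attachment (random recursive tree); for n = 3 the
  # third node picks each existing node with probability 1/2
  set.seed(109)
  first <- vapply(1:400, function(i) simulate_tree(0, 3)$edges[2L, 1L],
                  integer(1L))
  expect_equal(mean(first == 0L), 0.5, tolerance = 0.07)

  # strongly superlinear attachment collapses to a star
  set.seed(110)
  stars <- vapply(1:200, function(i) {
    max(tree_degrees(simulate_tree(10, 100))) == 99L
  }, logical(1L))
  expect_gte(mean(stars), 0.95)
})

test_that("graph candidate summaries match hand computations", {
  # path 0-1-2-3: degrees (1, 2, 2, 1)
  path <- grown_tree(4, rbind(c(0, 1), c(1, 2), c(2, 3)))
  s <- tree_candidate_summaries(path)
  expect_equal(s[["degree_sd"]], 0.5)
  expect_equal(s[["degree_gini"]], 1 / 6) # sum |k_i - k_j| / (2 n^2 kbar)
  expect_equal(s[["diameter"]], 3)
  # star: degrees (3, 1, 1, 1); 3 leaf pairs route through the center
  star <- grown_tree(4, rbind(c(0, 1), c(0, 2), c(0, 3)))
  s <- tree_candidate_summaries(star)
  expect_equal(s[["degree_sd"]], sqrt(0.75))
  expect_equal(s[["diameter"]], 2)
  expect_equal(s[["max_betweenness"]], 3)
  expect_error(tree_candidate_summaries(list(edges = 1)), "grown_tree")
})

test_that("simulators are reproducible under a fixed seed", {
  set.seed(42)
  a <- simulate_benchmark(10, 50)
  set.seed(42)
  b <- simulate_benchmark(10, 50)
  expect_identical(a, b)
  set.seed(42)
  ta <- simulate_tree_table(30, 20)
  set.seed(42)
  tb <- simulate_tree_table(30, 20)
  expect_identical(ta, tb)
})

test_that("tree tables carry resampled uniform distractors", {
  set.seed(111)
  tab <- simulate_tree_table(20, 50)
  tab <- candidate_summaries(tab)
  expect_equal(colnames(tab$summaries)[5L], "distractor")
  expect_true(all(tab$summaries[, 5L] >= 0 & tab$summaries[, 5L] <= 1))
  expect_gt(length(unique(tab$summaries[, 5L])), 45L)
})
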