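# Config-driven reproductions of the toy quantities and the benchmark /
# growing-tree method comparisons.

#' Gamma-toy information quantities
#'
#' Computes the closed-form and Monte Carlo quantities of the conjugate
#' gamma toy model: the prior entropy, the conditional posterior entropy
#' (CPE) at a reference second moment, the Monte Carlo expected posterior
#' entropy (EPE) of the sufficient statistic under the prior predictive,
#' and the fraction of prior-predictive draws whose CPE exceeds the prior
#' entropy (the failure mode of per-dataset entropy minimization: such
#' draws would discard the sufficient statistic).
#'
#' @param a,b gamma prior shape and rate.
#' @param n observations per draw.
#' @param m Monte Carlo draws.
#' @param t_ref second moment at which the example CPE is reported.
#' @return List with `prior_entropy`, `cpe_at_ref`, `epe`,
#'   `frac_cpe_increase`, and the posterior parameters at `t_ref`.
#' @export
run_gamma_toy <- function(a = 1.5, b = 1, n = 4L, m = 1e5L, t_ref = 0.3) {
  prior_entropy <- gamma_entropy(a, b)
  post_ref <- gamma_posterior(a, b, n, t_ref)
  cpe_at_ref <- gamma_entropy(post_ref$shape, post_ref$rate)
  tab <- simulate_gamma_toy(a, b, n, m)
  t <- tab$summaries[, 1L]
  shape_post <- a + n / 2
  rate_post <- b + n * t / 2
  epe <- epe_estimate(function(theta, tt) {
    dgamma(theta[, 1L], shape = a + n / 2, rate = b + n * tt[, 1L] / 2,
           log = TRUE)
  }, tab$params, tab$summaries, vectorized = TRUE)
  frac <- mean(gamma_entropy(shape_post, rate_post) > prior_entropy)
  list(prior_entropy = prior_entropy, cpe_at_ref = cpe_at_ref,
       posterior_at_ref = post_ref, epe = epe$value,
       frac_cpe_increase = frac, m = m)
}

#' Prior-dependence of optimal summaries in the piecewise model
#'
#' Estimates the mutual information between the parameter and each of two
#' candidate summaries (sample mean, log sample variance) under two normal
#' priors centred at -1 and +1, reproducing the observation that the
#' informative summary depends on where the prior puts its mass.
#'
#' @param m draws per prior.
#' @param n observations per draw.
#' @param prior_sd common prior standard deviation.
#' @param k_nn neighbor order for the MI estimator.
#' @return 2 x 2 matrix of MI estimates (rows: prior centre -1, +1;
#'   columns: sample mean, log variance).
#' @export
run_piecewise <- function(m = 1e5L, n = 100L, prior_sd = 0.25, k_nn = 4L) {
  out <- matrix(0, 2L, 2L,
                dimnames = list(c("centre_-1", "centre_+1"),
                                c("mean", "log_var")))
  for (i in 1:2) {
    centre <- c(-1, 1)[i]
    tab <- simulate_piecewise(centre, prior_sd, n, m)
    y <- tab$payloads[, , 1L]
    ybar <- rowMeans(y)
    logvar <- log(rowMeans((y - ybar)^2) * n / (n - 1))
    out[i, 1L] <- knn_mutual_information(tab$params, ybar, k = k_nn)$value
    out[i, 2L] <- knn_mutual_information(tab$params, logvar, k = k_nn)$value
  }
  out
}

# nlp/rmise over a list of per-example posterior samples
.score_samples <- function(samples_list, theta_true, lo = NULL, hi = NULL) {
  nlp <- vapply(seq_along(samples_list), function(i)
    nlp_kde(samples_list[[i]], theta_true[i, ], lo = lo, hi = hi),
    numeric(1L))
  rms <- vapply(seq_along(samples_list), function(i)
    rmise(samples_list[[i]], theta_true[i, ]), numeric(1L))
  list(nlp = nlp, rmise = rms)
}

# ABC for every test example given train/test summary matrices
.abc_all <- function(train_summaries, params, test_summaries, s) {
  moments <- summary_moments(train_summaries)
  lapply(seq_len(nrow(test_summaries)), function(i)
    rejection_sample(test_summaries[i, ], train_summaries, s,
                     moments = moments, params = params))
}

.scale_sizes <- function(scale, train_m, val_m, test_m, s) {
  list(train_m = max(1000L, ceiling(train_m * scale)),
       val_m = max(200L, ceiling(val_m * scale)),
       test_m = max(50L, ceiling(test_m * scale)),
       s = max(50L, ceiling(s * scale)))
}

#' Method comparison on the tanh-mixture benchmark
#'
#' Generates training, validation, and test reference tables from the
#' benchmark model, extracts summaries with each requested method, runs
#' rejection ABC (1,000 accepted samples by default) for every test
#' example, and reports the test-set mean negative log probability and
#' RMISE per method. The likelihood-based gold standard is obtained by
#' deterministic quadrature ([benchmark_true_posterior()]).
#'
#' @param train_m,val_m,test_m table sizes (defaults: full study sizes).
#' @param n observations per payload.
#' @param s accepted ABC samples (and posterior draws) per test example.
#' @param methods subset of `"quadrature"`, `"expert"`, `"mdn_compression"`,
#'   `"mdn_direct"`, `"nonlinear_regression"`, `"linear_regression"`,
#'   `"min_cpe"`, `"pls"`, `"prior"`.
#' @param control [train_control()] for the neural methods.
#' @param mdn_k Gaussian mixture components of the MDN head.
#' @param k_nn neighbor order for entropy-based selection.
#' @param scale optional global scale factor applied to all sizes and `s`.
#' @param verbose print progress messages?
#' @return List with `report` (a [metric_report()] `data.frame`), the
#'   fitted models in `fits`, and the per-method per-example metric values
#'   in `values`.
#' @export
run_benchmark <- function(train_m = 1e6L, val_m = 1e4L, test_m = 1e3L,
                          n = 10L, s = 1000L,
                          methods = c("quadrature", "expert",
                                      "mdn_compression", "mdn_direct",
                                      "nonlinear_regression",
                                      "linear_regression", "min_cpe",
                                      "pls", "prior"),
                          control = train_control(batch_size = 512L),
                          mdn_k = 2L, k_nn = 4L, scale = NULL,
                          verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is.null(scale)) {
    sz <- .scale_sizes(scale, train_m, val_m, test_m, s)
    train_m <- sz$train_m; val_m <- sz$val_m; test_m <- sz$test_m; s <- sz$s
  }
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating benchmark tables (m = %d / %d / %d)", train_m, val_m,
      test_m)
  train <- simulate_benchmark(n, train_m)
  val <- simulate_benchmark(n, val_m, split = "validation")
  test <- simulate_benchmark(n, test_m, split = "test")
  theta_test <- test$params
  need_cand <- any(methods %in% c("expert", "linear_regression", "min_cpe",
                                  "pls"))
  if (need_cand) {
    ctrain <- candidate_summaries(train)$summaries
    ctest <- candidate_summaries(test)$summaries
  }
  fits <- list()
  values <- list()
  rows <- list()
  add <- function(method, samples_list) {
    sc <- .score_samples(samples_list, theta_test)
    values[[method]] <<- sc
    rows[[method]] <<- metric_report(method, "benchmark", sc$nlp, sc$rmise)
  }
  if ("prior" %in% methods) {
    say("prior baseline")
    add("prior", lapply(seq_len(test_m), function(i)
      matrix(rnorm(s), ncol = 1L)))
  }
  if ("quadrature" %in% methods) {
    say("quadrature gold standard")
    add("quadrature", lapply(seq_len(test_m), function(i)
      grid_posterior_sample(benchmark_true_posterior(get_payload(test, i)),
                            s)))
  }
  if ("expert" %in% methods) {
    say("expert candidate summaries")
    add("expert", .abc_all(ctrain, train$params, ctest, s))
  }
  if ("linear_regression" %in% methods) {
    say("linear posterior-mean regression")
    fits$linear <- fit_linear_posterior_mean(ctrain, train$params)
    add("linear_regression",
        .abc_all(predict(fits$linear, ctrain), train$params,
                 predict(fits$linear, ctest), s))
  }
  if ("pls" %in% methods) {
    say("partial least squares")
    fits$pls <- fit_pls(ctrain, train$params)
    add("pls", .abc_all(predict(fits$pls, ctrain), train$params,
                        predict(fits$pls, ctest), s))
  }
  if ("min_cpe" %in% methods) {
    say("greedy minimum-CPE selection (per test example)")
    moments <- summary_moments(ctrain)
    add("min_cpe", lapply(seq_len(test_m), function(i) {
      sel <- min_cpe_select(ctest[i, ], train, s, k_nn = k_nn,
                            moments = moments)
      if (!length(sel$selected))
        return(matrix(rnorm(s), ncol = 1L)) # empty set: posterior = prior
      sub_m <- structure(list(mean = moments$mean[sel$selected],
                              sd = moments$sd[sel$selected]),
                         class = "summary_moments")
      rejection_sample(ctest[i, sel$selected],
                       ctrain[, sel$selected, drop = FALSE], s,
                       moments = sub_m, params = train$params)
    }))
  }
  if ("nonlinear_regression" %in% methods) {
    say("nonlinear posterior-mean network")
    fits$nonlinear <- fit_posterior_mean_net(train, val, control = control)
    add("nonlinear_regression",
        .abc_all(extract_summaries(fits$nonlinear, train), train$params,
                 extract_summaries(fits$nonlinear, test), s))
  }
  if (any(methods %in% c("mdn_compression", "mdn_direct"))) {
    say("MDN compression (EPE training)")
    fits$mdn <- fit_mdn_compressor(train, val,
                                   mdn = mdn_config("gaussian", k = mdn_k),
                                   control = control)
    t_train <- extract_summaries(fits$mdn, train)
    t_test <- extract_summaries(fits$mdn, test)
    if ("mdn_compression" %in% methods)
      add("mdn_compression", .abc_all(t_train, train$params, t_test, s))
    if ("mdn_direct" %in% methods) {
      mix <- predict(fits$mdn, t_test, from = "summaries", type = "mixture")
      add("mdn_direct", lapply(mix, mdn_sample, s = s))
    }
  }
  report <- do.call(rbind, rows[intersect(methods, names(rows))])
  class(report) <- c("metric_report", "data.frame")
  list(report = report, fits = fits, values = values,
       sizes = c(train_m = train_m, val_m = val_m, test_m = test_m, s = s))
}

#' Method comparison on the growing-tree model
#'
#' As [run_benchmark()] but for the preferential-attachment tree model:
#' `Uniform(0, 2)` prior on the attachment exponent, GIN compressor for
#' the neural methods, hand-crafted graph statistics plus a uniform
#' distractor as candidates, and NLP evaluated with boundary reflection at
#' the prior bounds. No likelihood-based row is produced (the likelihood
#' is intractable).
#'
#' @inheritParams run_benchmark
#' @param n_nodes nodes per simulated tree.
#' @param prior_lo,prior_hi uniform prior bounds.
#' @return As [run_benchmark()].
#' @export
run_growing_tree <- function(train_m = 1e5L, val_m = 1e3L, test_m = 1e3L,
                             n_nodes = 100L, s = 1000L,
                             methods = c("expert", "mdn_compression",
                                         "mdn_direct",
                                         "nonlinear_regression",
                                         "linear_regression", "min_cpe",
                                         "pls", "prior"),
                             control = train_control(batch_size = 32L),
                             mdn_k = 10L, k_nn = 4L, prior_lo = 0,
                             prior_hi = 2, scale = NULL, verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is.null(scale)) {
    sz <- .scale_sizes(scale, train_m, val_m, test_m, s)
    train_m <- sz$train_m; val_m <- sz$val_m; test_m <- sz$test_m; s <- sz$s
  }
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating trees (m = %d / %d / %d, n = %d nodes)", train_m, val_m,
      test_m, n_nodes)
  train <- simulate_tree_table(n_nodes, train_m, prior_lo, prior_hi)
  val <- simulate_tree_table(n_nodes, val_m, prior_lo, prior_hi,
                             split = "validation")
  test <- simulate_tree_table(n_nodes, test_m, prior_lo, prior_hi,
                              split = "test")
  theta_test <- test$params
  need_cand <- any(methods %in% c("expert", "linear_regression", "min_cpe",
                                  "pls"))
  if (need_cand) {
    say("computing graph candidate summaries")
    train <- candidate_summaries(train)
    ctrain <- train$summaries
    ctest <- candidate_summaries(test)$summaries
  }
  fits <- list(); values <- list(); rows <- list()
  add <- function(method, samples_list) {
    sc <- .score_samples(samples_list, theta_test, lo = prior_lo,
                         hi = prior_hi)
    values[[method]] <<- sc
    rows[[method]] <<- metric_report(method, "growing_tree", sc$nlp,
                                     sc$rmise)
  }
  if ("prior" %in% methods) {
    say("prior baseline")
    add("prior", lapply(seq_len(test_m), function(i)
      matrix(runif(s, prior_lo, prior_hi), ncol = 1L)))
  }
  if ("expert" %in% methods) {
    say("expert candidate summaries")
    add("expert", .abc_all(ctrain, train$params, ctest, s))
  }
  if ("linear_regression" %in% methods) {
    say("linear posterior-mean regression")
    fits$linear <- fit_linear_posterior_mean(ctrain, train$params)
    add("linear_regression",
        .abc_all(predict(fits$linear, ctrain), train$params,
                 predict(fits$linear, ctest), s))
  }
  if ("pls" %in% methods) {
    say("partial least squares")
    fits$pls <- fit_pls(ctrain, train$params)
    add("pls", .abc_all(predict(fits$pls, ctrain), train$params,
                        predict(fits$pls, ctest), s))
  }
  if ("min_cpe" %in% methods) {
    say("greedy minimum-CPE selection (per test example)")
    moments <- summary_moments(ctrain)
    add("min_cpe", lapply(seq_len(test_m), function(i) {
      sel <- min_cpe_select(ctest[i, ], train, s, k_nn = k_nn,
                            moments = moments)
      if (!length(sel$selected))
        return(matrix(runif(s, prior_lo, prior_hi), ncol = 1L))
      sub_m <- structure(list(mean = moments$mean[sel$selected],
                              sd = moments$sd[sel$selected]),
                         class = "summary_moments")
      rejection_sample(ctest[i, sel$selected],
                       ctrain[, sel$selected, drop = FALSE], s,
                       moments = sub_m, params = train$params)
    }))
  }
  if ("nonlinear_regression" %in% methods) {
    say("nonlinear posterior-mean network (GIN)")
    fits$nonlinear <- fit_posterior_mean_net(train, val, control = control)
    add("nonlinear_regression",
        .abc_all(extract_summaries(fits$nonlinear, train), train$params,
                 extract_summaries(fits$nonlinear, test), s))
  }
  if (any(methods %in% c("mdn_compression", "mdn_direct"))) {
    say("MDN compression (EPE training, GIN)")
    fits$mdn <- fit_mdn_compressor(train, val,
                                   mdn = mdn_config("gaussian", k = mdn_k),
                                   control = control)
    t_train <- extract_summaries(fits$mdn, train)
    t_test <- extract_summaries(fits$mdn, test)
    if ("mdn_compression" %in% methods)
      add("mdn_compression", .abc_all(t_train, train$params, t_test, s))
    if ("mdn_direct" %in% methods) {
      mix <- predict(fits$mdn, t_test, from = "summaries", type = "mixture")
      add("mdn_direct", lapply(mix, function(mp) {
        draws <- mdn_sample(mp, s)
        # clamp to the prior support: the Gaussian head has unbounded tails
        matrix(pmin(pmax(draws, prior_lo + 1e-9), prior_hi - 1e-9),
               ncol = 1L)
      }))
    }
  }
  report <- do.call(rbind, rows[intersect(methods, names(rows))])
  class(report) <- c("metric_report", "data.frame")
  list(report = report, fits = fits, values = values,
       sizes = c(train_m = train_m, val_m = val_m, test_m = test_m, s = s))
}

#' Read an externally produced candidate-summary table
#'
#' Ingests a CSV of prior draws with pre-computed candidate summaries in
#' the coalescent-study layout: a header row, two parameter columns
#' (mutation and recombination rates, `Uniform(0, 10)` prior), then seven
#' candidate-summary columns (six expert statistics and one uniform
#' distractor). The summaries are both the payload and the candidate block
#' of the resulting table, enabling the tabular-MLP methods to run on
#' externally supplied data.
#'
#' @param path CSV file path.
#' @param n_params number of leading parameter columns.
#' @param n_candidates number of candidate-summary columns.
#' @param split split label.
#' @return A vector-payload [reference_table()].
#' @export
load_candidate_summary_table <- function(path, n_params = 2L,
                                         n_candidates = 7L,
                                         split = "train") {
  df <- read.csv(path, check.names = FALSE)
  expected <- n_params + n_candidates
  if (ncol(df) != expected)
    .stopf("expected %d columns (%d parameters + %d candidates), found %d: %s",
           expected, n_params, n_candidates, ncol(df),
           paste(colnames(df), collapse = ", "))
  params <- as.matrix(df[, seq_len(n_params), drop = FALSE])
  cand <- as.matrix(df[, n_params + seq_len(n_candidates), drop = FALSE])
  if (any(params < 0 | params > 10))
    warning("parameters outside [0, 10] found; prior support may differ",
            call. = FALSE)
  reference_table(params, cand, summaries = cand, split = split,
                  model = "candidate_table")
}

#' Write a candidate-summary table as CSV
#'
#' Inverse of [load_candidate_summary_table()]; round-trips a
#' vector-payload table.
#'
#' @param table a vector-payload [reference_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_candidate_summary_table <- function(table, path) {
  if (payload_kind(table) != "vector")
    .stopf("only vector-payload tables can be written in this layout")
  p <- ncol(table$params)
  df <- data.frame(table$params, table$payloads, check.names = FALSE)
  colnames(df) <- c(colnames(table$params) %||%
                      paste0("theta", seq_len(p)),
                    colnames(table$payloads) %||%
                      paste0("s", seq_len(ncol(table$payloads))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a tree as an edge-list CSV
#'
#' Two integer columns with header `source,target`, 0-based node indices.
#'
#' @param tree a [grown_tree()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tree_csv <- function(tree, path) {
  df <- data.frame(source = tree$edges[, 1L], target = tree$edges[, 2L])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a tree from an edge-list CSV
#'
#' @param path CSV with `source,target` header and 0-based indices.
#' @return A [grown_tree()].
#' @export
read_tree_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("source", "target") %in% colnames(df)))
    .stopf("edge-list CSV needs `source` and `target` columns")
  edges <- cbind(df$source, df$target)
  grown_tree(max(edges) + 1L, edges)
}
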