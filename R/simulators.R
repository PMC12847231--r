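#' Conjugate gamma-normal toy model
#'
#' Draws `m` joint samples from the conjugate toy model in which a precision
#' \eqn{\theta \sim \mathrm{Gamma}(a, b)} and observations
#' \eqn{y_i \mid \theta \sim \mathrm{Normal}(0, \theta^{-1})},
#' \eqn{i = 1, \dots, n}. The second moment
#' \eqn{t = n^{-1} \sum_i y_i^2} is a sufficient statistic and is stored in
#' the summaries block.
#'
#' @param a,b gamma prior shape and rate (both positive).
#' @param n number of observations per draw.
#' @param m number of prior-predictive draws.
#' @param split split label for the resulting table.
#' @return A [reference_table()] with `m x 1` params, `m x n x 1` payloads,
#'   and the second moment as a single summary column.
#' @examples
#' set.seed(1)
#' tab <- simulate_gamma_toy(a = 1.5, b = 1, n = 4, m = 100)
#' mean(tab$params) # close to a / b = 1.5
#' @export
simulate_gamma_toy <- function(a, b, n, m, split = "train") {
  .check_positive(a, "a"); .check_positive(b, "b")
  n <- .check_count(n, "n"); m <- .check_count(m, "m")
  theta <- rgamma(m, shape = a, rate = b)
  y <- matrix(rnorm(m * n, sd = rep(1 / sqrt(theta), n)), nrow = m)
  t <- rowMeans(y^2)
  reference_table(theta, array(y, dim = c(m, n, 1L)), summaries = t,
                  split = split, model = "gamma_toy")
}

#' Second moment of a sample
#'
#' Computes \eqn{t = n^{-1} \sum_{i=1}^n y_i^2}, the sufficient statistic of
#' the zero-mean normal likelihood with unknown precision.
#'
#' @param y numeric vector or single-column matrix of observations.
#' @return Non-negative scalar.
#' @export
second_moment <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 1L) .stopf("`y` must contain at least one observation")
  mean(y^2)
}

#' Closed-form posterior of the gamma toy model
#'
#' The conjugate update: given `n` observations with second moment `t`, the
#' posterior of the precision is
#' \eqn{\mathrm{Gamma}(a + n/2,\; b + n t / 2)}.
#'
#' @param a,b prior shape and rate.
#' @param n number of observations (may be zero).
#' @param t second moment of the observations (non-negative).
#' @return List with elements `shape` and `rate`.
#' @examples
#' gamma_posterior(1.5, 1, 4, 0.3) # shape 3.5, rate 1.6
#' @export
gamma_posterior <- function(a, b, n, t) {
  .check_positive(a, "a"); .check_positive(b, "b")
  n <- .check_count(n, "n", min = 0L)
  if (!is.numeric(t) || any(t < 0)) .stopf("`t` must be non-negative")
  list(shape = a + n / 2, rate = b + n * t / 2)
}

#' Reflected-gamma toy model
#'
#' Variant of [simulate_gamma_toy()] in which the precision is
#' \eqn{|\theta|} with \eqn{|\theta| \sim \mathrm{Gamma}(a, b)} and the sign
#' of \eqn{\theta} is Rademacher(1/2), independent of the magnitude. The
#' model is non-identifiable: the posterior of \eqn{\theta} is bimodal and
#' symmetric about zero, so its mean carries no information.
#'
#' @inheritParams simulate_gamma_toy
#' @return A [reference_table()]; summaries hold the second moment, which is
#'   sufficient for \eqn{|\theta|} but not for the sign.
#' @export
simulate_reflected_gamma_toy <- function(a, b, n, m, split = "train") {
  tab <- simulate_gamma_toy(a, b, n, m, split = split)
  sign <- sample(c(-1, 1), n_draws(tab), replace = TRUE)
  tab$params <- tab$params * sign
  tab$model <- "reflected_gamma_toy"
  tab
}

#' Piecewise-likelihood model
#'
#' Simulates from the model with qualitatively different behaviour on either
#' side of \eqn{\theta = 0}:
#' \deqn{y_i \mid \theta \sim \mathrm{Normal}(0, e^\theta) \text{ if } \theta < 0,
#'       \quad y_i \mid \theta \sim \mathrm{Normal}(\theta, 1) \text{ if } \theta \ge 0,}
#' where the second argument is the variance; the likelihood is continuous
#' at the transition. The log sample variance is informative for negative
#' parameters and the sample mean for positive ones, so the optimal summary
#' depends on where the prior puts its mass.
#'
#' @param prior_mean,prior_sd normal prior location and standard deviation.
#' @param n observations per draw.
#' @param m number of draws.
#' @param split split label.
#' @return A [reference_table()] with `m x n x 1` payloads and no summaries.
#' @export
simulate_piecewise <- function(prior_mean, prior_sd, n, m, split = "train") {
  .check_positive(prior_sd, "prior_sd")
  n <- .check_count(n, "n"); m <- .check_count(m, "m")
  theta <- rnorm(m, prior_mean, prior_sd)
  sd_i <- ifelse(theta < 0, exp(theta / 2), 1)
  mean_i <- ifelse(theta < 0, 0, theta)
  y <- matrix(rnorm(m * n, mean = rep(mean_i, n), sd = rep(sd_i, n)),
              nrow = m)
  reference_table(theta, array(y, dim = c(m, n, 1L)), split = split,
                  model = "piecewise")
}

#' Bimodal tanh-mixture benchmark model
#'
#' Simulates the benchmark model designed to defeat moment-based summary
#' selection. A scalar parameter \eqn{\theta \sim \mathrm{Normal}(0, 1)}
#' generates `n` observations
#' \deqn{z_{i1} \mid \theta \sim \tfrac12 \sum_{u \in \{-1, 1\}}
#'   \mathrm{Normal}(u \tanh\theta,\; 1 - \tanh^2\theta),}
#' plus an independent standard-normal distractor column \eqn{z_{i2}}. Every
#' entry of \eqn{z} has zero mean and unit variance regardless of
#' \eqn{\theta}, and the posterior is bimodal in \eqn{\theta}.
#'
#' @param n observations per draw (rows of each payload matrix).
#' @param m number of draws.
#' @param split split label.
#' @return A [reference_table()] with `m x 1` params and `m x n x 2`
#'   payloads.
#' @export
simulate_benchmark <- function(n, m, split = "train") {
  n <- .check_count(n, "n"); m <- .check_count(m, "m")
  theta <- rnorm(m)
  th <- tanh(theta)
  scale <- sqrt(pmax(1 - th^2, 0))
  u <- matrix(sample(c(-1, 1), m * n, replace = TRUE), nrow = m)
  z1 <- u * th + matrix(rnorm(m * n), nrow = m) * scale
  z2 <- matrix(rnorm(m * n), nrow = m)
  payload <- array(c(z1, z2), dim = c(m, n, 2L))
  reference_table(theta, payload, split = split, model = "benchmark")
}

#' Candidate moment summaries for the benchmark model
#'
#' The first three even raw moments of each column of `z`:
#' \eqn{m_k = n^{-1} \sum_i z_i^k} for \eqn{k \in \{2, 4, 6\}}, column 1
#' first. Odd moments are uninformative because the likelihood is symmetric.
#'
#' @param z numeric `n x 2` matrix (one benchmark payload).
#' @return Length-6 numeric vector
#'   `(m2, m4, m6)` of column 1 followed by column 2.
#' @export
benchmark_candidate_summaries <- function(z) {
  if (!is.matrix(z) || ncol(z) != 2L)
    .stopf("`z` must be a matrix with two columns")
  c(mean(z[, 1L]^2), mean(z[, 1L]^4), mean(z[, 1L]^6),
    mean(z[, 2L]^2), mean(z[, 2L]^4), mean(z[, 2L]^6))
}

.benchmark_candidates_table <- function(table) {
  z <- table$payloads
  m2 <- function(x, k) rowMeans(x^k)
  cbind(m2(z[, , 1L], 2), m2(z[, , 1L], 4), m2(z[, , 1L], 6),
        m2(z[, , 2L], 2), m2(z[, , 2L], 4), m2(z[, , 2L], 6))
}

#' Undirected tree objects
#'
#' Constructs a tree on `n_nodes` nodes from an edge list. Node indices are
#' 0-based; a valid tree has exactly `n_nodes - 1` edges and is connected
#' and acyclic.
#'
#' @param n_nodes number of nodes.
#' @param edges integer `(n_nodes - 1) x 2` matrix of 0-based node pairs.
#' @param validate check connectivity/acyclicity (linear-time union-find)?
#' @return An object of class `"grown_tree"`.
#' @export
grown_tree <- function(n_nodes, edges, validate = TRUE) {
  n_nodes <- .check_count(n_nodes, "n_nodes", min = 1L)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) != n_nodes - 1L)
    .stopf("a tree on %d nodes must have %d edges, got %d",
           n_nodes, n_nodes - 1L, nrow(edges))
  if (nrow(edges) && (min(edges) < 0L || max(edges) >= n_nodes))
    .stopf("edge indices must lie in [0, n_nodes)")
  if (validate && nrow(edges)) {
    parent <- seq_len(n_nodes)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1L] + 1L); b <- find(edges[e, 2L] + 1L)
      if (a == b) .stopf("edge list contains a cycle")
      parent[a] <- b
    }
  }
  structure(list(n_nodes = n_nodes, edges = edges), class = "grown_tree")
}

#' @export
print.grown_tree <- function(x, ...) {
  cat(sprintf("Tree with %d nodes, %d edges; max degree %d\n",
              x$n_nodes, nrow(x$edges), max(tree_degrees(x))))
  invisible(x)
}

#' Node degrees of a tree
#' @param tree a [grown_tree()].
#' @return Integer vector of node degrees (0-based node order).
#' @export
tree_degrees <- function(tree) {
  tabulate(as.integer(tree$edges) + 1L, nbins = tree$n_nodes)
}

#' Preferential-attachment growing-tree simulator
#'
#' Grows a tree from a single isolated node. At each step a new node `j`
#' attaches to an existing node `i` with probability proportional to
#' \eqn{k_i^\theta}, where \eqn{k_i} is the current degree of node `i`. The
#' second node attaches deterministically to the first (whose degree is
#' still zero, so the kernel is applied only from step three onward).
#' \eqn{\theta = 0} gives a random recursive tree; large \eqn{\theta > 1}
#' produces star-like hubs.
#'
#' @param theta attachment kernel exponent.
#' @param n_nodes number of nodes (at least 2).
#' @return A [grown_tree()].
#' @export
simulate_tree <- function(theta, n_nodes) {
  n_nodes <- .check_count(n_nodes, "n_nodes", min = 2L)
  edges <- matrix(0L, nrow = n_nodes - 1L, ncol = 2L)
  edges[1L, ] <- c(0L, 1L)
  if (n_nodes > 2L) {
    deg <- integer(n_nodes)
    deg[1:2] <- 1L
    for (j in 3:n_nodes) {
      w <- deg[seq_len(j - 1L)]^theta
      target <- sample.int(j - 1L, 1L, prob = w)
      edges[j - 1L, ] <- c(target - 1L, j - 1L)
      deg[target] <- deg[target] + 1L
      deg[j] <- 1L
    }
  }
  grown_tree(n_nodes, edges, validate = FALSE)
}

#' Reference table of growing trees
#'
#' Draws `m` attachment exponents from a `Uniform(lo, hi)` prior and grows
#' one tree of `n_nodes` nodes per draw.
#'
#' @param n_nodes nodes per tree.
#' @param m number of draws.
#' @param prior_lo,prior_hi uniform prior bounds for the exponent.
#' @param split split label.
#' @return A [reference_table()] with tree payloads.
#' @export
simulate_tree_table <- function(n_nodes, m, prior_lo = 0, prior_hi = 2,
                                split = "train") {
  m <- .check_count(m, "m")
  if (prior_lo >= prior_hi) .stopf("`prior_lo` must be below `prior_hi`")
  theta <- runif(m, prior_lo, prior_hi)
  trees <- lapply(theta, simulate_tree, n_nodes = n_nodes)
  reference_table(theta, trees, split = split, model = "growing_tree")
}

#' Hand-crafted candidate summaries of a tree
#'
#' Computes the four graph statistics used as candidate summaries for the
#' growing-tree model: the standard deviation (population normalization) and
#' Gini coefficient of the degree distribution, the diameter in edges, and
#' the maximum betweenness centrality (unnormalized shortest-path pair
#' counts). A uniform distractor is appended separately by table-level
#' helpers, not here.
#'
#' @param tree a [grown_tree()].
#' @return Named length-4 numeric vector
#'   `(degree_sd, degree_gini, diameter, max_betweenness)`.
#' @export
tree_candidate_summaries <- function(tree) {
  if (!inherits(tree, "grown_tree")) .stopf("`tree` must be a grown_tree")
  deg <- tree_degrees(tree)
  n <- tree$n_nodes
  deg_sd <- sqrt(mean((deg - mean(deg))^2))
  gini <- mean(abs(outer(deg, deg, "-"))) / (2 * mean(deg))
  g <- igraph::graph_from_edgelist(tree$edges + 1L, directed = FALSE)
  diam <- igraph::diameter(g, unconnected = FALSE)
  btw <- max(igraph::betweenness(g, directed = FALSE, normalized = FALSE))
  c(degree_sd = deg_sd, degree_gini = gini, diameter = diam,
    max_betweenness = btw)
}

#' Candidate summaries for a whole table
#'
#' Fills (and returns) the `summaries` block of a reference table with the
#' model's hand-crafted candidate statistics: the six even moments for
#' benchmark payloads ([benchmark_candidate_summaries()]) or the four graph
#' statistics plus, optionally, one `Uniform(0, 1)` distractor resampled per
#' element for tree payloads ([tree_candidate_summaries()]). Vector payloads
#' are themselves the candidates and are copied unchanged.
#'
#' @param table a [reference_table()].
#' @param distractor append a uniform distractor column (trees only)?
#' @return The table with its `summaries` block set; columns are named.
#' @export
candidate_summaries <- function(table, distractor = payload_kind(table) == "tree") {
  kind <- payload_kind(table)
  s <- switch(kind,
    matrix = {
      if (dim(table$payloads)[3L] != 2L)
        .stopf("moment candidates are defined for two-column payloads")
      s <- .benchmark_candidates_table(table)
      colnames(s) <- c("m2_1", "m4_1", "m6_1", "m2_2", "m4_2", "m6_2")
      s
    },
    vector = table$payloads,
    tree = {
      s <- t(vapply(table$payloads, tree_candidate_summaries, numeric(4L)))
      if (distractor) s <- cbind(s, distractor = runif(nrow(s)))
      s
    }
  )
  table$summaries <- s
  table
}
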