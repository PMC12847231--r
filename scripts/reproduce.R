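#!/usr/bin/env Rscript
# Thin command-line wrapper over the epeabc experiment runners.
# Example:
#   Rscript scripts/reproduce.R --experiment benchmark --scale 0.1 --seed 1 \
#     --out results/benchmark.csv

suppressPackageStartupMessages({
  library(optparse)
  library(epeabc)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--experiment", type = "character",
              help = "one of gamma_toy, piecewise, benchmark, growing_tree"),
  make_option("--scale", type = "double", default = 1,
              help = "global scale factor for table sizes [default %default]"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--methods", type = "character", default = NULL,
              help = "comma-separated method subset (benchmark/growing_tree)"),
  make_option("--out", type = "character", default = NULL,
              help = "output CSV path (metric report or toy quantities)")
)))

if (is.null(opts$experiment))
  stop("--experiment is required", call. = FALSE)
set.seed(opts$seed)
methods <- if (!is.null(opts$methods))
  strsplit(opts$methods, ",")[[1L]]

out <- switch(opts$experiment,
  gamma_toy = {
    r <- run_gamma_toy(m = max(1000L, ceiling(1e5 * opts$scale)))
    data.frame(quantity = c("prior_entropy", "cpe_at_ref", "epe",
                            "frac_cpe_increase"),
               value = c(r$prior_entropy, r$cpe_at_ref, r$epe,
                         r$frac_cpe_increase))
  },
  piecewise = {
    mi <- run_piecewise(m = max(1000L, ceiling(1e5 * opts$scale)))
    data.frame(prior_centre = rep(rownames(mi), each = 2L),
               summary = rep(colnames(mi), 2L),
               mi = as.numeric(t(mi)))
  },
  benchmark = {
    a <- list(scale = opts$scale, verbose = TRUE)
    if (!is.null(methods)) a$methods <- methods
    do.call(run_benchmark, a)$report
  },
  growing_tree = {
    a <- list(scale = opts$scale, verbose = TRUE)
    if (!is.null(methods)) a$methods <- methods
    do.call(run_growing_tree, a)$report
  },
  stop("unknown experiment: ", opts$experiment, call. = FALSE)
)

print(out, row.names = FALSE)
if (!is.null(opts$out)) {
  dir.create(dirname(opts$out), showWarnings = FALSE, recursive = TRUE)
  write.csv(out, opts$out, row.names = FALSE)
  message("wrote ", opts$out)
}
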