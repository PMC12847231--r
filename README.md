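# epeabc

Learning low-dimensional summary statistics for approximate Bayesian
computation (ABC) by minimizing expected posterior entropy.

## What it is for

Likelihood-free inference compares observed with simulated data, and in
practice the comparison happens on a handful of summary statistics
`t(y)`. The choice of `t` caps the quality of the resulting posterior:
as the ABC tolerance shrinks, the accepted samples converge to the
*summary* posterior `f(θ | t(y))`, not the true posterior `f(θ | y)`.
`epeabc` is for statisticians and modellers who need informative
summaries for simulator-based models — i.i.d. samples, tables of
candidate statistics, or networks — and want a principled, automatic way
to obtain them, together with the classical baselines to compare
against.

## The objective

The package is organised around the expected posterior entropy (EPE)

    𝓗 = − ∫ dt dθ p(t, θ) log f(θ | t),

the prior-predictive average entropy of the summary posterior.
Minimizing 𝓗 over compressors t is equivalent to maximizing the mutual
information I{θ, t} and to minimizing the expected KL divergence from
the summary posterior to the true posterior, and it has a direct Monte
Carlo estimate from joint prior-predictive draws:

    𝓗̂ = − m⁻¹ Σᵢ log f̂(θᵢ | t(zᵢ)),

the usual conditional-density-estimation loss. `fit_mdn_compressor()`
trains a bottlenecked neural compressor (permutation-invariant set MLP,
tabular MLP, or graph isomorphism network, chosen by payload kind)
jointly with a mixture-density-network head on exactly this loss; the
bottleneck outputs are then used as ABC summaries. Baselines implemented
alongside: linear and neural posterior-mean regression (quadratic Bayes
risk), partial least squares scores, greedy minimum-entropy subset
selection over candidate statistics, expert candidates without
selection, and prior sampling. Everything is evaluated with the same
protocol: rejection ABC by accepted count on standardized summaries,
then negative log probability (Gaussian KDE, Scott bandwidth, boundary
reflection for bounded parameters) and RMISE of the true parameter,
averaged over a test set.

## Worked example

The conjugate gamma toy model (precision θ ~ Gamma(1.5, 1), four
zero-mean normal observations) has a closed-form posterior, which makes
the information quantities exact:

```r
library(epeabc)
set.seed(1)

gamma_entropy(1.5, 1)
#> [1] 1.360973
post <- gamma_posterior(1.5, 1, n = 4, t = 0.3)
gamma_entropy(post$shape, post$rate)
#> [1] 1.473078

toy <- run_gamma_toy(m = 1e5)
round(c(epe = toy$epe, frac_cpe_increase = toy$frac_cpe_increase), 3)
#>               epe frac_cpe_increase
#>             0.877             0.306
```

The posterior entropy for the dataset with second moment 0.3 (1.47
nats) *exceeds* the prior entropy (1.36 nats), so minimizing per-dataset
entropy would discard a sufficient statistic — which happens for ~31% of
prior-predictive draws. Averaged over datasets, the sufficient statistic
attains an EPE of 0.88 nats and is correctly preferred.

Learning a summary for the bimodal tanh-mixture benchmark, where every
data entry has zero mean and unit variance regardless of θ:

```r
train <- simulate_benchmark(n = 10, m = 50000)
val <- simulate_benchmark(n = 10, m = 2500, split = "validation")
fit <- fit_mdn_compressor(train, val, control = train_control(max_epochs = 20))
fit
#> EPE-minimizing MDN compression (set_mlp + gaussian mixture, k = 2)
#>   summaries: q = 1; trained 20 epochs; best validation EPE 1.0594 nats

test <- simulate_benchmark(n = 10, m = 200, split = "test")
t_train <- extract_summaries(fit, train)
t_test <- extract_summaries(fit, test)
moments <- summary_moments(t_train)
nlp <- vapply(seq_len(200), function(i) {
  accepted <- rejection_sample(t_test[i, ], t_train, s = 1000,
                               moments = moments, params = train$params)
  nlp_kde(accepted, test$params[i, ])
}, numeric(1))
round(aggregate_metric(nlp), 3)
#>  mean    se
#> 1.049 0.027
```

ABC with the single learned summary matches the exact likelihood-based
posterior computed by quadrature on the same test examples:

```r
gold <- vapply(seq_len(200), function(i) {
  gp <- benchmark_true_posterior(get_payload(test, i))
  nlp_kde(grid_posterior_sample(gp, 1000), test$params[i, ])
}, numeric(1))
round(aggregate_metric(gold), 3)
#>  mean    se
#> 1.047 0.030
```

A mean NLP of about 1.05 nats for both says the learned one-dimensional
summary loses essentially nothing relative to full likelihood-based
inference, while a prior-sample baseline sits at the prior entropy
(≈1.42–1.44). `run_benchmark()` and `run_growing_tree()` run the full
method comparisons; see the vignette in `vignettes/` for the methods and
the design choices.

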