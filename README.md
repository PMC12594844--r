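# biwrss

Estimation for the Marshall–Olkin **b**ivariate **i**nverse **W**eibull
(BIW) distribution under **r**anked **s**et **s**ampling with a
concomitant variable.

## The problem

Paired lifetime-type measurements (component failure times, paired
anthropometric measurements, reliability data) are often dependent and
heavy-tailed, and one member of the pair is frequently much cheaper to
rank than to measure. Ranked set sampling (RSS) exploits that: per cycle,
draw `m²` pairs, split them into `m` judgement sets, rank each set on the
cheap variable `x`, and *measure* only the `i`-th ranked pair of set `i` —
so `n = m·r` measured pairs carry the ordering information of `m²·r`
drawn ones. This package provides the BIW model itself and everything
needed to estimate its parameters from either simple random samples (SRS)
or RSS data, plus a Monte-Carlo engine to quantify what the ranked design
buys.

The model: three independent inverse Weibull shocks
`U_k ~ IW(α, λ_k)` (cdf `exp(−λ x^(−α))`) with common shape generate

```
X = max(U₁, U₃),   Y = max(U₂, U₃)
```

so the marginals are `X ~ IW(α, λ₁+λ₃)`, `Y ~ IW(α, λ₂+λ₃)`, the common
shock `U₃` makes the pair dependent, and the diagonal `{X = Y}` carries
positive mass `λ₃/(λ₁+λ₂+λ₃)`. Estimators:

* **MLE** — Newton–Raphson on log-parameters with step-halving and
  observed-information (Wald) intervals, for both designs; the RSS
  likelihood includes the order-statistic factors
  `F(x)^(i−1) [1−F(x)]^(m−i)` of the ranking variable.
* **Bayes** — independent gamma priors on the rates; exact
  mixture-of-gammas posterior and closed-form posterior means when `α` is
  known; Metropolis-within-Gibbs MCMC (adaptive burn-in, frozen
  afterwards) when it is not; central credible intervals.
* **Study engine** — MSE / bias / relative efficiency
  (`EFF = MSE_SRS/MSE_RSS`) / empirical coverage over designs ×
  estimators × set sizes, with Monte-Carlo standard errors and an
  auditable replication-failure count.

## Worked example

```r
library(biwrss)

truth <- biw_params(1, 0.5, 1, 1)
truth
#> BIW parameters (alpha, lam1, lam2, lam3): 1.0 0.5 1.0 1.0
#>   marginals: X ~ IW(alpha, 1.5 ), Y ~ IW(alpha, 2 )
#>   P(X = Y) = 0.4

set.seed(42)
rss <- rbiw_rss(m = 5, r = 6, truth)   # 30 measured pairs out of 150 drawn
biw_counts(rss)
#> # A tibble: 1 × 4
#>       n    n1    n2    n3
#>   <int> <int> <int> <int>
#> 1    30    11     4    15

fit <- fit_biw_mle(rss)
fit
#> BIW maximum-likelihood fit (rss, n = 30)
#> # A tibble: 4 × 5
#>   parameter estimate std.error  lower upper
#>   <chr>        <dbl>     <dbl>  <dbl> <dbl>
#> 1 alpha        1.12      0.108 0.905  1.33
#> 2 lam1         0.370     0.169 0.0392 0.701
#> 3 lam2         1.06      0.316 0.441  1.68
#> 4 lam3         1.35      0.224 0.913  1.79
#> log-likelihood: -188.5067 | converged: TRUE | iterations: 4
```

Each row is one model parameter with its Wald 95% interval from the
observed information; all four truths are covered here. The Bayesian
route gives matching answers with credible intervals:

```r
bay <- fit_biw_bayes(rss, biw_prior_preset("baseline"))
tidy(bay)
#> # A tibble: 4 × 5
#>   parameter estimate std.error lower upper
#>   <chr>        <dbl>     <dbl> <dbl> <dbl>
#> 1 alpha        1.13      0.110 0.929 1.36
#> 2 lam1         0.474     0.167 0.192 0.836
#> 3 lam2         1.15      0.319 0.604 1.85
#> 4 lam3         1.31      0.219 0.906 1.77
```

How much does ranking buy? A small design comparison (200 replications
per cell; `autoplot(st)` draws it):

```r
st <- biw_study(truth, m = c(5, 10), reps = 200, estimators = "mle", seed = 1)
biw_efficiency(st)
#> # A tibble: 8 × 6
#>   estimator     m parameter mse_srs mse_rss   eff
#>   <chr>     <int> <chr>       <dbl>   <dbl> <dbl>
#> 1 mle           5 alpha      0.287   0.156   1.84
#> 2 mle           5 lam1       2.15    0.526   4.09
#> 3 mle           5 lam2       8.37    3.27    2.56
#> 4 mle           5 lam3       1.10    0.808   1.36
#> 5 mle          10 alpha      0.0740  0.0266  2.78
#> 6 mle          10 lam1       0.198   0.0984  2.01
#> 7 mle          10 lam2       0.527   0.270   1.95
#> 8 mle          10 lam3       0.377   0.135   2.80
```

`eff > 1` means the ranked design beats simple random sampling at the
same number of measured pairs. Real paired data ingest through
`read_biw_pairs()` (CSV with `x`, `y` columns) and can be resampled into
an RSS design with `rss_subsample()`.

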