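# Independent oracles used across the suite. These deliberately avoid the
# compiled code paths: the likelihood oracle is assembled in R from the
# branch densities and marginal cdf, and derivatives come from central
# finite differences.

# branch-sum log-likelihood: sum of log joint-density branches plus the
# order-statistic terms of the ranking variable
loglik_oracle <- function(sample, params) {
  params <- as_biw_params_test(params)
  m <- attr(sample, "m")
  rk <- if ("rank" %in% names(sample)) sample[["rank"]] else rep(1L, nrow(sample))
  if (is.null(m)) m <- 1L
  lam13 <- params[2] + params[4]
  branch <- log(dbiw(sample$x, sample$y,
                     biw_params(params[1], params[2], params[3],
                                params[4]))$density)
  Fx <- piw(sample$x, params[1], lam13)
  sum(branch + (rk - 1) * log(Fx) + (m - rk) * log1p(-Fx))
}

as_biw_params_test <- function(p) {
  if (inherits(p, "biw_params")) as.double(p) else as.double(p)
}

fd_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(k) {
    e <- replace(numeric(length(x)), k, eps)
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

# Hessian as central differences of an analytic gradient function
fd_hessian <- function(grad_fn, x, eps = 1e-6) {
  cols <- lapply(seq_along(x), function(k) {
    e <- replace(numeric(length(x)), k, eps)
    (grad_fn(x + e) - grad_fn(x - e)) / (2 * eps)
  })
  do.call(cbind, cols)
}

# two-sided KS distance of a sample against a cdf
ks_stat <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fq <- cdf(x)
  max(abs(Fq - seq_len(n) / n), abs(Fq - (seq_len(n) - 1) / n))
}

ks_crit <- function(n, level = 0.05) {
  # asymptotic critical value c(level)/sqrt(n); 1.358 at the 5% level
  1.358 / sqrt(n)
}
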