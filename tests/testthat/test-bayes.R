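p_ref <- biw_params(1, 0.5, 1, 1)
prior_base <- biw_prior_preset("baseline")

# Riemann-grid posterior means from the likelihood-times-prior surface.
# The log-likelihood over the grid is assembled in vectorised R directly
# from the branch sufficient statistics (independent of the compiled code
# and of the mixture expansion).
loglik_grid <- function(sample, alpha, g) {
  m <- attr(sample, "m")
  rk <- if ("rank" %in% names(sample)) sample[["rank"]] else rep(1L, nrow(sample))
  X <- sample$x^(-alpha); Y <- sample$y^(-alpha)
  d1 <- sample$delta1; d2 <- sample$delta2; d3 <- sample$delta3
  n1 <- sum(d1); n2 <- sum(d2); n3 <- sum(d3)
  Z1 <- sum(d1 * Y); Z2 <- sum(d2 * X); Z3 <- sum(d2 * Y)
  Z4 <- sum(d1 * X); Z5 <- sum(d3 * X)
  Crk <- sum((rk - 1) * X)
  nb <- length(g)
  dm <- c(nb, nb, nb)
  l1 <- array(g, dm)
  l2 <- array(rep(g, each = nb), dm)
  l3 <- array(rep(g, each = nb * nb), dm)
  l13 <- l1 + l3; l23 <- l2 + l3
  ll <- n1 * (log(l13) + log(l2)) + n2 * (log(l1) + log(l23)) +
    n3 * log(l3) - l13 * (Z4 + Crk) - l2 * Z1 - l1 * Z2 - l23 * Z3 -
    (l1 + l2 + l3) * Z5
  for (i in seq_len(nrow(sample))) {
    v <- m - rk[i]
    if (v > 0) ll <- ll + v * log1p(-exp(-l13 * X[i]))
  }
  ll
}

quadrature_means <- function(sample, prior, alpha, upper = 20, nbin = 100) {
  g <- seq(upper / nbin / 2, upper - upper / nbin / 2, length.out = nbin)
  lp <- loglik_grid(sample, alpha, g)
  nb <- length(g)
  lp <- lp +
    array(stats::dgamma(g, prior$shape[1], rate = prior$rate[1], log = TRUE),
          c(nb, nb, nb)) +
    array(rep(stats::dgamma(g, prior$shape[2], rate = prior$rate[2],
                            log = TRUE), each = nb), c(nb, nb, nb)) +
    array(rep(stats::dgamma(g, prior$shape[3], rate = prior$rate[3],
                            log = TRUE), each = nb * nb), c(nb, nb, nb))
  w <- exp(lp - max(lp))
  z <- sum(w)
  c(lam1 = sum(sweep(w, 1, g, `*`)) / z,
    lam2 = sum(sweep(w, 2, g, `*`)) / z,
    lam3 = sum(sweep(w, 3, g, `*`)) / z)
}

test_that("prior presets carry the documented hyperparameters", {
  expect_equal(prior_base$shape, c(2, 2, 2))
  expect_equal(prior_base$rate, c(1, 1, 1))
  ni <- biw_prior_preset("noninformative")
  expect_equal(ni$shape, c(1, 1, 1))
  expect_equal(ni$rate, c(0.5, 0.5, 0.5))
  expect_error(biw_prior(0, 1, 1), "> 0")
})

test_that("the no-data posterior is the prior", {
  empty <- as_biw_sample(data.frame(x = numeric(0), y = numeric(0)))
  mx <- posterior_biw_mixture(empty, prior_base, alpha = 1)
  expect_equal(nrow(mx$components), 1)
  expect_equal(bayes_lambda_estimates(mx),
               c(lam1 = 2, lam2 = 2, lam3 = 2))
})

test_that("SRS mixture posterior integrates to one and matches quadrature", {
  set.seed(41)
  s <- rbiw_srs(3, p_ref)
  mx <- posterior_biw_mixture(s, prior_base, alpha = 1)
  expect_equal(sum(mx$components$weight), 1, tolerance = 1e-10)
  # normalisation of the density itself on a grid
  g <- seq(0.05, 20, by = 0.1)
  tot <- 0
  for (l3 in g) {
    gr <- expand.grid(l1 = g, l2 = g)
    tot <- tot + sum(dbiw_posterior(mx, gr$l1, gr$l2, l3)) * 0.1^3
  }
  expect_equal(tot, 1, tolerance = 1e-3)
  cf <- bayes_lambda_estimates(mx)
  qd <- quadrature_means(s, prior_base, alpha = 1, upper = 24, nbin = 160)
  expect_equal(cf, qd, tolerance = 5e-3)
})

test_that("RSS mixture (signed expansion) matches quadrature", {
  set.seed(42)
  s <- rbiw_rss(3, 1, p_ref)
  mx <- posterior_biw_mixture(s, prior_base, alpha = 1)
  expect_gt(nrow(mx$components), 1)
  expect_true(any(mx$components$weight < 0) || all(s$rank == attr(s, "m")))
  expect_equal(sum(mx$components$weight), 1, tolerance = 1e-10)
  cf <- bayes_lambda_estimates(mx)
  qd <- quadrature_means(s, prior_base, alpha = 1, upper = 24, nbin = 160)
  expect_equal(cf, qd, tolerance = 1e-2)
})

test_that("a dominating prior pins the estimator at the prior mean", {
  set.seed(43)
  s <- rbiw_srs(4, p_ref)
  strong <- biw_prior(2000, 2000, 2000, b1 = 1000)  # mean 2, tiny variance
  mx <- posterior_biw_mixture(s, strong, alpha = 1)
  expect_equal(unname(bayes_lambda_estimates(mx)), rep(2, 3),
               tolerance = 0.02)
})

test_that("capacity guard directs large expansions to MCMC", {
  set.seed(44)
  s <- rbiw_rss(10, 2, p_ref)
  expect_error(posterior_biw_mixture(s, prior_base, alpha = 1),
               "fit_biw_bayes")
})

test_that("fixed-alpha MCMC agrees with the closed-form posterior means", {
  set.seed(45)
  s <- rbiw_srs(6, p_ref)
  cf <- bayes_lambda_estimates(posterior_biw_mixture(s, prior_base, 1))
  fit <- fit_biw_bayes(s, prior_base, alpha = 1, iter = 12000,
                       burnin = 2000)
  mcse <- apply(as.matrix(fit$chain)[, 2:4], 2, sd) / sqrt(1000)
  expect_true(all(abs(fit$estimates[2:4] - cf) < 3 * 10 * mcse))
  expect_equal(unname(fit$estimates["alpha"]), 1)  # held fixed
})

test_that("MCMC chains are seed-reproducible", {
  set.seed(46); s <- rbiw_srs(20, p_ref)
  set.seed(1); f1 <- fit_biw_bayes(s, iter = 1500, burnin = 300)
  set.seed(1); f2 <- fit_biw_bayes(s, iter = 1500, burnin = 300)
  expect_identical(f1$chain, f2$chain)
})

test_that("credible intervals are empirical quantiles and widen with level", {
  set.seed(47)
  s <- rbiw_srs(30, p_ref)
  fit <- fit_biw_bayes(s, iter = 4000, burnin = 1000)
  ci95 <- credible_interval(fit, 0.95)
  ci50 <- credible_interval(fit, 0.50)
  expect_true(all(ci95$lower <= ci50$lower & ci50$upper <= ci95$upper))
  # constant chain degenerates to a point
  const <- fit
  const$chain[] <- 2.5
  cc <- credible_interval(const, 0.95)
  expect_equal(cc$lower, rep(2.5, 4), ignore_attr = TRUE)
  expect_equal(cc$upper, rep(2.5, 4), ignore_attr = TRUE)
  short <- fit
  short$chain <- short$chain[1:50, ]
  expect_error(credible_interval(short), "100")
  # quantile oracle: standard-normal draws recover +/- 1.96
  set.seed(48)
  zf <- fit
  zf$chain <- tibble::as_tibble(matrix(rnorm(4 * 10000), ncol = 4,
                                       dimnames = list(NULL, names(zf$chain))))
  cz <- credible_interval(zf, 0.95)
  expect_equal(cz$lower, rep(-1.96, 4), tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(cz$upper, rep(1.96, 4), tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("credible intervals are approximately calibrated", {
  set.seed(49)
  truth <- biw_params(1.5, 0.2, 0.8, 0.4)
  tv <- as.double(truth)
  reps <- 150
  hits <- matrix(NA, reps, 4)
  for (b in seq_len(reps)) {
    s <- rbiw_srs(150, truth)
    fit <- fit_biw_bayes(s, prior_base, iter = 2500, burnin = 600)
    hits[b, ] <- fit$intervals$lower <= tv & tv <= fit$intervals$upper
  }
  covg <- colMeans(hits)
  band <- 3 * sqrt(0.95 * 0.05 / reps)
  expect_true(all(abs(covg - 0.95) < band + 0.02))
})

test_that("matching prior presets coincide and the ranked design wins", {
  # conjugate protocol: shape fixed at its true value
  sens <- biw_prior_sensitivity(reps = 400, seed = 50,
                                mcmc_iter = 2000, mcmc_burnin = 500)
  wide <- tidyr::pivot_wider(
    dplyr::select(sens, "prior", "design", "parameter", "mse", "mse_se"),
    names_from = "prior", values_from = c("mse", "mse_se"))
  # baseline and alternative agree within 2 MC SEs
  slack2 <- 2 * sqrt(wide$mse_se_baseline^2 + wide$mse_se_alternative^2)
  expect_true(all(abs(wide$mse_baseline - wide$mse_alternative) <= slack2))
  # the ranked design never loses by more than 2 MC SEs
  bydesign <- tidyr::pivot_wider(
    dplyr::select(sens, "prior", "design", "parameter", "mse", "mse_se"),
    names_from = "design", values_from = c("mse", "mse_se"))
  slack3 <- 2 * sqrt(bydesign$mse_se_srs^2 + bydesign$mse_se_rss^2)
  expect_true(all(bydesign$mse_rss <= bydesign$mse_srs + slack3))
})
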