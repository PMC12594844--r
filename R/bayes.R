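#' Gamma prior specification for the BIW rate parameters
#'
#' Independent gamma priors \eqn{\lambda_i \sim Gamma(a_i, b_i)} for the
#' three rates. Three named presets mirror common choices: `"baseline"`
#' (shapes 2, rates 1, moderately informative), `"noninformative"` (shapes
#' 1, rates 0.5) and `"alternative"` (shapes `c = 2`, rates `d = 1`).
#'
#' @param a1,a2,a3 Shape hyperparameters, `> 0`.
#' @param b1,b2,b3 Rate hyperparameters, `> 0` (default: a single shared
#'   rate `b1`).
#' @return An object of class `biw_prior`.
#' @examples
#' biw_prior(2, 2, 2, b1 = 1)
#' biw_prior_preset("noninformative")
#' @export
biw_prior <- function(a1, a2, a3, b1 = 1, b2 = b1, b3 = b1) {
  v <- c(a1, a2, a3, b1, b2, b3)
  if (anyNA(v) || any(v <= 0)) abort("prior hyperparameters must be > 0")
  structure(list(shape = c(a1, a2, a3), rate = c(b1, b2, b3)),
            class = "biw_prior")
}

#' @rdname biw_prior
#' @param preset One of `"baseline"`, `"noninformative"`, `"alternative"`.
#' @export
biw_prior_preset <- function(preset = c("baseline", "noninformative",
                                        "alternative")) {
  switch(match.arg(preset),
         baseline = biw_prior(2, 2, 2, b1 = 1),
         noninformative = biw_prior(1, 1, 1, b1 = 0.5),
         alternative = biw_prior(2, 2, 2, b1 = 1))
}

#' @export
print.biw_prior <- function(x, ...) {
  cat("Gamma priors on (lam1, lam2, lam3): shape =",
      paste(format(x$shape), collapse = ", "),
      "| rate =", paste(format(x$rate), collapse = ", "), "\n")
  invisible(x)
}

#' Exact mixture-of-gammas posterior for known shape
#'
#' With \eqn{\alpha} known and independent gamma priors on the rates, the
#' posterior of \eqn{(\lambda_1, \lambda_2, \lambda_3)} is an exact finite
#' mixture of products of gamma densities: the powers
#' \eqn{\lambda_{13}^{N_1}} and \eqn{\lambda_{23}^{N_2}} expand binomially
#' (indices from 0), and under RSS each ranked factor
#' \eqn{[1 - e^{-\lambda_{13} x^{-\alpha}}]^{m-i}} expands into signed terms
#' indexed per observation, producing a full cross-product of components
#' with signed weights. Weights are computed with log-gamma arithmetic and
#' signed log-sum normalisation.
#'
#' @param data A `biw_sample` tibble (SRS or RSS).
#' @param prior A [biw_prior()] object.
#' @param alpha The known shape parameter.
#' @param max_components Capacity guard; an error directs to
#'   [fit_biw_bayes()] when the expansion would exceed it.
#' @return An object of class `biw_mixture`: a list with `components` (a
#'   tibble with signed `weight` and per-rate `shape1..3`, `rate1..3`),
#'   `alpha` and `prior`. Weights sum to 1.
#' @examples
#' set.seed(1)
#' s <- rbiw_srs(5, biw_params(1, 0.5, 1, 1))
#' mx <- posterior_biw_mixture(s, biw_prior_preset("baseline"), alpha = 1)
#' bayes_lambda_estimates(mx)
#' @export
posterior_biw_mixture <- function(data, prior, alpha,
                                  max_components = 1e6) {
  if (!inherits(data, "biw_sample")) data <- as_biw_sample(data)
  check_sample(data)
  if (!inherits(prior, "biw_prior")) abort("`prior` must be a `biw_prior`")
  if (alpha <= 0) abort("`alpha` must be > 0")
  s <- sample_to_raw(data)
  n1 <- sum(s$d1); n2 <- sum(s$d2); N <- length(s$x)
  xa <- s$x^(-alpha); ya <- s$y^(-alpha)
  # sufficient sums shared by all components
  Z1 <- sum(s$d1 * ya); Z2 <- sum(s$d2 * xa); Z3 <- sum(s$d2 * ya)
  Z5 <- sum(s$d3 * xa)
  Z4_base <- sum((s$d1 + s$rank - 1) * xa)
  # signed expansion of the ranked factors, one index per observation with
  # m - rank > 0; SRS has none and yields the single term l = 0
  free <- which(s$m - s$rank > 0)
  n_l <- prod(s$m - s$rank[free] + 1)
  n_comp <- n_l * (n1 + 1) * (n2 + 1)
  if (n_comp > max_components) {
    abort(paste0("posterior expansion needs ", n_comp,
                 " components (> capacity); use fit_biw_bayes() instead"))
  }
  if (length(free)) {
    grids <- lapply(free, function(i) 0:(s$m - s$rank[i]))
    lgrid <- as.matrix(expand.grid(grids))
    lsum <- rowSums(lgrid)
    logc_l <- rowSums(matrix(
      lchoose(rep(s$m - s$rank[free], each = nrow(lgrid)), as.vector(lgrid)),
      nrow = nrow(lgrid)))
    Z4 <- Z4_base + as.vector(lgrid %*% xa[free])
  } else {
    lsum <- 0; logc_l <- 0; Z4 <- Z4_base
  }
  T2 <- Z1 + Z3 + Z5
  lterms <- tibble::tibble(
    sign = ifelse(lsum %% 2 == 0, 1, -1),
    logc = logc_l,
    T1 = Z2 + Z4 + Z5,
    T3 = Z3 + Z4 + Z5
  )
  ks <- tidyr::expand_grid(k = 0:n1, sgrid = 0:n2)
  comp <- tidyr::expand_grid(lterms, ks)
  a <- prior$shape; b <- prior$rate
  comp <- dplyr::mutate(
    comp,
    shape1 = a[1] + n2 + .data$k,
    shape2 = a[2] + n1 + .data$sgrid,
    shape3 = a[3] + N - .data$k - .data$sgrid,
    rate1 = b[1] + .data$T1,
    rate2 = b[2] + T2,
    rate3 = b[3] + .data$T3,
    logw = .data$logc + lchoose(n1, .data$k) + lchoose(n2, .data$sgrid) +
      lgamma(.data$shape1) - .data$shape1 * log(.data$rate1) +
      lgamma(.data$shape2) - .data$shape2 * log(.data$rate2) +
      lgamma(.data$shape3) - .data$shape3 * log(.data$rate3)
  )
  # signed log-sum-exp normalisation
  mx <- max(comp$logw)
  tot <- sum(comp$sign * exp(comp$logw - mx))
  if (!is.finite(tot) || tot <= 0) {
    abort("signed mixture normalisation failed (cancellation)")
  }
  comp$weight <- comp$sign * exp(comp$logw - mx) / tot
  structure(
    list(
      components = dplyr::select(comp, "weight", dplyr::starts_with("shape"),
                                 dplyr::starts_with("rate")),
      alpha = alpha, prior = prior,
      design = attr(data, "design") %||% "srs"
    ),
    class = "biw_mixture"
  )
}

#' Posterior means of the rates under squared-error loss
#'
#' The Bayes estimator under squared-error loss is the posterior mean; for
#' the mixture representation it is the weighted sum of the component
#' shape/rate ratios.
#'
#' @param mixture A `biw_mixture` from [posterior_biw_mixture()].
#' @return Named numeric vector `(lam1, lam2, lam3)`.
#' @export
bayes_lambda_estimates <- function(mixture) {
  cmp <- mixture$components
  c(lam1 = sum(cmp$weight * cmp$shape1 / cmp$rate1),
    lam2 = sum(cmp$weight * cmp$shape2 / cmp$rate2),
    lam3 = sum(cmp$weight * cmp$shape3 / cmp$rate3))
}

#' Mixture posterior density
#'
#' Evaluates the joint posterior density of `(lam1, lam2, lam3)` at given
#' points; used mainly to validate the expansion against quadrature.
#'
#' @inheritParams bayes_lambda_estimates
#' @param lam1,lam2,lam3 Coordinate vectors (recycled to a common length).
#' @return Numeric vector of density values.
#' @export
dbiw_posterior <- function(mixture, lam1, lam2, lam3) {
  cmp <- mixture$components
  n <- max(length(lam1), length(lam2), length(lam3))
  lam1 <- rep_len(lam1, n); lam2 <- rep_len(lam2, n); lam3 <- rep_len(lam3, n)
  out <- numeric(n)
  for (j in seq_len(nrow(cmp))) {
    out <- out + cmp$weight[j] *
      stats::dgamma(lam1, cmp$shape1[j], rate = cmp$rate1[j]) *
      stats::dgamma(lam2, cmp$shape2[j], rate = cmp$rate2[j]) *
      stats::dgamma(lam3, cmp$shape3[j], rate = cmp$rate3[j])
  }
  out
}

#' Bayesian fit of the BIW model by MCMC
#'
#' Metropolis-within-Gibbs sampling with Gaussian random-walk proposals on
#' each log parameter, targeting prior times likelihood (the exact
#' [biw_loglik()]). The shape `alpha` carries a gamma prior (default shape
#' 2, rate 1) unless fixed via `alpha`. Proposal scales adapt toward 30%
#' acceptance during burn-in and are frozen afterwards. Point estimates are
#' post-burn-in means (squared-error loss); credible intervals are central
#' posterior quantiles.
#'
#' @inheritParams fit_biw_mle
#' @param prior A [biw_prior()] for the rates.
#' @param alpha Either `NULL` (unknown: sampled) or a fixed known value.
#' @param alpha_prior Length-2 numeric `(shape, rate)` of the gamma prior on
#'   `alpha` when sampled.
#' @param iter,burnin Total MCMC sweeps and burn-in (defaults 10000, 2000).
#' @param conf_level Credible level.
#' @return An object of class `biw_bayes` with `chain` (a tibble of
#'   post-burn-in draws), `estimates`, `intervals`, `acceptance`,
#'   `iter`, `burnin`.
#' @examples
#' set.seed(1)
#' s <- rbiw_srs(40, biw_params(1, 0.5, 1, 1))
#' fit <- fit_biw_bayes(s, iter = 2000, burnin = 500)
#' glance(fit)
#' @export
fit_biw_bayes <- function(data, prior = biw_prior_preset("baseline"),
                          alpha = NULL, alpha_prior = c(2, 1),
                          iter = 10000, burnin = 2000, conf_level = 0.95,
                          init = NULL) {
  if (!inherits(data, "biw_sample")) data <- as_biw_sample(data)
  check_sample(data)
  if (!inherits(prior, "biw_prior")) abort("`prior` must be a `biw_prior`")
  if (burnin >= iter) abort("`burnin` must be smaller than `iter`")
  s <- sample_to_raw(data)
  init <- if (is.null(init)) biw_init(s) else as.double(as_biw_params(init))
  res <- cpp_mcmc(s$x, s$y, s$d1, s$d2, s$d3, s$rank, s$m,
                  prior$shape, prior$rate, alpha_prior[1], alpha_prior[2],
                  !is.null(alpha), alpha %||% 1, init,
                  as.integer(iter), as.integer(burnin))
  nm <- c("alpha", "lam1", "lam2", "lam3")
  draws <- res$chain[(burnin + 1):iter, , drop = FALSE]
  colnames(draws) <- nm
  est <- colMeans(draws)
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  qs <- apply(draws, 2, quantile, probs = probs)
  acc <- setNames(drop(res$acceptance), nm)
  sampled <- if (is.null(alpha)) nm else nm[-1]
  if (any(acc[sampled] < 0.1 | acc[sampled] > 0.6)) {
    warn("MCMC acceptance rate outside [0.1, 0.6] after adaptation")
  }
  structure(
    list(
      chain = tibble::as_tibble(draws), estimates = est,
      intervals = tibble::tibble(parameter = nm, estimate = unname(est),
                                 lower = qs[1, ], upper = qs[2, ]),
      acceptance = acc, iter = iter, burnin = burnin,
      alpha_fixed = alpha, conf_level = conf_level,
      design = attr(data, "design") %||% "srs", n = length(s$x)
    ),
    class = "biw_bayes"
  )
}

#' Central credible interval from posterior draws
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2` of the
#' post-burn-in draws.
#'
#' @param fit A `biw_bayes` object (at least 100 post-burn-in draws).
#' @param level Credible level.
#' @return A tibble with `parameter`, `lower`, `upper`.
#' @export
credible_interval <- function(fit, level = 0.95) {
  if (!inherits(fit, "biw_bayes")) abort("`fit` must be a `biw_bayes`")
  if (nrow(fit$chain) < 100) {
    abort("need at least 100 post-burn-in draws")
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(as.matrix(fit$chain), 2, quantile, probs = probs)
  tibble::tibble(parameter = colnames(fit$chain),
                 lower = qs[1, ], upper = qs[2, ])
}

#' @export
print.biw_bayes <- function(x, ...) {
  cat("BIW Bayesian fit (", x$design, ", n = ", x$n, ", ",
      nrow(x$chain), " retained draws)\n", sep = "")
  print(x$intervals)
  invisible(x)
}

#' @rdname fit_biw_bayes
#' @param x A `biw_bayes` object.
#' @param ... Unused.
#' @method tidy biw_bayes
#' @export
tidy.biw_bayes <- function(x, ...) {
  dplyr::mutate(x$intervals,
                std.error = apply(as.matrix(x$chain), 2, sd),
                .after = "estimate")
}

#' @rdname fit_biw_bayes
#' @method glance biw_bayes
#' @export
glance.biw_bayes <- function(x, ...) {
  tibble::tibble(
    nobs = x$n, iter = x$iter, burnin = x$burnin,
    design = x$design, alpha_fixed = !is.null(x$alpha_fixed),
    min_acceptance = min(x$acceptance, na.rm = TRUE)
  )
}

#' Export an MCMC chain as CSV
#'
#' @param fit A `biw_bayes` object.
#' @param path Output path; columns `iteration`, `alpha`, `lam1`, `lam2`,
#'   `lam3`.
#' @return `path`, invisibly.
#' @export
write_chain_csv <- function(fit, path) {
  if (!inherits(fit, "biw_bayes")) abort("`fit` must be a `biw_bayes`")
  out <- dplyr::mutate(fit$chain, iteration = dplyr::row_number(),
                       .before = 1)
  readr::write_csv(out, path)
  invisible(path)
}
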