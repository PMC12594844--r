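#' Monte-Carlo comparison of designs and estimators
#'
#' Repeatedly simulates BIW data under SRS (sample size `m * r`) and RSS
#' (set size `m`, `r` cycles), fits each replication by maximum likelihood
#' and/or MCMC Bayes, and summarises per parameter the Monte-Carlo mean
#' squared error, bias, empirical interval coverage and their Monte-Carlo
#' standard errors. SRS cells use `n = m * r` so that the relative
#' efficiency EFF = MSE(SRS) / MSE(RSS) compares designs at equal measured
#' sample size. Replications whose fit fails to converge are redrawn with
#' fresh data and counted in `n_failed`.
#'
#' @param truth A [biw_params()] object: the data-generating parameters.
#' @param m Vector of set sizes.
#' @param r Number of cycles (default 1, so the cell sample size equals `m`).
#' @param reps Monte-Carlo replications per cell.
#' @param designs,estimators Subsets of `c("srs", "rss")` and
#'   `c("mle", "bayes")`.
#' @param prior [biw_prior()] used by the Bayes cells.
#' @param conf_level Nominal level of the coverage intervals.
#' @param seed Optional integer master seed; per-cell sub-seeds are derived
#'   from it so results do not depend on cell order.
#' @param mcmc_iter,mcmc_burnin MCMC sweeps per Bayes replication.
#' @param alpha_prior Gamma prior `(shape, rate)` on `alpha` for the Bayes
#'   cells (`alpha` is treated as unknown and sampled).
#' @return A tibble of class `biw_study` with one row per
#'   (design, estimator, m, parameter) cell: columns `mse`, `bias`,
#'   `coverage`, `mse_se`, `bias_se`, `coverage_se`, `n_failed`, `reps`, `n`.
#' @examples
#' \donttest{
#' st <- biw_study(biw_params(1, 0.5, 1, 1), m = c(5, 10), reps = 100,
#'                 estimators = "mle", seed = 1)
#' biw_efficiency(st)
#' }
#' @export
biw_study <- function(truth, m = c(5, 10, 15), r = 1, reps = 1000,
                      designs = c("srs", "rss"),
                      estimators = c("mle", "bayes"),
                      prior = biw_prior_preset("baseline"),
                      conf_level = 0.95, seed = NULL,
                      mcmc_iter = 3000, mcmc_burnin = 1000,
                      alpha_prior = c(2, 1)) {
  truth <- as_biw_params(truth)
  designs <- match.arg(designs, several.ok = TRUE)
  estimators <- match.arg(estimators, several.ok = TRUE)
  grid <- tidyr::expand_grid(design = designs, estimator = estimators,
                             m = as.integer(m))
  if (!is.null(seed)) set.seed(seed)
  grid$cell_seed <- sample.int(.Machine$integer.max, nrow(grid))
  cells <- purrr::pmap(grid, function(design, estimator, m, cell_seed) {
    set.seed(cell_seed)
    biw_study_cell(truth, design = design, estimator = estimator, m = m,
                   r = r, reps = reps, prior = prior,
                   conf_level = conf_level, mcmc_iter = mcmc_iter,
                   mcmc_burnin = mcmc_burnin, alpha_prior = alpha_prior)
  })
  out <- dplyr::bind_rows(cells)
  class(out) <- c("biw_study", class(out))
  attr(out, "truth") <- truth
  attr(out, "r") <- r
  out
}

#' One Monte-Carlo cell
#'
#' Workhorse behind [biw_study()]: a single (design, estimator, set size)
#' combination. Exposed for targeted experiments.
#'
#' @inheritParams biw_study
#' @param design `"srs"` or `"rss"`.
#' @param estimator `"mle"` or `"bayes"`.
#' @param m Set size (scalar).
#' @param keep_estimates Return the per-replication estimates in an
#'   attribute `estimates` (a `reps` x 4 matrix)?
#' @return A tibble with four rows (one per parameter).
#' @export
biw_study_cell <- function(truth, design, estimator, m, r = 1, reps = 1000,
                           prior = biw_prior_preset("baseline"),
                           conf_level = 0.95, mcmc_iter = 3000,
                           mcmc_burnin = 1000, alpha_prior = c(2, 1),
                           keep_estimates = FALSE) {
  truth <- as_biw_params(truth)
  tv <- as.double(truth)
  n <- as.integer(m * r)
  est <- matrix(NA_real_, reps, 4)
  cov <- matrix(NA, reps, 4)
  failed <- 0L
  max_attempts <- 50L * reps
  attempts <- 0L
  z <- qnorm(1 - (1 - conf_level) / 2)
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  for (b in seq_len(reps)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort("too many failed replications in a Monte-Carlo cell")
      }
      s <- if (design == "srs") sample_srs_raw(n, truth)
           else sample_rss_raw(m, r, truth)
      if (estimator == "mle") {
        fit <- cpp_fit_mle(s$x, s$y, s$d1, s$d2, s$d3, s$rank, s$m,
                           biw_init(s))
        v <- diag(matrix(fit$vcov, 4, 4))
        ok <- isTRUE(fit$converged) && all(is.finite(fit$estimates)) &&
          all(is.finite(v)) && all(v >= 0)
        if (ok) {
          e <- drop(fit$estimates)
          se <- sqrt(v)
          est[b, ] <- e
          cov[b, ] <- (tv >= e - z * se) & (tv <= e + z * se)
          break
        }
      } else {
        res <- cpp_mcmc(s$x, s$y, s$d1, s$d2, s$d3, s$rank, s$m,
                        prior$shape, prior$rate, alpha_prior[1],
                        alpha_prior[2], FALSE, 1, biw_init(s),
                        as.integer(mcmc_iter), as.integer(mcmc_burnin))
        draws <- res$chain[(mcmc_burnin + 1):mcmc_iter, , drop = FALSE]
        e <- colMeans(draws)
        if (all(is.finite(e))) {
          qs <- apply(draws, 2, quantile, probs = probs)
          est[b, ] <- e
          cov[b, ] <- (tv >= qs[1, ]) & (tv <= qs[2, ])
          break
        }
      }
      failed <- failed + 1L
    }
  }
  err <- sweep(est, 2, tv)
  tibble::tibble(
    design = design, estimator = estimator, m = as.integer(m),
    r = as.integer(r), n = n,
    parameter = c("alpha", "lam1", "lam2", "lam3"),
    truth = unname(tv),
    mse = colMeans(err^2),
    bias = colMeans(err),
    coverage = colMeans(cov),
    mse_se = apply(err^2, 2, sd) / sqrt(reps),
    bias_se = apply(err, 2, sd) / sqrt(reps),
    coverage_se = sqrt(colMeans(cov) * (1 - colMeans(cov)) / reps),
    reps = as.integer(reps), n_failed = failed,
    flagged = failed > 0.05 * reps
  ) -> out
  if (keep_estimates) attr(out, "estimates") <- est
  out
}

#' Relative efficiency of RSS versus SRS
#'
#' EFF = MSE(SRS) / MSE(RSS) per (estimator, parameter, m) at matched sample
#' size; values above 1 favour the ranked design.
#'
#' @param study A `biw_study` tibble containing both designs.
#' @return A tibble with columns `estimator`, `parameter`, `m`, `mse_srs`,
#'   `mse_rss`, `eff`.
#' @export
biw_efficiency <- function(study) {
  wide <- study |>
    dplyr::select("design", "estimator", "m", "parameter", "mse") |>
    tidyr::pivot_wider(names_from = "design", values_from = "mse",
                       names_prefix = "mse_")
  if (!all(c("mse_srs", "mse_rss") %in% names(wide))) {
    abort("`study` must contain both designs to compute efficiencies")
  }
  if (any(wide$mse_rss <= 0)) abort("zero MSE in the RSS cells")
  dplyr::mutate(wide, eff = .data$mse_srs / .data$mse_rss)
}

#' Prior-sensitivity study for the Bayes rate estimators
#'
#' Re-runs the Bayes cells at one set size under several prior
#' specifications with the shape parameter fixed at its true value (the
#' conjugate analysis conditions on a known shape), reporting MSE and Bias
#' of the rate estimators under each prior and design.
#'
#' @inheritParams biw_study
#' @param priors Named list of [biw_prior()] objects (defaults to the three
#'   presets).
#' @param m Single set size (default 10).
#' @return A tibble with one row per (prior, design, parameter in
#'   lam1..lam3): columns `mse`, `bias` and their Monte-Carlo standard
#'   errors.
#' @export
biw_prior_sensitivity <- function(truth = biw_params(1.5, 0.2, 0.8, 0.4),
                                  m = 10, r = 1, reps = 1000,
                                  priors = list(
                                    baseline = biw_prior_preset("baseline"),
                                    noninformative = biw_prior_preset("noninformative"),
                                    alternative = biw_prior_preset("alternative")),
                                  designs = c("srs", "rss"),
                                  seed = NULL,
                                  mcmc_iter = 3000, mcmc_burnin = 1000) {
  truth <- as_biw_params(truth)
  tv <- as.double(truth)
  n <- as.integer(m * r)
  grid <- tidyr::expand_grid(prior = names(priors), design = designs)
  if (!is.null(seed)) set.seed(seed)
  grid$cell_seed <- sample.int(.Machine$integer.max, nrow(grid))
  rows <- purrr::pmap(grid, function(prior, design, cell_seed) {
    set.seed(cell_seed)
    pr <- priors[[prior]]
    est <- matrix(NA_real_, reps, 4)
    for (b in seq_len(reps)) {
      s <- if (design == "srs") sample_srs_raw(n, truth)
           else sample_rss_raw(m, r, truth)
      init <- biw_init(s)
      res <- cpp_mcmc(s$x, s$y, s$d1, s$d2, s$d3, s$rank, s$m,
                      pr$shape, pr$rate, 2, 1, TRUE, truth$alpha, init,
                      as.integer(mcmc_iter), as.integer(mcmc_burnin))
      draws <- res$chain[(mcmc_burnin + 1):mcmc_iter, , drop = FALSE]
      est[b, ] <- colMeans(draws)
    }
    err <- sweep(est[, 2:4, drop = FALSE], 2, tv[2:4])
    tibble::tibble(
      prior = prior, design = design, m = as.integer(m),
      parameter = c("lam1", "lam2", "lam3"),
      truth = unname(tv[2:4]),
      mse = colMeans(err^2), bias = colMeans(err),
      mse_se = apply(err^2, 2, sd) / sqrt(reps),
      bias_se = apply(err, 2, sd) / sqrt(reps),
      reps = as.integer(reps)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write study tables to disk
#'
#' Emits the MSE, Bias, EFF and coverage summaries of a study as CSV (or
#' JSON) files with deterministic column order.
#'
#' @param study A `biw_study` tibble.
#' @param dir Output directory (created if missing).
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, the paths written.
#' @export
write_study_tables <- function(study, dir, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- list(
    mse = dplyr::select(study, "design", "estimator", "m", "parameter",
                        "mse", "mse_se"),
    bias = dplyr::select(study, "design", "estimator", "m", "parameter",
                         "bias", "bias_se"),
    coverage = dplyr::select(study, "design", "estimator", "m", "parameter",
                             "coverage", "coverage_se")
  )
  if (all(c("srs", "rss") %in% study$design)) {
    tabs$eff <- biw_efficiency(study)
  }
  paths <- purrr::imap_chr(tabs, function(tab, nm) {
    path <- file.path(dir, paste0(nm, ".", format))
    if (format == "csv") readr::write_csv(tab, path)
    else jsonlite::write_json(tab, path, digits = NA)
    path
  })
  invisible(paths)
}

#' Plot a Monte-Carlo study summary
#'
#' @param object A `biw_study` tibble.
#' @param metric Which summary to draw against the set size.
#' @param ... Unused.
#' @method autoplot biw_study
#' @export
autoplot.biw_study <- function(object, metric = c("mse", "bias", "coverage"),
                               ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$m, y = .data[[metric]],
                               colour = .data$design,
                               linetype = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "set size m", y = metric,
                  title = "BIW Monte-Carlo study") +
    ggplot2::theme_minimal()
}
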