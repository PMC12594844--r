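#' Maximum-likelihood fit of the BIW model
#'
#' Newton-Raphson maximisation of [biw_loglik()] on the log-parameter scale
#' (which enforces positivity), with step-halving whenever a step would
#' decrease the log-likelihood. Convergence is declared when the largest
#' absolute change in the natural parameters falls below `tol`
#' (default `1e-6`) or after `max_iter` iterations. The variance-covariance
#' matrix is the inverse of the observed information (negative Hessian) at
#' the optimum, and Wald confidence intervals are
#' \eqn{\hat\theta_k \pm z_{\gamma/2}\sqrt{v_{kk}}}.
#'
#' @param data A `biw_sample` tibble (SRS or RSS); plain data frames with
#'   `x`, `y` columns are coerced with [as_biw_sample()] as SRS.
#' @param init Optional starting [biw_params()]. The default derives the
#'   shape from a univariate inverse Weibull fit to the pooled
#'   `pmax(x, y)` sample (whose law is \eqn{IW(\alpha, \lambda_{123})}) and
#'   splits the rates by the region frequencies
#'   \eqn{P(x<y) = \lambda_2/\lambda_{123}} etc.
#' @param conf_level Confidence level of the Wald intervals.
#' @param tol,max_iter,max_halvings Newton-Raphson controls.
#' @return An object of class `biw_mle`: a list with `estimates`
#'   ([biw_params()]), `vcov`, `intervals` (tibble), `loglik`, `converged`,
#'   `iterations`, `gradient_norm`, `singular_info`, `counts` and
#'   `conf_level`.
#' @examples
#' set.seed(1)
#' s <- rbiw_srs(200, biw_params(1, 0.5, 1, 1))
#' fit <- fit_biw_mle(s)
#' tidy(fit)
#' @export
fit_biw_mle <- function(data, init = NULL, conf_level = 0.95,
                        tol = 1e-6, max_iter = 200, max_halvings = 30) {
  if (!inherits(data, "biw_sample")) data <- as_biw_sample(data)
  check_sample(data)
  s <- sample_to_raw(data)
  n <- length(s$x)
  if (n < 5) warn("fewer than 5 observations: the fit may be unstable")
  cnt <- biw_counts(data)
  if (cnt$n1 == 0 || cnt$n2 == 0) {
    warn("a region count is zero (n1 or n2): identifiability is weak")
  }
  init <- if (is.null(init)) biw_init(s) else as.double(as_biw_params(init))
  fit <- cpp_fit_mle(s$x, s$y, s$d1, s$d2, s$d3, s$rank, s$m,
                     init, max_iter = max_iter, tol = tol,
                     max_halvings = max_halvings)
  nm <- c("alpha", "lam1", "lam2", "lam3")
  est <- setNames(drop(fit$estimates), nm)
  vcov <- matrix(fit$vcov, 4, 4, dimnames = list(nm, nm))
  ints <- asymptotic_ci(vcov, est, conf_level)
  structure(
    list(
      estimates = biw_params(est[1], est[2], est[3], est[4]),
      vcov = vcov, intervals = ints, loglik = fit$loglik,
      converged = fit$converged, iterations = fit$iterations,
      gradient_norm = fit$gradient_norm, singular_info = fit$singular,
      counts = cnt, conf_level = conf_level,
      design = attr(data, "design") %||% "srs", n = n
    ),
    class = "biw_mle"
  )
}

# moment-style starting values; falls back to all ones
biw_init <- function(s) {
  n <- length(s$x)
  w <- pmax(s$x, s$y)
  lw <- log(w)
  alpha0 <- if (n >= 2 && sd(lw) > 0) pi / (sd(lw) * sqrt(6)) else 1
  if (!is.finite(alpha0)) alpha0 <- 1
  alpha0 <- min(max(alpha0, 0.05), 50)
  t123 <- mean(w^(-alpha0))
  l123 <- if (is.finite(t123) && t123 > 0) 1 / t123 else 1
  # region probabilities: P(x<y) = lam2/lam123 etc.; smoothed to stay interior
  f1 <- (sum(s$d1) + 0.5) / (n + 1.5)
  f2 <- (sum(s$d2) + 0.5) / (n + 1.5)
  f3 <- (sum(s$d3) + 0.5) / (n + 1.5)
  # rates clamped to a sane window: degenerate samples (all w far from 1
  # with a large provisional shape) can push 1/mean(w^-alpha) to overflow
  lams <- pmin(pmax(c(f2, f1, f3) * l123, 1e-4), 1e4)
  out <- c(alpha0, lams)
  if (!all(is.finite(out)) || any(out <= 0)) out <- rep(1, 4)
  out
}

#' Wald confidence intervals from a variance-covariance matrix
#'
#' @param vcov 4x4 variance-covariance matrix with nonnegative diagonal.
#' @param estimates Named numeric vector of point estimates.
#' @param conf_level Confidence level `1 - gamma`.
#' @return A tibble with columns `parameter`, `estimate`, `lower`, `upper`.
#' @examples
#' asymptotic_ci(diag(0.25, 4), c(alpha = 2, lam1 = 2, lam2 = 2, lam3 = 2))
#' @export
asymptotic_ci <- function(vcov, estimates, conf_level = 0.95) {
  v <- diag(vcov)
  if (any(v < 0)) {
    abort("negative variance on the diagonal: not an interior optimum")
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(v)
  tibble::tibble(
    parameter = names(estimates) %||% paste0("theta", seq_along(estimates)),
    estimate = unname(estimates),
    lower = unname(estimates - z * se),
    upper = unname(estimates + z * se)
  )
}

#' @export
print.biw_mle <- function(x, ...) {
  cat("BIW maximum-likelihood fit (", x$design, ", n = ", x$n, ")\n",
      sep = "")
  print(tidy(x))
  cat("log-likelihood:", format(x$loglik, digits = 7),
      "| converged:", x$converged,
      "| iterations:", x$iterations, "\n")
  invisible(x)
}

#' @rdname fit_biw_mle
#' @param x A `biw_mle` object.
#' @param ... Unused.
#' @method tidy biw_mle
#' @export
tidy.biw_mle <- function(x, ...) {
  dplyr::mutate(x$intervals,
                std.error = sqrt(diag(x$vcov)),
                .after = "estimate")
}

#' @rdname fit_biw_mle
#' @method glance biw_mle
#' @export
glance.biw_mle <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, nobs = x$n, converged = x$converged,
    iterations = x$iterations, gradient_norm = x$gradient_norm,
    design = x$design
  )
}

#' @export
logLik.biw_mle <- function(object, ...) {
  structure(object$loglik, df = 4L, nobs = object$n, class = "logLik")
}

#' Serialize a fit to JSON
#'
#' Writes point estimates, the (row-major) variance-covariance matrix,
#' intervals, log-likelihood and convergence diagnostics.
#'
#' @param fit A `biw_mle` or `biw_bayes` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- if (inherits(fit, "biw_mle")) {
    list(
      method = "mle", design = fit$design,
      estimates = as.list(as.double(fit$estimates)),
      vcov = as.vector(t(fit$vcov)), intervals = fit$intervals,
      loglik = fit$loglik, converged = fit$converged,
      iterations = fit$iterations
    )
  } else if (inherits(fit, "biw_bayes")) {
    list(
      method = "bayes", design = fit$design,
      estimates = as.list(fit$estimates),
      intervals = fit$intervals, acceptance = as.list(fit$acceptance),
      iter = fit$iter, burnin = fit$burnin
    )
  } else {
    abort("`fit` must be a biw_mle or biw_bayes object")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
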