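#' Log-likelihood of a BIW sample
#'
#' For SRS data the log-likelihood is the sum over observations of the log
#' of the joint-density branch selected by the event indicators. For RSS
#' data each observation at rank \eqn{i} (set size \eqn{m}) additionally
#' contributes the order-statistic terms
#' \eqn{(i - 1)\log F(x) + (m - i)\log\{1 - F(x)\}}, with \eqn{F} the
#' \eqn{IW(\alpha, \lambda_1 + \lambda_3)} marginal cdf of the ranking
#' variable. Both cases share one implementation (SRS is the \eqn{m = 1}
#' design).
#'
#' @param data A `biw_sample` tibble, see [rbiw_srs()], [rbiw_rss()] or
#'   [as_biw_sample()].
#' @param params A [biw_params()] object (or numeric `(alpha, lam1, lam2,
#'   lam3)`).
#' @return The log-likelihood (a scalar; `-Inf` outside the parameter
#'   domain).
#' @examples
#' set.seed(1)
#' p <- biw_params(1, 0.5, 1, 1)
#' s <- rbiw_rss(3, 4, p)
#' biw_loglik(s, p)
#' @export
biw_loglik <- function(data, params) {
  params <- as_biw_params(params)
  check_sample(data)
  s <- sample_to_raw(data)
  cpp_loglik(s$x, s$y, s$d1, s$d2, s$d3, s$rank, s$m,
             params$alpha, params$lam1, params$lam2, params$lam3)
}

#' Score vector and observed-information Hessian
#'
#' Analytic first and second derivatives of [biw_loglik()] with respect to
#' `(alpha, lam1, lam2, lam3)`, derived from the implemented log-likelihood.
#'
#' @inheritParams biw_loglik
#' @return For `biw_score()` a named numeric 4-vector; for `biw_hessian()` a
#'   symmetric 4x4 matrix.
#' @export
biw_score <- function(data, params) {
  score_hessian(data, params)$score
}

#' @rdname biw_score
#' @export
biw_hessian <- function(data, params) {
  score_hessian(data, params)$hessian
}

score_hessian <- function(data, params) {
  params <- as_biw_params(params)
  check_sample(data)
  s <- sample_to_raw(data)
  out <- cpp_score_hessian(s$x, s$y, s$d1, s$d2, s$d3, s$rank, s$m,
                           params$alpha, params$lam1, params$lam2,
                           params$lam3)
  nm <- c("alpha", "lam1", "lam2", "lam3")
  list(score = setNames(drop(out$score), nm),
       hessian = matrix(out$hessian, 4, 4, dimnames = list(nm, nm)))
}

check_sample <- function(data) {
  need <- c("x", "y", "delta1", "delta2", "delta3")
  if (!all(need %in% names(data))) {
    abort("`data` must be a BIW sample (see `as_biw_sample()`)")
  }
  if (any(data$x <= 0) || any(data$y <= 0)) {
    abort("sample coordinates must be positive")
  }
  ok <- (data$delta1 + data$delta2 + data$delta3) == 1L &
    (data$delta1 == as.integer(data$x < data$y) | data$delta3 == 1L) &
    (data$delta2 == as.integer(data$x > data$y) | data$delta3 == 1L)
  if (!all(ok)) {
    abort("event indicators are inconsistent with the coordinates")
  }
  invisible(data)
}
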