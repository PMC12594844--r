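#' Parameter vector of the bivariate inverse Weibull model
#'
#' The Marshall-Olkin bivariate inverse Weibull (BIW) distribution is built
#' from three independent inverse Weibull lifetimes \eqn{U_k \sim
#' IW(\alpha, \lambda_k)} sharing the shape \eqn{\alpha}, via
#' \eqn{X = \max(U_1, U_3)}, \eqn{Y = \max(U_2, U_3)}. The common-shock
#' component \eqn{U_3} makes \eqn{X} and \eqn{Y} dependent and puts positive
#' probability mass on the diagonal \eqn{\{X = Y\}}.
#'
#' @param alpha Common shape parameter, `> 0`.
#' @param lam1,lam2 Rate parameters of the individual shocks, `> 0`.
#' @param lam3 Rate parameter of the common shock, `>= 0`. `lam3 = 0` is the
#'   documented independence limit (no diagonal mass); all other parameters
#'   must be strictly positive.
#'
#' @return An object of class `biw_params`: a named list with the four
#'   parameters and the derived sums `lam13 = lam1 + lam3`,
#'   `lam23 = lam2 + lam3`, `lam123 = lam1 + lam2 + lam3`.
#'
#' @examples
#' biw_params(1, 0.5, 1, 1)
#' @export
biw_params <- function(alpha, lam1, lam2, lam3) {
  vals <- c(alpha = alpha, lam1 = lam1, lam2 = lam2, lam3 = lam3)
  if (anyNA(vals) || !all(is.finite(vals))) {
    abort("all BIW parameters must be finite numbers")
  }
  if (alpha <= 0 || lam1 <= 0 || lam2 <= 0) {
    abort("`alpha`, `lam1` and `lam2` must be strictly positive")
  }
  if (lam3 < 0) {
    abort("`lam3` must be nonnegative (0 only as the independence limit)")
  }
  structure(
    list(
      alpha = alpha, lam1 = lam1, lam2 = lam2, lam3 = lam3,
      lam13 = lam1 + lam3, lam23 = lam2 + lam3,
      lam123 = lam1 + lam2 + lam3
    ),
    class = "biw_params"
  )
}

#' @export
print.biw_params <- function(x, ...) {
  cat("BIW parameters (alpha, lam1, lam2, lam3):",
      format(c(x$alpha, x$lam1, x$lam2, x$lam3), digits = 6), "\n")
  cat("  marginals: X ~ IW(alpha,", format(x$lam13, digits = 6),
      "), Y ~ IW(alpha,", format(x$lam23, digits = 6), ")\n")
  cat("  P(X = Y) =", format(biw_singular_mass(x), digits = 6), "\n")
  invisible(x)
}

#' @export
as.double.biw_params <- function(x, ...) {
  c(alpha = x$alpha, lam1 = x$lam1, lam2 = x$lam2, lam3 = x$lam3)
}

as_biw_params <- function(p) {
  if (inherits(p, "biw_params")) return(p)
  p <- as.double(p)
  if (length(p) != 4) {
    abort("expected a `biw_params` object or a numeric vector (alpha, lam1, lam2, lam3)")
  }
  biw_params(p[[1]], p[[2]], p[[3]], p[[4]])
}
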