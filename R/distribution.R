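#' Univariate inverse Weibull distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the inverse Weibull distribution with cdf
#' \eqn{F(x) = \exp(-\lambda x^{-\alpha})}, \eqn{x > 0}.
#'
#' @param x,q Vector of positive quantiles.
#' @param p Vector of probabilities.
#' @param n Number of draws.
#' @param shape Shape parameter \eqn{\alpha > 0}.
#' @param rate Rate parameter \eqn{\lambda \ge 0} (`rate = 0` gives the
#'   degenerate-at-zero limit, only meaningful inside mixture limits).
#' @param log,log.p Logical; return log density / log probability.
#'
#' @return A numeric vector.
#' @examples
#' piw(1, shape = 2, rate = 1)   # exp(-1)
#' diw(1, shape = 1, rate = 1)
#' @name iw
NULL

check_iw_args <- function(shape, rate) {
  if (any(shape <= 0) || anyNA(shape)) abort("`shape` must be > 0")
  if (any(rate < 0) || anyNA(rate)) abort("`rate` must be >= 0")
}

#' @rdname iw
#' @export
piw <- function(q, shape, rate, log.p = FALSE) {
  check_iw_args(shape, rate)
  if (any(q <= 0 & is.finite(q))) abort("`q` must be positive")
  lp <- -rate * q^(-shape)
  if (log.p) lp else exp(lp)
}

#' @rdname iw
#' @export
diw <- function(x, shape, rate, log = FALSE) {
  check_iw_args(shape, rate)
  if (any(rate == 0)) abort("`rate` must be > 0 for the density")
  if (any(x <= 0)) abort("`x` must be positive")
  ld <- log(shape) + log(rate) - (shape + 1) * log(x) - rate * x^(-shape)
  if (log) ld else exp(ld)
}

#' @rdname iw
#' @export
qiw <- function(p, shape, rate) {
  check_iw_args(shape, rate)
  if (any(p < 0 | p > 1)) abort("`p` must be in [0, 1]")
  (-rate / log(p))^(1 / shape)
}

#' @rdname iw
#' @export
riw <- function(n, shape, rate) {
  check_iw_args(shape, rate)
  # inverse transform; rate = 0 yields exact zeros (degenerate limit)
  (-rate / log(runif(n)))^(1 / shape)
}

#' Joint distribution function of the BIW model
#'
#' The joint cdf factorises as
#' \eqn{F(x, y) = F_{IW}(x; \alpha, \lambda_1)\, F_{IW}(y; \alpha, \lambda_2)\,
#' F_{IW}(\min(x, y); \alpha, \lambda_3)}, giving three branches according to
#' the sign of \eqn{x - y}.
#'
#' @param x,y Vectors of positive coordinates (recycled to common length).
#' @param params A [biw_params()] object.
#' @param log.p Logical; return the log probability.
#' @return Numeric vector of joint probabilities \eqn{P(X \le x, Y \le y)}.
#' @examples
#' p <- biw_params(1, 0.5, 1, 1)
#' pbiw(1, 2, p)
#' @export
pbiw <- function(x, y, params, log.p = FALSE) {
  params <- as_biw_params(params)
  if (any(x <= 0) || any(y <= 0)) abort("coordinates must be positive")
  lp <- piw(x, params$alpha, params$lam1, log.p = TRUE) +
    piw(y, params$alpha, params$lam2, log.p = TRUE) +
    piw(pmin(x, y), params$alpha, params$lam3, log.p = TRUE)
  if (log.p) lp else exp(lp)
}

#' Joint density of the BIW model
#'
#' Evaluates the joint pdf, which has an absolutely continuous part on the
#' off-diagonal regions \eqn{x < y} and \eqn{x > y} and a singular part on
#' the diagonal: for \eqn{x = y} the returned value is the one-dimensional
#' density of the diagonal mass, parameterised by \eqn{x}.
#'
#' @inheritParams pbiw
#' @param log Logical; return the log density.
#' @return A [tibble::tibble] with columns `x`, `y`, `density` and `region`
#'   (one of `"x<y"`, `"x>y"`, `"x=y"`).
#' @examples
#' dbiw(1, 2, biw_params(1, 0.5, 1, 1))
#' @export
dbiw <- function(x, y, params, log = FALSE) {
  params <- as_biw_params(params)
  if (any(x <= 0) || any(y <= 0)) abort("coordinates must be positive")
  k <- vctrs_recycle(x, y)
  x <- k$x; y <- k$y
  a <- params$alpha
  lx <- log(x); ly <- log(y)
  ld <- ifelse(
    x < y,
    log(params$lam13) + log(params$lam2) + 2 * log(a) -
      (a + 1) * (lx + ly) - params$lam13 * x^(-a) - params$lam2 * y^(-a),
    ifelse(
      x > y,
      log(params$lam1) + log(params$lam23) + 2 * log(a) -
        (a + 1) * (lx + ly) - params$lam1 * x^(-a) - params$lam23 * y^(-a),
      # diagonal: lam3 = 0 carries no mass (density 0)
      ifelse(rep(params$lam3 > 0, length(x)),
             log(params$lam3) + log(a) - (a + 1) * lx -
               params$lam123 * x^(-a),
             -Inf)
    )
  )
  tibble::tibble(
    x = x, y = y,
    density = if (log) ld else exp(ld),
    region = biw_region(x, y)
  )
}

vctrs_recycle <- function(x, y) {
  n <- max(length(x), length(y))
  list(x = rep_len(x, n), y = rep_len(y, n))
}

#' Diagonal region label for a pair of coordinates
#'
#' @inheritParams pbiw
#' @return Character vector with values `"x<y"`, `"x>y"` or `"x=y"`.
#' @export
biw_region <- function(x, y) {
  ifelse(x < y, "x<y", ifelse(x > y, "x>y", "x=y"))
}

#' Probability mass on the diagonal
#'
#' In the Marshall-Olkin construction \eqn{X = Y} exactly when the common
#' shock dominates both individual shocks. Mapping to the exponential scale
#' (\eqn{T_k = U_k^{-\alpha} \sim Exp(\lambda_k)}) this is the event that
#' \eqn{T_3} is the minimum of three independent exponentials, so
#' \eqn{P(X = Y) = \lambda_3 / (\lambda_1 + \lambda_2 + \lambda_3)}.
#'
#' @inheritParams pbiw
#' @return A probability.
#' @examples
#' biw_singular_mass(biw_params(1, 0.5, 1, 1))  # 0.4
#' @export
biw_singular_mass <- function(params) {
  params <- as_biw_params(params)
  params$lam3 / params$lam123
}
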