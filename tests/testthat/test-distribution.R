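test_that("inverse Weibull cdf/pdf match direct substitution and limits", {
  expect_equal(piw(1, shape = 2, rate = 1), exp(-1))
  expect_equal(piw(2, shape = 1, rate = 3), exp(-1.5))
  expect_equal(piw(1e12, shape = 0.7, rate = 2), 1, tolerance = 1e-6)
  expect_equal(diw(1, shape = 1, rate = 1), exp(-1))
  # nondecreasing in x
  xs <- seq(0.05, 20, length.out = 200)
  expect_true(all(diff(piw(xs, 1.3, 0.8)) >= 0))
  # density integrates to one
  expect_equal(
    stats::integrate(function(x) diw(x, 1.5, 2), 0, Inf)$value, 1,
    tolerance = 1e-6
  )
  # cdf derivative equals pdf (central differences at x = 0.7)
  eps <- 1e-6
  expect_equal(
    (piw(0.7 + eps, 1.5, 2) - piw(0.7 - eps, 1.5, 2)) / (2 * eps),
    diw(0.7, 1.5, 2), tolerance = 1e-6
  )
  expect_error(piw(-1, 1, 1), "positive")
  expect_error(diw(1, -1, 1), "shape")
})

test_that("quantile function inverts the cdf", {
  p <- c(0.05, 0.3, 0.5, 0.9)
  expect_equal(piw(qiw(p, 1.7, 0.6), 1.7, 0.6), p)
})

test_that("joint cdf branches, symmetry and marginal limits are consistent", {
  p <- biw_params(1, 0.5, 1, 1)
  # diagonal branch: F(t, t) = F_IW(t; alpha, lam123)
  t <- c(0.4, 1, 3)
  expect_equal(pbiw(t, t, p), piw(t, p$alpha, p$lam123))
  # hand evaluation of the x < y branch
  expect_equal(pbiw(1, 2, p), exp(-1.5) * exp(-0.5), tolerance = 1e-12)
  # independence limit factorises
  p0 <- biw_params(1.2, 0.5, 1, 0)
  expect_equal(pbiw(0.8, 1.7, p0),
               piw(0.8, 1.2, 0.5) * piw(1.7, 1.2, 1))
  # swap symmetry
  ps <- biw_params(1.3, 0.7, 0.2, 0.9)
  pr <- biw_params(1.3, 0.2, 0.7, 0.9)
  expect_equal(pbiw(0.6, 1.4, ps), pbiw(1.4, 0.6, pr))
  # marginal limits
  expect_equal(pbiw(0.9, 1e9, p), piw(0.9, p$alpha, p$lam13),
               tolerance = 1e-9)
  expect_equal(pbiw(1e9, 0.9, p), piw(0.9, p$alpha, p$lam23),
               tolerance = 1e-9)
  expect_error(pbiw(-1, 1, p), "positive")
})

test_that("joint density matches hand values, regions and the cdf", {
  p <- biw_params(1, 0.5, 1, 1)
  d <- dbiw(1, 2, p)
  # lam13 * lam2 * alpha^2 * x^(-2) * y^(-2) * exp(-lam13*1 - lam2*0.5)
  expect_equal(d$density, 1.5 * 1 * 0.25 * exp(-2), tolerance = 1e-12)
  expect_equal(d$region, "x<y")
  # swap symmetry of the two continuous branches
  ps <- biw_params(1.4, 0.3, 1.1, 0.6)
  pr <- biw_params(1.4, 1.1, 0.3, 0.6)
  expect_equal(dbiw(0.5, 1.8, ps)$density, dbiw(1.8, 0.5, pr)$density)
  expect_equal(dbiw(0.5, 0.5, ps)$region, "x=y")
  # mixed partial of the cdf equals the off-diagonal density
  set.seed(4)
  for (i in 1:10) {
    x <- runif(1, 0.3, 3); y <- runif(1, 0.3, 3)
    if (abs(x - y) < 0.05) y <- y + 0.1
    e <- 1e-4
    num <- (pbiw(x + e, y + e, p) - pbiw(x + e, y - e, p) -
              pbiw(x - e, y + e, p) + pbiw(x - e, y - e, p)) / (4 * e^2)
    expect_equal(dbiw(x, y, p)$density, num, tolerance = 1e-4)
  }
  expect_error(dbiw(0, 1, p), "positive")
})

test_that("continuous and singular parts sum to unit mass", {
  p <- biw_params(1, 0.5, 1, 1)
  # map both coordinates through u = 1/(1+x) so the slowly decaying tails
  # become a proper integral on the unit square
  back <- function(u) (1 - u) / u
  jac <- function(u) 1 / u^2
  cont <- function(ux, uy) {
    x <- back(ux); y <- back(uy)
    dbiw(x, y, p)$density * jac(ux) * jac(uy)
  }
  off <- stats::integrate(function(ux) {
    vapply(ux, function(u) {
      stats::integrate(function(uy) cont(u, uy), 0, 1,
                       rel.tol = 1e-9)$value
    }, numeric(1))
  }, 0, 1, rel.tol = 1e-7)$value
  diag_mass <- stats::integrate(function(u) {
    t <- back(u)
    dbiw(t, t, p)$density * jac(u)
  }, 0, 1, rel.tol = 1e-9)$value
  expect_equal(off + diag_mass, 1, tolerance = 1e-4)
  expect_equal(diag_mass, biw_singular_mass(p), tolerance = 1e-6)
})

test_that("singular mass follows the exponential-minimum identity", {
  expect_equal(biw_singular_mass(biw_params(1, 0.5, 1, 1)), 0.4)
  expect_equal(biw_singular_mass(biw_params(2, 1, 2, 0)), 0)
  # comonotone limit: lam1 = lam2 -> 0
  expect_equal(biw_singular_mass(biw_params(1, 1e-12, 1e-12, 1)), 1,
               tolerance = 1e-9)
})

test_that("parameter constructor validates its domain", {
  p <- biw_params(1.5, 0.2, 0.8, 0.4)
  expect_equal(p$lam13, 0.6)
  expect_equal(p$lam23, 1.2)
  expect_equal(p$lam123, 1.4)
  expect_error(biw_params(0, 1, 1, 1), "positive")
  expect_error(biw_params(1, -1, 1, 1), "positive")
  expect_error(biw_params(1, 1, 1, -0.1), "nonnegative")
})
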