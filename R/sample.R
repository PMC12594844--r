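#' Event indicators for a bivariate pair
#'
#' Each observation of the BIW model falls in exactly one of three regions:
#' `delta1 = 1` when `x < y`, `delta2 = 1` when `x > y`, and `delta3 = 1` on
#' the diagonal `x == y` (exact equality; simulated ties are exact because
#' both coordinates equal the stored common-shock draw).
#'
#' @param x,y Positive numeric vectors of equal length.
#' @param tie_tol Nonnegative tolerance for declaring a tie in ingested real
#'   data; the default `0` requires exact equality.
#' @return A tibble with integer columns `delta1`, `delta2`, `delta3`.
#' @examples
#' biw_indicators(c(1, 2, 1.5), c(2, 1, 1.5))
#' @export
biw_indicators <- function(x, y, tie_tol = 0) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  tie <- abs(x - y) <= tie_tol
  tibble::tibble(
    delta1 = as.integer(!tie & x < y),
    delta2 = as.integer(!tie & x > y),
    delta3 = as.integer(tie)
  )
}

# fast internal generators returning plain lists (used by the study engine)
sample_srs_raw <- function(n, params) {
  z1 <- (-params$lam1 / log(runif(n)))^(1 / params$alpha)
  z2 <- (-params$lam2 / log(runif(n)))^(1 / params$alpha)
  z3 <- (-params$lam3 / log(runif(n)))^(1 / params$alpha)
  x <- pmax(z1, z3)
  y <- pmax(z2, z3)
  d3 <- as.integer(x == y)
  d1 <- as.integer(x < y)
  list(x = x, y = y, d1 = d1, d2 = as.integer(1L - d1 - d3), d3 = d3,
       rank = rep.int(1L, n), m = 1L)
}

sample_rss_raw <- function(m, r, params) {
  x <- numeric(m * r); y <- numeric(m * r)
  idx <- 0L
  for (j in seq_len(r)) {
    s <- sample_srs_raw(m * m, params)
    xm <- matrix(s$x, nrow = m)          # column i = judgement set i
    ym <- matrix(s$y, nrow = m)
    for (i in seq_len(m)) {
      o <- order(xm[, i])[i]             # i-th order statistic of set i
      idx <- idx + 1L
      x[idx] <- xm[o, i]
      y[idx] <- ym[o, i]                 # concomitant travels with its x
    }
  }
  d3 <- as.integer(x == y)
  d1 <- as.integer(x < y)
  list(x = x, y = y, d1 = d1, d2 = as.integer(1L - d1 - d3), d3 = d3,
       rank = rep.int(seq_len(m), r), m = as.integer(m),
       cycle = rep(seq_len(r), each = m))
}

raw_to_tibble <- function(s, design) {
  out <- tibble::tibble(
    x = s$x, y = s$y,
    delta1 = s$d1, delta2 = s$d2, delta3 = s$d3
  )
  if (design == "rss") {
    out <- tibble::add_column(out, cycle = s$cycle, rank = s$rank,
                              .before = 1)
  } else {
    out <- tibble::add_column(out, index = seq_along(s$x), .before = 1)
  }
  new_biw_sample(out, design = design, m = s$m,
                 r = if (design == "rss") max(s$cycle) else NA_integer_)
}

new_biw_sample <- function(df, design, m, r) {
  structure(df,
            class = c("biw_sample", class(tibble::tibble())),
            design = design, m = as.integer(m),
            r = if (is.na(r)) NA_integer_ else as.integer(r))
}

#' Draw a bivariate simple random sample from the BIW model
#'
#' Inverse-transform sampling of the three latent inverse Weibull shocks:
#' \eqn{Z_k = (-\lambda_k / \log U_k)^{1/\alpha}} with \eqn{U_k} uniform,
#' then \eqn{X = \max(Z_1, Z_3)}, \eqn{Y = \max(Z_2, Z_3)} and the event
#' indicators of the three regions.
#'
#' @param n Sample size.
#' @param params A [biw_params()] object.
#' @return A `biw_sample` tibble with columns `index`, `x`, `y`, `delta1`,
#'   `delta2`, `delta3` and attributes `design = "srs"`, `m = 1`.
#' @examples
#' set.seed(1)
#' rbiw_srs(5, biw_params(1, 0.5, 1, 1))
#' @export
rbiw_srs <- function(n, params) {
  params <- as_biw_params(params)
  if (length(n) != 1 || n < 1) abort("`n` must be a positive integer")
  raw_to_tibble(sample_srs_raw(as.integer(n), params), "srs")
}

#' Draw a ranked set sample from the BIW model
#'
#' Per cycle, draws \eqn{m^2} pairs, partitions them into \eqn{m} judgement
#' sets of size \eqn{m}, ranks each set by the ranking variable `x`
#' (ascending, ties kept in draw order) and retains from set \eqn{i} the
#' \eqn{i}-th order statistic \eqn{X_{(i)}} together with its concomitant
#' \eqn{Y_{[i]}}. Repeated for `r` cycles, so `m * r` pairs are measured out
#' of `m^2 * r` drawn.
#'
#' @param m Set size.
#' @param r Number of cycles.
#' @inheritParams rbiw_srs
#' @return A `biw_sample` tibble with columns `cycle`, `rank`, `x`, `y`,
#'   `delta1`, `delta2`, `delta3` and attributes `design = "rss"`, `m`, `r`.
#' @examples
#' set.seed(1)
#' rbiw_rss(3, 2, biw_params(1, 0.5, 1, 1))
#' @export
rbiw_rss <- function(m, r, params) {
  params <- as_biw_params(params)
  if (length(m) != 1 || m < 1) abort("`m` must be a positive integer")
  if (length(r) != 1 || r < 1) abort("`r` must be a positive integer")
  raw_to_tibble(sample_rss_raw(as.integer(m), as.integer(r), params), "rss")
}

#' Coerce a data frame of pairs to a BIW sample
#'
#' Validates coordinates, computes (or recomputes) the event indicators and
#' attaches the design metadata used by the likelihood. RSS data must carry
#' `cycle` and `rank` columns; `m` defaults to the largest observed rank.
#'
#' @param data A data frame with numeric columns `x` and `y` (positive), and
#'   for `design = "rss"` integer columns `cycle` and `rank`.
#' @param design `"srs"` or `"rss"`.
#' @param m Set size for RSS data; defaults to `max(rank)`.
#' @param tie_tol Tie tolerance passed to [biw_indicators()].
#' @return A `biw_sample` tibble.
#' @export
as_biw_sample <- function(data, design = c("srs", "rss"), m = NULL,
                          tie_tol = 0) {
  design <- match.arg(design)
  if (!all(c("x", "y") %in% names(data))) {
    abort("`data` must contain columns `x` and `y`")
  }
  if (!is.numeric(data$x) || !is.numeric(data$y)) {
    abort("columns `x` and `y` must be numeric")
  }
  bad <- which(!is.finite(data$x) | !is.finite(data$y) |
                 data$x <= 0 | data$y <= 0)
  if (length(bad)) {
    abort(paste0("non-positive or non-numeric coordinates in rows: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  ind <- biw_indicators(data$x, data$y, tie_tol = tie_tol)
  if (design == "rss") {
    if (!all(c("cycle", "rank") %in% names(data))) {
      abort("RSS data must contain `cycle` and `rank` columns")
    }
    m <- m %||% max(data$rank)
    if (any(data$rank < 1 | data$rank > m)) {
      abort("`rank` values must lie in 1..m")
    }
    out <- tibble::tibble(cycle = as.integer(data$cycle),
                          rank = as.integer(data$rank),
                          x = data$x, y = data$y) |>
      dplyr::bind_cols(ind)
    new_biw_sample(out, "rss", m, max(out$cycle))
  } else {
    out <- tibble::tibble(index = seq_along(data$x),
                          x = data$x, y = data$y) |>
      dplyr::bind_cols(ind)
    new_biw_sample(out, "srs", 1L, NA_integer_)
  }
}

#' Event counts of a BIW sample
#'
#' @param data A `biw_sample` tibble (or any data frame with the indicator
#'   columns).
#' @return A one-row tibble with `n`, `n1`, `n2`, `n3` (indicator totals over
#'   all observations; for RSS these are totals over all ranks and cycles).
#' @export
biw_counts <- function(data) {
  tibble::tibble(
    n = nrow(data),
    n1 = sum(data$delta1), n2 = sum(data$delta2), n3 = sum(data$delta3)
  )
}

sample_to_raw <- function(data) {
  design <- attr(data, "design") %||% "srs"
  m <- attr(data, "m") %||% 1L
  rank <- if (design == "rss") as.integer(data$rank) else rep.int(1L, nrow(data))
  list(x = data$x, y = data$y,
       d1 = as.integer(data$delta1), d2 = as.integer(data$delta2),
       d3 = as.integer(data$delta3), rank = rank, m = as.integer(m))
}
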