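#' Read paired observations from CSV
#'
#' Reads a two-column (at minimum) CSV with numeric columns `x` (ranking /
#' concomitant variable) and `y` (study variable), validates positivity and
#' computes the event indicators. Real measurements rarely tie exactly;
#' `tie_tol` (default 0, i.e. exact equality only) lets users declare
#' near-ties as diagonal events. The number of detected ties is reported in
#' a message.
#'
#' @param path CSV file with a header row containing `x` and `y`.
#' @param tie_tol Tie tolerance, see [biw_indicators()].
#' @return A `biw_sample` tibble with `design = "srs"`.
#' @export
read_biw_pairs <- function(path, tie_tol = 0) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("x", "y") %in% names(df))) {
    abort(paste0("missing required columns `x` and `y` in ", path))
  }
  out <- as_biw_sample(df, design = "srs", tie_tol = tie_tol)
  nt <- sum(out$delta3)
  if (nt > 0) message(nt, " tied pair(s) assigned to the diagonal branch")
  out
}

#' Write a BIW sample to CSV
#'
#' Full-precision CSV with a header; RSS samples carry `cycle` and `rank`
#' columns, SRS samples an `index` column.
#'
#' @param data A `biw_sample` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biw_sample <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

#' Read a BIW sample back from CSV
#'
#' Counterpart of [write_biw_sample()]: restores the design metadata from
#' the column layout.
#'
#' @param path CSV written by [write_biw_sample()].
#' @return A `biw_sample` tibble.
#' @export
read_biw_sample <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  design <- if (all(c("cycle", "rank") %in% names(df))) "rss" else "srs"
  as_biw_sample(df, design = design)
}

#' Ranked-set resampling from a finite population table
#'
#' Applies the RSS construction to an observed population of pairs: per
#' cycle, `m^2` rows are drawn with replacement, partitioned into `m` sets
#' of `m`, each set is ranked by `x`, and the `i`-th ranked pair of set `i`
#' is retained. Useful for design comparisons on real paired data.
#'
#' @param data Data frame with numeric columns `x` and `y` (at least `m^2`
#'   rows).
#' @param m Set size.
#' @param r Number of cycles.
#' @return A `biw_sample` tibble with `design = "rss"`.
#' @export
rss_subsample <- function(data, m, r) {
  if (!all(c("x", "y") %in% names(data))) {
    abort("`data` must contain columns `x` and `y`")
  }
  if (nrow(data) < m * m) {
    abort("`data` must have at least m^2 rows")
  }
  x <- numeric(m * r); y <- numeric(m * r)
  idx <- 0L
  for (j in seq_len(r)) {
    rows <- sample.int(nrow(data), m * m, replace = TRUE)
    xm <- matrix(data$x[rows], nrow = m)
    ym <- matrix(data$y[rows], nrow = m)
    for (i in seq_len(m)) {
      o <- order(xm[, i])[i]
      idx <- idx + 1L
      x[idx] <- xm[o, i]
      y[idx] <- ym[o, i]
    }
  }
  as_biw_sample(
    tibble::tibble(cycle = rep(seq_len(r), each = m),
                   rank = rep(seq_len(m), r), x = x, y = y),
    design = "rss", m = m
  )
}
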