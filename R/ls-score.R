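#' Center a series at zero
#'
#' Subtracts the sample mean. Centering is a required preprocessing step for
#' the local-similarity significance approximations, which assume mean-zero
#' weakly stationary series.
#'
#' @param x Numeric vector (a single time series).
#' @return Numeric vector with sample mean 0.
#' @examples
#' center(c(1, 2, 3))
#' @export
center <- function(x) {
  check_series(x, "x", min_len = 1L)
  x - mean(x)
}

#' Standardize a series to mean zero and unit variance
#'
#' Uses the 1/n variance convention (population-style), matching the variance
#' convention used throughout the package's autocovariance computations.
#' Intended for abundance tables where series live on very different scales;
#' the dependent-data LSA p-values themselves are invariant to positive
#' per-series scaling, so standardization mainly aids interpretation of
#' scores and plots.
#'
#' @param x Numeric vector of length >= 2 with positive variance.
#' @return Numeric vector with mean 0 and 1/n-variance 1.
#' @examples
#' standardize(c(0, 2))
#' @export
standardize <- function(x) {
  check_series(x, "x", min_len = 2L)
  v <- mean((x - mean(x))^2)
  if (v <= 0) {
    abort("Cannot standardize a zero-variance series.",
          class = "deplsa_error_degenerate")
  }
  (x - mean(x)) / sqrt(v)
}

new_lsa_alignment <- function(parts, n, max_delay) {
  structure(
    list(score = parts$score, delay = as.integer(parts$delay),
         start_x = as.integer(parts$start_x), start_y = as.integer(parts$start_y),
         length = as.integer(parts$length), sign = as.integer(parts$sign),
         n = as.integer(n), max_delay = as.integer(max_delay)),
    class = "lsa_alignment")
}

#' Local similarity score of two time series
#'
#' Computes the local similarity (LS) score `s_D`: the maximum, over all
#' pairs of equal-length aligned subintervals whose starting positions differ
#' by at most `max_delay`, and over both association signs, of the absolute
#' sum of pointwise products. The dynamic programme keeps positive and
#' negative accumulators per alignment diagonal (a Smith-Waterman-style local
#' alignment of the product series) and runs in O(n * (2D+1)).
#'
#' The score is the *unnormalized* maximal partial sum: the significance
#' tests later form the statistic `s_D / (scale * sqrt(n))`. No centering is
#' applied here; the test wrappers ([ddlsa_test()], [tlsa_test()]) center
#' explicitly.
#'
#' Positions are reported 1-based. The delay is `start_y - start_x`, so a
#' positive delay means `x` leads `y`. When several alignments achieve the
#' maximal score the lexicographically smallest `(delay, start_x, length)` is
#' reported (positive sign preferred on a full tie), so results are
#' deterministic.
#'
#' @param x,y Numeric vectors of equal length n >= 2, no missing values.
#' @param max_delay Maximum offset D (nonnegative integer < n) between the
#'   two interval start positions.
#' @return An object of class `lsa_alignment`: a list with elements `score`,
#'   `delay`, `start_x`, `start_y`, `length`, `sign`, `n`, `max_delay`.
#'   Use [tidy()] to get a one-row tibble.
#' @seealso [ls_score_bruteforce()] for the exhaustive reference
#'   implementation used in verification.
#' @examples
#' ls_score(c(1, -1, 2), c(1, 1, 1), max_delay = 0)
#' @export
ls_score <- function(x, y, max_delay = 0) {
  n <- check_pair(x, y)
  D <- check_delay(max_delay, n)
  new_lsa_alignment(cpp_ls_score(as.double(x), as.double(y), D), n, D)
}

#' Exhaustive local similarity score (reference implementation)
#'
#' Enumerates every admissible `(start_x, start_y, length, sign)` combination
#' and returns the maximal absolute aligned product sum. This is the
#' brute-force oracle against which the dynamic programme is verified; it is
#' quadratic and refuses series longer than `max_n`.
#'
#' @inheritParams ls_score
#' @param max_n Refuse inputs longer than this (cost guard).
#' @return An `lsa_alignment`, identical in contract to [ls_score()].
#' @export
ls_score_bruteforce <- function(x, y, max_delay = 0, max_n = 100) {
  n <- check_pair(x, y)
  D <- check_delay(max_delay, n)
  if (n > max_n) {
    abort(sprintf("Series length %d exceeds the brute-force cap max_n = %d.",
                  n, max_n), class = "deplsa_error_size")
  }
  # lexicographic tie-break on (delay, start_x, length), positive sign
  # preferred on a full tie; mirrors the dynamic programme's rule
  better <- function(cand, cur) {
    if (cand$score != cur$score) return(cand$score > cur$score)
    if (cand$delay != cur$delay) return(cand$delay < cur$delay)
    if (cand$start_x != cur$start_x) return(cand$start_x < cur$start_x)
    if (cand$length != cur$length) return(cand$length < cur$length)
    cand$sign > cur$sign
  }
  best <- list(score = 0, delay = 0L, start_x = 1L, start_y = 1L,
               length = 0L, sign = 1L)
  for (d in -D:D) {                      # delay = start_y - start_x
    for (sx in seq_len(n)) {
      sy <- sx + d
      if (sy < 1 || sy > n) next
      L <- n - max(sx, sy) + 1L
      sums <- cumsum(x[sx:(sx + L - 1L)] * y[sy:(sy + L - 1L)])
      for (len in seq_len(L)) {
        if (sums[len] == 0) next   # zero-sum intervals are not alignments
        cand <- list(score = abs(sums[len]), delay = d, start_x = sx,
                     start_y = sy, length = len,
                     sign = if (sums[len] >= 0) 1L else -1L)
        if (better(cand, best)) best <- cand
      }
    }
  }
  new_lsa_alignment(best, n, D)
}

#' @export
print.lsa_alignment <- function(x, ...) {
  cat("Local similarity alignment\n")
  cat(sprintf("  score s_D = %.6g (%s association), D = %d\n",
              x$score, if (x$sign > 0) "positive" else "negative", x$max_delay))
  cat(sprintf("  x[%d..%d] ~ y[%d..%d]  (length %d, delay %d)\n",
              x$start_x, x$start_x + x$length - 1L,
              x$start_y, x$start_y + x$length - 1L, x$length, x$delay))
  invisible(x)
}

#' @method tidy lsa_alignment
#' @export
tidy.lsa_alignment <- function(x, ...) {
  tibble::tibble(score = x$score, delay = x$delay, start_x = x$start_x,
                 start_y = x$start_y, length = x$length, sign = x$sign,
                 n = x$n, max_delay = x$max_delay)
}
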