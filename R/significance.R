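method_labels <- c(tlsa = "TLSA", ddlsa = "DDLSA", permutation = "permutation",
                   pcc = "PCC", srcc = "SRCC", lsares_ar = "LSAres-AR",
                   lsares_arma = "LSAres-ARMA")

new_lsa_test <- function(method, score, statistic, p_value, n,
                         alignment = NULL, variance = NULL, flag = NULL,
                         fits = NULL) {
  structure(list(method = method, score = score, statistic = statistic,
                 p_value = p_value, n = as.integer(n), alignment = alignment,
                 variance = variance, flag = flag, fits = fits),
            class = "lsa_test")
}

#' @export
print.lsa_test <- function(x, ...) {
  cat(sprintf("%s association test (n = %d)\n", x$method, x$n))
  cat(sprintf("  score = %.6g, statistic = %.6g, p-value = %.4g\n",
              x$score, x$statistic, x$p_value))
  if (!is.null(x$alignment)) {
    a <- x$alignment
    cat(sprintf("  aligned x[%d..%d] ~ y[%d..%d], delay %d, %s\n",
                a$start_x, a$start_x + a$length - 1L,
                a$start_y, a$start_y + a$length - 1L, a$delay,
                if (a$sign > 0) "positive" else "negative"))
  }
  if (!is.null(x$flag)) cat("  note:", x$flag, "\n")
  invisible(x)
}

#' @rdname lsa_test_methods
#' @param x An `lsa_test` object.
#' @param ... Unused.
#' @method tidy lsa_test
#' @export
tidy.lsa_test <- function(x, ...) {
  a <- x$alignment
  tibble::tibble(
    method = x$method, score = x$score, statistic = x$statistic,
    p_value = x$p_value, n = x$n,
    delay = if (is.null(a)) NA_integer_ else a$delay,
    start_x = if (is.null(a)) NA_integer_ else a$start_x,
    start_y = if (is.null(a)) NA_integer_ else a$start_y,
    length = if (is.null(a)) NA_integer_ else a$length,
    sign = if (is.null(a)) NA_integer_ else a$sign)
}

#' Accessor methods for association test results
#'
#' `tidy()` returns a one-row tibble with the score, statistic, p-value and
#' (when the method aligns intervals) the maximizing alignment; `glance()`
#' adds the variance diagnostics (estimate kind, bandwidth, AR(1) plug-in
#' coefficient) used to scale the statistic.
#'
#' @name lsa_test_methods
#' @method glance lsa_test
#' @export
glance.lsa_test <- function(x, ...) {
  v <- x$variance
  tibble::tibble(
    method = x$method, p_value = x$p_value, n = x$n,
    omega_sq = if (is.null(v)) NA_real_ else v$omega_sq,
    variance_kind = if (is.null(v)) NA_character_ else v$kind,
    bandwidth = if (is.null(v)) NA_integer_ else v$bandwidth,
    phi_hat = if (is.null(v)) NA_real_ else v$phi_hat,
    floored = if (is.null(v)) NA else v$floored)
}

lsa_tail_test <- function(x, y, max_delay, variance_fun, method) {
  n <- check_pair(x, y, min_len = 4L)
  D <- check_delay(max_delay, n)
  xc <- x - mean(x)
  yc <- y - mean(y)
  check_nondegenerate(xc, yc)
  aln <- ls_score(xc, yc, D)
  v <- variance_fun(xc, yc)
  stat <- aln$score / sqrt(v$omega_sq * n)
  new_lsa_test(method, aln$score, stat, ld_tail(stat, D), n,
               alignment = aln, variance = v,
               flag = if (v$floored) "variance floored at positivity threshold")
}

#' Theoretical LSA significance (i.i.d. assumption)
#'
#' Centers both series, computes the LS score `s_D`, and evaluates the tail
#' probability [ld_tail()] at `s_D / (sigma_hat sqrt(n))` where `sigma_hat^2`
#' is the i.i.d. product-series variance [iid_variance()]. Anti-conservative
#' when the series are autocorrelated; see [ddlsa_test()].
#'
#' @param x,y Numeric series of equal length (n >= 4), no missing values.
#' @param max_delay Maximum interval start offset D.
#' @return An object of class `lsa_test`.
#' @examples
#' set.seed(1)
#' tlsa_test(rnorm(50), rnorm(50), max_delay = 2)
#' @export
tlsa_test <- function(x, y, max_delay = 0) {
  lsa_tail_test(x, y, max_delay, iid_variance, "TLSA")
}

#' Data-driven LSA significance for dependent series
#'
#' The dependent-data test: centers both series, computes the LS score
#' `s_D`, and evaluates [ld_tail()] at `s_D / (omega_hat sqrt(n))` where
#' `omega_hat^2` is the Bartlett-kernel long-run variance of the product
#' series ([longrun_variance()]). Under weak stationarity this controls the
#' type I error even when both series are strongly autocorrelated, unlike
#' [tlsa_test()] or [permutation_test()]. The p-value is invariant to
#' positive per-series rescaling (score and scale cancel).
#'
#' @inheritParams tlsa_test
#' @return An object of class `lsa_test`.
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = 0.5), 100))
#' y <- as.numeric(arima.sim(list(ar = 0.5), 100))
#' ddlsa_test(x, y)
#' @export
ddlsa_test <- function(x, y, max_delay = 0) {
  lsa_tail_test(x, y, max_delay, longrun_variance, "DDLSA")
}

#' Permutation significance of the LS score
#'
#' Fixes `y`, uniformly reshuffles `x` `n_perm` times, and reports the
#' fraction of permuted LS scores at least as large as the observed one
#' (the plain fraction; set `add_one = TRUE` for the never-zero
#' `(b + 1)/(N + 1)` variant). Valid only for independent observations:
#' permutation destroys autocorrelation, so the test is oversized for
#' dependent series.
#'
#' @inheritParams tlsa_test
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed; the permutation stream is then
#'   reproducible and the caller's RNG state is left untouched.
#' @param add_one Use the `(b + 1)/(N + 1)` correction (default `FALSE`).
#' @return An object of class `lsa_test`.
#' @export
permutation_test <- function(x, y, max_delay = 0, n_perm = 1000, seed = NULL,
                             add_one = FALSE) {
  n <- check_pair(x, y)
  D <- check_delay(max_delay, n)
  if (length(n_perm) != 1 || is.na(n_perm) || n_perm < 1) {
    abort("`n_perm` must be a positive integer.", class = "deplsa_error_param")
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  obs <- ls_score(xc, yc, D)
  perm <- with_seed(seed,
                    cpp_perm_scores(as.double(xc), as.double(yc), D,
                                    as.integer(n_perm)))
  b <- sum(perm >= obs$score)
  p <- if (add_one) (b + 1) / (n_perm + 1) else b / n_perm
  new_lsa_test("permutation", obs$score, obs$score, p, n, alignment = obs)
}

correlation_t_test <- function(x, y, r, method) {
  n <- length(x)
  flag <- NULL
  if (abs(r) >= 1 - 1e-12) {   # perfect up to correlation round-off
    stat <- sign(r) * Inf
    p <- 0
    flag <- "perfect correlation: statistic infinite"
  } else {
    stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(abs(stat), df = n - 2, lower.tail = FALSE)
  }
  new_lsa_test(method, r, stat, p, n, flag = flag)
}

#' Pearson and Spearman correlation tests
#'
#' Whole-series (global) association baselines: the correlation `r` (for
#' SRCC, the Pearson correlation of midranks) with the two-sided p-value of
#' `t = r sqrt((n-2)/(1-r^2))` against a Student t distribution with `n - 2`
#' degrees of freedom. A perfect correlation gives `p = 0` with a flag.
#' These assume i.i.d. observations and are oversized under autocorrelation.
#'
#' @param x,y Numeric series of equal length n >= 3, positive variance.
#' @return An object of class `lsa_test` whose `score` is the correlation.
#' @export
pcc_test <- function(x, y) {
  check_pair(x, y, min_len = 3L)
  check_nondegenerate(x, y)
  correlation_t_test(x, y, cor(x, y), "PCC")
}

#' @rdname pcc_test
#' @export
srcc_test <- function(x, y) {
  check_pair(x, y, min_len = 3L)
  rx <- rank(x)
  ry <- rank(y)
  check_nondegenerate(rx, ry)
  correlation_t_test(x, y, cor(rx, ry), "SRCC")
}

#' Ljung-Box test for autocorrelation
#'
#' Portmanteau screen used to decide whether a series is autocorrelated
#' (and hence whether the i.i.d.-based significance methods are trustworthy
#' for it): `Q = n(n+2) sum_{k=1}^h rho_hat(k)^2 / (n-k)` against a
#' chi-square with `h` degrees of freedom. Delegates to
#' [stats::Box.test()] after validating the input.
#'
#' @param x Numeric series, positive variance.
#' @param max_lag Number of autocorrelation lags h (default 10), `< n`.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
ljung_box_test <- function(x, max_lag = 10) {
  check_series(x, "x", min_len = 3L)
  n <- length(x)
  if (length(max_lag) != 1 || is.na(max_lag) || max_lag < 1 || max_lag >= n) {
    abort("`max_lag` must be an integer in [1, n - 1].",
          class = "deplsa_error_param")
  }
  if (mean((x - mean(x))^2) <= 0) {
    abort("Constant series: autocorrelation is undefined.",
          class = "deplsa_error_degenerate")
  }
  bt <- Box.test(x, lag = as.integer(max_lag), type = "Ljung-Box")
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p_value = unname(bt$p.value))
}
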