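check_coef <- function(value, name) {
  if (length(value) != 1 || is.na(value) || abs(value) >= 1) {
    abort(sprintf("`%s` must be a single value in (-1, 1).", name),
          class = "deplsa_error_param")
  }
  value
}

as_pair_tibble <- function(pair) {
  tibble::tibble(time = seq_along(pair$x), x = pair$x, y = pair$y)
}

# fast internal generators returning list(x, y) -------------------------------

sim_null_pair <- function(model, rho1, rho2, n, burn_in = 100L) {
  N <- burn_in + n
  keep <- (burn_in + 1L):N
  if (model == "ar1") {
    x <- stats::filter(rnorm(N), rho1, method = "recursive", init = rnorm(1))
    y <- stats::filter(rnorm(N), rho2, method = "recursive", init = rnorm(1))
    return(list(x = as.numeric(x)[keep], y = as.numeric(y)[keep]))
  }
  ex <- rnorm(N)
  # ARMA(1,1) innovations: add 0.5 * previous innovation, then AR-filter
  x <- stats::filter(ex + 0.5 * c(rnorm(1), ex[-N]), rho1,
                     method = "recursive", init = rnorm(1))
  if (model == "arma11") {
    ey <- rnorm(N)
    y <- stats::filter(ey + 0.5 * c(rnorm(1), ey[-N]), rho2,
                       method = "recursive", init = rnorm(1))
    return(list(x = as.numeric(x)[keep], y = as.numeric(y)[keep]))
  }
  # arma11_tar1: Y is threshold AR(1), coefficient rho2 below the
  # threshold -1 and 0.5 above, no MA part
  ey <- rnorm(N)
  y <- numeric(N)
  y[1] <- rnorm(1)
  for (t in 2:N) {
    y[t] <- if (y[t - 1] <= -1) rho2 * y[t - 1] + ey[t] else 0.5 * y[t - 1] + ey[t]
  }
  list(x = as.numeric(x)[keep], y = y[keep])
}

middle_window <- function(n, frac_p) {
  m <- floor(n * frac_p)
  start <- floor((n - m) / 2) + 1L
  c(start = start, end = start + m - 1L, m = m)
}

sim_local_ar_pair <- function(rho1, rho, frac_p, n) {
  sigma_sq <- (1 - rho^2) / rho^2
  # X: stationary AR(1) with unit marginal variance, no burn-in needed
  ex <- c(rnorm(1), rnorm(n - 1, sd = sqrt(1 - rho1^2)))
  x <- as.numeric(stats::filter(ex, rho1, method = "recursive"))
  w <- middle_window(n, frac_p)
  rho2 <- rho1 / (1 + sigma_sq)
  sd2 <- sqrt(1 - rho2^2)
  y <- numeric(n)
  inside <- seq_len(n) >= w["start"] & seq_len(n) <= w["end"]
  for (t in seq_len(n)) {
    if (inside[t]) {
      y[t] <- (x[t] + rnorm(1, sd = sqrt(sigma_sq))) / sqrt(1 + sigma_sq)
    } else if (t == 1L) {
      y[t] <- rnorm(1)
    } else {
      y[t] <- rho2 * y[t - 1] + rnorm(1, sd = sd2)
    }
  }
  list(x = x, y = y)
}

sim_bivariate_ar_pair <- function(rho1, rho2, rho, frac_p, n) {
  r_t <- (1 - rho1 * rho2) * rho / sqrt((1 - rho1^2) * (1 - rho2^2))
  if (abs(r_t) > 1) {
    abort(sprintf(
      "Infeasible innovation correlation %.4f (must lie in [-1, 1]).", r_t),
      class = "deplsa_error_param")
  }
  w <- middle_window(n, frac_p)
  inside <- seq_len(n) >= w["start"] & seq_len(n) <= w["end"]
  # innovation pairs: jointly normal, correlated only inside the window
  r1 <- if (inside[1]) rho else 0
  ex <- numeric(n)
  ey <- numeric(n)
  ex[1] <- rnorm(1)
  ey[1] <- r1 * ex[1] + sqrt(1 - r1^2) * rnorm(1)
  if (n > 1) {
    z1 <- rnorm(n - 1)
    z2 <- rnorm(n - 1)
    rt <- ifelse(inside[-1], r_t, 0)
    ex[-1] <- sqrt(1 - rho1^2) * z1
    ey[-1] <- sqrt(1 - rho2^2) * (rt * z1 + sqrt(1 - rt^2) * z2)
  }
  list(x = as.numeric(stats::filter(ex, rho1, method = "recursive")),
       y = as.numeric(stats::filter(ey, rho2, method = "recursive")))
}

# exported, validating wrappers ----------------------------------------------

#' Simulate an unassociated pair of stationary series (null models)
#'
#' Generates independent `x` and `y` from one of three null models used to
#' study the size of the association tests:
#' \describe{
#'   \item{`"ar1"`}{AR(1): `X_t = rho1 X_{t-1} + e_t` (and likewise `y` with
#'     `rho2`), standard normal innovations.}
#'   \item{`"arma11"`}{ARMA(1,1) with MA coefficient 0.5 on both series.
#'     With `rho1 = rho2 = -0.5` the AR and MA parts cancel and the series
#'     are white noise.}
#'   \item{`"arma11_tar1"`}{`x` as in `"arma11"`; `y` is threshold AR(1):
#'     coefficient `rho2` when `Y_{t-1} <= -1`, otherwise 0.5.}
#' }
#' Each recursion starts from a standard normal draw and the first
#' `burn_in` samples are discarded, so the retained length-`n` series are
#' approximately stationary.
#'
#' @param model One of `"ar1"`, `"arma11"`, `"arma11_tar1"`.
#' @param rho1,rho2 Autoregressive coefficients in (-1, 1).
#' @param n Output series length.
#' @param burn_in Number of initial samples to discard (default 100).
#' @param seed Optional integer seed (leaves the caller's RNG untouched).
#' @return A tibble with columns `time`, `x`, `y`.
#' @examples
#' simulate_null("ar1", rho1 = 0.5, rho2 = 0.5, n = 100, seed = 1)
#' @export
simulate_null <- function(model = c("ar1", "arma11", "arma11_tar1"),
                          rho1, rho2, n, burn_in = 100, seed = NULL) {
  model <- match.arg(model)
  check_coef(rho1, "rho1")
  check_coef(rho2, "rho2")
  stopifnot(n >= 1, burn_in >= 0)
  as_pair_tibble(with_seed(seed, sim_null_pair(model, rho1, rho2, n,
                                               as.integer(burn_in))))
}

#' Simulate a locally associated pair (local AR alternative)
#'
#' `x` is a stationary AR(1) with coefficient `rho1` and unit marginal
#' variance. In the middle `floor(n * frac_p)` time points,
#' `Y_t = (X_t + xi_t) / sqrt(1 + sigma^2)` with `xi_t ~ N(0, sigma^2)` and
#' `sigma^2 = (1 - rho^2)/rho^2`, so that `cor(X_t, Y_t) = rho` inside the
#' window; outside it, `y` follows an independent AR(1) with coefficient
#' `rho1 / (1 + sigma^2)` and unit marginal variance. The window is placed
#' symmetrically, starting at `floor((n - m)/2) + 1` (1-based).
#'
#' @param rho1 AR coefficient of `x`, in (-1, 1).
#' @param rho Within-window correlation, in (-1, 1), nonzero.
#' @param frac_p Correlated fraction of the series, in (0, 1].
#' @inheritParams simulate_null
#' @return A tibble with columns `time`, `x`, `y`.
#' @export
simulate_local_ar <- function(rho1, rho, frac_p, n, seed = NULL) {
  check_coef(rho1, "rho1")
  check_coef(rho, "rho")
  if (rho == 0) {
    abort("`rho` must be nonzero (the noise variance (1 - rho^2)/rho^2 is undefined at 0).",
          class = "deplsa_error_param")
  }
  if (length(frac_p) != 1 || is.na(frac_p) || frac_p <= 0 || frac_p > 1 ||
      floor(n * frac_p) < 1) {
    abort("`frac_p` must lie in (0, 1] with floor(n * frac_p) >= 1.",
          class = "deplsa_error_param")
  }
  as_pair_tibble(with_seed(seed, sim_local_ar_pair(rho1, rho, frac_p, n)))
}

#' Simulate a locally associated pair (bivariate AR alternative)
#'
#' Both series are AR(1) recursions (`rho1`, `rho2`) with jointly normal
#' innovations. Inside the middle `floor(n * frac_p)` window the innovation
#' pairs are correlated — `cor(e_1^X, e_1^Y) = rho` at the first point and
#' `(1 - rho1 rho2) rho / sqrt((1 - rho1^2)(1 - rho2^2))` thereafter — which
#' makes the stationary series correlation equal `rho` with unit marginal
#' variances; outside the window the innovations are independent. With
#' `rho = 0` this reduces exactly to two independent AR(1) series.
#'
#' @inheritParams simulate_local_ar
#' @param rho2 AR coefficient of `y`, in (-1, 1).
#' @param rho Within-window series correlation (the implied innovation
#'   correlation must lie in `[-1, 1]`, otherwise an error reports it).
#' @return A tibble with columns `time`, `x`, `y`.
#' @export
simulate_bivariate_ar <- function(rho1, rho2, rho, frac_p, n, seed = NULL) {
  check_coef(rho1, "rho1")
  check_coef(rho2, "rho2")
  if (length(rho) != 1 || is.na(rho) || abs(rho) > 1) {
    abort("`rho` must lie in [-1, 1].", class = "deplsa_error_param")
  }
  if (length(frac_p) != 1 || is.na(frac_p) || frac_p <= 0 || frac_p > 1 ||
      floor(n * frac_p) < 1) {
    abort("`frac_p` must lie in (0, 1] with floor(n * frac_p) >= 1.",
          class = "deplsa_error_param")
  }
  as_pair_tibble(with_seed(seed, sim_bivariate_ar_pair(rho1, rho2, rho,
                                                       frac_p, n)))
}
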