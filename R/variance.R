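#' Sample autocovariance with the 1/n convention
#'
#' \deqn{\hat\gamma(k) = \frac{1}{n}\sum_{j=1}^{n-|k|}
#'   (v_j - \bar v)(v_{j+|k|} - \bar v)}
#' Note the divisor is `n`, not `n - k`: this biased form keeps the Bartlett
#' long-run variance estimate positive semi-definite.
#'
#' @param x Numeric vector.
#' @param lag Integer vector of lags, each with `|lag| <= n - 1`.
#' @return Numeric vector of autocovariances, one per lag.
#' @examples
#' sample_autocovariance(c(1, 2, 3), 0:1)
#' @export
sample_autocovariance <- function(x, lag) {
  check_series(x, "x", min_len = 1L)
  n <- length(x)
  lag <- abs(as.integer(lag))
  if (any(is.na(lag)) || any(lag >= n)) {
    abort("Each |lag| must be at most n - 1.", class = "deplsa_error_param")
  }
  m <- mean(x)
  vapply(lag, function(k) {
    sum((x[seq_len(n - k)] - m) * (x[seq_len(n - k) + k] - m)) / n
  }, numeric(1))
}

new_variance_estimate <- function(omega_sq, kind, bandwidth = 0L,
                                  phi_hat = NA_real_, tau_hat = NA_real_,
                                  floored = FALSE) {
  structure(list(omega_sq = omega_sq, kind = kind,
                 bandwidth = as.integer(bandwidth), phi_hat = phi_hat,
                 tau_hat = tau_hat, floored = floored),
            class = "lsa_variance")
}

#' @export
print.lsa_variance <- function(x, ...) {
  cat(sprintf("%s variance estimate: %.6g", x$kind, x$omega_sq))
  if (x$kind == "long_run") {
    cat(sprintf("  (bandwidth %d, phi_hat %.3f)", x$bandwidth, x$phi_hat))
  }
  if (x$floored) cat("  [positivity floor applied]")
  cat("\n")
  invisible(x)
}

#' @method tidy lsa_variance
#' @export
tidy.lsa_variance <- function(x, ...) {
  tibble::tibble(omega_sq = x$omega_sq, kind = x$kind, bandwidth = x$bandwidth,
                 phi_hat = x$phi_hat, tau_hat = x$tau_hat, floored = x$floored)
}

check_nondegenerate <- function(x, y) {
  if (mean((x - mean(x))^2) <= 0 || mean((y - mean(y))^2) <= 0) {
    abort("Zero-variance series: local similarity significance is undefined.",
          class = "deplsa_error_degenerate")
  }
}

#' Long-run variance of the product series (Bartlett kernel, AR(1) plug-in)
#'
#' Estimates the long-run variance
#' `omega^2 = lim var(sum Z_i) / n` of the product series `Z_t = x_t y_t`
#' under the null of no association between two centered, weakly stationary
#' series. The null factorization `gamma_z(k) ~ gamma_x(k) gamma_y(k)`
#' gives the Bartlett-weighted estimate
#' \deqn{\hat\omega_n^2 = \hat\gamma_x(0)\hat\gamma_y(0) +
#'   2\sum_{k=1}^{b_w}(1 - k/b_w)\,\hat\gamma_x(k)\hat\gamma_y(k),}
#' with the bandwidth chosen by Andrews' AR(1) plug-in rule: an AR(1)
#' coefficient `phi_hat` is fitted to the demeaned products
#' `u_t = Z_t - mean(Z)`, `tau_hat = 4 phi_hat^2 / (1 - phi_hat^2)^2`, and
#' `b_w = floor(1.1447 (tau_hat n)^{1/3})`, clamped to `[0, n - 1]`.
#'
#' Numerical safeguards: `phi_hat` is clamped to `[-0.97, 0.97]` (the
#' bandwidth rule explodes as `|phi| -> 1`) and the estimate is floored at
#' `1e-3 * gamma_x(0) gamma_y(0)` since the truncated kernel sum can go
#' nonpositive in pathological samples; the flag `floored` records this.
#' When `b_w = 0` the sum is empty and the estimate reduces to
#' `gamma_x(0) gamma_y(0)`.
#'
#' @param x,y Centered numeric vectors of equal length n >= 4.
#' @return An object of class `lsa_variance` with elements `omega_sq`,
#'   `kind = "long_run"`, `bandwidth`, `phi_hat`, `tau_hat`, `floored`.
#' @export
longrun_variance <- function(x, y) {
  n <- check_pair(x, y, min_len = 4L)
  check_nondegenerate(x, y)
  z <- x * y
  u <- z - mean(z)
  den <- sum(u[-1]^2)
  phi <- if (den > 0) sum(u[-1] * u[-n]) / den else 0
  phi <- max(-0.97, min(0.97, phi))
  tau <- 4 * phi^2 / (1 - phi^2)^2
  bw <- min(n - 1L, max(0L, as.integer(floor(1.1447 * (tau * n)^(1 / 3)))))
  g0 <- sample_autocovariance(x, 0) * sample_autocovariance(y, 0)
  omega_sq <- g0
  if (bw >= 1L) {
    k <- seq_len(bw)
    omega_sq <- g0 + 2 * sum((1 - k / bw) * sample_autocovariance(x, k) *
                               sample_autocovariance(y, k))
  }
  floor_val <- 1e-3 * g0
  floored <- omega_sq < floor_val
  new_variance_estimate(max(omega_sq, floor_val), "long_run", bw, phi, tau,
                        floored)
}

#' Product-series variance under the i.i.d. assumption
#'
#' The classical (theoretical LSA) scale: `sigma^2 = var(X_t Y_t)` computed
#' with the 1/n convention on the product series. Valid only when both
#' series are i.i.d.; for autocorrelated series use [longrun_variance()].
#' Floored at `1e-3 * gamma_x(0) gamma_y(0)` when the product series is
#' degenerate (flagged).
#'
#' @inheritParams longrun_variance
#' @return An `lsa_variance` with `kind = "iid"` and `bandwidth = 0`.
#' @export
iid_variance <- function(x, y) {
  n <- check_pair(x, y)
  check_nondegenerate(x, y)
  z <- x * y
  s2 <- mean((z - mean(z))^2)
  floor_val <- 1e-3 * sample_autocovariance(x, 0) * sample_autocovariance(y, 0)
  floored <- s2 < floor_val
  new_variance_estimate(max(s2, floor_val), "iid", 0L, floored = floored)
}
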