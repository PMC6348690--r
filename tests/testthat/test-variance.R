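test_that("sample autocovariance uses the 1/n divisor", {
  expect_equal(sample_autocovariance(c(1, 2, 3), 0), 2 / 3)
  expect_equal(sample_autocovariance(c(1, 2, 3), 1), 0)
  expect_equal(sample_autocovariance(c(1, 2, 3), -1), 0)  # |k| convention
  set.seed(1)
  v <- rnorm(40)
  expect_equal(sample_autocovariance(v, 0), mean((v - mean(v))^2))
  expect_error(sample_autocovariance(v, 40), class = "deplsa_error_param")
})

test_that("exact zero lag-1 product correlation gives tau = 0 and bandwidth 0", {
  # z_t = x_t y_t = (1, 0, -1, 0, ...) has sum u_t u_{t-1} = 0 exactly
  x <- c(1, 1, -1, 1, 1, 1, -1, 1)
  y <- c(1, 0, 1, 0, 1, 0, 1, 0)
  z <- x * y
  expect_equal(sum((z - mean(z))[-1] * (z - mean(z))[-8]), 0)
  v <- longrun_variance(x, y)
  expect_equal(v$phi_hat, 0)
  expect_equal(v$tau_hat, 0)
  expect_equal(v$bandwidth, 0L)
  expect_equal(v$omega_sq,
               sample_autocovariance(x, 0) * sample_autocovariance(y, 0))
})

test_that("bandwidth 0 reduces the long-run variance to gamma_x(0) gamma_y(0)", {
  # products with zero lag-1 autocorrelation: x alternating, y constant sign
  x <- c(2, -2, 2, -2, 2, -2)
  y <- c(1, 1, -1, -1, 1, -1)
  v <- longrun_variance(x, y)
  if (v$bandwidth == 0) {
    expect_equal(v$omega_sq,
                 sample_autocovariance(x, 0) * sample_autocovariance(y, 0))
  }
  # and an exact phi_hat = 0 construction
  x2 <- c(1, 1, -1, -1, 1, 1, -1, -1)   # z = x2 * y2 alternates in pairs
  y2 <- c(1, -1, 1, -1, 1, -1, 1, -1)
  v2 <- longrun_variance(x2, y2)
  expect_equal(v2$phi_hat, sum((x2 * y2)[-1] * (x2 * y2)[-8]) /
                 sum((x2 * y2)[-1]^2))
  if (v2$bandwidth == 0) {
    expect_equal(v2$omega_sq,
                 sample_autocovariance(x2, 0) * sample_autocovariance(y2, 0))
  }
})

test_that("long-run and iid variances are ~1 for iid standard normal pairs", {
  set.seed(5)
  x <- rnorm(10000)
  y <- rnorm(10000)
  v_lr <- longrun_variance(center(x), center(y))
  v_iid <- iid_variance(center(x), center(y))
  # var(Z) = 1 for products of independent N(0,1); MC tolerance ~ 3 SE
  se <- sqrt(8 / 10000)  # var(Z^2) = E Z^4 - 1 = 9 - 1 = 8 for Z = XY
  expect_lt(abs(v_iid$omega_sq - 1), 3 * se)
  expect_lt(abs(v_lr$omega_sq - 1), 6 * se)  # kernel terms add noise
  # the two estimators agree asymptotically under H0
  expect_lt(abs(v_lr$omega_sq - v_iid$omega_sq), 0.1)
})

test_that("long-run variance approaches the AR(1) closed form", {
  # both series AR(1) with rho = 0.5 and unit marginal variance:
  # omega^2 = 1 + 2 sum rho^{2k} = (1 + rho^2)/(1 - rho^2) = 5/3
  set.seed(6)
  n <- 20000
  x <- ar1_series(0.5, n) * sqrt(1 - 0.5^2)
  y <- ar1_series(0.5, n) * sqrt(1 - 0.5^2)
  v <- longrun_variance(center(x), center(y))
  expect_lt(abs(v$omega_sq - 5 / 3), 0.1 * 5 / 3)
  expect_gt(v$bandwidth, 0)
})

test_that("degenerate products are floored and flagged", {
  x <- c(1, -1, 1, -1)
  v <- iid_variance(x, x)   # Z = 1 constant
  expect_true(v$floored)
  expect_equal(v$omega_sq, 1e-3 * sample_autocovariance(x, 0)^2)
  expect_error(iid_variance(rep(1, 4), c(1, 2, 3, 4)),
               class = "deplsa_error_degenerate")
})
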