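test_that("generators are deterministic given a seed and leave the RNG alone", {
  set.seed(30)
  before <- rnorm(1)
  set.seed(30)
  a <- simulate_null("ar1", 0.5, 0.3, n = 50, seed = 7)
  b <- simulate_null("ar1", 0.5, 0.3, n = 50, seed = 7)
  expect_identical(a, b)
  expect_identical(rnorm(1), before)   # seed argument did not disturb the stream
  expect_identical(simulate_local_ar(0.5, 0.5, 0.6, 100, seed = 3),
                   simulate_local_ar(0.5, 0.5, 0.6, 100, seed = 3))
  expect_identical(simulate_bivariate_ar(0.5, 0.5, 0.4, 1, 100, seed = 3),
                   simulate_bivariate_ar(0.5, 0.5, 0.4, 1, 100, seed = 3))
})

test_that("null models produce series with the configured autocorrelation", {
  d <- simulate_null("ar1", rho1 = 0.5, rho2 = -0.3, n = 20000, seed = 31)
  r1 <- cor(d$x[-1], d$x[-nrow(d)])
  r2 <- cor(d$y[-1], d$y[-nrow(d)])
  expect_lt(abs(r1 - 0.5), 0.02)
  expect_lt(abs(r2 + 0.3), 0.02)
  # independent by construction
  expect_lt(abs(cor(d$x, d$y)), 0.03)
  # rho = 0 degenerates to iid
  d0 <- simulate_null("ar1", 0, 0, n = 20000, seed = 32)
  expect_lt(abs(cor(d0$x[-1], d0$x[-nrow(d0)])), 0.02)
})

test_that("ARMA(1,1) with rho = -0.5 cancels to white noise", {
  # AR and MA polynomials cancel: (1 + 0.5B) X = (1 + 0.5B) e
  set.seed(33)
  rej <- replicate(200, {
    d <- simulate_null("arma11", -0.5, -0.5, n = 300)
    ljung_box_test(d$x, 10)$p_value <= 0.05
  })
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("threshold AR null switches coefficient at the -1 threshold", {
  d <- simulate_null("arma11_tar1", 0.5, 0.8, n = 30000, seed = 34)
  y <- d$y
  below <- which(y[-length(y)] <= -1)
  # regression of y_t on y_{t-1} restricted to the below-threshold regime
  slope_below <- coef(lm(y[below + 1] ~ y[below]))[2]
  above <- which(y[-length(y)] > -1)
  slope_above <- coef(lm(y[above + 1] ~ y[above]))[2]
  expect_lt(abs(slope_below - 0.8), 0.1)
  expect_lt(abs(slope_above - 0.5), 0.1)
})

test_that("local AR alternative has the designed window correlation and unit variances", {
  d <- simulate_local_ar(rho1 = 0.5, rho = 0.5, frac_p = 1, n = 100000,
                         seed = 35)
  expect_lt(abs(cor(d$x, d$y) - 0.5), 0.01)
  expect_lt(abs(var(d$x) - 1), 0.03)
  expect_lt(abs(var(d$y) - 1), 0.03)

  # flanks are independent of x when p < 1
  d2 <- simulate_local_ar(0.5, 0.5, 0.5, n = 40000, seed = 36)
  m <- floor(40000 * 0.5)
  st <- floor((40000 - m) / 2) + 1
  inside <- seq_len(40000) >= st & seq_len(40000) <= st + m - 1
  expect_lt(abs(cor(d2$x[inside], d2$y[inside]) - 0.5), 0.02)
  expect_lt(abs(cor(d2$x[!inside], d2$y[!inside])), 0.03)
  expect_error(simulate_local_ar(0.5, 0, 0.6, 100), class = "deplsa_error_param")
})

test_that("bivariate AR alternative hits the target correlation and reduces at rho = 0", {
  d <- simulate_bivariate_ar(0.5, 0.5, rho = 0.4, frac_p = 1, n = 100000,
                             seed = 37)
  expect_lt(abs(cor(d$x, d$y) - 0.4), 0.01)
  expect_lt(abs(var(d$x) - 1), 0.03)
  expect_lt(abs(var(d$y) - 1), 0.03)

  # rho = 0: two independent AR(1) series
  d0 <- simulate_bivariate_ar(0.5, 0.5, rho = 0, frac_p = 1, n = 50000,
                              seed = 38)
  expect_lt(abs(cor(d0$x, d0$y)), 0.02)
  expect_lt(abs(cor(d0$x[-1], d0$x[-50000]) - 0.5), 0.02)

  # rho1 = rho2 = 0: iid bivariate normal with correlation rho
  di <- simulate_bivariate_ar(0, 0, rho = 0.6, frac_p = 1, n = 50000,
                              seed = 39)
  expect_lt(abs(cor(di$x, di$y) - 0.6), 0.02)
  expect_lt(abs(cor(di$x[-1], di$x[-50000])), 0.02)

  # infeasible innovation correlation is reported
  expect_error(simulate_bivariate_ar(0.9, -0.9, rho = 0.9, frac_p = 1, n = 100),
               class = "deplsa_error_param")
})

test_that("parameter validation catches out-of-range coefficients", {
  expect_error(simulate_null("ar1", 1, 0.5, n = 10), class = "deplsa_error_param")
  expect_error(simulate_local_ar(0.5, 0.5, frac_p = 0, n = 10),
               class = "deplsa_error_param")
  expect_error(simulate_local_ar(0.5, 0.5, frac_p = 0.001, n = 10),
               class = "deplsa_error_param")
})
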