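test_that("DDLSA and TLSA p-values are invariant to positive per-series scaling", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    a <- runif(1, 0.01, 50)
    b <- runif(1, 0.01, 50)
    for (D in c(0, 2)) {
      expect_equal(ddlsa_test(a * x, b * y, D)$p_value,
                   ddlsa_test(x, y, D)$p_value, tolerance = 1e-12)
      expect_equal(tlsa_test(a * x, b * y, D)$p_value,
                   tlsa_test(x, y, D)$p_value, tolerance = 1e-12)
    }
  }
})

test_that("tail p-value decreases as the score grows at fixed scale", {
  # same sigma and n, increasing statistic => decreasing p
  p <- ld_tail(seq(0.5, 5, by = 0.5), 0)
  expect_true(all(diff(p) < 0))
})

test_that("DDLSA reduces to TLSA when the bandwidth is zero under H0", {
  set.seed(11)
  diffs <- replicate(50, {
    x <- rnorm(200)
    y <- rnorm(200)
    d <- ddlsa_test(x, y)
    t <- tlsa_test(x, y)
    if (d$variance$bandwidth == 0) abs(d$p_value - t$p_value) else NA_real_
  })
  diffs <- diffs[!is.na(diffs)]
  expect_gt(length(diffs), 5)
  # gamma_z(0) vs gamma_x(0) gamma_y(0): asymptotically equal under H0
  expect_lt(median(diffs), 0.05)
})

test_that("permutation test is deterministic given a seed and handles constants", {
  set.seed(12)
  x <- rnorm(60)
  y <- rnorm(60)
  p1 <- permutation_test(x, y, max_delay = 1, n_perm = 200, seed = 99)
  p2 <- permutation_test(x, y, max_delay = 1, n_perm = 200, seed = 99)
  expect_identical(p1$p_value, p2$p_value)
  # a constant x scores 0 against centered y in every permutation => p = 1
  pc <- permutation_test(rep(2, 30), rnorm(30), n_perm = 50, seed = 1)
  expect_equal(pc$p_value, 1)
  expect_error(permutation_test(x, y, n_perm = 0), class = "deplsa_error_param")
})

test_that("correlation tests match their textbook forms", {
  expect_equal(pcc_test(c(1, 2, 3), c(3, 2, 1))$score, -1)
  perfect <- pcc_test(1:10 + 0, 1:10 + 0)
  expect_equal(perfect$score, 1)
  expect_equal(perfect$p_value, 0)
  expect_false(is.null(perfect$flag))

  set.seed(13)
  x <- rnorm(50)
  y <- rnorm(50)
  ct <- stats::cor.test(x, y)
  mine <- pcc_test(x, y)
  expect_equal(mine$score, unname(ct$estimate))
  expect_equal(mine$p_value, ct$p.value)
  # SRCC is the Pearson correlation of midranks
  expect_equal(srcc_test(x, y)$score, cor(rank(x), rank(y)))
})

test_that("Ljung-Box screen has power against AR(1) and errors on constants", {
  set.seed(14)
  rejections <- replicate(40, {
    ljung_box_test(ar1_series(0.6, 300), max_lag = 10)$p_value <= 0.05
  })
  expect_gt(mean(rejections), 0.9)
  expect_error(ljung_box_test(rep(1, 50)), class = "deplsa_error_degenerate")
  expect_error(ljung_box_test(rnorm(20), max_lag = 20),
               class = "deplsa_error_param")
})

test_that("Ljung-Box size is near nominal for white noise", {
  set.seed(15)
  rej <- replicate(400, ljung_box_test(rnorm(200), 10)$p_value <= 0.05)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("degenerate series are rejected by the LSA tests", {
  expect_error(tlsa_test(rep(1, 30), rnorm(30)),
               class = "deplsa_error_degenerate")
  expect_error(ddlsa_test(rnorm(30), rep(0, 30)),
               class = "deplsa_error_degenerate")
})
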