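test_that("centering and standardization follow the stated conventions", {
  expect_equal(center(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(center(c(5, 5, 5)), c(0, 0, 0))
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(sample(2:50, 1), mean = runif(1, -5, 5))
    expect_equal(mean(center(v)), 0)
    s <- standardize(v)
    expect_equal(mean(s), 0)
    expect_equal(mean(s^2), 1)          # 1/n variance convention
    expect_equal(standardize(s), s)     # idempotent
  }
  # hand computation: mean 2, 1/n-variance 2/3
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1) / sqrt(2 / 3))
  expect_equal(standardize(c(0, 2)), c(-1, 1))
  expect_error(standardize(rep(3, 10)), class = "deplsa_error_degenerate")
  expect_error(center(numeric(0)), class = "deplsa_error_input")
})

test_that("ls_score matches hand-worked examples", {
  a <- ls_score(c(1, -1, 2), c(1, 1, 1), max_delay = 0)
  expect_equal(a$score, 2)
  expect_equal(a$sign, 1L)

  a <- ls_score(c(1, 1), c(-1, -1), max_delay = 0)
  expect_equal(a$score, 2)
  expect_equal(a$sign, -1L)

  expect_equal(ls_score(c(0, 0, 0), c(1, -2, 3))$score, 0)
  expect_equal(ls_score_bruteforce(c(0, 0, 0), c(1, -2, 3))$score, 0)
})

test_that("ls_score validates its inputs", {
  expect_error(ls_score(1:3, 1:4), class = "deplsa_error_shape")
  expect_error(ls_score(1:3 + 0, 3:1 + 0, max_delay = 3),
               class = "deplsa_error_param")
  expect_error(ls_score(c(1, NA, 2), c(1, 1, 1)), class = "deplsa_error_input")
  expect_error(ls_score_bruteforce(rnorm(101), rnorm(101), max_n = 100),
               class = "deplsa_error_size")
})

test_that("dynamic programme equals exhaustive enumeration on random instances", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(2:30, 1)
    D <- sample(0:min(3, n - 1), 1)
    pair <- random_pair(n, dist = sample(c("normal", "integer"), 1))
    dp <- ls_score(pair$x, pair$y, D)
    bf <- ls_score_bruteforce(pair$x, pair$y, D)
    expect_equal(dp$score, bf$score)
    # reported alignment must reproduce the score and satisfy the bounds
    expect_lte(abs(dp$start_x - dp$start_y), D)
    expect_lte(dp$start_x + dp$length - 1, n)
    expect_lte(dp$start_y + dp$length - 1, n)
    if (dp$length > 0) {
      ix <- dp$start_x:(dp$start_x + dp$length - 1)
      iy <- dp$start_y:(dp$start_y + dp$length - 1)
      expect_equal(dp$sign * sum(pair$x[ix] * pair$y[iy]), dp$score)
    }
  }
})

test_that("LS score obeys symmetry, sign-flip, scaling and delay monotonicity", {
  set.seed(202)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    D <- sample(0:3, 1)
    D <- min(D, n - 1)
    p <- random_pair(n)
    a <- ls_score(p$x, p$y, D)
    sym <- ls_score(p$y, p$x, D)
    expect_equal(sym$score, a$score)
    expect_equal(sym$delay, -a$delay)

    flip <- ls_score(-p$x, p$y, D)
    expect_equal(flip$score, a$score)
    expect_equal(flip$sign, -a$sign)

    k1 <- runif(1, 0.1, 5)
    k2 <- runif(1, 0.1, 5)
    expect_equal(ls_score(k1 * p$x, k2 * p$y, D)$score, k1 * k2 * a$score)

    scores <- vapply(0:min(4, n - 1), function(d) ls_score(p$x, p$y, d)$score,
                     numeric(1))
    expect_true(all(diff(scores) >= 0))
  }
})

test_that("unrestricted delay equals the full local alignment maximum", {
  set.seed(303)
  for (i in 1:10) {
    n <- sample(4:15, 1)
    p <- random_pair(n)
    expect_equal(ls_score(p$x, p$y, n - 1)$score,
                 ls_score_bruteforce(p$x, p$y, n - 1)$score)
  }
})
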