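method_ids <- c("pcc", "srcc", "tlsa", "permutation", "lsares_ar",
                "lsares_arma", "ddlsa")

# p-value of one method applied to one simulated pair
apply_method <- function(x, y, method, max_delay, n_perm = 1000) {
  switch(method,
    pcc = pcc_test(x, y)$p_value,
    srcc = srcc_test(x, y)$p_value,
    tlsa = tlsa_test(x, y, max_delay)$p_value,
    permutation = permutation_test(x, y, max_delay, n_perm = n_perm)$p_value,
    lsares_ar = lsares_test(x, y, max_delay, family = "AR")$p_value,
    lsares_arma = lsares_test(x, y, max_delay, family = "ARMA")$p_value,
    ddlsa = ddlsa_test(x, y, max_delay)$p_value,
    abort(sprintf("Unknown method `%s`.", method), class = "deplsa_error_param"))
}

mc_run <- function(generator, method, max_delay, alpha, reps, seed, n_perm,
                   info) {
  seeds <- derive_seeds(seed, reps)
  failures <- 0L
  rejections <- 0L
  for (i in seq_len(reps)) {
    p <- with_seed(seeds[i], {
      pair <- generator()
      tryCatch(apply_method(pair$x, pair$y, method, max_delay, n_perm),
               error = function(e) NA_real_)
    })
    if (is.na(p)) failures <- failures + 1L
    else if (p <= alpha) rejections <- rejections + 1L
  }
  if (failures > 0.01 * reps) {
    abort(sprintf("%d of %d replicates failed (> 1%%).", failures, reps),
          class = "deplsa_error_harness")
  }
  ok <- reps - failures
  rate <- rejections / ok
  tibble::tibble(
    method = method_labels[[method]], !!!info, max_delay = max_delay,
    alpha = alpha, reps = reps, failures = failures,
    rejections = rejections, rejection_rate = rate,
    mc_se = sqrt(rate * (1 - rate) / ok))
}

#' Empirical type I error of an association test
#'
#' Monte-Carlo size experiment: simulates `reps` independent series pairs
#' from a null model ([simulate_null()]), applies the chosen significance
#' method to each, and reports the fraction of p-values at or below `alpha`
#' together with its binomial Monte-Carlo standard error. For a valid test
#' this fraction should be close to `alpha`; for the i.i.d.-based methods it
#' grows well beyond `alpha` as the autoregressive coefficients increase.
#'
#' Each replicate runs on its own RNG sub-stream derived from `seed`, so
#' results are reproducible and different methods can be compared on
#' identical simulated data by passing the same `seed`. Replicates whose
#' test fails are skipped; more than 1% failures is an error.
#'
#' @param method One of `"pcc"`, `"srcc"`, `"tlsa"`, `"permutation"`,
#'   `"lsares_ar"`, `"lsares_arma"`, `"ddlsa"`.
#' @param model Null model, see [simulate_null()].
#' @param rho1,rho2 Autoregressive coefficients.
#' @param n Series length.
#' @param max_delay Maximum delay D (default 0, as in the size studies).
#' @param alpha Nominal level (default 0.05).
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Master seed (default 1).
#' @param n_perm Permutations per replicate for `method = "permutation"`.
#' @param burn_in Burn-in samples discarded by the null generator.
#' @return A one-row tibble: `method`, `model`, `rho1`, `rho2`, `n`,
#'   `max_delay`, `alpha`, `reps`, `failures`, `rejections`,
#'   `rejection_rate`, `mc_se`.
#' @examples
#' empirical_size("ddlsa", "ar1", rho1 = 0.5, rho2 = 0.5, n = 100,
#'                reps = 50, seed = 1)
#' @export
empirical_size <- function(method = method_ids,
                           model = c("ar1", "arma11", "arma11_tar1"),
                           rho1, rho2, n, max_delay = 0, alpha = 0.05,
                           reps = 10000, seed = 1, n_perm = 1000,
                           burn_in = 100) {
  method <- match.arg(method)
  model <- match.arg(model)
  check_coef(rho1, "rho1")
  check_coef(rho2, "rho2")
  stopifnot(reps >= 1)
  mc_run(function() sim_null_pair(model, rho1, rho2, n, as.integer(burn_in)),
         method, max_delay, alpha, as.integer(reps), seed, n_perm,
         info = list(model = model, rho1 = rho1, rho2 = rho2, n = n))
}

#' Empirical power under a locally associated alternative
#'
#' As [empirical_size()], but the pairs are drawn from one of the locally
#' associated alternatives ([simulate_local_ar()] or
#' [simulate_bivariate_ar()]), so the rejection rate estimates power. With
#' `alt_model = "bivariate_ar"` and `rho = 0` the null is recovered and the
#' power collapses to the size.
#'
#' @inheritParams empirical_size
#' @param alt_model `"local_ar"` or `"bivariate_ar"`.
#' @param rho Within-window correlation (association strength).
#' @param rho2 AR coefficient of `y` (bivariate model only; default `rho1`).
#' @param frac_p Correlated fraction of the series, in (0, 1].
#' @return A one-row tibble as in [empirical_size()], plus `rho` and
#'   `frac_p` columns.
#' @export
empirical_power <- function(method = method_ids,
                            alt_model = c("local_ar", "bivariate_ar"),
                            rho1, rho, frac_p, n, rho2 = rho1, max_delay = 0,
                            alpha = 0.05, reps = 10000, seed = 1,
                            n_perm = 1000) {
  method <- match.arg(method)
  alt_model <- match.arg(alt_model)
  stopifnot(reps >= 1)
  generator <- if (alt_model == "local_ar") {
    check_coef(rho1, "rho1")
    check_coef(rho, "rho")
    if (rho == 0) abort("`rho` must be nonzero under the local AR alternative.",
                        class = "deplsa_error_param")
    function() sim_local_ar_pair(rho1, rho, frac_p, n)
  } else {
    function() sim_bivariate_ar_pair(rho1, rho2, rho, frac_p, n)
  }
  mc_run(generator, method, max_delay, alpha, as.integer(reps), seed, n_perm,
         info = list(model = alt_model, rho1 = rho1, rho2 = rho2, rho = rho,
                     frac_p = frac_p, n = n))
}

#' Size or power over a parameter grid
#'
#' Convenience sweep: calls [empirical_size()] (or [empirical_power()] when
#' a `rho` column is present) for every row of `grid` and binds the
#' one-row results, giving a tidy table ready for plotting.
#'
#' @param grid Data frame whose columns are arguments of [empirical_size()]
#'   or [empirical_power()] (e.g. `method`, `model`/`alt_model`, `rho1`,
#'   `rho2`, `rho`, `frac_p`, `n`).
#' @param ... Arguments common to all rows (e.g. `reps`, `seed`, `alpha`).
#' @return A tibble with one row per grid row.
#' @examples
#' grid <- expand.grid(method = c("tlsa", "ddlsa"), n = c(50, 100),
#'                     stringsAsFactors = FALSE)
#' run_experiment_grid(grid, model = "ar1", rho1 = 0.5, rho2 = 0.5,
#'                     reps = 20, seed = 1)
#' @export
run_experiment_grid <- function(grid, ...) {
  common <- list(...)
  fixed_power <- "rho" %in% c(names(grid), names(common))
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    args <- c(as.list(grid[i, , drop = FALSE]), common)
    args <- args[!duplicated(names(args))]
    do.call(if (fixed_power) empirical_power else empirical_size, args)
  })
}
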