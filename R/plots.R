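#' Plot standardized abundance profiles
#'
#' Line plot of (optionally standardized) abundance series over time, one
#' line per factor — the usual way to eyeball autocorrelation and shared
#' seasonality before interpreting association tests.
#'
#' @param table Abundance tibble ([read_abundance()]), complete.
#' @param factors Factor IDs to show (default: all).
#' @param standardize Standardize each series first (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_abundance <- function(table, factors = NULL, standardize = TRUE) {
  m <- abundance_matrix(table)
  if (!is.null(factors)) m <- m[rownames(m) %in% factors, , drop = FALSE]
  if (standardize) m <- t(apply(m, 1, standardize))
  long <- tibble::tibble(
    factor_id = rep(rownames(m), each = ncol(m)),
    time = rep(seq_len(ncol(m)), nrow(m)),
    abundance = as.vector(t(m)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$abundance,
                                     colour = .data$factor_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time point",
                  y = if (standardize) "standardized abundance" else "abundance",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot power (or size) curves from a Monte-Carlo experiment
#'
#' Rejection rate against series length, one curve per method, with
#' pointwise 2-SE Monte-Carlo ribbons and the nominal level as a reference
#' line — the standard display for size/power sweeps produced by
#' [run_experiment_grid()].
#'
#' @param results Tibble of rows from [empirical_size()] /
#'   [empirical_power()].
#' @param alpha Nominal level drawn as a dashed reference (default 0.05).
#' @return A ggplot object.
#' @export
plot_rejection_rates <- function(results, alpha = 0.05) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$n, y = .data$rejection_rate,
                               colour = .data$method)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(0, .data$rejection_rate - 2 * .data$mc_se),
                   ymax = pmin(1, .data$rejection_rate + 2 * .data$mc_se),
                   fill = .data$method),
      alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::labs(x = "number of time points", y = "rejection rate",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
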