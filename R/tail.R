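#' Tail probability of the normalized local similarity score
#'
#' Asymptotic upper-tail function for the LS-score statistic
#' `s_D / (scale * sqrt(n))`. For a statistic value `x > 0` and maximum delay
#' `D` it evaluates
#' \deqn{1 - 8^{2D+1} \left[\sum_{k \ge 1} \left(\frac{1}{x^2} +
#'   \frac{1}{(2k-1)^2\pi^2}\right)
#'   \exp\left(-\frac{(2k-1)^2\pi^2}{2x^2}\right)\right]^{2D+1}.}
#' The series is truncated once a term's contribution falls below 1e-16
#' (hard cap of 1000 terms; the terms decay like `exp(-c k^2)` so far fewer
#' are ever needed) and the result is clamped to `[0, 1]`.
#'
#' As `x` tends to 0 the exponential kills every term and the value tends
#' to 1; as `x` tends to infinity the bracket tends to
#' `sum 1/((2k-1)^2 pi^2) = 1/8` and the value tends to 0.
#'
#' @param x Numeric vector of statistic values. Nonpositive values return 1
#'   by convention (a zero score can never be significant).
#' @param max_delay Maximum delay D (nonnegative integer).
#' @return Numeric vector of tail probabilities in `[0, 1]`.
#' @examples
#' ld_tail(2, max_delay = 0)
#' @export
ld_tail <- function(x, max_delay = 0) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort("`x` must be numeric, finite and non-missing.",
          class = "deplsa_error_input")
  }
  if (length(max_delay) != 1 || is.na(max_delay) || max_delay < 0 ||
      max_delay != as.integer(max_delay)) {
    abort("`max_delay` must be a single nonnegative integer.",
          class = "deplsa_error_param")
  }
  D <- as.integer(max_delay)
  vapply(x, ld_tail_one, numeric(1), D = D)
}

ld_tail_one <- function(x, D) {
  if (x <= 0) return(1)
  total <- 0
  recip <- 0
  capped <- TRUE
  for (k in seq_len(1000L)) {
    odd2 <- (2 * k - 1)^2
    term <- (1 / x^2 + 1 / (odd2 * pi^2)) * exp(-odd2 * pi^2 / (2 * x^2))
    total <- total + term
    recip <- recip + 1 / (odd2 * pi^2)
    if (term < 1e-16) {
      capped <- FALSE
      break
    }
  }
  if (capped) {
    # huge x: the k cap bites while terms are still ~1/((2k-1)^2 pi^2);
    # fold in the analytic tail of that series (sums to 1/8 in total) so the
    # bracket reaches 1/8 and the probability clamps to 0 as x -> Inf
    total <- total + (1 / 8 - recip) * exp(-(2 * 1001 - 1)^2 * pi^2 / (2 * x^2))
  }
  p <- 1 - 8^(2 * D + 1) * total^(2 * D + 1)
  min(1, max(0, p))
}
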