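#' Relative risk from a 2x2 table
#'
#' Computes the risk ratio, its Katz log-method confidence interval, and a
#' Pearson chi-squared p-value from intervention/control event counts —
#' the preprocessing needed when a source study reports raw counts rather
#' than a relative risk.
#'
#' @param a events in the intervention arm.
#' @param n1 intervention-arm denominator.
#' @param c events in the control arm (must be positive: a zero control
#'   risk leaves the relative risk undefined).
#' @param n0 control-arm denominator.
#' @param alpha two-sided confidence level is `1 - alpha`.
#' @param correct apply the Yates continuity correction to the chi-squared
#'   statistic (off by default, matching an uncorrected test).
#'
#' @details All arguments are vectorized.  The confidence interval uses
#'   the normal approximation on the log relative risk with standard error
#'   `sqrt(1/a - 1/n1 + 1/c - 1/n0)`.  When `a = 0` the relative risk is 0
#'   and the interval is undefined (`ci_defined = FALSE`), not an error.
#'
#' @return a tibble with columns `rr`, `ci_low`, `ci_high`, `ci_defined`,
#'   `p_chi2`.
#' @examples
#' rr_from_2x2(10, 100, 20, 100)  # rr = 0.5
#' @export
rr_from_2x2 <- function(a, n1, c, n0, alpha = 0.05, correct = FALSE) {
  if (any(a < 0 | c < 0 | n1 <= 0 | n0 <= 0))
    stop("counts must be non-negative and denominators positive")
  if (any(a > n1) || any(c > n0))
    stop("events cannot exceed their denominator")
  if (any(c == 0))
    stop("undefined risk: control arm has zero events (c = 0)")
  if (any(a != floor(a) | c != floor(c) | n1 != floor(n1) |
          n0 != floor(n0)))
    stop("counts must be integers")

  rr <- (a / n1) / (c / n0)
  z <- stats::qnorm(1 - alpha / 2)
  se <- suppressWarnings(sqrt(1 / a - 1 / n1 + 1 / c - 1 / n0))
  ci_defined <- a > 0 & is.finite(se)
  ci_low <- ifelse(ci_defined, exp(log(rr) - z * se), NA_real_)
  ci_high <- ifelse(ci_defined, exp(log(rr) + z * se), NA_real_)

  b <- n1 - a; d <- n0 - c
  n <- n1 + n0
  delta <- abs(a * d - b * c)
  if (correct) delta <- pmax(delta - n / 2, 0)
  denom <- as.numeric(n1) * n0 * (a + c) * (b + d)
  x2 <- ifelse(denom > 0, n * delta^2 / denom, 0)
  p <- ifelse(denom > 0, stats::pchisq(x2, df = 1, lower.tail = FALSE), 1)

  tibble::tibble(rr = rr, ci_low = ci_low, ci_high = ci_high,
                 ci_defined = ci_defined, p_chi2 = p)
}

#' Convert an odds ratio to a relative risk
#'
#' Uses the baseline-risk correction `RR = OR / (1 - p0 + p0 * OR)`, where
#' `p0` is the outcome risk in the unexposed (control) group.
#'
#' @param or_value odds ratio (> 0); vectorized.
#' @param p0 control-group risk in `[0, 1)`.
#' @return the relative risk.
#' @examples
#' or_to_rr(0.5, 0.2)  # 0.5 / 0.9
#' or_to_rr(0.5, 0)    # rare-outcome limit: equals the odds ratio
#' @export
or_to_rr <- function(or_value, p0) {
  if (any(or_value <= 0)) stop("odds ratio must be > 0")
  if (any(p0 < 0 | p0 >= 1))
    stop("p0 must be in [0, 1): the conversion is undefined at p0 = 1")
  or_value / (1 - p0 + p0 * or_value)
}
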