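#' Zero-truncated negative binomial distribution
#'
#' Density, random generation and moment utilities for the zero-truncated
#' negative binomial (ZTNB) distribution used to model the number of
#' hypoglycemia events per affected admission.  The distribution is
#' parameterized by the mean `mu` and dispersion `size` of the *untruncated*
#' negative binomial; zero truncation conditions on at least one event.
#'
#' @param x vector of positive integer counts.
#' @param n number of draws.
#' @param mu mean of the untruncated negative binomial (> 0).
#' @param size dispersion parameter of the untruncated negative binomial
#'   (> 0); the variance of the untruncated distribution is
#'   `mu + mu^2 / size`, so larger `size` means less overdispersion.
#'
#' @return `dztnb` returns the probability mass at `x`; `rztnb` returns `n`
#'   integer draws (all at least 1); `ztnb_mean` and `ztnb_p_multi` return
#'   the truncated mean and the probability of two or more events.
#'
#' @examples
#' sum(dztnb(1:100, mu = 1.7, size = 1))  # ~1
#' ztnb_mean(mu = 1.7, size = 1)
#' @export
dztnb <- function(x, mu, size) {
  stopifnot(mu > 0, size > 0)
  p0 <- stats::dnbinom(0, size = size, mu = mu)
  out <- stats::dnbinom(x, size = size, mu = mu) / (1 - p0)
  out[x < 1] <- 0
  out
}

#' @rdname dztnb
#' @export
rztnb <- function(n, mu, size) {
  stopifnot(mu > 0, size > 0)
  p0 <- stats::dnbinom(0, size = size, mu = mu)
  # inverse-CDF sampling restricted to the upper (1 - p0) tail: exact
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnbinom(u, size = size, mu = mu)
}

#' @rdname dztnb
#' @export
ztnb_mean <- function(mu, size) {
  p0 <- stats::dnbinom(0, size = size, mu = mu)
  mu / (1 - p0)
}

#' @rdname dztnb
#' @export
ztnb_p_multi <- function(mu, size) {
  p0 <- stats::dnbinom(0, size = size, mu = mu)
  1 - stats::dnbinom(1, size = size, mu = mu) / (1 - p0)
}

# untruncated mu that yields a given zero-truncated mean at fixed size
ztnb_mu_for_mean <- function(mean, size, tol = 1e-12) {
  stopifnot(mean > 1, size > 0)
  f <- function(mu) ztnb_mean(mu, size) - mean
  upper <- mean
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(1e-10, upper), tol = tol)$root
}

#' Moment-match the zero-truncated negative binomial
#'
#' Solves for the ZTNB parameters whose truncated mean and probability of
#' two or more events match the supplied targets.  The truncated mean is
#' strictly increasing in `mu` at fixed `size`, and at fixed truncated mean
#' the probability of two or more events is strictly increasing in `size`
#' (from the logarithmic-series limit as `size -> 0` to the zero-truncated
#' Poisson limit as `size -> Inf`), so a nested root-finder converges.
#'
#' @param mean target mean events per affected admission (> 1, or exactly 1
#'   for the degenerate one-event-per-admission distribution).
#' @param p_multi target probability that an affected admission has two or
#'   more events, in `[0, 1)`; ignored (must be 0 or `NULL`) when
#'   `mean == 1`.
#' @param tol absolute tolerance on both matched moments.
#'
#' @return a list with elements `mu`, `size`, `mean`, `p_multi` (the
#'   achieved moments) and `degenerate` (logical).  For a degenerate fit
#'   `mu` and `size` are `NA`.
#'
#' @examples
#' fit <- ztnb_fit(mean = 2.702, p_multi = 0.63)
#' ztnb_mean(fit$mu, fit$size)
#' @export
ztnb_fit <- function(mean, p_multi, tol = 1e-9) {
  if (!is.numeric(mean) || length(mean) != 1L || mean < 1)
    stop("`mean` must be a single number >= 1 (zero-truncated counts)")
  if (mean == 1) {
    if (!is.null(p_multi) && p_multi != 0)
      stop("infeasible targets: mean = 1 forces P(>=2 events) = 0, got ",
           p_multi)
    return(list(mu = NA_real_, size = NA_real_, mean = 1, p_multi = 0,
                degenerate = TRUE))
  }
  if (!is.numeric(p_multi) || length(p_multi) != 1L ||
      p_multi <= 0 || p_multi >= 1)
    stop("`p_multi` must be a single probability in (0, 1)")

  p2_at <- function(log_size) {
    size <- exp(log_size)
    mu <- ztnb_mu_for_mean(mean, size)
    ztnb_p_multi(mu, size)
  }
  lo <- -14; hi <- 14
  p_lo <- p2_at(lo); p_hi <- p2_at(hi)
  if (p_multi < p_lo || p_multi > p_hi)
    stop(sprintf(paste0("infeasible targets: with mean %.6g, P(>=2) must ",
                        "lie in [%.4f, %.4f]; got %.4f"),
                 mean, p_lo, p_hi, p_multi))
  log_size <- stats::uniroot(function(ls) p2_at(ls) - p_multi, c(lo, hi),
                             tol = tol)$root
  size <- exp(log_size)
  mu <- ztnb_mu_for_mean(mean, size)
  list(mu = mu, size = size,
       mean = ztnb_mean(mu, size),
       p_multi = ztnb_p_multi(mu, size),
       degenerate = FALSE)
}
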