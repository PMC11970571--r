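## Correlation ("point-biserial") power analysis via the noncentral t
## distribution.

#' Power of the test of zero correlation
#'
#' Power of the t test of `H0: rho = 0` at sample size `n`: the test
#' statistic under the alternative follows a noncentral t distribution
#' with `df = n - 2` and noncentrality
#' `delta = |rho| * sqrt(n) / sqrt(1 - rho^2)`; power is the mass beyond
#' the critical value `qt(1 - alpha/tails, df)` (plus the negligible
#' opposite tail for two-sided tests). This is the standard
#' "point-biserial model" correlation power computation.
#'
#' @param n sample size (>= 4).
#' @param rho effect size, `|rho| < 1`.
#' @param alpha significance level in (0, 1).
#' @param tails 1 or 2 (default 2).
#' @return scalar power in (0, 1).
#' @examples
#' power_correlation(47, 0.75, alpha = 4e-4, tails = 2)
#' @export
power_correlation <- function(n, rho, alpha = 0.05, tails = 2) {
  if (!tails %in% c(1, 2)) stop("`tails` must be 1 or 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (n < 4) stop("`n` must be at least 4", call. = FALSE)
  df <- n - 2
  delta <- abs(rho) * sqrt(n) / sqrt(1 - rho^2)
  tcrit <- qt(1 - alpha / tails, df)
  pow <- pt(tcrit, df, ncp = delta, lower.tail = FALSE)
  if (tails == 2) pow <- pow + pt(-tcrit, df, ncp = delta)
  unname(pow)
}

#' Smallest sample size reaching a target power
#'
#' Monotone search for the smallest integer `n >= 4` with
#' `power_correlation(n, rho, alpha, tails) >= target_power`.
#'
#' @param rho effect size.
#' @param alpha significance level.
#' @param target_power target in `(alpha, 1)`.
#' @param tails 1 or 2.
#' @param n_max search cap (default 1e6).
#' @return integer sample size.
#' @export
required_n <- function(rho, alpha = 0.05, target_power = 0.8, tails = 2,
                       n_max = 1e6) {
  if (target_power <= alpha || target_power >= 1)
    stop("`target_power` must lie in (alpha, 1)", call. = FALSE)
  lo <- 4L
  if (power_correlation(lo, rho, alpha, tails) >= target_power) return(lo)
  hi <- lo
  repeat {
    hi <- hi * 2L
    if (hi > n_max) stop("target power unreachable below n_max",
                         call. = FALSE)
    if (power_correlation(hi, rho, alpha, tails) >= target_power) break
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (power_correlation(mid, rho, alpha, tails) >= target_power) {
      hi <- mid
    } else {
      lo <- mid
    }
  }
  hi
}

#' Minimum detectable effect size
#'
#' Bisection on `rho` in (0, 1) for `power(rho) = target_power` at fixed
#' `n`, to a tolerance of 1e-6.
#'
#' @param n sample size.
#' @param alpha significance level.
#' @param target_power target in `(alpha, 1)`.
#' @param tails 1 or 2.
#' @return scalar effect size.
#' @export
min_detectable_rho <- function(n, alpha = 0.05, target_power = 0.8,
                               tails = 2) {
  if (target_power <= alpha || target_power >= 1)
    stop("`target_power` must lie in (alpha, 1)", call. = FALSE)
  f <- function(r) power_correlation(n, r, alpha, tails) - target_power
  lo <- 1e-9; hi <- 1 - 1e-9
  if (f(hi) < 0) stop("target power unreachable at this n", call. = FALSE)
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Bonferroni-adjusted alpha
#'
#' @param alpha family-wise level.
#' @param m number of comparisons.
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  alpha / m
}

#' Fisher-z approximation to correlation power (cross-check)
#'
#' Normal-approximation power via the Fisher transformation; provided
#' as an independent sanity check on [power_correlation()], not used by
#' the analysis.
#'
#' @inheritParams power_correlation
#' @return scalar power.
#' @export
power_correlation_fisherz <- function(n, rho, alpha = 0.05, tails = 2) {
  z <- atanh(abs(rho)) * sqrt(n - 3)
  zc <- qnorm(1 - alpha / tails)
  pow <- pnorm(z - zc)
  if (tails == 2) pow <- pow + pnorm(-z - zc)
  unname(pow)
}

#' @importFrom stats pnorm qnorm
NULL
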