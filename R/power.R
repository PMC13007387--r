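#' Power of a paired t test
#'
#' Exact noncentral-t power for a paired design: noncentrality `d * sqrt(n)`,
#' `n - 1` degrees of freedom.
#'
#' @param n Number of pairs (>= 2).
#' @param d Cohen's d of the paired difference.
#' @param alpha Significance level.
#' @param tails `"one"` or `"two"`.
#' @return Power in `[0, 1]`.
#' @export
paired_t_power <- function(n, d, alpha = 0.02, tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == "one") {
    pt(qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
  } else {
    tc <- qt(1 - alpha / 2, df)
    pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
  }
}

#' Required sample size for a paired t test
#'
#' Smallest integer n at which [paired_t_power()] reaches the requested
#' power.
#'
#' @param d Cohen's d (> 0).
#' @param alpha Significance level.
#' @param power Target power.
#' @param tails `"one"` or `"two"`.
#' @return Integer n.
#' @export
required_n_paired <- function(d, alpha = 0.02, power = 0.90,
                              tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (d <= 0) stop_oxy("oxydrift_bounds", "unattainable: d must be > 0")
  stopifnot(power > 0, power < 1)
  n <- 3L
  while (paired_t_power(n, d, alpha, tails) < power) {
    n <- n + 1L
    if (n > 1e6) stop_oxy("oxydrift_bounds", "required n exceeds 1e6")
  }
  n
}

#' Required sample size for a paired equivalence test (TOST)
#'
#' Normal-approximation sample size for two one-sided paired t tests with
#' symmetric bounds `+/- d` (Cohen's d units):
#' `ceiling(((z[1-alpha] + z[1-(1-power)/2]) / d)^2)`. This is the planning
#' formula for equivalence designs, distinct from the noncentral-t power of
#' an ordinary paired test.
#'
#' @param d Equivalence bound in Cohen's d units (> 0).
#' @param alpha One-sided level of each test.
#' @param power Target power at a true effect of zero.
#' @return Integer n.
#' @export
required_n_tost <- function(d, alpha = 0.02, power = 0.90) {
  if (d <= 0) stop_oxy("oxydrift_bounds", "unattainable: d must be > 0")
  ceiling(((qnorm(1 - alpha) + qnorm(1 - (1 - power) / 2)) / d)^2)
}

#' Small-telescopes smallest effect size of interest
#'
#' The SESOI is the effect size that an original study of `n_original` pairs
#' would have had `power` (conventionally 33%) to detect: the d solving
#' `paired_t_power(n_original, d, alpha, tails) = power`. Monotone
#' decreasing in `n_original`.
#'
#' @param n_original Sample size of the original study (>= 3).
#' @param alpha Significance level of the original test.
#' @param tails `"one"` or `"two"`.
#' @param power Detection power defining the SESOI (default 0.33).
#' @return d_SESOI.
#' @export
sesoi_small_telescopes <- function(n_original, alpha = 0.02,
                                   tails = c("one", "two"), power = 0.33) {
  tails <- match.arg(tails)
  stopifnot(n_original >= 3)
  uniroot(function(d) paired_t_power(n_original, d, alpha, tails) - power,
          interval = c(1e-8, 50), tol = 1e-10)$root
}
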