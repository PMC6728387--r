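# Cross-estimate arithmetic: fixed-effect meta-analysis, one-tailed
# sex-difference z-tests, and binary-outcome MR power calculations.

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools log-scale estimates across cohorts with inverse-variance
#' weights (via `metafor::rma.uni(method = "FE")`):
#' `b = sum(b_i / se_i^2) / sum(se_i^-2)`, `se = sqrt(1 / sum(se_i^-2))`.
#' With a single estimate the input is returned unchanged; with equal
#' SEs the pooled point is the arithmetic mean. No between-study
#' heterogeneity model is fitted: with two cohorts a random-effects
#' variance is not meaningfully estimable.
#'
#' @param b Numeric vector of log ORs (or betas).
#' @param se Positive standard errors, same length.
#' @param scale `"log_or"` (default) or `"beta"`.
#' @param level Confidence level (default 0.95).
#' @return An [estimate_ci()]; number of studies in `attr(, "n_studies")`.
#' @export
#' @examples
#' # pooling two published MI estimates
#' ukb <- se_from_ci(2.87, 1.30, 6.33)
#' ext <- se_from_ci(1.90, 1.04, 3.49)
#' meta_fixed(c(ukb$point, ext$point), c(ukb$se, ext$se))  # OR ~ 2.21
meta_fixed <- function(b, se, scale = c("log_or", "beta"), level = 0.95) {
  scale <- match.arg(scale)
  stopifnot(length(b) >= 1L, length(b) == length(se), all(se > 0),
            all(is.finite(b)))
  fit <- metafor::rma.uni(yi = b, sei = se, method = "FE")
  est <- estimate_ci(as.numeric(fit$beta), fit$se, scale = scale,
                     level = level)
  attr(est, "n_studies") <- length(b)
  est
}

#' One-tailed z-test for a sex difference in effect size
#'
#' Tests whether the male-stratum estimate exceeds the female-stratum
#' estimate: `z = (b_men - b_women) / sqrt(se_men^2 + se_women^2)`,
#' with one-tailed `p = 1 - pnorm(z)` under the default
#' `direction = "men_greater"`. Identical estimates give p = 0.5; a
#' much larger female estimate pushes p towards 1. A two-sided
#' alternative is available.
#'
#' @param b_men,se_men Male-stratum log OR (or beta) and SE.
#' @param b_women,se_women Female-stratum log OR (or beta) and SE.
#' @param direction `"men_greater"` (one-tailed, default) or
#'   `"two_sided"`.
#' @return List with `z` and `p`.
#' @export
#' @examples
#' m <- se_from_ci(4.27, 1.60, 11.3)
#' w <- se_from_ci(0.80, 0.23, 2.84)
#' sex_difference_test(m$point, m$se, w$point, w$se)  # p ~ 0.02
sex_difference_test <- function(b_men, se_men, b_women, se_women,
                                direction = c("men_greater", "two_sided")) {
  direction <- match.arg(direction)
  check_number(se_men, "se_men", lower = 0, open_lower = TRUE)
  check_number(se_women, "se_women", lower = 0, open_lower = TRUE)
  z <- (b_men - b_women) / sqrt(se_men^2 + se_women^2)
  p <- switch(direction,
              men_greater = pnorm(z, lower.tail = FALSE),
              two_sided = 2 * pnorm(-abs(z)))
  list(z = z, p = p, direction = direction)
}

#' Power of a two-sample MR analysis with a binary outcome
#'
#' Large-sample power to detect a causal odds ratio when the outcome
#' sample has `n_total` individuals of whom `n_cases` are cases and the
#' instruments explain a fraction `r2` of the exposure variance:
#' `power = pnorm(sqrt(N * R2 * K * (1 - K)) * |log(OR)| - z_{1-alpha/2})`
#' with case fraction `K = n_cases / n_total`. At OR = 1 this reduces
#' to `alpha / 2` (the upper-tail rejection rate under the null), and
#' power increases strictly with each of N, R2 and K(1 - K) for
#' OR != 1. Vectorized over its arguments.
#'
#' @param n_total Total outcome-sample size.
#' @param n_cases Number of cases (`< n_total`).
#' @param r2 Variance in the exposure explained by the instruments, in
#'   (0, 1).
#' @param odds_ratio Causal odds ratio per unit (typically per SD) of
#'   the exposure.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in (0, 1).
#' @export
#' @examples
#' mr_power_binary(392010, 14442, 0.01, 1.27)  # ~0.80
mr_power_binary <- function(n_total, n_cases, r2, odds_ratio, alpha = 0.05) {
  stopifnot(all(n_total > 0), all(n_cases > 0), all(n_cases < n_total),
            all(r2 > 0 & r2 < 1), all(odds_ratio > 0),
            all(alpha > 0 & alpha < 1))
  k <- n_cases / n_total
  pnorm(sqrt(n_total * r2 * k * (1 - k)) * abs(log(odds_ratio)) -
          qnorm(1 - alpha / 2))
}

#' Minimal detectable odds ratio at a target power
#'
#' Exact inverse of [mr_power_binary()]:
#' `OR = exp((qnorm(power) + z_{1-alpha/2}) / sqrt(N * R2 * K * (1-K)))`.
#' Strictly decreasing in each of N, R2 and K(1 - K). Vectorized.
#'
#' @inheritParams mr_power_binary
#' @param power Target power in (alpha, 1) (default 0.8).
#' @return The smallest odds ratio (> 1) detectable at the target
#'   power.
#' @export
#' @examples
#' detectable_or_binary(392010, 14442, 0.01)  # ~1.27
detectable_or_binary <- function(n_total, n_cases, r2, power = 0.8,
                                 alpha = 0.05) {
  stopifnot(all(n_total > 0), all(n_cases > 0), all(n_cases < n_total),
            all(r2 > 0 & r2 < 1), all(alpha > 0 & alpha < 1),
            all(power > alpha & power < 1))
  k <- n_cases / n_total
  exp((qnorm(power) + qnorm(1 - alpha / 2)) /
        sqrt(n_total * r2 * k * (1 - k)))
}
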