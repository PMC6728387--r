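#' Point estimate with confidence interval
#'
#' Container for an estimate on the log-odds or continuous-trait scale
#' with its standard error, normal-theory confidence interval, and
#' two-sided p-value. All estimators and meta-analytic helpers in the
#' package return this class.
#'
#' @param point Point estimate (log OR when `scale = "log_or"`).
#' @param se Standard error, `>= 0`. A zero SE flags a degenerate
#'   (width-zero) interval; `p` is then `NA`.
#' @param scale `"log_or"` or `"beta"`.
#' @param level Confidence level, default 0.95. The normal quantile is
#'   used exactly (1.959964 at 95%), not rounded to 1.96.
#' @param p Optional p-value override; computed from the normal
#'   approximation when omitted.
#'
#' @return An object of class `mr_ci`: a list with elements `scale`,
#'   `point`, `se`, `ci_low`, `ci_high`, `p`, `level`, `degenerate`.
#' @seealso [se_from_ci()] to reconstruct the SE from a published
#'   OR and CI.
#' @export
#' @examples
#' estimate_ci(log(2.21), 0.245)
estimate_ci <- function(point, se, scale = c("log_or", "beta"),
                        level = 0.95, p = NULL) {
  scale <- match.arg(scale)
  check_number(point, "point")
  check_number(se, "se", lower = 0)
  check_number(level, "level", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  z <- qnorm((1 + level) / 2)
  degenerate <- se == 0
  if (is.null(p)) {
    p <- if (degenerate) NA_real_ else 2 * pnorm(-abs(point) / se)
  }
  structure(
    list(scale = scale, point = point, se = se,
         ci_low = point - z * se, ci_high = point + z * se,
         p = p, level = level, degenerate = degenerate),
    class = "mr_ci"
  )
}

#' Reconstruct a log-scale estimate from a published OR and CI
#'
#' Back-calculates the log odds ratio and its standard error from a
#' printed odds ratio with confidence limits, as needed to feed
#' published results into meta-analysis or sex-difference tests:
#' `se = (log(ci_high) - log(ci_low)) / (2 * z)` with the exact normal
#' quantile `z = qnorm((1 + level) / 2)`.
#'
#' A warning is raised when the point estimate sits more than
#' `0.05 * se` away from the midpoint of the log CI, which indicates
#' rounding (or an asymmetric interval) in the source.
#'
#' @param or Odds ratio, `> 0`.
#' @param ci_low,ci_high Confidence limits on the OR scale, `> 0`,
#'   with `ci_low <= or <= ci_high`.
#' @param level Confidence level of the printed interval (default 0.95).
#'
#' @return An [estimate_ci()] object on the `log_or` scale. A point CI
#'   of width zero yields `se = 0` and `degenerate = TRUE`.
#' @export
#' @examples
#' se_from_ci(4.27, 1.60, 11.3)  # se ~ 0.4987 on the log scale
se_from_ci <- function(or, ci_low, ci_high, level = 0.95) {
  check_number(or, "or", lower = 0, open_lower = TRUE)
  check_number(ci_low, "ci_low", lower = 0, open_lower = TRUE)
  check_number(ci_high, "ci_high", lower = 0, open_lower = TRUE)
  if (!(ci_low <= or && or <= ci_high)) {
    stop("expected ci_low <= or <= ci_high", call. = FALSE)
  }
  z <- qnorm((1 + level) / 2)
  point <- log(or)
  se <- (log(ci_high) - log(ci_low)) / (2 * z)
  if (se > 0) {
    mid <- (log(ci_high) + log(ci_low)) / 2
    if (abs(point - mid) > 0.05 * se) {
      warning(sprintf(
        "point OR is off the CI midpoint by %.3g log units (> 5%% of the SE); source values are likely rounded",
        abs(point - mid)), call. = FALSE)
    }
  }
  estimate_ci(point, se, scale = "log_or", level = level)
}

# vectorized back-calculation for tables of published ORs; returns the
# input with b and se columns appended
se_from_ci_table <- function(df, level = 0.95) {
  stopifnot(all(c("or", "ci_low", "ci_high") %in% names(df)))
  z <- qnorm((1 + level) / 2)
  df$b <- log(df$or)
  df$se <- (log(df$ci_high) - log(df$ci_low)) / (2 * z)
  df
}

#' @export
print.mr_ci <- function(x, ...) {
  lab <- if (x$scale == "log_or") "log OR" else "beta"
  cat(sprintf("%s %.4f (SE %.4f), %d%% CI %.4f to %.4f, p = %.3g\n",
              lab, x$point, x$se, round(100 * x$level),
              x$ci_low, x$ci_high, x$p))
  if (x$scale == "log_or") {
    cat(sprintf("  OR %.3f (%.3f to %.3f)\n",
                exp(x$point), exp(x$ci_low), exp(x$ci_high)))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_ci <- function(x, ...) {
  out <- data.frame(scale = x$scale, point = x$point, se = x$se,
                    ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
                    stringsAsFactors = FALSE)
  if (x$scale == "log_or") {
    out$or <- exp(x$point)
    out$or_ci_low <- exp(x$ci_low)
    out$or_ci_high <- exp(x$ci_high)
  }
  out
}
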