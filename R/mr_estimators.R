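# Two-sample MR estimators: per-SNP Wald ratios, IVW with
# multiplicative random effects, weighted median, mode-based estimate,
# and MR-PRESSO outlier detection/correction.

new_mr_estimate <- function(method, estimate, n_snps, heterogeneity = NULL,
                            outliers = NULL, seed = NULL) {
  stopifnot(inherits(estimate, "mr_ci"), n_snps >= 1)
  structure(list(method = method, estimate = estimate, n_snps = n_snps,
                 heterogeneity = heterogeneity, outliers = outliers,
                 seed = seed),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method, x$n_snps))
  print(x$estimate)
  if (!is.null(x$heterogeneity)) {
    cat(sprintf("  heterogeneity: RSS = %.3f, phi = %.3f\n",
                x$heterogeneity$rss, x$heterogeneity$phi))
  }
  if (length(x$outliers)) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy table of MR estimates
#'
#' @param ... `mr_estimate` objects (or a single list of them).
#' @return A data frame with one row per estimate: method, n_snps,
#'   estimate, se, ci_low, ci_high, p, or, or_ci_low, or_ci_high, phi,
#'   outliers.
#' @export
mr_tidy <- function(...) {
  ests <- list(...)
  if (length(ests) == 1L && !inherits(ests[[1]], "mr_estimate")) {
    ests <- ests[[1]]
  }
  rows <- lapply(ests, function(e) {
    stopifnot(inherits(e, "mr_estimate"))
    data.frame(method = e$method, n_snps = e$n_snps,
               estimate = e$estimate$point, se = e$estimate$se,
               ci_low = e$estimate$ci_low, ci_high = e$estimate$ci_high,
               p = e$estimate$p,
               or = exp(e$estimate$point),
               or_ci_low = exp(e$estimate$ci_low),
               or_ci_high = exp(e$estimate$ci_high),
               phi = if (is.null(e$heterogeneity)) NA_real_ else e$heterogeneity$phi,
               outliers = paste(e$outliers %||% character(0), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-SNP Wald ratio estimates
#'
#' The quotient of the genetic association with the outcome and the
#' genetic association with the exposure, per SNP:
#' `theta_j = beta_outcome / beta_exposure`. The default standard error
#' is the first-order delta approximation
#' `se_j = se_outcome / |beta_exposure|`, which ignores exposure-side
#' uncertainty and matches the inverse-variance weights used by the
#' multi-SNP estimators; `second_order = TRUE` adds the exposure-side
#' term `sqrt(se_y^2/bx^2 + by^2 se_x^2 / bx^4)`.
#'
#' @param hset A [harmonized_set()] (or harmonized data frame).
#' @param second_order Use the second-order delta-method SE.
#' @return Data frame with columns `snp_id`, `theta`, `se`, `weight`
#'   (`weight = se^-2` exactly).
#' @export
wald_ratio <- function(hset, second_order = FALSE) {
  d <- as_harmonized_set(hset)$data
  zero <- d$beta_exposure == 0
  if (any(zero)) {
    stop("beta_exposure is zero for SNP(s): ",
         paste(d$snp_id[zero], collapse = ", "), call. = FALSE)
  }
  theta <- d$beta_outcome / d$beta_exposure
  se <- if (second_order) {
    sqrt(d$se_outcome^2 / d$beta_exposure^2 +
           d$beta_outcome^2 * d$se_exposure^2 / d$beta_exposure^4)
  } else {
    d$se_outcome / abs(d$beta_exposure)
  }
  data.frame(snp_id = d$snp_id, theta = theta, se = se, weight = se^-2,
             stringsAsFactors = FALSE)
}

# closed-form IVW core used by every caller (equivalently WLS of
# beta_outcome on beta_exposure through the origin, weights se_outcome^-2)
ivw_core <- function(bx, by, sy, variance_model = "multiplicative_random") {
  w <- sy^-2
  sxx <- sum(w * bx^2)
  theta <- sum(w * bx * by) / sxx
  se_fixed <- sqrt(1 / sxx)
  j <- length(bx)
  rss <- sum(w * (by - theta * bx)^2)
  phi <- if (j >= 2) max(1, sqrt(rss / (j - 1))) else 1
  se <- if (variance_model == "multiplicative_random") se_fixed * phi else se_fixed
  list(theta = theta, se = se, se_fixed = se_fixed, rss = rss, phi = phi)
}

#' Inverse-variance weighted MR estimate
#'
#' Weighted least-squares regression of the outcome associations on the
#' exposure associations through the origin with weights
#' `se_outcome^-2`; equivalently the inverse-variance weighted average
#' of the per-SNP Wald ratios. Under the default multiplicative
#' random-effects model the fixed-effect SE is scaled by
#' `phi = max(1, sqrt(RSS / (J - 1)))`, so between-SNP over-dispersion
#' widens the interval while under-dispersion is never allowed to
#' shrink it.
#'
#' @inheritParams wald_ratio
#' @param variance_model `"multiplicative_random"` (default) or
#'   `"fixed"`. A single-SNP set falls back to the fixed model with a
#'   warning.
#' @return An `mr_estimate` with heterogeneity diagnostics
#'   (`rss`, `phi`).
#' @export
mr_ivw <- function(hset, variance_model = c("multiplicative_random", "fixed")) {
  variance_model <- match.arg(variance_model)
  d <- as_harmonized_set(hset)$data
  if (!nrow(d)) stop("empty instrument set", call. = FALSE)
  if (nrow(d) == 1L && variance_model == "multiplicative_random") {
    warning("single SNP: multiplicative random effects undefined, using fixed",
            call. = FALSE)
    variance_model <- "fixed"
  }
  fit <- ivw_core(d$beta_exposure, d$beta_outcome, d$se_outcome, variance_model)
  new_mr_estimate(
    method = if (variance_model == "fixed") "ivw_fixed" else "ivw_mre",
    estimate = estimate_ci(fit$theta, fit$se, scale = "log_or"),
    n_snps = nrow(d),
    heterogeneity = list(rss = fit$rss, phi = fit$phi, df = nrow(d) - 1L))
}

# weighted median of ratio estimates: sort, take cumulative weight
# midpoints s_j = cum(w')_j - w'_j/2, linearly interpolate at 0.5
weighted_median_core <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  wn <- w[o] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (0.5 <= s[1]) return(th[1])
  j <- length(th)
  if (0.5 >= s[j]) return(th[j])
  approx(s, th, xout = 0.5, ties = "ordered")$y
}

# parametric bootstrap over per-SNP normal draws; returns SD of the
# statistic computed by `fun(bx, by)`
parametric_bootstrap_sd <- function(bx, sx, by, sy, n_boot, fun) {
  j <- length(bx)
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bxs <- rnorm(j, bx, sx)
    bys <- rnorm(j, by, sy)
    reps[b] <- fun(bxs, bys)
  }
  sd(reps)
}

#' Weighted median MR estimate
#'
#' The 50% point of the inverse-variance-weighted empirical
#' distribution of the per-SNP Wald ratios; consistent as long as valid
#' instruments contribute more than half of the total weight. The
#' standard error comes from a parametric bootstrap: exposure and
#' outcome associations are resampled from per-SNP normal
#' distributions, the weighted median recomputed, and the SD across
#' replicates taken.
#'
#' @inheritParams wald_ratio
#' @param n_boot Bootstrap replicates (default 1000; fewer than 100
#'   triggers a warning about unstable SEs).
#' @param seed Integer seed for the bootstrap, recorded in the result.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed = NULL) {
  d <- as_harmonized_set(hset)$data
  if (nrow(d) < 3L) {
    stop("weighted median requires at least 3 SNPs (use the Wald ratio or IVW)",
         call. = FALSE)
  }
  if (n_boot < 100) warning("n_boot < 100 gives unstable bootstrap SEs",
                            call. = FALSE)
  wr <- wald_ratio(d)
  point <- weighted_median_core(wr$theta, wr$weight)
  se <- with_seed(seed, parametric_bootstrap_sd(
    d$beta_exposure, d$se_exposure, d$beta_outcome, d$se_outcome, n_boot,
    function(bxs, bys) weighted_median_core(bys / bxs, (bxs / d$se_outcome)^2)))
  new_mr_estimate("weighted_median", estimate_ci(point, se, scale = "log_or"),
                  n_snps = nrow(d), seed = seed)
}

# weighted normal-kernel mode of the ratio estimates; bandwidth
# h = phi * 0.9 * min(sd, mad) * J^(-1/5) (modified Silverman; R's
# mad() already includes the 1/0.6745 normal consistency factor)
mode_bandwidth <- function(theta, phi_bandwidth) {
  s <- sd(theta)
  m <- mad(theta)
  base <- if (m > 0) min(s, m) else s
  phi_bandwidth * 0.9 * base * length(theta)^(-1 / 5)
}

mode_core <- function(theta, w, h) {
  if (!is.finite(h) || h <= 0) return(theta[which.max(w)])
  wn <- w / sum(w)
  dens <- function(x) {
    vapply(x, function(g) sum(wn * dnorm(g, mean = theta, sd = h)), numeric(1))
  }
  grid <- seq(min(theta) - 2 * h, max(theta) + 2 * h, length.out = 512L)
  d <- dens(grid)
  i <- which.max(d)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(512L, i + 1L)]
  if (lo == hi) return(grid[i])
  optimize(dens, c(lo, hi), maximum = TRUE, tol = h * 1e-6)$maximum
}

#' Mode-based MR estimate
#'
#' The mode of a weighted normal-kernel density of the per-SNP Wald
#' ratios, consistent when the largest cluster of instruments (a
#' plurality) is valid even if no majority is. Weights are the simple
#' inverse-variance ratio weights; the kernel bandwidth is the modified
#' Silverman rule `phi_bandwidth * 0.9 * min(sd, mad) * J^(-1/5)`, and
#' the argmax is located on a dense grid then refined locally. The SE
#' comes from the same parametric bootstrap as the weighted median.
#' Doubling `phi_bandwidth` smooths the density; the estimate varies
#' continuously with it.
#'
#' @inheritParams mr_weighted_median
#' @param phi_bandwidth Bandwidth multiplier (default 1).
#' @return An `mr_estimate`. When all ratios coincide the common ratio
#'   is returned with a bootstrap SE.
#' @export
mr_mode <- function(hset, phi_bandwidth = 1, n_boot = 1000, seed = NULL) {
  check_number(phi_bandwidth, "phi_bandwidth", lower = 0, open_lower = TRUE)
  d <- as_harmonized_set(hset)$data
  if (nrow(d) < 3L) {
    stop("mode-based estimate requires at least 3 SNPs", call. = FALSE)
  }
  if (n_boot < 100) warning("n_boot < 100 gives unstable bootstrap SEs",
                            call. = FALSE)
  wr <- wald_ratio(d)
  point <- mode_core(wr$theta, wr$weight, mode_bandwidth(wr$theta, phi_bandwidth))
  se <- with_seed(seed, parametric_bootstrap_sd(
    d$beta_exposure, d$se_exposure, d$beta_outcome, d$se_outcome, n_boot,
    function(bxs, bys) {
      th <- bys / bxs
      mode_core(th, (bxs / d$se_outcome)^2, mode_bandwidth(th, phi_bandwidth))
    }))
  new_mr_estimate("mode_based", estimate_ci(point, se, scale = "log_or"),
                  n_snps = nrow(d), seed = seed)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based detection and correction of horizontally
#' pleiotropic outliers. The observed global statistic is the weighted
#' residual sum of squares of each SNP's outcome association around its
#' leave-one-out IVW prediction. Its null distribution is built from
#' `n_sim` parametric simulations drawing exposure associations around
#' their estimates and outcome associations around the leave-one-out
#' fitted values; the global empirical p-value uses the add-one
#' correction `(1 + #{RSS_sim >= RSS_obs}) / (n_sim + 1)` so it is
#' never zero. Per-SNP outlier p-values come from each SNP's simulated
#' squared-residual distribution, Bonferroni-adjusted by the number of
#' SNPs; SNPs with adjusted p below `outlier_alpha` are flagged and the
#' outlier-corrected IVW re-estimated without them. The distortion is
#' reported as the relative difference between corrected and raw
#' estimates.
#'
#' @inheritParams wald_ratio
#' @param n_sim Number of null simulations (default 10,000; raise to
#'   100,000 for publication-grade global p-values).
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   per-SNP outlier test (default 0.05).
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `mr_presso`: list with `global_rss`,
#'   `global_p`, `per_snp` (data frame: `snp_id`, `p_raw`, `p_adj`,
#'   `outlier`), `raw` and `corrected` (`mr_estimate`s; `corrected` is
#'   `NULL` with `all_outliers = TRUE` when every SNP is flagged),
#'   `distortion`, `n_sim`, `seed`.
#' @export
mr_presso <- function(hset, n_sim = 10000, outlier_alpha = 0.05, seed = NULL) {
  d <- as_harmonized_set(hset)$data
  j <- nrow(d)
  if (j < 4L) stop("MR-PRESSO requires at least 4 SNPs", call. = FALSE)
  check_number(outlier_alpha, "outlier_alpha", 0, 1, open_lower = TRUE)
  bx <- d$beta_exposure; sx <- d$se_exposure
  by <- d$beta_outcome; sy <- d$se_outcome
  w <- sy^-2

  s_xx <- sum(w * bx^2)
  s_xy <- sum(w * bx * by)
  theta_loo <- (s_xy - w * bx * by) / (s_xx - w * bx^2)
  res_obs <- by - theta_loo * bx
  rss_obs <- sum(w * res_obs^2)

  sims <- with_seed(seed, {
    bxs <- matrix(rnorm(n_sim * j, mean = rep(bx, each = n_sim),
                        sd = rep(sx, each = n_sim)), n_sim, j)
    bys <- matrix(rnorm(n_sim * j, mean = rep(theta_loo * bx, each = n_sim),
                        sd = rep(sy, each = n_sim)), n_sim, j)
    list(bx = bxs, by = bys)
  })
  wm <- matrix(w, n_sim, j, byrow = TRUE)
  sxx_sim <- rowSums(wm * sims$bx^2)
  sxy_sim <- rowSums(wm * sims$bx * sims$by)
  theta_loo_sim <- (sxy_sim - wm * sims$bx * sims$by) /
    (sxx_sim - wm * sims$bx^2)
  res_sim <- sims$by - theta_loo_sim * sims$bx
  rss_sim <- rowSums(wm * res_sim^2)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  p_raw <- (1 + colSums(res_sim^2 >= matrix(res_obs^2, n_sim, j, byrow = TRUE))) /
    (n_sim + 1)
  p_adj <- pmin(1, p_raw * j)
  outlier <- p_adj < outlier_alpha

  raw <- mr_ivw(d)
  corrected <- NULL
  all_outliers <- all(outlier)
  if (any(outlier) && !all_outliers) {
    corrected <- mr_ivw(d[!outlier, , drop = FALSE])
    corrected$method <- "presso_corrected"
    corrected$outliers <- d$snp_id[outlier]
  }
  raw$method <- "presso_raw"
  distortion <- if (!is.null(corrected) && raw$estimate$point != 0) {
    (corrected$estimate$point - raw$estimate$point) / abs(raw$estimate$point)
  } else NA_real_

  structure(list(global_rss = rss_obs, global_p = global_p,
                 per_snp = data.frame(snp_id = d$snp_id, p_raw = p_raw,
                                      p_adj = p_adj, outlier = outlier,
                                      stringsAsFactors = FALSE),
                 raw = raw, corrected = corrected,
                 all_outliers = all_outliers, distortion = distortion,
                 n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO (%d simulations): global RSS = %.3f, global p = %.4g\n",
              x$n_sim, x$global_rss, x$global_p))
  flagged <- x$per_snp$snp_id[x$per_snp$outlier]
  if (x$all_outliers) {
    cat("  every SNP flagged as an outlier; no corrected estimate\n")
  } else if (length(flagged)) {
    cat("  outliers:", paste(flagged, collapse = ", "), "\n")
    cat(sprintf("  distortion (corrected vs raw): %+.1f%%\n",
                100 * x$distortion))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}
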