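# Synthetic-data generators emulating the two-sample MR design:
# individual-level one-sample datasets, two-sample summary statistics
# from per-SNP regressions in disjoint samples, and a fast
# sampling-distribution-level generator for estimator calibration.

#' Configuration for the synthetic-data generators
#'
#' Defaults describe the study design the package validates against:
#' 10 biallelic instruments jointly explaining ~1% of the exposure
#' variance, an exposure GWAS of 100,000 individuals, a disjoint
#' outcome sample of 300,000 with a binary outcome at case fraction
#' 0.037 (a myocardial-infarction-like rate), a causal log OR of
#' ln(2), and moderate confounding affecting both exposure and
#' outcome.
#'
#' @param n_snps Number of independent biallelic instruments (J >= 2).
#' @param eaf_range Interval for effect-allele frequencies.
#' @param target_r2 Exposure variance explained by the instruments
#'   jointly, in (0, 0.5); instrument effects are scaled to hit it in
#'   expectation and the achieved sample value is reported.
#' @param n_exposure,n_outcome Sizes of the two disjoint samples.
#' @param theta Causal effect of the exposure on the outcome: log OR
#'   for a binary outcome, beta for a continuous one.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param case_fraction Binary-outcome case fraction; the logistic
#'   intercept is solved numerically to achieve it.
#' @param pleiotropy `"none"`, `"balanced"` (mean-zero direct effects,
#'   independent of instrument strength, so the InSIDE condition
#'   holds) or `"directional"` (shifted mean).
#' @param pleiotropy_mean,pleiotropy_sd Direct-effect distribution
#'   parameters (outcome scale per allele).
#' @param confounding Strength of the shared confounder on both
#'   exposure and outcome (standardized scale).
#' @param gamma_rel Optional vector of relative instrument strengths
#'   (length `n_snps`); defaults to uniform draws in (0.7, 1.3). Only
#'   the relative pattern matters: effects are rescaled to hit
#'   `target_r2`. Supply the published per-allele betas here to mirror
#'   a real instrument set.
#' @param seed Integer seed; all generator output is bit-reproducible
#'   under a fixed seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_snps = 10, eaf_range = c(0.1, 0.9),
                              target_r2 = 0.01, n_exposure = 100000,
                              n_outcome = 300000, theta = log(2),
                              outcome_type = c("binary", "continuous"),
                              case_fraction = 0.037,
                              pleiotropy = c("none", "balanced", "directional"),
                              pleiotropy_mean = 0, pleiotropy_sd = 0,
                              confounding = 0.3, gamma_rel = NULL,
                              seed = NULL) {
  outcome_type <- match.arg(outcome_type)
  pleiotropy <- match.arg(pleiotropy)
  check_number(n_snps, "n_snps", lower = 2)
  stopifnot(length(eaf_range) == 2L, eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] <= eaf_range[2])
  check_number(target_r2, "target_r2", 0, 0.5, open_lower = TRUE,
               open_upper = TRUE)
  check_number(n_exposure, "n_exposure", lower = 10)
  check_number(n_outcome, "n_outcome", lower = 10)
  check_number(theta, "theta")
  check_number(case_fraction, "case_fraction", 0, 1, open_lower = TRUE,
               open_upper = TRUE)
  check_number(confounding, "confounding", lower = 0)
  if (target_r2 + confounding^2 >= 1) {
    stop("target_r2 + confounding^2 must be < 1 for a unit-variance exposure",
         call. = FALSE)
  }
  if (pleiotropy != "none" && pleiotropy_sd <= 0 && pleiotropy_mean == 0) {
    stop("pleiotropy scenario '", pleiotropy,
         "' needs a nonzero pleiotropy_mean or pleiotropy_sd", call. = FALSE)
  }
  if (!is.null(gamma_rel)) {
    stopifnot(length(gamma_rel) == n_snps, all(is.finite(gamma_rel)),
              all(gamma_rel > 0))
  }
  structure(list(n_snps = as.integer(n_snps), eaf_range = eaf_range,
                 target_r2 = target_r2, n_exposure = as.integer(n_exposure),
                 n_outcome = as.integer(n_outcome), theta = theta,
                 outcome_type = outcome_type, case_fraction = case_fraction,
                 pleiotropy = pleiotropy, pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd, confounding = confounding,
                 gamma_rel = gamma_rel, seed = seed),
            class = "simulation_config")
}

# shared genetic architecture: frequencies, per-allele effects scaled so
# the instruments explain target_r2 of a unit-variance exposure, SNP
# labels and (non-palindromic) allele pairs
draw_genetics <- function(config) {
  j <- config$n_snps
  f <- runif(j, config$eaf_range[1], config$eaf_range[2])
  gamma0 <- config$gamma_rel %||% runif(j, 0.7, 1.3)  # relative strengths
  var_raw <- sum(gamma0^2 * 2 * f * (1 - f))
  gamma <- gamma0 * sqrt(config$target_r2 / var_raw)
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pick <- pairs[sample.int(nrow(pairs), j, replace = TRUE), , drop = FALSE]
  list(snp_id = sprintf("rs_sim%03d", seq_len(j)), f = f, gamma = gamma,
       effect_allele = pick[, 1], other_allele = pick[, 2])
}

draw_direct_effects <- function(config, scale_ref) {
  j <- config$n_snps
  switch(config$pleiotropy,
         none = numeric(j),
         balanced = rnorm(j, 0, config$pleiotropy_sd * scale_ref),
         directional = rnorm(j, config$pleiotropy_mean * scale_ref,
                             config$pleiotropy_sd * scale_ref))
}

# exposure = genetics + confounder + noise, unit variance in expectation
build_exposure <- function(dosages, gamma, u, config) {
  n <- nrow(dosages)
  noise_sd <- sqrt(1 - config$target_r2 - config$confounding^2)
  as.vector(dosages %*% gamma) + config$confounding * u +
    noise_sd * rnorm(n)
}

solve_intercept <- function(lp, k) {
  # root-finding only sets the design's case fraction; a 100k subsample
  # of the linear predictor pins it down far beyond the needed accuracy
  if (length(lp) > 1e5) lp <- lp[seq_len(1e5)]
  f <- function(a) mean(plogis(a + lp)) - k
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) {
    stop(sprintf("case fraction %.3g unreachable with this linear predictor (range %.3g..%.3g)",
                 k, mean(plogis(lo + lp)), mean(plogis(hi + lp))), call. = FALSE)
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# per-SNP simple linear regressions of x on each dosage column
per_snp_linear <- function(dosages, x) {
  n <- nrow(dosages)
  dbar <- colMeans(dosages)
  xbar <- mean(x)
  sdd <- colSums(dosages^2) - n * dbar^2
  sdx <- as.vector(crossprod(dosages, x)) - n * dbar * xbar
  sxx <- sum((x - xbar)^2)
  b <- sdx / sdd
  resvar <- pmax(0, (sxx - b * sdx)) / (n - 2)
  se <- sqrt(resvar / sdd)
  p <- 2 * pnorm(-abs(b / se))
  list(beta = b, se = se, p = p)
}

# per-SNP marginal logistic regressions; dosages take values 0/1/2 so
# each fit collapses to a 3-row grouped binomial GLM
per_snp_logistic <- function(dosages, y) {
  j <- ncol(dosages)
  beta <- se <- p <- numeric(j)
  dose <- c(0, 1, 2)
  for (k in seq_len(j)) {
    d <- dosages[, k]
    cases <- c(sum(y[d == 0]), sum(y[d == 1]), sum(y[d == 2]))
    tot <- c(sum(d == 0), sum(d == 1), sum(d == 2))
    keep <- tot > 0
    fit <- glm.fit(cbind(1, dose[keep]), cases[keep] / tot[keep],
                   weights = tot[keep], family = binomial())
    mu <- fit$fitted.values
    w <- tot[keep] * mu * (1 - mu)
    xk <- cbind(1, dose[keep])
    vc <- chol2inv(chol(crossprod(xk, xk * w)))
    beta[k] <- fit$coefficients[2]
    se[k] <- sqrt(vc[2, 2])
    p[k] <- 2 * pnorm(-abs(beta[k] / se[k]))
  }
  list(beta = beta, se = se, p = p)
}

#' Simulate an individual-level one-sample dataset
#'
#' Generates biallelic dosages `Binomial(2, f_j)`, a unit-variance
#' exposure built from the instrument effects plus a shared normal
#' confounder plus noise, and a binary (logistic, intercept solved for
#' the target case fraction) or continuous outcome with causal effect
#' `theta` on the exposure. Sex, age, genotyping-array and
#' principal-component covariates are attached with modest outcome
#' effects so covariate-adjusted score regressions are exercised.
#'
#' @param config A [simulation_config()].
#' @return An `individual_dataset`: list with `dosages` (n x J matrix),
#'   `snp_info`, `exposure`, `outcome`, `sex`, `covariates`, and
#'   `truth` (the generating parameters, including the achieved
#'   instrument R-squared).
#' @export
simulate_individual <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    gen <- draw_genetics(config)
    n <- config$n_exposure
    j <- config$n_snps
    dosages <- matrix(rbinom(n * j, 2L, rep(gen$f, each = n)), n, j,
                      dimnames = list(NULL, gen$snp_id))
    u <- rnorm(n)
    x <- build_exposure(dosages, gen$gamma, u, config)
    sex <- ifelse(runif(n) < 0.456, "male", "female")
    covariates <- data.frame(
      age_z = rnorm(n),
      array = as.numeric(runif(n) < 0.5),
      pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n)
    )
    lp_cov <- 0.2 * covariates$age_z + log(1.7) * (sex == "male")
    if (config$outcome_type == "binary") {
      lp <- config$theta * x + config$confounding * u + lp_cov
      a <- solve_intercept(lp, config$case_fraction)
      outcome <- rbinom(n, 1L, plogis(a + lp))
    } else {
      outcome <- config$theta * x + config$confounding * u + lp_cov + rnorm(n)
    }
    fit <- per_snp_linear(dosages, x)
    achieved_r2 <- sum(fit$beta^2 * (colSums(dosages^2) / n - colMeans(dosages)^2)) /
      var(x) * (n / (n - 1))
    list(dosages = dosages,
         snp_info = data.frame(snp_id = gen$snp_id,
                               effect_allele = gen$effect_allele,
                               other_allele = gen$other_allele,
                               eaf = gen$f, stringsAsFactors = FALSE),
         exposure = x, outcome = outcome, sex = sex,
         covariates = covariates,
         truth = list(theta = config$theta, gamma = gen$gamma, f = gen$f,
                      achieved_r2 = achieved_r2, config = config))
  })
}

#' Simulate two-sample GWAS summary statistics
#'
#' Generates two disjoint individual-level samples sharing one genetic
#' architecture: per-SNP exposure betas and SEs from single-SNP linear
#' regressions in the exposure sample, and per-SNP outcome associations
#' (log ORs from marginal logistic regressions, or betas from linear
#' regressions) in the outcome sample. Horizontal pleiotropy adds
#' per-SNP direct effects on the outcome, scaled relative to the
#' median genetic effect on the outcome so `pleiotropy_sd = 1` means
#' direct effects comparable to the causal path.
#'
#' @param config A [simulation_config()].
#' @return List with `exposure` and `outcome` ([snp_assoc()] tables
#'   sharing allele coding) and `truth` (theta, per-SNP instrument
#'   effects, direct effects, achieved R-squared).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    gen <- draw_genetics(config)
    j <- config$n_snps

    # sample 1: exposure GWAS
    n1 <- config$n_exposure
    d1 <- matrix(rbinom(n1 * j, 2L, rep(gen$f, each = n1)), n1, j)
    x1 <- build_exposure(d1, gen$gamma, rnorm(n1), config)
    fx <- per_snp_linear(d1, x1)
    achieved_r2 <- sum(fx$beta^2 * (colSums(d1^2) / n1 - colMeans(d1)^2)) /
      var(x1) * (n1 / (n1 - 1))

    # sample 2: outcome GWAS, disjoint individuals
    n2 <- config$n_outcome
    d2 <- matrix(rbinom(n2 * j, 2L, rep(gen$f, each = n2)), n2, j)
    u2 <- rnorm(n2)
    x2 <- build_exposure(d2, gen$gamma, u2, config)
    alpha <- draw_direct_effects(config,
                                 scale_ref = abs(config$theta) * stats::median(gen$gamma))
    lp <- config$theta * x2 + config$confounding * u2 +
      as.vector(d2 %*% alpha)
    if (config$outcome_type == "binary") {
      a0 <- solve_intercept(lp, config$case_fraction)
      y2 <- rbinom(n2, 1L, plogis(a0 + lp))
      fy <- per_snp_logistic(d2, y2)
    } else {
      y2 <- lp + rnorm(n2)
      fy <- per_snp_linear(d2, y2)
    }

    mk <- function(fit, n, eaf) {
      snp_assoc(data.frame(snp_id = gen$snp_id,
                           effect_allele = gen$effect_allele,
                           other_allele = gen$other_allele,
                           eaf = eaf, beta = fit$beta, se = fit$se,
                           p = pmax(fit$p, 1e-320), n = n,
                           stringsAsFactors = FALSE),
                check_p = FALSE)
    }
    list(exposure = mk(fx, n1, colMeans(d1) / 2),
         outcome = mk(fy, n2, colMeans(d2) / 2),
         truth = list(theta = config$theta, gamma = gen$gamma,
                      direct_effects = alpha, f = gen$f,
                      achieved_r2 = achieved_r2, config = config))
  })
}

#' Simulate summary statistics from their sampling distribution
#'
#' Large-sample shortcut for estimator calibration studies: instead of
#' generating individuals, per-SNP estimates are drawn directly from
#' the normal sampling model implied by the design
#' (`beta_exposure ~ N(gamma_j, se_x)`,
#' `beta_outcome ~ N(theta * gamma_j + alpha_j, se_y)`), with SEs at
#' their large-sample values for the configured sample sizes and, for
#' binary outcomes, case fraction. Orders of magnitude faster than
#' [simulate_two_sample()] and exact for studying the estimators'
#' own calibration.
#'
#' @param config A [simulation_config()].
#' @return Same structure as [simulate_two_sample()].
#' @export
simulate_summary_stats <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    gen <- draw_genetics(config)
    j <- config$n_snps
    v <- 2 * gen$f * (1 - gen$f)
    se_x <- sqrt((1 - config$target_r2) / (config$n_exposure * v))
    if (config$outcome_type == "binary") {
      k <- config$case_fraction
      se_y <- 1 / sqrt(config$n_outcome * k * (1 - k) * v)
    } else {
      var_y <- config$theta^2 + config$confounding^2 + 1 +
        2 * config$theta * config$confounding^2
      se_y <- sqrt(var_y / (config$n_outcome * v))
    }
    alpha <- draw_direct_effects(config,
                                 scale_ref = abs(config$theta) * stats::median(gen$gamma))
    bx <- rnorm(j, gen$gamma, se_x)
    by <- rnorm(j, config$theta * gen$gamma + alpha, se_y)
    mk <- function(beta, se) {
      snp_assoc(data.frame(snp_id = gen$snp_id,
                           effect_allele = gen$effect_allele,
                           other_allele = gen$other_allele,
                           eaf = gen$f, beta = beta, se = se,
                           p = pmax(2 * pnorm(-abs(beta / se)), 1e-320),
                           n = NA, stringsAsFactors = FALSE),
                check_p = FALSE)
    }
    list(exposure = mk(bx, se_x), outcome = mk(by, se_y),
         truth = list(theta = config$theta, gamma = gen$gamma,
                      direct_effects = alpha, f = gen$f,
                      achieved_r2 = config$target_r2, config = config))
  })
}
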