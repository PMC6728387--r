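# Wald ratios, IVW, weighted median, mode-based estimate and MR-PRESSO

test_that("wald_ratio is the quotient with a first-order delta SE", {
  h <- harmonized_set("rs1", 0.015, 0.003, 0.030, 0.010)
  wr <- wald_ratio(h)
  expect_equal(wr$theta, 2)
  expect_equal(wr$se, 0.010 / 0.015)
  expect_equal(wr$weight, wr$se^-2)

  # sign antisymmetry in the exposure beta
  wr2 <- wald_ratio(harmonized_set("rs1", -0.015, 0.003, 0.030, 0.010))
  expect_equal(wr2$theta, -2)
  expect_equal(wr2$se, wr$se)

  expect_equal(wald_ratio(harmonized_set("rs1", 0.015, 0.003, 0, 0.01))$theta, 0)
  expect_error(wald_ratio(harmonized_set("rs1", 0, 0.003, 0.03, 0.01)), "rs1")

  # second-order SE adds the exposure-side term
  wr3 <- wald_ratio(h, second_order = TRUE)
  expect_equal(wr3$se,
               sqrt(0.01^2 / 0.015^2 + 0.03^2 * 0.003^2 / 0.015^4))
  expect_gt(wr3$se, wr$se)
})

test_that("IVW equals the closed-form weighted least squares oracle", {
  # 5-SNP instance with arbitrary betas/SEs; oracle evaluated from sums
  bx <- c(0.012, -0.02, 0.031, 0.008, 0.017)
  by <- c(0.030, -0.01, 0.090, 0.004, 0.020)
  sy <- c(0.011, 0.009, 0.020, 0.012, 0.008)
  w <- sy^-2
  oracle_theta <- sum(w * bx * by) / sum(w * bx^2)
  oracle_se_fixed <- sqrt(1 / sum(w * bx^2))
  rss <- sum(w * (by - oracle_theta * bx)^2)
  oracle_phi <- max(1, sqrt(rss / 4))

  est <- mr_ivw(make_hset(bx, by, sy = sy))
  expect_equal(est$estimate$point, oracle_theta, tolerance = 1e-10)
  expect_equal(est$estimate$se, oracle_se_fixed * oracle_phi, tolerance = 1e-10)
  expect_equal(est$heterogeneity$phi, oracle_phi, tolerance = 1e-10)

  fixed <- mr_ivw(make_hset(bx, by, sy = sy), variance_model = "fixed")
  expect_equal(fixed$estimate$se, oracle_se_fixed, tolerance = 1e-10)
})

test_that("IVW degenerates to the Wald ratio for one SNP and phi = 1 for exact agreement", {
  expect_warning(one <- mr_ivw(harmonized_set("rs1", 0.02, 0.004, 0.05, 0.01)),
                 "single SNP")
  wr <- wald_ratio(harmonized_set("rs1", 0.02, 0.004, 0.05, 0.01))
  expect_equal(one$estimate$point, wr$theta)
  expect_equal(one$estimate$se, wr$se)

  # all SNPs sharing an exact ratio: RSS = 0, phi = 1, fixed = random
  bx <- c(0.01, 0.02, 0.03)
  est <- mr_ivw(make_hset(bx, 1.7 * bx))
  expect_equal(est$estimate$point, 1.7)
  expect_equal(est$heterogeneity$rss, 0, tolerance = 1e-20)
  expect_equal(est$heterogeneity$phi, 1)
  expect_gte(est$heterogeneity$phi, 1)
})

test_that("IVW point and multiplicative-random SE are invariant to rescaling outcome SEs", {
  bx <- c(0.012, -0.02, 0.031, 0.008, 0.017)
  by <- c(0.06, -0.002, 0.02, 0.01, 0.08)  # heterogeneous, phi > 1
  sy <- c(0.011, 0.009, 0.020, 0.012, 0.008)
  base <- mr_ivw(make_hset(bx, by, sy = sy))
  expect_gt(base$heterogeneity$phi, 1)
  for (c in c(0.5, 0.9)) {  # keeps phi above the floor
    scaled <- mr_ivw(make_hset(bx, by, sy = c * sy))
    expect_equal(scaled$estimate$point, base$estimate$point, tolerance = 1e-12)
    expect_equal(scaled$estimate$se, base$estimate$se, tolerance = 1e-12)
  }
  # the fixed-effect point is invariant too (weights rescale uniformly)
  expect_equal(mr_ivw(make_hset(bx, by, sy = 2 * sy))$estimate$point,
               base$estimate$point, tolerance = 1e-12)
})

test_that("all estimators are equivariant under allele flips and outcome negation", {
  set.seed(42)
  bx <- runif(8, 0.01, 0.05)
  by <- 0.4 * bx + rnorm(8, 0, 0.01)
  sy <- runif(8, 0.008, 0.02)
  h <- make_hset(bx, by, sy = sy)
  fits <- list(
    ivw = function(h) mr_ivw(h)$estimate$point,
    wm = function(h) mr_weighted_median(h, n_boot = 100, seed = 7)$estimate$point,
    mbe = function(h) mr_mode(h, n_boot = 100, seed = 7)$estimate$point
  )
  for (f in fits) {
    base <- f(h)
    # an allele recoding negates both betas and leaves the estimate alone
    expect_equal(f(make_hset(-bx, -by, sy = sy)), base, tolerance = 1e-8)
    # negating every outcome beta alone negates the estimate
    expect_equal(f(make_hset(bx, -by, sy = sy)), -base, tolerance = 1e-8)
  }
})

test_that("weighted median interpolates the cumulative-weight breakpoints", {
  # equal weights, symmetric ratios
  h <- make_hset(c(1, 1, 1), c(1, 2, 3))
  expect_equal(mr_weighted_median(h, n_boot = 100, seed = 1)$estimate$point, 2)

  # weights {0.25, 0.5, 0.25}: breakpoints s = {0.125, 0.5, 0.875};
  # brute-force interpolation oracle over the breakpoints gives exactly 2
  sy <- 1 / sqrt(c(0.25, 0.5, 0.25))
  h2 <- make_hset(c(1, 1, 1), c(1, 2, 10), sy = sy)
  s <- cumsum(c(0.25, 0.5, 0.25)) - c(0.25, 0.5, 0.25) / 2
  oracle <- approx(s, c(1, 2, 10), xout = 0.5)$y
  expect_equal(oracle, 2)
  expect_equal(mr_weighted_median(h2, n_boot = 100, seed = 1)$estimate$point,
               oracle)

  expect_error(mr_weighted_median(make_hset(c(1, 1), c(1, 2))), "3 SNPs")
  expect_warning(mr_weighted_median(h, n_boot = 50, seed = 1), "unstable")
})

test_that("equal-weight weighted median equals the ordinary interpolated median", {
  set.seed(11)
  for (j in c(4, 7)) {
    th <- sort(rnorm(j))
    h <- make_hset(rep(1, j), th)
    got <- mr_weighted_median(h, n_boot = 100, seed = 2)$estimate$point
    # oracle: interpolate the sorted ratios at cumulative midpoints
    s <- (seq_len(j) - 0.5) / j
    expect_equal(got, approx(s, th, xout = 0.5)$y, tolerance = 1e-12)
  }
})

test_that("weighted median resists up to half the weight being invalid", {
  # 10 valid SNPs at theta ~ 0.5 with 60% of weight, 40% at theta = 3
  set.seed(3)
  theta_v <- 0.5 + rnorm(10, 0, 0.02)
  theta_i <- 3 + rnorm(4, 0, 0.02)
  w <- c(rep(0.06, 10), rep(0.10, 4))
  bx <- rep(1, 14)
  sy <- 1 / sqrt(w)
  h <- make_hset(bx, c(theta_v, theta_i), sy = sy)
  wm <- mr_weighted_median(h, n_boot = 200, seed = 4)$estimate$point
  expect_lt(abs(wm - 0.5), 0.1)
  # IVW, by contrast, is dragged towards the invalid cluster
  expect_gt(mr_ivw(h)$estimate$point, 1)
})

test_that("mode-based estimate finds the plurality cluster", {
  # all ratios equal: returns the common ratio
  h <- make_hset(c(1, 1, 1), c(2, 2, 2))
  expect_equal(mr_mode(h, n_boot = 100, seed = 5)$estimate$point, 2)

  # 7 SNPs near 1 plus 3 outliers near 5: estimate near 1, far from the
  # weighted mean; grid-search density oracle agrees
  set.seed(6)
  th <- c(1 + rnorm(7, 0, 0.05), 5 + rnorm(3, 0, 0.05))
  h2 <- make_hset(rep(1, 10), th)
  est <- mr_mode(h2, n_boot = 100, seed = 6)$estimate$point
  expect_lt(abs(est - 1), 0.2)
  expect_gt(abs(est - mean(th)), 0.5)
  grid <- seq(-1, 7, length.out = 4001)
  hbw <- 0.9 * min(sd(th), mad(th)) * 10^(-1 / 5)
  dens <- vapply(grid, function(g) sum(dnorm(g, th, hbw)), numeric(1))
  expect_equal(est, grid[which.max(dens)], tolerance = 0.05)

  # doubling the bandwidth multiplier changes the estimate continuously
  e1 <- mr_mode(h2, phi_bandwidth = 1, n_boot = 100, seed = 6)$estimate$point
  e2 <- mr_mode(h2, phi_bandwidth = 2, n_boot = 100, seed = 6)$estimate$point
  expect_true(is.finite(e2))
  expect_lt(abs(e2 - e1), 1)
})

test_that("stochastic estimators are reproducible under a fixed seed", {
  set.seed(8)
  h <- make_hset(runif(6, 0.01, 0.03), runif(6, 0.005, 0.02))
  a <- mr_weighted_median(h, n_boot = 200, seed = 99)
  b <- mr_weighted_median(h, n_boot = 200, seed = 99)
  expect_identical(a$estimate$se, b$estimate$se)
  c1 <- mr_mode(h, n_boot = 200, seed = 99)
  c2 <- mr_mode(h, n_boot = 200, seed = 99)
  expect_identical(c1$estimate$se, c2$estimate$se)
  p1 <- mr_presso(h, n_sim = 100, seed = 99)
  p2 <- mr_presso(h, n_sim = 100, seed = 99)
  expect_identical(p1$global_p, p2$global_p)
  expect_identical(p1$per_snp, p2$per_snp)
  # the bootstrap does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(mr_weighted_median(h, n_boot = 100, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("MR-PRESSO flags an injected pleiotropic outlier and corrects towards truth", {
  sim <- simulate_summary_stats(simulation_config(theta = 0.3, seed = 424242))
  h <- harmonize(sim$exposure, sim$outcome)
  d <- as.data.frame(h)
  d$beta_outcome[3] <- d$beta_outcome[3] + 10 * d$se_outcome[3]
  pr <- mr_presso(d, n_sim = 2000, seed = 11)
  expect_lt(pr$global_p, 0.05)
  expect_true(pr$per_snp$outlier[3])
  expect_equal(pr$corrected$outliers, d$snp_id[pr$per_snp$outlier])
  expect_lt(abs(pr$corrected$estimate$point - 0.3),
            abs(pr$raw$estimate$point - 0.3))
  expect_true(is.finite(pr$distortion))
  # empirical p-values can never be exactly zero (add-one correction)
  expect_gte(pr$global_p, 1 / (pr$n_sim + 1))
  expect_true(all(pr$per_snp$p_raw >= 1 / (pr$n_sim + 1)))
})

test_that("MR-PRESSO input contract: at least 4 SNPs", {
  expect_error(mr_presso(make_hset(c(1, 1, 1), c(1, 2, 3))), "4 SNPs")
})

test_that("mr_tidy collects estimates into one table with OR columns", {
  h <- make_hset(c(0.01, 0.02, 0.03, 0.04), c(0.005, 0.011, 0.014, 0.022))
  tab <- mr_tidy(mr_ivw(h), mr_weighted_median(h, n_boot = 100, seed = 1))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$or, exp(tab$estimate))
  expect_true(all(c("phi", "ci_low", "or_ci_high") %in% names(tab)))
})
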