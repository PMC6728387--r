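# reading, validation, CI arithmetic and allele harmonization

test_that("the bundled insulin instruments load as 12 validated records", {
  tbl <- bundled_instruments("insulin")
  expect_s3_class(tbl, "snp_assoc")
  expect_equal(nrow(tbl), 12L)
  expect_equal(tbl$beta[tbl$snp_id == "rs983309"], 0.029)
  expect_equal(tbl$effect_allele[tbl$snp_id == "rs983309"], "T")
  expect_true(all(tbl$se > 0))

  # a round-trip through a delimited file re-reads identically
  path <- write_sumstats(tbl[, c("snp_id", "effect_allele", "beta", "se", "p")])
  back <- read_summary_table(path)
  expect_equal(back$beta, tbl$beta)
  expect_equal(back$se, tbl$se)
})

test_that("read_summary_table auto-detects conventional headers", {
  path <- write_sumstats(data.frame(SNP = c("rs1", "rs2"), EA = c("a", "g"),
                                    OA = c("g", "a"), EAF = c(0.2, 0.4),
                                    BETA = c(0.1, -0.2), SE = c(0.05, 0.04),
                                    P = c(0.05, 1e-6), N = 1000))
  tbl <- read_summary_table(path)
  expect_equal(tbl$snp_id, c("rs1", "rs2"))
  expect_equal(tbl$effect_allele, c("A", "G"))  # upper-cased
  expect_equal(tbl$beta, c(0.1, -0.2))

  # comma-delimited with the same content parses identically
  path2 <- write_sumstats(data.frame(SNP = "rs1", EA = "A", BETA = 0.1,
                                     SE = 0.05), sep = ",", ext = ".csv")
  expect_equal(read_summary_table(path2)$se, 0.05)
})

test_that("header-only files give an empty table; missing columns fail", {
  path <- write_sumstats(data.frame(SNP = character(0), EA = character(0),
                                    BETA = numeric(0), SE = numeric(0)))
  expect_equal(nrow(read_summary_table(path)), 0L)

  path2 <- write_sumstats(data.frame(SNP = "rs1", EA = "A", BETA = 0.1))
  expect_error(read_summary_table(path2), "se")
})

test_that("malformed rows are rejected with the violated invariant", {
  path <- write_sumstats(data.frame(SNP = c("rs1", "rs2"), EA = c("A", "G"),
                                    BETA = c(0.1, 0.2), SE = c(0.05, 0)))
  expect_error(read_summary_table(path), "se > 0")
  expect_error(make_assoc("rs1", "Z", 0.1, 0.05), "A/C/G/T")
  expect_error(make_assoc("rs1", "A", 0.1, 0.05, p = 1.5), "\\(0, 1\\]")
  expect_error(make_assoc(c("rs1", "rs1"), "A", 0.1, 0.05), "duplicate")
})

test_that("p-values inconsistent with beta/se warn but do not fail", {
  expect_warning(
    snp_assoc(data.frame(snp_id = "rs1", effect_allele = "A", beta = 0.1,
                         se = 0.05, p = 0.9)),
    "factor of 2")
  # a rounded-but-consistent p is silent
  expect_silent(
    snp_assoc(data.frame(snp_id = "rs1", effect_allele = "A", beta = 0.1,
                         se = 0.05, p = 0.046)))
})

test_that("se_from_ci matches the closed-form oracle on published CIs", {
  # oracle: (log(hi) - log(lo)) / (2 * qnorm(0.975)), evaluated directly
  e1 <- se_from_ci(4.27, 1.60, 11.3)
  expect_equal(e1$se, (log(11.3) - log(1.60)) / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(e1$se, 0.4986824, tolerance = 1e-6)
  expect_equal(e1$point, log(4.27))

  e2 <- se_from_ci(1.90, 1.04, 3.49)
  expect_equal(e2$se, 0.3088529, tolerance = 1e-6)

  d <- se_from_ci(1.0, 1.0, 1.0)
  expect_equal(d$se, 0)
  expect_true(d$degenerate)

  expect_error(se_from_ci(-1, 0.5, 2), "or")
  expect_error(se_from_ci(2, 3, 4), "ci_low <= or <= ci_high")
})

test_that("se_from_ci round-trips a CI built as exp(b +/- z*se)", {
  z <- qnorm(0.975)
  for (b in c(-0.7, 0, 1.3)) {
    for (s in c(0.05, 0.5)) {
      e <- se_from_ci(exp(b), exp(b - z * s), exp(b + z * s))
      expect_equal(e$point, b, tolerance = 1e-12)
      expect_equal(e$se, s, tolerance = 1e-12)
    }
  }
  # visibly asymmetric interval warns about rounding
  expect_warning(se_from_ci(2.0, 1.5, 2.2), "midpoint")
})

test_that("harmonize keeps, flips and drops as the allele pairs dictate", {
  ex <- make_assoc(c("rs1", "rs2", "rs3"), c("A", "A", "A"),
                   c(0.015, 0.015, 0.015), c(0.003, 0.003, 0.003),
                   oa = c("G", "G", "C"))
  out <- make_assoc(c("rs1", "rs2", "rs3"), c("A", "G", "A"),
                    c(0.03, 0.03, 0.03), c(0.01, 0.01, 0.01),
                    oa = c("G", "A", "G"))
  h <- harmonize(ex, out)
  expect_equal(h$log$action[h$log$snp_id == "rs1"], "kept")
  expect_equal(h$log$action[h$log$snp_id == "rs2"], "flipped")
  expect_equal(h$data$beta_outcome[h$data$snp_id == "rs2"], -0.03)
  expect_equal(h$log$action[h$log$snp_id == "rs3"], "dropped_mismatch")
  expect_equal(h$data$beta_outcome[h$data$snp_id == "rs1"], 0.03)
})

test_that("palindromic SNPs follow the policy", {
  ex <- make_assoc("rs1", "A", 0.015, 0.003, oa = "T", eaf = 0.50)
  out <- make_assoc("rs1", "A", 0.03, 0.01, oa = "T", eaf = 0.50)
  h <- harmonize(ex, out, palindromic_policy = "drop")
  expect_equal(h$log$action, "dropped_palindromic")

  # ambiguous frequency also drops under the eaf-informative policy
  h2 <- harmonize(ex, out)
  expect_equal(h2$log$action, "dropped_palindromic")

  # informative, concordant frequencies keep the SNP
  ex3 <- make_assoc("rs1", "A", 0.015, 0.003, oa = "T", eaf = 0.10)
  out3 <- make_assoc("rs1", "A", 0.03, 0.01, oa = "T", eaf = 0.12)
  h3 <- harmonize(ex3, out3)
  expect_equal(h3$log$action, "kept")

  # discordant frequencies imply a strand flip of this A/T pair
  out4 <- make_assoc("rs1", "A", 0.03, 0.01, oa = "T", eaf = 0.88)
  h4 <- harmonize(ex3, out4)
  expect_equal(h4$log$action, "flipped")
  expect_equal(h4$data$beta_outcome, -0.03)
})

test_that("palindromic flagging is symmetric in the two inputs", {
  ex <- make_assoc(c("rs1", "rs2"), c("A", "C"), c(0.01, 0.02), c(0.003, 0.003),
                   oa = c("T", "G"), eaf = c(0.5, 0.3))
  out <- make_assoc(c("rs1", "rs2"), c("A", "C"), c(0.1, 0.2), c(0.01, 0.01),
                    oa = c("T", "G"), eaf = c(0.5, 0.3))
  pal1 <- subset(harmonize(ex, out)$log, grepl("palindromic", action))$snp_id
  pal2 <- subset(harmonize(out, ex)$log, grepl("palindromic", action))$snp_id
  expect_setequal(pal1, pal2)
})

test_that("harmonize trusts the effect allele when the other is missing", {
  ex <- make_assoc("rs1", "A", 0.015, 0.003)  # no other allele (as printed)
  out <- make_assoc("rs1", "A", 0.03, 0.01, oa = "G")
  h <- harmonize(ex, out)
  expect_equal(h$log$action, "kept")
  expect_equal(h$log$note, "assumed_forward")
})

test_that("harmonize is idempotent", {
  ex <- make_assoc(c("rs1", "rs2"), c("A", "C"), c(0.015, 0.02), c(0.003, 0.004),
                   oa = c("G", "T"))
  out <- make_assoc(c("rs1", "rs2"), c("G", "C"), c(0.03, 0.05), c(0.01, 0.01),
                    oa = c("A", "T"))
  h1 <- harmonize(ex, out)
  h2 <- harmonize(ex, snp_assoc(h1$outcome_oriented, check_p = FALSE))
  expect_equal(h2$data, h1$data)
  expect_true(all(h2$log$action == "kept"))
})

test_that("harmonized_set enforces its invariants", {
  expect_error(harmonized_set("rs1", 0.1, 0, 0.2, 0.1), "positive")
  expect_error(harmonized_set(c("rs1", "rs1"), c(0.1, 0.2), c(0.1, 0.1),
                              c(0.2, 0.3), c(0.1, 0.1)), "duplicate")
  expect_error(harmonized_set("rs1", NA, 0.1, 0.2, 0.1), "finite")
})

test_that("harmonized sets serialize with the orientation log", {
  ex <- make_assoc(c("rs1", "rs2"), c("A", "A"), c(0.015, 0.02), c(0.003, 0.004),
                   oa = c("G", "C"))
  out <- make_assoc(c("rs1", "rs2"), c("G", "G"), c(0.03, 0.05), c(0.01, 0.01),
                    oa = c("A", "A"))
  path <- tempfile(fileext = ".tsv")
  write_harmonized(harmonize(ex, out), path)
  back <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_setequal(back$snp_id, c("rs1", "rs2"))
  expect_true("action" %in% names(back))
  expect_equal(back$action[back$snp_id == "rs1"], "flipped")
  expect_equal(back$action[back$snp_id == "rs2"], "dropped_mismatch")
})

test_that("se_from_p inverts the two-sided normal p-value", {
  se <- se_from_p(0.029, 3.8e-14)
  expect_equal(2 * pnorm(-abs(0.029 / se)), 3.8e-14, tolerance = 1e-10)
})
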