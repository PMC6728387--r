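# Accessors for the bundled reference tables: the published insulin /
# BMI-adjusted-insulin instrument sets, the confounder-screen p-values
# reported alongside them, the 10-SNP insulin-resistance score, the
# published sex- and source-specific odds ratios, and the cohort
# constants used in the power calculations.

bundled_path <- function(name) {
  path <- system.file("extdata", name, package = "sexmr")
  if (!nzchar(path)) stop("bundled file not found: ", name, call. = FALSE)
  path
}

#' Bundled genetic instruments for insulin exposures
#'
#' The 12 genome-wide significant SNPs predicting fasting insulin and
#' the 12 predicting BMI-adjusted fasting insulin (a proxy for insulin
#' resistance) from a large European GWAS of ~108,000 adults, with
#' gene, effect allele, beta (per effect allele) and p-value. The
#' `note` column carries the curated pleiotropy annotations (BMI,
#' alcohol, or the FTO obesity locus) that drive the published main
#' 7-SNP and 9-SNP analysis sets. Standard errors are reconstructed
#' from beta and p via [se_from_p()] since the source table prints
#' betas and p-values only.
#'
#' @param set `"insulin"` or `"insulin_bmi_adjusted"`.
#' @return A [snp_assoc()] table with additional `gene` and `note`
#'   columns.
#' @export
#' @examples
#' nrow(bundled_instruments("insulin"))  # 12
bundled_instruments <- function(set = c("insulin", "insulin_bmi_adjusted")) {
  set <- match.arg(set)
  file <- sprintf("instruments_%s.tsv", set)
  raw <- read.table(bundled_path(file), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "", fill = TRUE)
  raw$note[is.na(raw$note)] <- ""
  df <- data.frame(snp_id = raw$snp, effect_allele = raw$effect_allele,
                   beta = raw$beta, se = se_from_p(raw$beta, raw$p),
                   p = raw$p, n = 108557, stringsAsFactors = FALSE)
  out <- snp_assoc(df)
  out$gene <- raw$gene
  out$note <- raw$note
  out
}

#' Bundled confounder-screen p-values
#'
#' Association p-values of candidate instruments with measured
#' confounders (alcohol drinking, BMI), as reported for the SNPs that
#' failed the Bonferroni screen, including the men-only BMI association
#' used in the male sensitivity set. Columns: `snp`, `confounder`,
#' `stratum` (`overall`/`men`), `p`.
#'
#' @return A data frame.
#' @export
bundled_screen <- function() {
  read.table(bundled_path("screen_pvalues.tsv"), header = TRUE, sep = "\t",
             stringsAsFactors = FALSE)
}

#' Bundled insulin-resistance genetic score definition
#'
#' The previously validated 10-SNP insulin-resistance allele score:
#' rsID, exposure-raising (risk) allele, and unit weight.
#'
#' @return A data frame with columns `snp`, `risk_allele`, `weight`.
#' @export
bundled_score <- function() {
  read.table(bundled_path("score_snps.tsv"), header = TRUE, sep = "\t",
             stringsAsFactors = FALSE)
}

#' Bundled published odds ratios by outcome, source and sex
#'
#' The published sex- and source-specific odds ratios with 95%
#' confidence intervals and p-values for myocardial infarction, angina
#' and heart failure, by exposure (insulin, BMI-adjusted insulin,
#' insulin-resistance genetic score), together with case counts.
#' These feed the meta-analysis and sex-difference reproductions.
#'
#' @param log_scale Append log-scale `b` and `se` columns recovered
#'   from the printed CIs (default `TRUE`).
#' @return A data frame.
#' @export
bundled_estimates <- function(log_scale = TRUE) {
  df <- read.table(bundled_path("published_estimates.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  if (log_scale) df <- se_from_ci_table(df)
  df
}

#' Bundled cohort constants for power calculations
#'
#' Named list of the analytic sample constants: total QC-passing cohort
#' size (`n_total` = 392,010), recruited male fraction
#' (`male_fraction` = 0.456), external validation study counts
#' (`external_mi_cases`, `external_noncases`), the variance in the
#' exposure explained by the instruments (`instrument_r2` = 0.01) and
#' the exposure GWAS sample size.
#'
#' @return A named list of numbers.
#' @export
bundled_cohort <- function() {
  df <- read.table(bundled_path("cohort.tsv"), header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  as.list(setNames(df$value, df$key))
}
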