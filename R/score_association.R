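# One-sample genetic-risk-score analysis: allele-score construction
# from individual-level dosages and covariate-adjusted logistic
# regression.

#' Define an allele score
#'
#' @param snp_ids Character vector of rsIDs entering the score.
#' @param risk_alleles Optional exposure-raising alleles, one per SNP;
#'   when supplied and a dataset reports its coded alleles, dosages are
#'   flipped (`2 - d`) where the coding disagrees.
#' @param weights Per-SNP weights (default all 1, an unweighted allele
#'   count).
#' @param standardize Standardize the score to mean 0, SD 1 in the
#'   analysis sample (default `TRUE`, so regression coefficients are
#'   per SD of the score).
#' @return An object of class `score_definition`.
#' @export
score_definition <- function(snp_ids, risk_alleles = NULL, weights = 1,
                             standardize = TRUE) {
  snp_ids <- as.character(snp_ids)
  weights <- rep_len(as.numeric(weights), length(snp_ids))
  stopifnot(all(is.finite(weights)))
  if (!is.null(risk_alleles)) {
    risk_alleles <- toupper(as.character(risk_alleles))
    stopifnot(length(risk_alleles) == length(snp_ids),
              all(risk_alleles %in% VALID_ALLELES))
  }
  structure(list(snp_ids = snp_ids, risk_alleles = risk_alleles,
                 weights = weights, standardize = isTRUE(standardize)),
            class = "score_definition")
}

#' Build per-individual allele scores
#'
#' Computes `score_i = sum_j weight_j * dosage_ij` with dosages
#' oriented to the risk alleles, optionally standardized in the sample.
#'
#' @param data An `individual_dataset` (see [simulate_individual()]) or
#'   a dosage matrix with rsID column names; an `individual_dataset`
#'   may carry a `snp_info` table whose `effect_allele` gives the
#'   dosage coding.
#' @param score A [score_definition()].
#' @return Numeric vector of scores, one per individual.
#' @export
build_score <- function(data, score) {
  stopifnot(inherits(score, "score_definition"))
  if (is.matrix(data)) {
    dosages <- data
    snp_info <- NULL
  } else {
    dosages <- data$dosages
    snp_info <- data$snp_info
  }
  idx <- match(tolower(score$snp_ids), tolower(colnames(dosages)))
  if (anyNA(idx)) {
    stop("score SNP(s) missing from dosage columns: ",
         paste(score$snp_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  d <- dosages[, idx, drop = FALSE]
  if (!is.null(score$risk_alleles) && !is.null(snp_info)) {
    coded <- snp_info$effect_allele[match(tolower(score$snp_ids),
                                          tolower(snp_info$snp_id))]
    for (k in seq_along(idx)) {
      if (is.na(coded[k])) next
      if (coded[k] == score$risk_alleles[k]) next
      if (allele_complement(coded[k]) == score$risk_alleles[k]) next
      d[, k] <- 2 - d[, k]
    }
  }
  s <- as.vector(d %*% score$weights)
  if (score$standardize) {
    if (sd(s) == 0) stop("score is constant; cannot standardize", call. = FALSE)
    s <- (s - mean(s)) / sd(s)
  }
  s
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit (IRLS, via `stats::glm.fit`) with
#' Wald standard errors from the inverse observed information. The
#' design matrix must be full column rank and include its own intercept
#' column.
#'
#' @param outcome Binary 0/1 vector with both classes present.
#' @param predictors Numeric matrix, n x p, including an intercept
#'   column.
#' @param tol Convergence tolerance (relative deviance change between
#'   IRLS iterations; default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 50).
#' @return List with `coefficients`, `se`, `z`, `p`, `fitted`,
#'   `vcov`, `converged`, `iterations`.
#' @export
fit_logistic <- function(outcome, predictors, tol = 1e-8, max_iter = 50L) {
  outcome <- as.numeric(outcome)
  stopifnot(all(outcome %in% c(0, 1)))
  if (length(unique(outcome)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  predictors <- as.matrix(predictors)
  if (is.null(colnames(predictors))) {
    colnames(predictors) <- paste0("x", seq_len(ncol(predictors)))
  }
  qr_x <- qr(predictors)
  if (qr_x$rank < ncol(predictors)) {
    dropped <- colnames(predictors)[qr_x$pivot[(qr_x$rank + 1):ncol(predictors)]]
    stop("design matrix is rank deficient (collinear column(s): ",
         paste(dropped, collapse = ", "), ")", call. = FALSE)
  }
  # glm.fit's own warnings (e.g., fitted probabilities of 0/1) are
  # superseded by the explicit separation and convergence checks below
  fit <- suppressWarnings(
    glm.fit(predictors, outcome, family = binomial(),
            control = glm.control(epsilon = tol, maxit = max_iter)))
  if (!fit$converged) {
    stop(sprintf("IRLS did not converge in %d iterations (deviance %.6g)",
                 fit$iter, fit$deviance), call. = FALSE)
  }
  coefs <- fit$coefficients
  col_sd <- apply(predictors, 2, sd)
  scaled <- abs(coefs) * ifelse(col_sd > 0, col_sd, 1)
  if (any(scaled[col_sd > 0] > 15)) {
    stop("separation detected (standardized coefficient > 15); ",
         "penalized regression is out of scope", call. = FALSE)
  }
  mu <- fit$fitted.values
  wt <- mu * (1 - mu)
  info <- crossprod(predictors, predictors * wt)
  vcov <- chol2inv(chol(info))
  se <- setNames(sqrt(diag(vcov)), names(coefs))
  z <- coefs / se
  list(coefficients = coefs, se = se, z = z, p = 2 * pnorm(-abs(z)),
       fitted = mu, vcov = vcov, converged = fit$converged,
       iterations = fit$iter)
}

#' Genetic-risk-score association with a binary outcome
#'
#' Builds the allele score in the requested stratum and fits a
#' covariate-adjusted logistic regression of the outcome on the score,
#' the dataset's covariates, and (in the overall analysis) sex. The
#' reported coefficient is the log OR per score unit (per SD when the
#' score is standardized).
#'
#' @param data An `individual_dataset`: list with `dosages`, `outcome`,
#'   `sex` (`"male"`/`"female"`), `covariates` (data frame or matrix),
#'   optionally `snp_info`.
#' @param score A [score_definition()].
#' @param stratum `"overall"`, `"men"` or `"women"`.
#' @param tol,max_iter Passed to [fit_logistic()].
#' @return An [estimate_ci()] on the `log_or` scale, with the full fit
#'   in `attr(, "fit")` and the stratum size in `attr(, "n")`.
#' @export
score_association <- function(data, score,
                              stratum = c("overall", "men", "women"),
                              tol = 1e-8, max_iter = 50L) {
  stratum <- match.arg(stratum)
  keep <- switch(stratum,
                 overall = rep(TRUE, length(data$outcome)),
                 men = data$sex == "male",
                 women = data$sex == "female")
  if (!any(keep)) stop("stratum '", stratum, "' is empty", call. = FALSE)
  y <- data$outcome[keep]
  if (length(unique(y)) < 2L) {
    stop("stratum '", stratum, "' has a single outcome class", call. = FALSE)
  }
  sub <- list(dosages = data$dosages[keep, , drop = FALSE],
              snp_info = data$snp_info)
  s <- build_score(sub, score)
  covar <- as.matrix(data$covariates)[keep, , drop = FALSE]
  x <- cbind(intercept = 1, score = s, covar)
  if (stratum == "overall" && !is.null(data$sex)) {
    x <- cbind(x, sex_male = as.numeric(data$sex[keep] == "male"))
  }
  fit <- fit_logistic(y, x, tol = tol, max_iter = max_iter)
  est <- estimate_ci(fit$coefficients[["score"]], fit$se[["score"]],
                     scale = "log_or")
  attr(est, "fit") <- fit
  attr(est, "n") <- sum(keep)
  attr(est, "n_cases") <- sum(y)
  est
}
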