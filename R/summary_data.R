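# Summary-statistics data model: reading, validation, harmonization.

# canonical column names and the headers auto-detected for each
COLUMN_SYNONYMS <- list(
  snp_id        = c("snp", "snp_id", "rsid", "variant", "markername", "id"),
  effect_allele = c("ea", "effect_allele", "a1", "allele1", "alt"),
  other_allele  = c("oa", "other_allele", "a2", "allele2", "ref",
                    "non_effect_allele"),
  eaf           = c("eaf", "freq", "af", "effect_allele_frequency", "maf"),
  beta          = c("beta", "b", "effect", "est"),
  se            = c("se", "stderr", "standard_error", "sebeta"),
  p             = c("p", "pval", "p_value", "pvalue", "p.value"),
  n             = c("n", "samplesize", "n_total", "nobs")
)

MANDATORY_COLUMNS <- c("snp_id", "effect_allele", "beta", "se")

#' Construct a table of per-SNP summary associations
#'
#' Coerces a data frame with canonical columns into the validated
#' `snp_assoc` table used across the package: one row per SNP with its
#' association to a single trait.
#'
#' @param df Data frame with columns `snp_id`, `effect_allele`, `beta`,
#'   `se` and optionally `other_allele`, `eaf`, `p`, `n`.
#' @param check_p Warn when a supplied p-value disagrees with the normal
#'   two-sided p implied by `beta/se` by more than a factor of 2
#'   (p-values in published tables are often rounded, so this is a
#'   warning, never an error). Default `TRUE`.
#'
#' @return The data frame, upper-cased alleles, with class
#'   `c("snp_assoc", "data.frame")`.
#' @export
snp_assoc <- function(df, check_p = TRUE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(names(COLUMN_SYNONYMS), names(df))) df[[col]] <- NA
  df <- df[, names(COLUMN_SYNONYMS)]
  df$snp_id <- as.character(df$snp_id)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  df$other_allele[df$other_allele %in% c("", "NA", ".")] <- NA_character_
  for (col in c("eaf", "beta", "se", "p", "n")) df[[col]] <- as.numeric(df[[col]])

  bad <- validate_snp_rows(df)
  if (length(bad)) {
    stop("malformed summary-statistic rows:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  }
  if (check_p) {
    has_p <- !is.na(df$p) & df$p > 1e-300
    implied <- 2 * pnorm(-abs(df$beta / df$se))
    off <- has_p & implied > 0 &
      (df$p / implied > 2 | df$p / implied < 0.5)
    if (any(off)) {
      warning(sprintf(
        "p-value inconsistent with |beta/se| by more than a factor of 2 for: %s",
        paste(df$snp_id[off], collapse = ", ")), call. = FALSE)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("snp_assoc", "data.frame")
  df
}

# per-row invariant checks; returns character descriptions of failures
validate_snp_rows <- function(df) {
  msgs <- character(0)
  line <- function(i) sprintf("row %d (%s)", i, df$snp_id[i] %||% "?")
  for (i in seq_len(nrow(df))) {
    if (is.na(df$snp_id[i]) || !nzchar(df$snp_id[i])) {
      msgs <- c(msgs, sprintf("row %d: empty snp_id", i)); next
    }
    if (!df$effect_allele[i] %in% VALID_ALLELES) {
      msgs <- c(msgs, sprintf("%s: effect_allele '%s' is not one of A/C/G/T",
                              line(i), df$effect_allele[i]))
    }
    if (!is.na(df$other_allele[i])) {
      if (!df$other_allele[i] %in% VALID_ALLELES) {
        msgs <- c(msgs, sprintf("%s: other_allele '%s' is not one of A/C/G/T",
                                line(i), df$other_allele[i]))
      } else if (df$other_allele[i] == df$effect_allele[i]) {
        msgs <- c(msgs, sprintf("%s: effect and other allele are identical",
                                line(i)))
      }
    }
    if (is.na(df$beta[i]) || !is.finite(df$beta[i])) {
      msgs <- c(msgs, sprintf("%s: beta is missing or non-finite", line(i)))
    }
    if (is.na(df$se[i]) || !(df$se[i] > 0)) {
      msgs <- c(msgs, sprintf("%s: violates invariant se > 0", line(i)))
    }
    if (!is.na(df$p[i]) && !(df$p[i] > 0 && df$p[i] <= 1)) {
      msgs <- c(msgs, sprintf("%s: p-value outside (0, 1]", line(i)))
    }
    if (!is.na(df$eaf[i]) && !(df$eaf[i] >= 0 && df$eaf[i] <= 1)) {
      msgs <- c(msgs, sprintf("%s: eaf outside [0, 1]", line(i)))
    }
  }
  if (anyDuplicated(tolower(df$snp_id))) {
    dup <- unique(df$snp_id[duplicated(tolower(df$snp_id))])
    msgs <- c(msgs, paste("duplicate snp_id:", paste(dup, collapse = ", ")))
  }
  msgs
}

#' Read a delimited table of GWAS summary statistics
#'
#' Reads a tab- or comma-delimited file with a header row into a
#' validated [snp_assoc()] table. Conventional column names (`SNP`,
#' `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`, `N` and common variants) are
#' auto-detected case-insensitively; `column_map` overrides the
#' detection for non-standard headers.
#'
#' @param path Path to the file.
#' @param column_map Optional named list/character vector mapping
#'   canonical names (`snp_id`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `p`, `n`) to the actual column headers.
#' @param sep Field separator; guessed from the header line (tab if it
#'   contains tabs, else comma) when `NULL`.
#' @inheritParams snp_assoc
#'
#' @return A `snp_assoc` data frame, one record per data row. Malformed
#'   rows (non-positive SE, invalid alleles, p outside (0,1]) abort with
#'   an error naming each offending row; a missing mandatory column
#'   aborts naming the column.
#' @export
read_summary_table <- function(path, column_map = NULL, sep = NULL,
                               check_p = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", fill = TRUE)
  lowered <- tolower(names(raw))
  resolve <- function(canonical) {
    if (!is.null(column_map) && canonical %in% names(column_map)) {
      actual <- column_map[[canonical]]
      if (!actual %in% names(raw)) {
        stop(sprintf("mapped column '%s' (for %s) not present in %s",
                     actual, canonical, path), call. = FALSE)
      }
      return(actual)
    }
    hit <- which(lowered %in% COLUMN_SYNONYMS[[canonical]])
    if (length(hit)) names(raw)[hit[1L]] else NA_character_
  }
  found <- vapply(names(COLUMN_SYNONYMS), resolve, character(1))
  missing_mandatory <- MANDATORY_COLUMNS[is.na(found[MANDATORY_COLUMNS])]
  if (length(missing_mandatory)) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_mandatory, collapse = ", "), call. = FALSE)
  }
  cols <- lapply(names(found), function(canonical) {
    if (is.na(found[[canonical]])) rep(NA, nrow(raw)) else raw[[found[[canonical]]]]
  })
  names(cols) <- names(found)
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  if (nrow(out) == 0L) {
    class(out) <- c("snp_assoc", "data.frame")
    return(out)
  }
  snp_assoc(out, check_p = check_p)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome associations to the exposure's effect alleles so
#' per-SNP Wald ratios can be formed across two samples. SNPs are
#' matched case-insensitively on rsID; the result is restricted to the
#' intersection of the two sets. When the outcome's effect allele equals
#' the exposure's other allele (directly or on the complementary
#' strand), the outcome beta sign is flipped and the allele frequency
#' mirrored. Palindromic SNPs (A/T or C/G pairs) are strand-ambiguous
#' and handled by `palindromic_policy`:
#'
#' * `"keep_if_eaf_informative"` (default): dropped when either
#'   effect-allele frequency is missing or falls inside `eaf_window`;
#'   otherwise oriented so the two frequencies agree.
#' * `"drop"`: always dropped.
#'
#' Allele pairs that are neither identical nor swapped (on either
#' strand) are dropped with a logged reason rather than raising an
#' error. When a source reports no other allele, harmonization trusts
#' the effect-allele match alone and logs the record as
#' `assumed_forward`.
#'
#' @param exposure,outcome [snp_assoc()] tables (or data frames
#'   coercible to one).
#' @param palindromic_policy `"keep_if_eaf_informative"` or `"drop"`.
#' @param eaf_window Frequency interval treated as uninformative for
#'   orienting palindromic SNPs; default `c(0.42, 0.58)`.
#' @param exposure_name,outcome_name Labels carried into the result.
#'
#' @return An object of class `harmonized_set`: a list with
#'   * `data`: data frame `snp_id`, `beta_exposure`, `se_exposure`,
#'     `beta_outcome`, `se_outcome` (one row per retained SNP);
#'   * `log`: data frame `snp_id`, `action`
#'     (`kept`/`flipped`/`dropped_palindromic`/`dropped_missing`/
#'     `dropped_mismatch`), `note`;
#'   * `outcome_oriented`: the outcome rows after orientation (for
#'     serialization and idempotence checks);
#'   * `exposure_name`, `outcome_name`.
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_policy = c("keep_if_eaf_informative", "drop"),
                      eaf_window = c(0.42, 0.58),
                      exposure_name = "exposure", outcome_name = "outcome") {
  palindromic_policy <- match.arg(palindromic_policy)
  if (!inherits(exposure, "snp_assoc")) exposure <- snp_assoc(exposure, check_p = FALSE)
  if (!inherits(outcome, "snp_assoc")) outcome <- snp_assoc(outcome, check_p = FALSE)
  stopifnot(length(eaf_window) == 2L, eaf_window[1] <= eaf_window[2])

  key_x <- tolower(exposure$snp_id)
  key_y <- tolower(outcome$snp_id)
  shared <- intersect(key_x, key_y)
  actions <- character(0); notes <- character(0); snps <- character(0)
  rec <- vector("list", length(shared))
  oriented <- vector("list", length(shared))

  ambiguous_eaf <- function(f) {
    is.na(f) || (f >= eaf_window[1] && f <= eaf_window[2])
  }

  for (k in seq_along(shared)) {
    ex <- exposure[match(shared[k], key_x), ]
    oy <- outcome[match(shared[k], key_y), ]
    snps[k] <- ex$snp_id
    note <- ""
    ea_x <- ex$effect_allele; oa_x <- ex$other_allele
    ea_y <- oy$effect_allele; oa_y <- oy$other_allele

    palindromic <- isTRUE(is_palindromic_pair(ea_x, oa_x)) ||
      isTRUE(is_palindromic_pair(ea_y, oa_y))

    if (palindromic) {
      if (palindromic_policy == "drop") {
        actions[k] <- "dropped_palindromic"; notes[k] <- "policy drop"
        next
      }
      if (ambiguous_eaf(ex$eaf) || ambiguous_eaf(oy$eaf)) {
        actions[k] <- "dropped_palindromic"
        notes[k] <- "eaf missing or inside ambiguous window"
        next
      }
      # label-based tentative orientation, then strand check by frequency
      flip <- !is.na(ea_y) && (identical(ea_y, oa_x) ||
                                 identical(allele_complement(ea_y), oa_x))
      eaf_y_aligned <- if (flip) 1 - oy$eaf else oy$eaf
      if ((ex$eaf - 0.5) * (eaf_y_aligned - 0.5) < 0) {
        flip <- !flip
        note <- "palindromic oriented by eaf"
      } else {
        note <- "palindromic, eaf concordant"
      }
      action <- if (flip) "flipped" else "kept"
    } else {
      # a candidate orientation must interpret the whole outcome pair
      # coherently (as-is or complemented), never allele-by-allele;
      # missing alleles make their comparison vacuous
      same_pair <- function(e, o) {
        identical(e, ea_x) && (is.na(oa_x) || is.na(o) || identical(o, oa_x))
      }
      swapped_pair <- function(e, o) {
        ((is.na(oa_x) || identical(e, oa_x)) &&
           (is.na(o) || identical(o, ea_x)) &&
           !(is.na(oa_x) && is.na(o)))
      }
      ea_yc <- allele_complement(ea_y)
      oa_yc <- allele_complement(oa_y)
      if (same_pair(ea_y, oa_y) || same_pair(ea_yc, oa_yc)) {
        action <- "kept"
      } else if (swapped_pair(ea_y, oa_y) || swapped_pair(ea_yc, oa_yc)) {
        action <- "flipped"
      } else {
        actions[k] <- "dropped_mismatch"
        notes[k] <- sprintf("alleles %s/%s vs %s/%s neither identical nor swapped",
                            ea_x, ifelse(is.na(oa_x), "?", oa_x),
                            ea_y, ifelse(is.na(oa_y), "?", oa_y))
        next
      }
      if (is.na(oa_x) || is.na(oa_y)) {
        note <- "assumed_forward"
      }
    }

    beta_y <- if (action == "flipped") -oy$beta else oy$beta
    if (any(is.na(c(ex$beta, ex$se, beta_y, oy$se))) ||
        ex$se <= 0 || oy$se <= 0) {
      actions[k] <- "dropped_missing"
      notes[k] <- "missing or invalid beta/se"
      next
    }
    actions[k] <- action; notes[k] <- note
    rec[[k]] <- data.frame(snp_id = ex$snp_id,
                           beta_exposure = ex$beta, se_exposure = ex$se,
                           beta_outcome = beta_y, se_outcome = oy$se,
                           stringsAsFactors = FALSE)
    oy2 <- oy
    if (action == "flipped") {
      oy2$beta <- -oy$beta
      oy2$effect_allele <- ea_x
      oy2$other_allele <- oa_x
      if (!is.na(oy$eaf)) oy2$eaf <- 1 - oy$eaf
    } else {
      oy2$effect_allele <- ea_x
      if (!is.na(oa_x)) oy2$other_allele <- oa_x
    }
    oriented[[k]] <- oy2
  }

  data <- do.call(rbind, rec[!vapply(rec, is.null, TRUE)])
  if (is.null(data)) {
    data <- data.frame(snp_id = character(0), beta_exposure = numeric(0),
                       se_exposure = numeric(0), beta_outcome = numeric(0),
                       se_outcome = numeric(0), stringsAsFactors = FALSE)
  }
  oriented_df <- do.call(rbind, oriented[!vapply(oriented, is.null, TRUE)])
  log <- data.frame(snp_id = snps, action = actions, note = notes,
                    stringsAsFactors = FALSE)
  new_harmonized_set(data, log = log, outcome_oriented = oriented_df,
                     exposure_name = exposure_name,
                     outcome_name = outcome_name)
}

new_harmonized_set <- function(data, log = NULL, outcome_oriented = NULL,
                               exposure_name = "exposure",
                               outcome_name = "outcome") {
  needed <- c("snp_id", "beta_exposure", "se_exposure",
              "beta_outcome", "se_outcome")
  stopifnot(all(needed %in% names(data)))
  data <- data[, needed]
  num <- as.matrix(data[, -1])
  if (nrow(data)) {
    if (!all(is.finite(num))) stop("harmonized records must be finite", call. = FALSE)
    if (any(data$se_exposure <= 0) || any(data$se_outcome <= 0)) {
      stop("harmonized SEs must be positive", call. = FALSE)
    }
    if (anyDuplicated(tolower(data$snp_id))) {
      stop("duplicate snp_id in harmonized set", call. = FALSE)
    }
  }
  rownames(data) <- NULL
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 data = data, log = log, outcome_oriented = outcome_oriented),
            class = "harmonized_set")
}

#' Construct a harmonized instrument set directly
#'
#' Builds the per-SNP container consumed by all MR estimators from
#' already-aligned exposure and outcome associations (e.g., simulated
#' data that shares one allele coding).
#'
#' @param snp_id Character vector of rsIDs (unique).
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome Numeric
#'   vectors of per-SNP associations; SEs must be positive.
#' @param exposure_name,outcome_name Labels.
#' @return A `harmonized_set` object; see [harmonize()].
#' @export
harmonized_set <- function(snp_id, beta_exposure, se_exposure,
                           beta_outcome, se_outcome,
                           exposure_name = "exposure",
                           outcome_name = "outcome") {
  data <- data.frame(snp_id = as.character(snp_id),
                     beta_exposure = beta_exposure,
                     se_exposure = se_exposure,
                     beta_outcome = beta_outcome,
                     se_outcome = se_outcome,
                     stringsAsFactors = FALSE)
  new_harmonized_set(data, exposure_name = exposure_name,
                     outcome_name = outcome_name)
}

as_harmonized_set <- function(x) {
  if (inherits(x, "harmonized_set")) return(x)
  if (is.data.frame(x)) return(new_harmonized_set(x))
  stop("expected a harmonized_set or a data frame with harmonized columns",
       call. = FALSE)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized instrument set: %s -> %s, %d SNP(s)\n",
              x$exposure_name, x$outcome_name, nrow(x$data)))
  if (!is.null(x$log)) {
    tab <- table(x$log$action)
    cat("  actions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  print(x$data)
  invisible(x)
}

#' @export
as.data.frame.harmonized_set <- function(x, ...) x$data

#' Serialize a harmonized set to a delimited table
#'
#' Writes one row per input SNP with the harmonized numeric fields and
#' the orientation log (action and note) as columns; dropped SNPs keep
#' their log entry with missing numeric fields.
#'
#' @param hset A `harmonized_set`.
#' @param path Output file path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(hset, path) {
  hset <- as_harmonized_set(hset)
  log <- hset$log %||% data.frame(snp_id = hset$data$snp_id,
                                  action = "kept", note = "",
                                  stringsAsFactors = FALSE)
  out <- merge(log, hset$data, by = "snp_id", all.x = TRUE, sort = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standard error implied by a beta and its p-value
#'
#' Reconstructs the standard error from an effect size and a two-sided
#' normal p-value, `se = |beta| / qnorm(p/2, lower.tail = FALSE)`.
#' Useful for instrument tables that print betas and p-values only.
#'
#' @param beta Effect estimate(s).
#' @param p Two-sided p-value(s) in (0, 1).
#' @return Numeric vector of standard errors.
#' @export
#' @examples
#' se_from_p(0.029, 3.8e-14)
se_from_p <- function(beta, p) {
  stopifnot(all(p > 0 & p < 1))
  abs(beta) / qnorm(p / 2, lower.tail = FALSE)
}
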