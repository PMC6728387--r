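# Instrument selection: LD-independence pruning, Bonferroni-corrected
# confounder screening, and curated pleiotropy exclusions.

new_selection_report <- function(input_ids, kept, dropped, threshold_used = NA_real_,
                                 notes = character(0)) {
  stopifnot(is.data.frame(dropped),
            all(c("snp_id", "reason") %in% names(dropped)))
  if (length(intersect(tolower(kept), tolower(dropped$snp_id)))) {
    stop("internal: kept and dropped overlap", call. = FALSE)
  }
  if (!setequal(tolower(c(kept, dropped$snp_id)), tolower(input_ids))) {
    stop("internal: kept + dropped must partition the input SNPs", call. = FALSE)
  }
  structure(list(kept = kept, dropped = dropped,
                 threshold_used = threshold_used, notes = notes),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Instrument selection: %d kept, %d dropped",
              length(x$kept), nrow(x$dropped)))
  if (!is.na(x$threshold_used)) cat(sprintf(" (threshold %g)", x$threshold_used))
  cat("\n")
  if (nrow(x$dropped)) {
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf("  - %s: %s\n", x$dropped$snp_id[i], x$dropped$reason[i]))
    }
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' @export
as.data.frame.selection_report <- function(x, ...) {
  rbind(
    data.frame(snp_id = x$kept, status = "kept", reason = "",
               stringsAsFactors = FALSE),
    data.frame(snp_id = x$dropped$snp_id, status = "dropped",
               reason = x$dropped$reason, stringsAsFactors = FALSE)
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param n_phenotypes Number of phenotypes tested (a positive integer;
#'   2,000 phenotype screens gives 0.05/2000 = 2.5e-5).
#' @return `alpha / n_phenotypes`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 2000)  # 2.5e-5
bonferroni_threshold <- function(alpha, n_phenotypes) {
  check_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(n_phenotypes, "n_phenotypes", lower = 1)
  if (n_phenotypes != round(n_phenotypes)) {
    stop("`n_phenotypes` must be an integer", call. = FALSE)
  }
  alpha / n_phenotypes
}

#' Screen candidate instruments against measured confounders
#'
#' Drops every candidate SNP associated with any screened confounder at
#' `p < threshold` (strict inequality: a p-value exactly at the
#' threshold is kept) within the chosen stratum. The recorded reason
#' names the confounder with the smallest p-value. SNPs with no
#' screening rows are kept and logged as unscreened.
#'
#' @param candidates Character vector of rsIDs (or a data frame with a
#'   `snp_id` column).
#' @param screen Data frame with columns `snp` (or `snp_id`),
#'   `confounder`, `stratum`, `p`.
#' @param threshold Significance threshold in (0, 1); see
#'   [bonferroni_threshold()].
#' @param stratum Screen stratum to use (e.g., `"overall"`, `"men"`,
#'   `"women"`).
#' @return A `selection_report`.
#' @export
confounder_screen <- function(candidates, screen, threshold,
                              stratum = "overall") {
  if (is.data.frame(candidates)) candidates <- candidates$snp_id
  candidates <- as.character(candidates)
  check_number(threshold, "threshold", 0, 1, open_lower = TRUE)
  names(screen)[names(screen) == "snp_id"] <- "snp"
  stopifnot(all(c("snp", "confounder", "p") %in% names(screen)))
  if (!"stratum" %in% names(screen)) screen$stratum <- "overall"
  stopifnot(all(screen$p > 0 & screen$p <= 1))
  sub <- screen[tolower(screen$stratum) == tolower(stratum), , drop = FALSE]

  kept <- character(0); notes <- character(0)
  dropped <- data.frame(snp_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (snp in candidates) {
    rows <- sub[tolower(sub$snp) == tolower(snp), , drop = FALSE]
    if (!nrow(rows)) {
      kept <- c(kept, snp)
      notes <- c(notes, sprintf("%s: unscreened in stratum '%s'", snp, stratum))
    } else if (min(rows$p) < threshold) {
      worst <- rows$confounder[which.min(rows$p)]
      dropped <- rbind(dropped, data.frame(
        snp_id = snp, reason = paste0("confounder:", worst),
        stringsAsFactors = FALSE))
    } else {
      kept <- c(kept, snp)
    }
  }
  new_selection_report(candidates, kept, dropped, threshold_used = threshold,
                       notes = notes)
}

#' Prune candidates to pairwise LD independence
#'
#' Greedy clumping: candidates are ordered by ascending exposure
#' p-value (ties broken lexicographically by rsID) and a SNP is kept
#' iff its squared correlation is below `r2_max` against every SNP
#' already kept. The r-squared values are user-supplied (e.g., from an
#' external LD service); the matrix must be symmetric with unit
#' diagonal and cover every candidate pair.
#'
#' @param candidates Data frame with columns `snp_id` and `p` (exposure
#'   association p-value).
#' @param r2 Square numeric matrix with rsID dimnames.
#' @param r2_max Pruning threshold (default 0.01).
#' @return A `selection_report` (dropped reason `"ld"`).
#' @export
ld_filter <- function(candidates, r2, r2_max = 0.01) {
  stopifnot(is.data.frame(candidates),
            all(c("snp_id", "p") %in% names(candidates)))
  check_number(r2_max, "r2_max", 0, 1)
  ids <- as.character(candidates$snp_id)
  if (!is.matrix(r2) || is.null(rownames(r2)) || is.null(colnames(r2))) {
    stop("`r2` must be a matrix with rsID dimnames", call. = FALSE)
  }
  rn <- tolower(rownames(r2)); cn <- tolower(colnames(r2))
  idx <- match(tolower(ids), rn)
  jdx <- match(tolower(ids), cn)
  missing_ids <- ids[is.na(idx) | is.na(jdx)]
  if (length(missing_ids)) {
    stop("r2 matrix is missing candidate SNP(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  m <- r2[idx, jdx, drop = FALSE]
  if (anyNA(m)) {
    pairs <- which(is.na(m), arr.ind = TRUE)
    desc <- apply(pairs, 1, function(ij) paste(ids[ij[1]], ids[ij[2]], sep = "-"))
    stop("r2 matrix has missing pair(s): ",
         paste(unique(desc), collapse = ", "), call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-8) stop("r2 matrix is not symmetric", call. = FALSE)
  if (max(abs(diag(m) - 1)) > 1e-8) {
    stop("r2 matrix diagonal must be 1", call. = FALSE)
  }

  ord <- order(candidates$p, ids)
  kept_idx <- integer(0)
  dropped <- data.frame(snp_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (i in ord) {
    if (all(m[i, kept_idx] < r2_max)) {
      kept_idx <- c(kept_idx, i)
    } else {
      dropped <- rbind(dropped, data.frame(snp_id = ids[i], reason = "ld",
                                           stringsAsFactors = FALSE))
    }
  }
  new_selection_report(ids, ids[sort(kept_idx)], dropped,
                       threshold_used = r2_max)
}

#' Remove curated pleiotropic SNPs
#'
#' Applies a user-supplied exclusion list (e.g., known obesity loci or
#' hits from curated genotype-phenotype databases). Excluding a SNP
#' that is not among the candidates is logged, not an error.
#'
#' @param candidates Character vector of rsIDs (or data frame with
#'   `snp_id`).
#' @param exclusions Data frame with columns `snp_id` and `source`, or
#'   a character vector of rsIDs (source then recorded as
#'   `"curated"`).
#' @return A `selection_report` (dropped reason `"curated:<source>"`).
#' @export
apply_curated_exclusions <- function(candidates, exclusions) {
  if (is.data.frame(candidates)) candidates <- candidates$snp_id
  candidates <- as.character(candidates)
  if (is.character(exclusions)) {
    exclusions <- data.frame(snp_id = exclusions,
                             source = rep("curated", length(exclusions)),
                             stringsAsFactors = FALSE)
  }
  if (is.null(exclusions) || !nrow(exclusions)) {
    return(new_selection_report(candidates, candidates,
                                data.frame(snp_id = character(0),
                                           reason = character(0),
                                           stringsAsFactors = FALSE)))
  }
  stopifnot(all(c("snp_id", "source") %in% names(exclusions)))
  hit <- tolower(candidates) %in% tolower(exclusions$snp_id)
  dropped_ids <- candidates[hit]
  reasons <- vapply(dropped_ids, function(s) {
    src <- exclusions$source[match(tolower(s), tolower(exclusions$snp_id))]
    paste0("curated:", src)
  }, character(1))
  absent <- setdiff(tolower(exclusions$snp_id), tolower(candidates))
  notes <- if (length(absent)) {
    sprintf("exclusion of absent SNP(s): %s", paste(absent, collapse = ", "))
  } else character(0)
  new_selection_report(candidates, candidates[!hit],
                       data.frame(snp_id = dropped_ids, reason = unname(reasons),
                                  stringsAsFactors = FALSE),
                       notes = notes)
}

#' Full instrument-selection pipeline
#'
#' Composes the three filters in the fixed order LD-independence
#' pruning (when an r-squared matrix is supplied), Bonferroni-corrected
#' confounder screening, then curated exclusions, and merges the
#' per-stage reports. On the bundled instrument tables with their
#' reported screening p-values and the FTO curated exclusion this
#' reproduces the published main sets: 7 insulin SNPs and 9
#' BMI-adjusted-insulin SNPs.
#'
#' @param candidates A [snp_assoc()] table (needs `snp_id` and `p`).
#' @param screen Confounder screen table; see [confounder_screen()].
#'   `NULL` skips the stage.
#' @param alpha,n_phenotypes Bonferroni inputs (defaults 0.05 and
#'   2000).
#' @param r2,r2_max LD inputs; `r2 = NULL` skips LD pruning (candidates
#'   assumed pre-pruned, which is logged).
#' @param exclusions Curated exclusions; see
#'   [apply_curated_exclusions()]. `NULL` skips the stage.
#' @param stratum Stratum for the confounder screen.
#' @return A `selection_report` with stagewise reasons.
#' @export
#' @examples
#' ins <- bundled_instruments("insulin")
#' sel <- select_instruments(ins, screen = bundled_screen(),
#'                           exclusions = c("rs1421085"))
#' length(sel$kept)  # 7
select_instruments <- function(candidates, screen = NULL, alpha = 0.05,
                               n_phenotypes = 2000, r2 = NULL, r2_max = 0.01,
                               exclusions = NULL, stratum = "overall") {
  if (!is.data.frame(candidates)) {
    candidates <- data.frame(snp_id = as.character(candidates), p = NA_real_,
                             stringsAsFactors = FALSE)
  }
  ids <- as.character(candidates$snp_id)
  dropped <- data.frame(snp_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  notes <- character(0)
  current <- ids

  if (!is.null(r2)) {
    rep_ld <- ld_filter(candidates[, c("snp_id", "p")], r2, r2_max)
    dropped <- rbind(dropped, rep_ld$dropped)
    current <- rep_ld$kept
  } else {
    notes <- c(notes, "LD pruning skipped: candidates supplied as independent")
  }

  threshold <- bonferroni_threshold(alpha, n_phenotypes)
  if (!is.null(screen)) {
    rep_cf <- confounder_screen(current, screen, threshold, stratum)
    dropped <- rbind(dropped, rep_cf$dropped)
    notes <- c(notes, rep_cf$notes)
    current <- rep_cf$kept
  }

  if (!is.null(exclusions)) {
    rep_cu <- apply_curated_exclusions(current, exclusions)
    dropped <- rbind(dropped, rep_cu$dropped)
    notes <- c(notes, rep_cu$notes)
    current <- rep_cu$kept
  }

  new_selection_report(ids, current, dropped, threshold_used = threshold,
                       notes = notes)
}
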