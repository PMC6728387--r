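# Config-driven orchestration: instrument selection -> harmonization ->
# MR estimation per outcome and stratum -> sex contrasts -> power
# annotations, with a machine-readable manifest of every decision.

resolve_table <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) {
      stop(sprintf("pipeline input for %s references a missing file: %s",
                   what, x), call. = FALSE)
    }
    return(read_summary_table(x))
  }
  if (is.data.frame(x)) {
    return(if (inherits(x, "snp_assoc")) x else snp_assoc(x, check_p = FALSE))
  }
  stop(sprintf("pipeline input for %s must be a file path or data frame", what),
       call. = FALSE)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full sex-specific MR pipeline
#'
#' Orchestrates the analysis end-to-end from a configuration list:
#' instrument selection per exposure, harmonization against every
#' outcome/stratum table, MR estimation with the configured methods
#' (including any sensitivity instrument sets), one-tailed
#' sex-difference tests on the IVW estimates, and power annotations.
#' Results are deterministic given the configured seed; per-invocation
#' estimator seeds are derived from it and recorded in the manifest.
#'
#' @param config A list with elements:
#' \describe{
#'   \item{exposures}{named list of exposure summary tables (data
#'     frames or file paths).}
#'   \item{outcomes}{named list; each outcome is a named list of
#'     stratum tables (data frames or file paths), e.g.
#'     `list(mi = list(overall = ..., men = ..., women = ...))`.}
#'   \item{selection}{optional list with `screen`, `alpha`,
#'     `n_phenotypes`, `r2`, `r2_max`, `exclusions`, `stratum`; passed
#'     to [select_instruments()]. Omit to use every exposure SNP.}
#'   \item{instrument_sets}{optional named list (per exposure) of named
#'     rsID vectors defining additional sensitivity sets; the selected
#'     set is always reported as `"main"`.}
#'   \item{estimators}{list with `methods` (subset of `"ivw"`,
#'     `"weighted_median"`, `"mode"`, `"presso"`), `n_boot`, `n_sim`,
#'     `seed`.}
#'   \item{contrasts}{optional list of 2-element character vectors
#'     naming the (men, women) strata to contrast (default
#'     `c("men", "women")` when both exist).}
#'   \item{power}{optional data frame with columns `outcome`,
#'     `stratum`, `n_total`, `n_cases`, `r2` (and optionally `alpha`,
#'     `power`) for detectable-OR annotations.}
#' }
#' @return An object of class `mr_report`: list with `selection`,
#'   `estimates` (tidy data frame over exposure x outcome x stratum x
#'   instrument set x method), `contrasts`, `power`, and `manifest`.
#' @export
run_mr_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$exposures),
            !is.null(config$outcomes))
  est_cfg <- config$estimators %||% list()
  methods <- est_cfg$methods %||% c("ivw", "weighted_median", "mode")
  n_boot <- est_cfg$n_boot %||% 1000
  n_sim <- est_cfg$n_sim %||% 10000
  seed <- est_cfg$seed %||% 1L

  exposures <- lapply(names(config$exposures), function(nm) {
    run_stage(paste0("read_exposure:", nm),
              resolve_table(config$exposures[[nm]], nm))
  })
  names(exposures) <- names(config$exposures)

  selection <- list()
  sets <- list()
  for (nm in names(exposures)) {
    sel_cfg <- config$selection
    if (is.null(sel_cfg)) {
      kept <- exposures[[nm]]$snp_id
      selection[[nm]] <- NULL
    } else {
      rep <- run_stage(paste0("select:", nm), select_instruments(
        exposures[[nm]],
        screen = sel_cfg$screen,
        alpha = sel_cfg$alpha %||% 0.05,
        n_phenotypes = sel_cfg$n_phenotypes %||% 2000,
        r2 = sel_cfg$r2, r2_max = sel_cfg$r2_max %||% 0.01,
        exclusions = sel_cfg$exclusions,
        stratum = sel_cfg$stratum %||% "overall"))
      selection[[nm]] <- rep
      kept <- rep$kept
    }
    sets[[nm]] <- c(list(main = kept),
                    config$instrument_sets[[nm]] %||% list())
  }

  est_rows <- list()
  ivw_store <- list()  # for contrasts
  run_idx <- 0L
  for (ex_nm in names(exposures)) {
    for (out_nm in names(config$outcomes)) {
      strata <- config$outcomes[[out_nm]]
      for (st_nm in names(strata)) {
        out_tbl <- run_stage(sprintf("read_outcome:%s/%s", out_nm, st_nm),
                             resolve_table(strata[[st_nm]],
                                           paste(out_nm, st_nm)))
        for (set_nm in names(sets[[ex_nm]])) {
          snps <- sets[[ex_nm]][[set_nm]]
          ex_tbl <- exposures[[ex_nm]]
          ex_sub <- ex_tbl[tolower(ex_tbl$snp_id) %in% tolower(snps), ,
                           drop = FALSE]
          hset <- run_stage(sprintf("harmonize:%s->%s/%s", ex_nm, out_nm, st_nm),
                            harmonize(ex_sub, out_tbl,
                                      exposure_name = ex_nm,
                                      outcome_name = paste(out_nm, st_nm)))
          ests <- list()
          for (m in methods) {
            run_idx <- run_idx + 1L
            m_seed <- seed + run_idx
            e <- run_stage(sprintf("%s:%s->%s/%s", m, ex_nm, out_nm, st_nm),
              switch(m,
                ivw = mr_ivw(hset),
                weighted_median = mr_weighted_median(hset, n_boot = n_boot,
                                                     seed = m_seed),
                mode = mr_mode(hset, n_boot = n_boot, seed = m_seed),
                presso = mr_presso(hset, n_sim = n_sim, seed = m_seed)$raw,
                stop("unknown method: ", m)))
            ests[[m]] <- e
            if (m == "ivw" && set_nm == "main") {
              ivw_store[[paste(ex_nm, out_nm, st_nm, sep = "|")]] <- e
            }
          }
          tidy <- mr_tidy(ests)
          tidy <- cbind(data.frame(exposure = ex_nm, outcome = out_nm,
                                   stratum = st_nm, instrument_set = set_nm,
                                   stringsAsFactors = FALSE), tidy)
          est_rows[[length(est_rows) + 1L]] <- tidy
        }
      }
    }
  }
  estimates <- do.call(rbind, est_rows)
  rownames(estimates) <- NULL

  contrast_rows <- list()
  pairs <- config$contrasts %||% list(c("men", "women"))
  for (ex_nm in names(exposures)) {
    for (out_nm in names(config$outcomes)) {
      for (pair in pairs) {
        em <- ivw_store[[paste(ex_nm, out_nm, pair[1], sep = "|")]]
        ew <- ivw_store[[paste(ex_nm, out_nm, pair[2], sep = "|")]]
        if (is.null(em) || is.null(ew)) next
        tst <- sex_difference_test(em$estimate$point, em$estimate$se,
                                   ew$estimate$point, ew$estimate$se)
        contrast_rows[[length(contrast_rows) + 1L]] <- data.frame(
          exposure = ex_nm, outcome = out_nm,
          stratum_men = pair[1], stratum_women = pair[2],
          z = tst$z, p_one_tailed = tst$p, stringsAsFactors = FALSE)
      }
    }
  }
  contrasts <- if (length(contrast_rows)) do.call(rbind, contrast_rows) else NULL

  power <- NULL
  if (!is.null(config$power)) {
    pw <- config$power
    pw$detectable_or <- detectable_or_binary(
      pw$n_total, pw$n_cases, pw$r2,
      power = pw$power %||% 0.8, alpha = pw$alpha %||% 0.05)
    power <- pw
  }

  manifest <- list(
    seed = seed, methods = methods, n_boot = n_boot, n_sim = n_sim,
    package_version = as.character(utils::packageVersion("sexmr")),
    selection = lapply(selection, as.data.frame),
    instrument_sets = sets)

  structure(list(selection = selection, estimates = estimates,
                 contrasts = contrasts, power = power, manifest = manifest),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat("MR pipeline report\n")
  cat(sprintf("  %d estimate row(s) over %d exposure(s)\n",
              nrow(x$estimates), length(unique(x$estimates$exposure))))
  if (!is.null(x$contrasts)) {
    cat(sprintf("  %d sex contrast(s)\n", nrow(x$contrasts)))
  }
  if (!is.null(x$power)) cat(sprintf("  %d power row(s)\n", nrow(x$power)))
  invisible(x)
}
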