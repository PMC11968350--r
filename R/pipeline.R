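# Orchestration of the full screen: many exposures against one outcome
# (forward), reverse MR, per-class FDR tiering, mediation scan, reports.

.default_thresholds <- function() {
  list(
    instrument_p = "auto", clump_r2 = 0.001, outcome_p = 0.05,
    f_min = 10, palindrome_eaf_window = 0.08
  )
}

.merge_defaults <- function(user, defaults) {
  if (is.null(user)) return(defaults)
  for (nm in names(defaults)) if (is.null(user[[nm]])) user[[nm]] <- defaults[[nm]]
  user
}

#' Read a screen configuration from YAML
#'
#' The YAML lists exposure files (with `trait_id`, `trait_class`, optional
#' `n_default`), one outcome file, an optional LD-matrix file and optional
#' mediator files, plus threshold overrides. File paths are resolved
#' relative to the YAML's directory and loaded into memory.
#'
#' @param path YAML file path.
#' @return config list consumable by [run_screen()].
#' @export
read_screen_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  load_table <- function(entry) {
    read_summary_stats(
      resolve(entry$file),
      trait_id = entry$trait_id %||% basename(entry$file),
      trait_class = entry$trait_class %||% "disease",
      n_default = entry$n_default
    )
  }
  cfg$exposures <- lapply(cfg$exposures, load_table)
  cfg$outcome <- load_table(cfg$outcome)
  if (!is.null(cfg$mediators)) cfg$mediators <- lapply(cfg$mediators, load_table)
  if (!is.null(cfg$ld)) cfg$ld <- read_ld_matrix(resolve(cfg$ld))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One exposure-outcome MR with QC, estimators, sensitivity and the
# pleiotropy remediation rule. Returns a one-row data.frame.
.mr_one_pair <- function(exposure, outcome, ld, thresholds, nb_sim = 1000,
                         outlier_alpha = 0.05, seed = NULL, steiger = TRUE) {
  th <- .merge_defaults(thresholds, .default_thresholds())
  empty_row <- function(status, nsnp = 0L) {
    data.frame(
      exposure = attr(exposure, "trait_id"),
      trait_class = attr(exposure, "trait_class"),
      outcome = attr(outcome, "trait_id"),
      status = status, nsnp = nsnp,
      beta = NA_real_, se = NA_real_, pval = NA_real_,
      or_ = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
      beta_egger = NA_real_, egger_intercept = NA_real_, egger_intercept_p = NA_real_,
      beta_wmedian = NA_real_, beta_wmode = NA_real_,
      Q = NA_real_, Q_p = NA_real_,
      presso_global_p = NA_real_, n_outliers_removed = 0L,
      steiger_direction = NA, steiger_p = NA_real_,
      F_aggregate = NA_real_, R2_total = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  iset <- tryCatch(
    build_instrument_set(
      exposure, outcome,
      ld = ld,
      p_threshold = th$instrument_p, clump_r2 = th$clump_r2,
      outcome_p = th$outcome_p, f_min = th$f_min, steiger = steiger,
      palindrome_eaf_window = th$palindrome_eaf_window
    ),
    error = function(e) e
  )
  if (inherits(iset, "error")) {
    row <- empty_row("skipped_error")
    row$note <- conditionMessage(iset)
    return(row)
  }
  pair <- iset$pair
  if (n_instruments(pair) < 2) {
    row <- empty_row("skipped_no_instruments", n_instruments(pair))
    row$note <- ""
    return(row)
  }

  estimate_row <- function(pair, n_removed) {
    J <- n_instruments(pair)
    ivw <- to_odds_ratio(mr_ivw(pair))
    sens <- run_sensitivity(pair,
      nb_sim = nb_sim, outlier_alpha = outlier_alpha, seed = seed
    )
    egger <- if (J >= 3) mr_egger(pair) else NULL
    wmed <- if (J >= 3) mr_weighted_median(pair, n_boot = 0) else NULL
    wmode <- if (J >= 3) mr_weighted_mode(pair, n_boot = 0) else NULL
    list(sens = sens, row = data.frame(
      exposure = attr(exposure, "trait_id"),
      trait_class = attr(exposure, "trait_class"),
      outcome = attr(outcome, "trait_id"),
      status = "ok", nsnp = J,
      beta = ivw$beta, se = ivw$se, pval = ivw$pval,
      or_ = ivw$or_, or_ci_low = ivw$or_ci_low, or_ci_high = ivw$or_ci_high,
      beta_egger = if (is.null(egger)) NA_real_ else egger$beta,
      egger_intercept = if (is.null(egger)) NA_real_ else egger$extras$intercept,
      egger_intercept_p = if (is.null(egger)) NA_real_ else egger$extras$intercept_pval,
      beta_wmedian = if (is.null(wmed)) NA_real_ else wmed$beta,
      beta_wmode = if (is.null(wmode)) NA_real_ else wmode$beta,
      Q = if (is.null(sens$Q)) NA_real_ else sens$Q$Q,
      Q_p = if (is.null(sens$Q)) NA_real_ else sens$Q$pval,
      presso_global_p = if (is.null(sens$presso)) NA_real_ else sens$presso$global_p,
      n_outliers_removed = n_removed,
      steiger_direction = if (is.null(sens$steiger)) NA else sens$steiger$direction,
      steiger_p = if (is.null(sens$steiger)) NA_real_ else sens$steiger$pval,
      F_aggregate = iset$F_aggregate, R2_total = iset$R2_total,
      stringsAsFactors = FALSE
    ))
  }

  fit <- estimate_row(pair, 0L)
  pleio <- function(f) {
    (!is.null(f$sens$egger_intercept) && f$sens$egger_intercept$pval < 0.05) ||
      (!is.null(f$sens$presso) && f$sens$presso$global_p < 0.05)
  }
  note <- ""
  if (pleio(fit)) {
    # remediation: drop MR-PRESSO outliers and re-estimate once
    out_ids <- if (!is.null(fit$sens$presso)) {
      fit$sens$presso$outliers$variant_id[fit$sens$presso$outliers$outlier]
    } else {
      character(0)
    }
    if (length(out_ids) && n_instruments(pair) - length(out_ids) >= 2) {
      pair2 <- .pair_subset(pair, !pair$variant_id %in% out_ids, "presso_outlier")
      fit2 <- estimate_row(pair2, length(out_ids))
      if (pleio(fit2)) {
        fit2$row$status <- "pleiotropy_unresolved"
        note <- "pleiotropy persists after outlier removal"
      } else {
        note <- sprintf("removed %d MR-PRESSO outlier(s)", length(out_ids))
      }
      fit <- fit2
    } else {
      fit$row$status <- "pleiotropy_unresolved"
      note <- "pleiotropy detected; no removable outliers"
    }
  }
  fit$row$note <- note
  fit$row
}

#' Run the forward causal screen
#'
#' For each configured exposure against the outcome: p-value thresholding
#' (auto by trait class), LD clumping, harmonization, outcome-overlap
#' exclusion, weak-instrument and Steiger filters, the estimator suite,
#' the sensitivity battery with the pleiotropy remediation rule (remove
#' MR-PRESSO outliers once; mark `pleiotropy_unresolved` if pleiotropy
#' persists), then per-trait-class BH-FDR tiering of the IVW p-values.
#' Per-exposure failures downgrade to a skipped row; they never abort the
#' screen.
#'
#' @param config list (or YAML path, see [read_screen_config()]) with
#'   elements `exposures` (list of [sumstats()]), `outcome`, optional `ld`
#'   ([ld_matrix()]), optional `thresholds`, `nb_sim`, `outlier_alpha`,
#'   `fdr` (list with `significant`, `suggestive_p`, `family`).
#' @param seed integer seed for the stochastic diagnostics.
#' @return data.frame of class `screen_result`, one row per exposure.
#' @export
run_screen <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_screen_config(config)
  seed <- seed %||% config$seed
  fdr_cfg <- .merge_defaults(
    config$fdr, list(significant = 0.1, suggestive_p = 0.05, family = "trait_class")
  )
  rows <- lapply(seq_along(config$exposures), function(i) {
    .mr_one_pair(
      config$exposures[[i]], config$outcome, config$ld,
      config$thresholds,
      nb_sim = config$nb_sim %||% 1000,
      outlier_alpha = config$outlier_alpha %||% 0.05,
      seed = if (is.null(seed)) NULL else seed + i
    )
  })
  res <- do.call(rbind, rows)
  ok <- res$status == "ok"
  res$fdr <- NA_real_
  res$tier <- NA_character_
  if (any(ok)) {
    fam <- if (identical(fdr_cfg$family, "trait_class")) res$trait_class[ok] else rep("all", sum(ok))
    sub <- tier_results(res[ok, , drop = FALSE],
      p_col = "pval", family = fam,
      fdr_cut = fdr_cfg$significant, p_cut = fdr_cfg$suggestive_p
    )
    res$fdr[ok] <- sub$fdr
    res$tier[ok] <- sub$tier
  }
  class(res) <- c("screen_result", "data.frame")
  attr(res, "seed") <- seed
  res
}

#' Run the reverse screen (disease as exposure)
#'
#' Same pipeline with exposure and outcome roles exchanged: the disease
#' trait's variants (instrumented at the genome-wide 5e-8 threshold that
#' `"auto"` resolves for disease traits) are tested against each original
#' exposure as outcome.
#'
#' @param config as for [run_screen()]; `config$outcome` becomes the
#'   exposure and each entry of `config$exposures` an outcome.
#' @param seed integer seed.
#' @return `screen_result` data.frame, one row per original exposure.
#' @export
run_reverse <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_screen_config(config)
  seed <- seed %||% config$seed
  fdr_cfg <- .merge_defaults(
    config$fdr, list(significant = 0.1, suggestive_p = 0.05, family = "trait_class")
  )
  rows <- lapply(seq_along(config$exposures), function(i) {
    .mr_one_pair(
      config$outcome, config$exposures[[i]], config$ld, config$thresholds,
      nb_sim = config$nb_sim %||% 1000,
      outlier_alpha = config$outlier_alpha %||% 0.05,
      seed = if (is.null(seed)) NULL else seed + 1000L + i
    )
  })
  res <- do.call(rbind, rows)
  ok <- res$status == "ok"
  res$fdr <- NA_real_
  res$tier <- NA_character_
  if (any(ok)) {
    sub <- tier_results(res[ok, , drop = FALSE],
      p_col = "pval", family = NULL,
      fdr_cut = fdr_cfg$significant, p_cut = fdr_cfg$suggestive_p
    )
    res$fdr[ok] <- sub$fdr
    res$tier[ok] <- sub$tier
  }
  class(res) <- c("screen_result", "data.frame")
  attr(res, "seed") <- seed
  res
}

#' Mediation scan driven by forward screen results
#'
#' For every exposure whose forward tier is `significant` or `suggestive`,
#' and every configured mediator: estimates step A (exposure -> mediator)
#' and step B (mediator -> outcome) with the same instrument pipeline, and
#' when both IVW p-values pass `p_cut` decomposes the forward total effect
#' with [two_step_mediation()]. Pairs failing a step are listed with the
#' failing step; results are sorted by decreasing |proportion mediated|.
#'
#' @param config as for [run_screen()], with a `mediators` list.
#' @param forward_results the [run_screen()] output.
#' @param seed integer seed.
#' @param p_cut per-step significance threshold (default 0.05).
#' @return data.frame: one row per (exposure, mediator) candidate pair.
#' @export
run_mediation_scan <- function(config, forward_results, seed = NULL, p_cut = 0.05) {
  if (is.character(config)) config <- read_screen_config(config)
  if (is.null(config$mediators) || !length(config$mediators)) {
    stop("config$mediators must list at least one mediator table")
  }
  keep <- forward_results$status == "ok" &
    forward_results$tier %in% c("significant", "suggestive")
  exposures <- config$exposures[
    vapply(config$exposures, function(e) attr(e, "trait_id"), character(1)) %in%
      forward_results$exposure[keep]
  ]
  if (!length(exposures)) {
    return(data.frame(
      exposure = character(0), mediator = character(0), status = character(0),
      stringsAsFactors = FALSE
    ))
  }
  step_a <- list()
  step_b <- list()
  for (mi in seq_along(config$mediators)) {
    med <- config$mediators[[mi]]
    b_row <- .mr_one_pair(
      med, config$outcome, config$ld, config$thresholds,
      nb_sim = config$nb_sim %||% 1000,
      seed = if (is.null(seed)) NULL else seed + 2000L + mi
    )
    step_b[[length(step_b) + 1]] <- data.frame(
      mediator = attr(med, "trait_id"),
      beta = b_row$beta, se = b_row$se,
      pval = ifelse(is.na(b_row$pval), 1, b_row$pval),
      stringsAsFactors = FALSE
    )
    for (ei in seq_along(exposures)) {
      a_row <- .mr_one_pair(
        exposures[[ei]], med, config$ld, config$thresholds,
        nb_sim = config$nb_sim %||% 1000,
        seed = if (is.null(seed)) NULL else seed + 3000L + 100L * mi + ei
      )
      step_a[[length(step_a) + 1]] <- data.frame(
        exposure = attr(exposures[[ei]], "trait_id"),
        mediator = attr(med, "trait_id"),
        beta = a_row$beta, se = a_row$se,
        pval = ifelse(is.na(a_row$pval), 1, a_row$pval),
        stringsAsFactors = FALSE
      )
    }
  }
  totals <- forward_results[keep, c("exposure", "beta", "se"), drop = FALSE]
  mediation_scan(
    totals, do.call(rbind, step_a), do.call(rbind, step_b), p_cut = p_cut
  )
}

#' Write screen outputs as TSV plus a JSON run manifest
#'
#' @param result a `screen_result`.
#' @param dir output directory (created if needed).
#' @param mediation optional mediation-scan table.
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(result, dir, mediation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, 6))
    df
  }
  utils::write.table(fmt(as.data.frame(result)), file.path(dir, "screen.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(mediation)) {
    utils::write.table(fmt(mediation), file.path(dir, "mediation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  manifest <- list(
    package = "mrscreen",
    version = as.character(utils::packageVersion("mrscreen")),
    seed = attr(result, "seed"),
    n_rows = nrow(result),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}
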