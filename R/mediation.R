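# Two-step MR mediation: indirect/direct effects and proportion mediated
# with delta-method confidence intervals.

#' Two-step MR mediation decomposition
#'
#' Combines the exposure -> mediator effect (`a`), the mediator -> outcome
#' effect (`b`) and the total exposure -> outcome effect (`c`):
#' mediation (indirect) effect `= a * b`, direct effect `= c - a * b`,
#' proportion mediated `= 100 * a * b / c` (percent). First-order
#' delta-method standard errors assume the three estimates come from
#' non-overlapping samples (no covariance terms):
#' `SE(ab) = sqrt(a^2 SE_b^2 + b^2 SE_a^2)`; the ratio-delta SE of the
#' proportion is `|prop| * sqrt(SE_ab^2/(ab)^2 + SE_c^2/c^2)`. A
#' numerator-only variant (`100 * SE_ab / |c|`) is also reported, since
#' published proportions are sometimes intervalled that way. 95% CIs are
#' `estimate +/- 1.96 * SE`. Proportions outside \[0, 100\]% are reported
#' as computed and flagged, never truncated.
#'
#' @param a,b,c point estimates for steps A, B and the total effect.
#' @param se_a,se_b,se_c their standard errors (all > 0).
#' @return object of class `mediation_result`: components `a`, `b`, `c`,
#'   `indirect`, `direct`, `proportion` (each with `se`, `ci_low`,
#'   `ci_high` where applicable), `consistent` (sign agreement of indirect
#'   and total) and `flags`.
#' @export
two_step_mediation <- function(a, se_a, b, se_b, c, se_c) {
  if (any(c(se_a, se_b, se_c) <= 0)) stop("all standard errors must be > 0")
  if (c == 0) stop("total effect c must be nonzero for the decomposition")
  indirect <- a * b
  se_ind <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  direct <- c - indirect
  # direct = c - ab, independent samples
  se_dir <- sqrt(se_c^2 + se_ind^2)
  proportion <- 100 * indirect / c
  se_prop_num <- 100 * se_ind / abs(c)
  se_prop_ratio <- if (indirect != 0) {
    abs(proportion) * sqrt(se_ind^2 / indirect^2 + se_c^2 / c^2)
  } else {
    se_prop_num
  }
  flags <- character(0)
  consistent <- sign(indirect) == sign(c)
  if (indirect != 0 && !consistent) flags <- c(flags, "inconsistent_mediation")
  if (abs(c) < 2 * se_c) flags <- c(flags, "unstable_total_effect")
  if (proportion < 0 || proportion > 100) flags <- c(flags, "proportion_outside_0_100")
  ci <- function(est, se) c(est - 1.96 * se, est + 1.96 * se)
  ci_ind <- ci(indirect, se_ind)
  ci_prop <- ci(proportion, se_prop_ratio)
  structure(list(
    a = list(beta = a, se = se_a),
    b = list(beta = b, se = se_b),
    c = list(beta = c, se = se_c),
    indirect = list(
      beta = indirect, se = se_ind, ci_low = ci_ind[1], ci_high = ci_ind[2]
    ),
    direct = list(beta = direct, se = se_dir),
    proportion = list(
      estimate = proportion, se = se_prop_ratio,
      se_ratio = se_prop_ratio, se_numerator = se_prop_num,
      ci_low = ci_prop[1], ci_high = ci_prop[2]
    ),
    consistent = consistent, flags = flags
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation_result> indirect = %.4g (95%% CI %.4g..%.4g), direct = %.4g, proportion = %.3g%%\n",
    x$indirect$beta, x$indirect$ci_low, x$indirect$ci_high,
    x$direct$beta, x$proportion$estimate
  ))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(
    a = x$a$beta, a_se = x$a$se, b = x$b$beta, b_se = x$b$se,
    c = x$c$beta, c_se = x$c$se,
    indirect = x$indirect$beta, indirect_se = x$indirect$se,
    indirect_ci_low = x$indirect$ci_low, indirect_ci_high = x$indirect$ci_high,
    direct = x$direct$beta,
    proportion = x$proportion$estimate, proportion_se = x$proportion$se,
    proportion_se_numerator = x$proportion$se_numerator,
    proportion_ci_low = x$proportion$ci_low,
    proportion_ci_high = x$proportion$ci_high,
    consistent = x$consistent,
    flags = paste(x$flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Mediation scan over candidate (exposure, mediator) pairs
#'
#' Tabular scan over precomputed MR estimates: one decomposition per
#' (exposure, mediator) pair whose step A (exposure -> mediator) and step B
#' (mediator -> outcome) estimates are both significant at `p_cut`; pairs
#' failing either step are listed with the failing step.
#'
#' @param exposure_estimates data.frame of total effects with columns
#'   `exposure`, `beta`, `se` (significant exposure -> outcome results).
#' @param step_a data.frame with columns `exposure`, `mediator`, `beta`,
#'   `se`, `pval`.
#' @param step_b data.frame with columns `mediator`, `beta`, `se`, `pval`.
#' @param p_cut per-step significance threshold (default 0.05).
#' @return data.frame with one row per candidate pair: `exposure`,
#'   `mediator`, `status` (`ok` / `step_a_not_significant` /
#'   `step_b_not_significant`), and the decomposition columns for `ok`
#'   rows, sorted by decreasing `|proportion|`.
#' @export
mediation_scan <- function(exposure_estimates, step_a, step_b, p_cut = 0.05) {
  rows <- list()
  for (i in seq_len(nrow(step_a))) {
    exp_id <- step_a$exposure[i]
    med_id <- step_a$mediator[i]
    tot <- exposure_estimates[exposure_estimates$exposure == exp_id, , drop = FALSE]
    if (!nrow(tot)) next
    bi <- which(step_b$mediator == med_id)
    base <- data.frame(
      exposure = exp_id, mediator = med_id, status = NA_character_,
      stringsAsFactors = FALSE
    )
    if (step_a$pval[i] >= p_cut) {
      base$status <- "step_a_not_significant"
      rows[[length(rows) + 1]] <- base
      next
    }
    if (!length(bi) || step_b$pval[bi[1]] >= p_cut) {
      base$status <- "step_b_not_significant"
      rows[[length(rows) + 1]] <- base
      next
    }
    med <- two_step_mediation(
      a = step_a$beta[i], se_a = step_a$se[i],
      b = step_b$beta[bi[1]], se_b = step_b$se[bi[1]],
      c = tot$beta[1], se_c = tot$se[1]
    )
    base$status <- "ok"
    rows[[length(rows) + 1]] <- cbind(base, as.data.frame(med))
  }
  if (!length(rows)) {
    return(data.frame(
      exposure = character(0), mediator = character(0), status = character(0),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    if (!"proportion" %in% names(r)) {
      r[setdiff(names(rows[[which.max(vapply(rows, ncol, 1L))]]), names(r))] <- NA
    }
    r
  }))
  if (!"proportion" %in% names(out)) return(out)
  key <- abs(out$proportion)
  key[is.na(key)] <- -Inf
  out[order(-key), , drop = FALSE]
}
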