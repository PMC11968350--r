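# Heterogeneity, pleiotropy, outlier and directionality diagnostics.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j * (Gamma_j - fitted_j)^2)` with `w_j = 1/se_Gamma_j^2`,
#' about either the IVW fit (df `J - 1`) or the Egger fit (df `J - 2`);
#' p from the upper chi-square tail. `P > 0.05` is read as absence of
#' significant heterogeneity among instruments.
#'
#' @param pair a `harmonized_pair`.
#' @param about `"ivw"` or `"egger"`.
#' @return list with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(pair, about = c("ivw", "egger")) {
  about <- match.arg(about)
  J <- n_instruments(pair)
  w <- 1 / pair$se_Gamma^2
  if (about == "ivw") {
    if (J < 2) stop("Q about IVW requires at least 2 instruments")
    fit <- mr_ivw(pair, effects_model = "fixed")
    Q <- sum(w * (pair$Gamma - fit$beta * pair$gamma)^2)
    df <- J - 1
  } else {
    if (J < 3) stop("Q about Egger requires at least 3 instruments")
    est <- mr_egger(pair)
    s <- ifelse(pair$gamma < 0, -1, 1)
    fitted <- est$extras$intercept + est$beta * (pair$gamma * s)
    Q <- sum(w * (pair$Gamma * s - fitted)^2)
    df <- J - 2
  }
  list(Q = Q, df = df, pval = stats::pchisq(Q, df = df, lower.tail = FALSE))
}

# Leave-one-out IVW point estimates, vectorized.
.loo_ivw_beta <- function(g, G, w) {
  num <- sum(w * g * G)
  den <- sum(w * g^2)
  (num - w * g * G) / (den - w * g^2)
}

#' MR-PRESSO: global pleiotropy test, outlier detection, distortion test
#'
#' The observed residual sum of squares uses leave-one-out IVW fits:
#' `RSS_obs = sum_j w_j (Gamma_j - beta_(-j) gamma_j)^2`. Each of `nb_sim`
#' replicates redraws `gamma* ~ N(gamma, se_gamma)` and
#' `Gamma* ~ N(beta_(-j) gamma, se_Gamma)` and recomputes the RSS with
#' leave-one-out fits on the simulated data; the global empirical p is
#' `(1 + #\{RSS* >= RSS_obs\}) / (nb_sim + 1)` (never exactly zero).
#' Per-variant outlier p-values compare each observed weighted residual
#' against its simulated distribution, Bonferroni-adjusted by J; the
#' distortion p compares the estimate shift after outlier removal against
#' random re-assignments of the outlier labels. All random draws are keyed
#' to the variants sorted by id, so input order does not change results.
#'
#' @param pair a `harmonized_pair` with at least 4 variants.
#' @param nb_sim number of simulated replicates (>= 100; default 1000).
#' @param outlier_alpha significance level for the Bonferroni-adjusted
#'   per-variant p (default 0.05).
#' @param seed integer seed for the simulation stream.
#' @return list with `global_p`, `outliers` (data.frame: variant_id,
#'   raw_p, adj_p, outlier), `distortion_p`, `beta_raw`, `beta_outlier_free`,
#'   `seed`.
#' @export
mr_presso <- function(pair, nb_sim = 1000, outlier_alpha = 0.05, seed = NULL) {
  J <- n_instruments(pair)
  if (J < 4) stop("MR-PRESSO requires at least 4 instruments, got ", J)
  if (nb_sim < 100) stop("nb_sim must be at least 100")
  ord <- order(pair$variant_id)
  ids <- pair$variant_id[ord]
  g <- pair$gamma[ord]
  G <- pair$Gamma[ord]
  sx <- pair$se_gamma[ord]
  sy <- pair$se_Gamma[ord]
  w <- 1 / sy^2

  loo <- .loo_ivw_beta(g, G, w)
  resid_obs <- w * (G - loo * g)^2
  rss_obs <- sum(resid_obs)

  sim <- .with_seed(seed, {
    gs <- matrix(stats::rnorm(nb_sim * J, mean = rep(g, each = nb_sim),
      sd = rep(sx, each = nb_sim)), nrow = nb_sim)
    Gs <- matrix(stats::rnorm(nb_sim * J, mean = rep(loo * g, each = nb_sim),
      sd = rep(sy, each = nb_sim)), nrow = nb_sim)
    wm <- matrix(w, nrow = nb_sim, ncol = J, byrow = TRUE)
    num <- rowSums(wm * gs * Gs)
    den <- rowSums(wm * gs^2)
    loo_s <- (num - wm * gs * Gs) / (den - wm * gs^2)
    resid_s <- wm * (Gs - loo_s * gs)^2
    list(resid = resid_s, rss = rowSums(resid_s))
  })

  global_p <- (1 + sum(sim$rss >= rss_obs)) / (nb_sim + 1)
  raw_p <- (1 + colSums(sim$resid >= matrix(resid_obs, nrow = nb_sim, ncol = J, byrow = TRUE))) /
    (nb_sim + 1)
  adj_p <- pmin(1, raw_p * J)
  is_out <- adj_p < outlier_alpha
  outliers <- data.frame(
    variant_id = ids, raw_p = raw_p, adj_p = adj_p, outlier = is_out,
    stringsAsFactors = FALSE
  )

  beta_raw <- sum(w * g * G) / sum(w * g^2)
  distortion_p <- NA_real_
  beta_free <- NA_real_
  n_out <- sum(is_out)
  if (n_out > 0 && J - n_out >= 2) {
    keep <- !is_out
    beta_free <- sum(w[keep] * g[keep] * G[keep]) / sum(w[keep] * g[keep]^2)
    d_obs <- beta_free - beta_raw
    d_perm <- .with_seed(if (is.null(seed)) NULL else seed + 1L, {
      vapply(seq_len(nb_sim), function(i) {
        drop <- sample.int(J, n_out)
        kk <- setdiff(seq_len(J), drop)
        sum(w[kk] * g[kk] * G[kk]) / sum(w[kk] * g[kk]^2) - beta_raw
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_perm) >= abs(d_obs))) / (nb_sim + 1)
  }
  list(
    global_p = global_p, outliers = outliers, distortion_p = distortion_p,
    beta_raw = beta_raw, beta_outlier_free = beta_free, seed = seed
  )
}

#' Leave-one-out IVW analysis
#'
#' Sequentially removes each instrument and recomputes the IVW estimate,
#' exposing variants that single-handedly drive the causal estimate.
#'
#' @param pair a `harmonized_pair` with at least 3 variants.
#' @return data.frame with one row per omitted variant: `variant_id`,
#'   `beta`, `se`, `pval`.
#' @export
leave_one_out <- function(pair) {
  J <- n_instruments(pair)
  if (J < 3) stop("leave-one-out requires at least 3 instruments, got ", J)
  rows <- lapply(seq_len(J), function(j) {
    sub <- .pair_subset(pair, seq_len(J) != j, "loo_omitted")
    est <- mr_ivw(sub)
    data.frame(
      variant_id = pair$variant_id[j], beta = est$beta, se = est$se,
      pval = est$pval, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Whole-set Steiger directionality test
#'
#' Compares total variance explained by the instrument set on the exposure
#' versus the outcome. Direction `TRUE` supports exposure -> outcome. The
#' p-value uses the normal test on the difference of Fisher-transformed
#' correlations `sqrt(R2)` with the two GWAS sample sizes.
#'
#' @param pair a `harmonized_pair` with sample sizes for both traits.
#' @return list with `direction`, `pval`, `r2_exposure`, `r2_outcome`.
#' @export
steiger_directionality <- function(pair) {
  if (any(is.na(pair$exposure_n)) || any(is.na(pair$outcome_n))) {
    stop("sample sizes for both traits are required")
  }
  r2_exp <- sum(r_squared_per_variant(
    beta = pair$gamma, pval = pair$exposure_pval, n = pair$exposure_n, mode = "from_pn"
  ))
  r2_out <- sum(r_squared_per_variant(
    beta = pair$Gamma, pval = pair$outcome_pval, n = pair$outcome_n, mode = "from_pn"
  ))
  n1 <- stats::median(pair$exposure_n)
  n2 <- stats::median(pair$outcome_n)
  r1 <- sqrt(min(r2_exp, 1))
  r2 <- sqrt(min(r2_out, 1))
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(
    direction = r2_exp > r2_out,
    pval = 2 * stats::pnorm(-abs(z)),
    r2_exposure = r2_exp, r2_outcome = r2_out
  )
}

#' Full sensitivity battery for one pair
#'
#' Cochran's Q (about IVW), the Egger intercept test, MR-PRESSO (when J >=
#' 4), leave-one-out estimates, and the whole-set Steiger directionality
#' test, with the seeds used recorded for replay.
#'
#' @param pair a `harmonized_pair`.
#' @param nb_sim,outlier_alpha MR-PRESSO controls.
#' @param seed integer seed.
#' @return list of class `sensitivity_report`.
#' @export
run_sensitivity <- function(pair, nb_sim = 1000, outlier_alpha = 0.05, seed = NULL) {
  J <- n_instruments(pair)
  rep <- list(
    Q = if (J >= 2) cochran_q(pair, "ivw") else NULL,
    egger_intercept = if (J >= 3) {
      e <- mr_egger(pair)
      list(
        value = e$extras$intercept, se = e$extras$intercept_se,
        pval = e$extras$intercept_pval
      )
    } else {
      NULL
    },
    presso = if (J >= 4) mr_presso(pair, nb_sim, outlier_alpha, seed) else NULL,
    loo = if (J >= 3) leave_one_out(pair) else NULL,
    steiger = if (!any(is.na(pair$exposure_n)) && !any(is.na(pair$outcome_n))) {
      steiger_directionality(pair)
    } else {
      NULL
    },
    seeds = list(presso = seed)
  )
  structure(rep, class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>\n")
  if (!is.null(x$Q)) cat(sprintf("  Q = %.4g (df %d), p = %.3g\n", x$Q$Q, x$Q$df, x$Q$pval))
  if (!is.null(x$egger_intercept)) {
    cat(sprintf(
      "  Egger intercept = %.4g (se %.4g), p = %.3g\n",
      x$egger_intercept$value, x$egger_intercept$se, x$egger_intercept$pval
    ))
  }
  if (!is.null(x$presso)) cat(sprintf("  MR-PRESSO global p = %.3g\n", x$presso$global_p))
  if (!is.null(x$steiger)) {
    cat(sprintf(
      "  Steiger direction exposure->outcome: %s (p = %.3g)\n",
      x$steiger$direction, x$steiger$pval
    ))
  }
  invisible(x)
}
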