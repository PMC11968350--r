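# Instrument selection and quality control: p-value thresholding, greedy LD
# clumping, outcome-overlap exclusion, F-statistic filtering, Steiger filtering.

#' Construct an LD matrix of squared correlations
#'
#' @param r2 square symmetric matrix of squared correlations, entries in
#'   \[0,1\], unit diagonal.
#' @param variant_ids variant identifiers (taken from `dimnames(r2)` when
#'   omitted).
#' @return object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, variant_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(variant_ids)) stop("variant_ids required (or set dimnames on r2)")
  if (nrow(r2) != ncol(r2)) stop("r2 must be square")
  dimnames(r2) <- list(variant_ids, variant_ids)
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("r2 diagonal must be 1")
  if (min(r2) < -1e-12 || max(r2) > 1 + 1e-12) stop("r2 entries must lie in [0,1]")
  structure(r2, class = c("ld_matrix", "matrix", "array"))
}

#' Read / write an LD matrix as square TSV with a variant-id header
#' @param path file path.
#' @return [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ld_matrix(as.matrix(raw), variant_ids = names(raw))
}

#' @rdname read_ld_matrix
#' @param x an `ld_matrix`.
#' @export
write_ld_matrix <- function(x, path) {
  out <- as.data.frame(unclass(x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Instrument p-value thresholding
#'
#' Keeps variants with `pval < threshold`. `"auto"` resolves the threshold
#' from the trait class: the genome-wide 5e-8 by default, loosened to 1e-5
#' for gut-microbiota and metabolite traits and 5e-5 for skin-microbiota
#' traits, where genome-wide-significant loci are scarce.
#'
#' @param table a [sumstats()] table.
#' @param threshold numeric p-value cut or `"auto"`.
#' @return filtered [sumstats()] table.
#' @export
select_by_pvalue <- function(table, threshold = "auto") {
  stopifnot(inherits(table, "sumstats"))
  thr <- resolve_p_threshold(threshold, attr(table, "trait_class"))
  p <- table$pval
  p[is.na(p)] <- 2 * stats::pnorm(-abs(table$beta / table$se))[is.na(p)]
  .reclass_sumstats(as.data.frame(table)[p < thr, , drop = FALSE], table)
}

#' @rdname select_by_pvalue
#' @param trait_class trait class used when `threshold = "auto"`.
#' @export
resolve_p_threshold <- function(threshold, trait_class) {
  if (identical(threshold, "auto")) {
    switch(trait_class,
      gut_microbiota = 1e-5,
      metabolite = 1e-5,
      skin_microbiota = 5e-5,
      5e-8
    )
  } else {
    stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 1)
    threshold
  }
}

#' Greedy LD clumping against a squared-correlation matrix
#'
#' Candidates are sorted by ascending p-value (ties broken by variant id)
#' and kept only if their r-squared with every previously kept variant is
#' below `r2_threshold`, mirroring the usual clumping of instruments to
#' approximate independence (default r2 < 0.001).
#'
#' @param candidates a [sumstats()] table.
#' @param ld an [ld_matrix()] covering every candidate.
#' @param r2_threshold squared-correlation threshold.
#' @return clumped [sumstats()] table.
#' @export
clump <- function(candidates, ld, r2_threshold = 0.001) {
  stopifnot(inherits(candidates, "sumstats"), inherits(ld, "ld_matrix"))
  ids <- candidates$variant_id
  missing_ids <- setdiff(ids, rownames(ld))
  if (length(missing_ids)) {
    stop("candidate(s) missing from LD matrix: ", paste(missing_ids, collapse = ", "))
  }
  p <- candidates$pval
  p[is.na(p)] <- 2 * stats::pnorm(-abs(candidates$beta / candidates$se))[is.na(p)]
  ord <- order(p, ids)
  kept <- character(0)
  for (i in ord) {
    id <- ids[i]
    if (!length(kept) || all(ld[id, kept] < r2_threshold)) kept <- c(kept, id)
  }
  keep_rows <- candidates$variant_id %in% kept
  .reclass_sumstats(as.data.frame(candidates)[keep_rows, , drop = FALSE], candidates)
}

#' Exclude instruments marginally associated with the outcome
#'
#' Variants whose two-sided outcome p-value (normal approximation
#' `2 * pnorm(-|Gamma/se|)`) falls below `p_cut` are moved to the drop log
#' with reason `outcome_associated`. When the harmonized pair carries a
#' file p-value that disagrees with the approximation by more than 10%, a
#' warning is issued (the approximation is still used, so the rule also
#' works on tables lacking a p column).
#'
#' @param pair a `harmonized_pair`.
#' @param p_cut exclusion threshold (default 0.05).
#' @return filtered `harmonized_pair`.
#' @export
exclude_outcome_associated <- function(pair, p_cut = 0.05) {
  stopifnot(inherits(pair, "harmonized_pair"))
  p_calc <- 2 * stats::pnorm(-abs(pair$Gamma / pair$se_Gamma))
  p_file <- pair$outcome_pval
  off <- !is.na(p_file) & p_calc > 0 & abs(p_file - p_calc) / p_calc > 0.10
  if (any(off)) {
    warning(sprintf(
      "outcome p for %s differs from the normal approximation by >10%%; using the approximation",
      paste(pair$variant_id[off], collapse = ", ")
    ), call. = FALSE)
  }
  .pair_subset(pair, p_calc >= p_cut, "outcome_associated")
}

#' Per-variant variance explained
#'
#' `"from_pn"` converts the marginal p-value into a squared partial
#' correlation via the t statistic at `n - 2` degrees of freedom:
#' `t = qt(p/2, n-2, lower=FALSE)`, `r2 = t^2 / (t^2 + n - 2)`.
#' `"from_beta_eaf"` assumes a standardized trait and uses
#' `r2 = 2 * eaf * (1 - eaf) * beta^2`.
#'
#' @param beta,eaf,pval,n per-variant statistics (vectors allowed).
#' @param mode `"from_pn"` or `"from_beta_eaf"`.
#' @return variance-explained fraction(s).
#' @export
r_squared_per_variant <- function(beta = NULL, eaf = NULL, pval = NULL, n = NULL,
                                  mode = c("from_pn", "from_beta_eaf")) {
  mode <- match.arg(mode)
  if (mode == "from_pn") {
    if (is.null(pval) || is.null(n)) stop("from_pn mode requires pval and n")
    if (any(n <= 2, na.rm = TRUE)) stop("from_pn mode requires n > 2")
    t2 <- stats::qt(pmin(pval, 1) / 2, df = n - 2, lower.tail = FALSE)^2
    r2 <- t2 / (t2 + n - 2)
    if (!is.null(beta)) r2[beta == 0] <- 0
    r2
  } else {
    if (is.null(beta) || is.null(eaf)) stop("from_beta_eaf mode requires beta and eaf")
    if (any(is.na(eaf))) stop("from_beta_eaf mode requires eaf for every variant")
    2 * eaf * (1 - eaf) * beta^2
  }
}

#' Instrument-strength F statistic
#'
#' `F = (R2 * (n - k - 1)) / (k * (1 - R2))` with `R2` the variance in the
#' exposure explained by the `k` instruments and `n` the GWAS sample size.
#' `F < 10` conventionally indicates weak instruments.
#'
#' @param R2 variance-explained fraction in \[0, 1).
#' @param n sample size (`n > k + 1`).
#' @param k number of instruments.
#' @return F value.
#' @export
f_statistic <- function(R2, n, k = 1) {
  if (any(R2 < 0 | R2 >= 1)) stop("R2 must lie in [0, 1)")
  if (any(n <= k + 1)) stop("need n > k + 1")
  if (any(k < 1)) stop("k must be >= 1")
  (R2 * (n - k - 1)) / (k * (1 - R2))
}

#' Remove weak instruments (per-variant F below a floor)
#'
#' Computes each variant's F with `k = 1` from its variance explained on
#' the exposure ([r_squared_per_variant()], `from_pn`) and drops variants
#' with `F < f_min` (reason `weak_instrument`).
#'
#' @param pair a `harmonized_pair` with exposure sample sizes.
#' @param f_min weak-instrument floor (default 10).
#' @return filtered `harmonized_pair`.
#' @export
filter_weak <- function(pair, f_min = 10) {
  stopifnot(inherits(pair, "harmonized_pair"))
  if (!n_instruments(pair)) return(pair)
  if (any(is.na(pair$exposure_n))) stop("exposure sample sizes required for the F filter")
  r2 <- r_squared_per_variant(
    beta = pair$gamma, pval = pair$exposure_pval, n = pair$exposure_n,
    mode = "from_pn"
  )
  f <- f_statistic(r2, pair$exposure_n, k = 1)
  .pair_subset(pair, f >= f_min, "weak_instrument")
}

#' Per-variant Steiger filtering
#'
#' Drops variants explaining more variance in the outcome than in the
#' exposure (reason `steiger_reverse`); exact ties are kept with the
#' `steiger_tie` flag set.
#'
#' @param pair a `harmonized_pair` with sample sizes for both traits.
#' @return filtered `harmonized_pair`.
#' @export
steiger_filter <- function(pair) {
  stopifnot(inherits(pair, "harmonized_pair"))
  if (!n_instruments(pair)) return(pair)
  if (any(is.na(pair$exposure_n)) || any(is.na(pair$outcome_n))) {
    stop("exposure and outcome sample sizes required for Steiger filtering")
  }
  r2_exp <- r_squared_per_variant(
    beta = pair$gamma, pval = pair$exposure_pval, n = pair$exposure_n, mode = "from_pn"
  )
  r2_out <- r_squared_per_variant(
    beta = pair$Gamma, pval = pair$outcome_pval, n = pair$outcome_n, mode = "from_pn"
  )
  pair$steiger_tie <- r2_out == r2_exp
  .pair_subset(pair, r2_out <= r2_exp, "steiger_reverse")
}

#' Full instrument-selection pipeline for one exposure-outcome pair
#'
#' Applies, in order: p-value thresholding (auto by trait class), greedy LD
#' clumping, allele harmonization, outcome-overlap exclusion, the
#' weak-instrument F filter, and per-variant Steiger filtering, and
#' summarises the surviving set (count, aggregate variance explained as the
#' sum of per-variant r-squared, aggregate F).
#'
#' @param exposure,outcome [sumstats()] tables.
#' @param ld [ld_matrix()] covering the thresholded candidates (`NULL`
#'   skips clumping, e.g. when candidates are known to be independent).
#' @param p_threshold instrument p threshold or `"auto"`.
#' @param clump_r2 clumping threshold.
#' @param outcome_p outcome-overlap exclusion threshold.
#' @param f_min weak-instrument floor.
#' @param steiger apply the per-variant Steiger filter?
#' @param palindrome_eaf_window see [harmonize()].
#' @return list of class `instrument_set`: `pair`, `k`, `R2_total`,
#'   `F_aggregate`, `filter_log` (per-variant filter decisions).
#' @export
build_instrument_set <- function(exposure, outcome, ld = NULL,
                                 p_threshold = "auto", clump_r2 = 0.001,
                                 outcome_p = 0.05, f_min = 10, steiger = TRUE,
                                 palindrome_eaf_window = 0.08) {
  candidates <- select_by_pvalue(exposure, p_threshold)
  clumped <- if (!is.null(ld) && nrow(candidates)) clump(candidates, ld, clump_r2) else candidates
  pre_clump <- setdiff(candidates$variant_id, clumped$variant_id)
  pair <- harmonize(clumped, outcome, palindrome_eaf_window)
  pair <- exclude_outcome_associated(pair, outcome_p)
  pair <- filter_weak(pair, f_min)
  if (steiger) pair <- steiger_filter(pair)
  if (length(pre_clump)) {
    pair$drop_log <- rbind(
      data.frame(variant_id = pre_clump, reason = "ld_clumped", stringsAsFactors = FALSE),
      pair$drop_log
    )
  }
  k <- n_instruments(pair)
  if (k) {
    r2 <- r_squared_per_variant(
      beta = pair$gamma, pval = pair$exposure_pval, n = pair$exposure_n, mode = "from_pn"
    )
    R2_total <- sum(r2)
    n_exp <- stats::median(pair$exposure_n)
    F_aggregate <- if (n_exp > k + 1 && R2_total < 1) f_statistic(R2_total, n_exp, k) else NA_real_
  } else {
    R2_total <- 0
    F_aggregate <- NA_real_
  }
  # the filter log tracks exposure candidates; outcome-only variants from
  # harmonization bookkeeping are not candidates
  filter_log <- rbind(
    pair$drop_log[pair$drop_log$reason != "not_in_exposure", , drop = FALSE],
    if (k) data.frame(variant_id = pair$variant_id, reason = "kept", stringsAsFactors = FALSE)
  )
  structure(list(
    pair = pair, k = k, R2_total = R2_total, F_aggregate = F_aggregate,
    filter_log = filter_log
  ), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf(
    "<instrument_set> %s -> %s: k=%d, R2=%.4g, F=%.4g\n",
    x$pair$exposure_id, x$pair$outcome_id, x$k, x$R2_total, x$F_aggregate
  ))
  invisible(x)
}

#' Export a per-variant filter log as TSV
#' @param x an `instrument_set`.
#' @param path output path.
#' @export
write_filter_log <- function(x, path) {
  utils::write.table(x$filter_log, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
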