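# Cross-cutting statistics: BH-FDR with significance tiering, simplified
# bivariate LD-score regression, hypergeometric pathway enrichment.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (delegates to
#' `stats::p.adjust(method = "BH")`), returned in input order.
#'
#' @param pvals vector of p-values in \[0, 1\].
#' @return adjusted values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1] and be non-missing")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Significance tier of an IVW result
#'
#' `significant` when FDR < 0.1; `suggestive` when the raw IVW p < 0.05
#' but FDR >= 0.1; otherwise `null`.
#'
#' @param pval raw IVW p-value(s).
#' @param fdr BH-adjusted value(s).
#' @param fdr_cut,p_cut tier thresholds (defaults 0.1 and 0.05).
#' @return character vector of tier labels.
#' @export
tier <- function(pval, fdr, fdr_cut = 0.1, p_cut = 0.05) {
  stopifnot(all(pval >= 0 & pval <= 1), all(fdr >= 0 & fdr <= 1))
  ifelse(fdr < fdr_cut, "significant",
    ifelse(pval < p_cut, "suggestive", "null")
  )
}

#' Attach FDR and tiers to a result table, by family
#'
#' Adjusts the raw p-values within each family (by default the exposure
#' trait class, matching per-class reporting of screen results) and labels
#' each row's tier.
#'
#' @param results data.frame with a p-value column.
#' @param p_col name of the raw p column.
#' @param family optional vector (or column name) defining adjustment
#'   families; `NULL` adjusts all rows together.
#' @param fdr_cut,p_cut tier thresholds.
#' @return `results` with `fdr` and `tier` columns appended.
#' @export
tier_results <- function(results, p_col = "pval", family = NULL,
                         fdr_cut = 0.1, p_cut = 0.05) {
  p <- results[[p_col]]
  fam <- if (is.null(family)) {
    rep("all", nrow(results))
  } else if (length(family) == 1 && is.character(family) && family %in% names(results)) {
    results[[family]]
  } else {
    family
  }
  fdr <- rep(NA_real_, nrow(results))
  for (f in unique(fam)) {
    idx <- which(fam == f & !is.na(p))
    if (length(idx)) fdr[idx] <- bh_fdr(p[idx])
  }
  results$fdr <- fdr
  results$tier <- ifelse(is.na(p) | is.na(fdr), NA_character_,
    tier(ifelse(is.na(p), 1, p), ifelse(is.na(fdr), 1, fdr), fdr_cut, p_cut)
  )
  results
}

#' Simplified bivariate LD-score regression
#'
#' Univariate step: regress `chi2_j = z_j^2` on the LD scores `l_j` with a
#' free intercept and weights `1/max(l_j, 1)`; the slope times `M/N` is
#' the SNP heritability. Bivariate step: regress `z1_j * z2_j` on `l_j`;
#' the slope times `M/sqrt(N1*N2)` is the genetic covariance. The genetic
#' correlation is `rg = rho_g / sqrt(h2_1 * h2_2)`. This is a single-step
#' weighted least squares (no block jackknife, no two-step intercept
#' constraint); it is designed for synthetic-data recovery, not as a
#' reimplementation of the full published LDSC tool.
#'
#' @param z1,z2 z-score vectors (length >= 50).
#' @param ld_scores per-variant LD scores (>= 1).
#' @param N1,N2 GWAS sample sizes.
#' @param M number of SNPs the LD scores sum over.
#' @return list of class `ldsc_result`: `h2_1`, `h2_2`, `rho_g`, `rg`
#'   (NA with a flag when a heritability estimate in the denominator is
#'   non-positive), `rg_clamped` (report value clamped to \[-1, 1\]),
#'   `intercepts`, `flags`.
#' @export
ldsc_bivariate <- function(z1, z2, ld_scores, N1, N2, M = length(ld_scores)) {
  J <- length(ld_scores)
  stopifnot(length(z1) == J, length(z2) == J)
  if (J < 50) stop("at least 50 variants are required")
  if (any(ld_scores < 1)) stop("LD scores must be >= 1")
  w <- 1 / pmax(ld_scores, 1)
  f1 <- .wls2(ld_scores, z1^2, w)
  f2 <- .wls2(ld_scores, z2^2, w)
  fc <- .wls2(ld_scores, z1 * z2, w)
  h2_1 <- f1$slope * M / N1
  h2_2 <- f2$slope * M / N2
  rho_g <- fc$slope * M / sqrt(N1 * N2)
  flags <- character(0)
  if (h2_1 < 0 || h2_2 < 0) flags <- c(flags, "negative_h2")
  rg <- if (h2_1 > 0 && h2_2 > 0) rho_g / sqrt(h2_1 * h2_2) else NA_real_
  if (is.na(rg)) flags <- c(flags, "rg_undefined")
  rg_clamped <- if (is.na(rg)) NA_real_ else max(-1, min(1, rg))
  if (!is.na(rg) && abs(rg) > 1) flags <- c(flags, "rg_clamped")
  structure(list(
    h2_1 = h2_1, h2_2 = h2_2, rho_g = rho_g, rg = rg, rg_clamped = rg_clamped,
    intercepts = c(
      univariate_1 = f1$intercept, univariate_2 = f2$intercept,
      bivariate = fc$intercept
    ),
    N1 = N1, N2 = N2, M = M, flags = flags
  ), class = "ldsc_result")
}

#' @export
print.ldsc_result <- function(x, ...) {
  cat(sprintf(
    "<ldsc_result> h2 = %.3g / %.3g, rho_g = %.3g, rg = %.3g\n",
    x$h2_1, x$h2_2, x$rho_g, x$rg
  ))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Hypergeometric pathway over-representation test
#'
#' For each pathway (intersected with the universe of size `M`): with `K`
#' pathway members, `n` hits and `k` overlapping compounds, the upper-tail
#' p-value is `P(X >= k)` for `X ~ Hypergeometric(K, M - K, n)`. BH
#' adjustment is applied across pathways; `significant` marks raw
#' `p < p_cut` (default 0.01).
#'
#' @param hits character vector of hit compounds (subset of `universe`).
#' @param library named list of pathways, each a character vector of
#'   compound ids (see [read_pathway_library()]).
#' @param universe character vector of all testable compounds.
#' @param p_cut raw-p significance level.
#' @return data.frame, one row per pathway: `pathway`, `K`, `n`, `k`,
#'   `pval`, `fdr`, `significant`, sorted by ascending p.
#' @export
hypergeom_enrich <- function(hits, library, universe, p_cut = 0.01) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe must be non-empty")
  hits <- unique(intersect(hits, universe))
  M <- length(universe)
  n <- length(hits)
  rows <- lapply(names(library), function(pw) {
    members <- intersect(library[[pw]], universe)
    K <- length(members)
    k <- length(intersect(members, hits))
    p <- stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(
      pathway = pw, K = K, n = n, k = k, pval = p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$pval)
  out$significant <- out$pval < p_cut
  out[order(out$pval, out$pathway), , drop = FALSE]
}

#' Read / write a pathway library TSV (pathway_name, compound_id pairs)
#' @param path file path.
#' @return named list mapping pathway name to compound id vector.
#' @export
read_pathway_library <- function(path) {
  raw <- utils::read.table(path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE
  )
  split(raw$compound_id, raw$pathway_name)
}

#' @rdname read_pathway_library
#' @param library named list of pathways.
#' @export
write_pathway_library <- function(library, path) {
  out <- data.frame(
    pathway_name = rep(names(library), lengths(library)),
    compound_id = unlist(library, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
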