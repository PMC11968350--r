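# Synthetic GWAS summary statistics with known ground truth: causal chains,
# pleiotropy, block LD, weak instruments, LDSC inputs, toy pathway libraries.
# Statistics are generated directly at the summary level: per-variant
# standardized effects plus sampling noise 1/sqrt(2*maf*(1-maf)*n), which is
# orders of magnitude faster than genotype-level simulation and sufficient
# for parameter-recovery testing.

#' Simulation configuration for a GWAS summary-statistics triplet
#'
#' Defines the generative model for an exposure / (optional) mediator /
#' outcome trio with a known causal chain. Per-variant sampling noise is
#' `se = 1/sqrt(2 maf (1-maf) n)` (standardized traits, per-allele scale);
#' binary outcomes reuse the same machinery with betas read as log-odds.
#'
#' @param m_snps total number of variants.
#' @param j_causal number of variants with a nonzero exposure effect
#'   (assigned to distinct LD-block leads).
#' @param maf_range uniform bounds for minor-allele frequencies, in (0, 0.5].
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes. Defaults follow
#'   the scale of desk-sized metabolite-style exposure GWAS (~8,300) and a
#'   large biobank case-control outcome (244,562).
#' @param beta_total total exposure -> outcome effect (used when no
#'   mediation chain is requested).
#' @param a,b,c_prime mediation chain: exposure -> mediator, mediator ->
#'   outcome, and direct exposure -> outcome effects. When given, the total
#'   effect is `c_prime + a*b` and a mediator table is emitted.
#' @param j_causal_mediator number of mediator-specific causal variants
#'   (block leads distinct from the exposure's; defaults to `j_causal`).
#'   Without own instruments the mediator -> outcome step of two-step MR is
#'   not identified.
#' @param exposure_r2 variance in the exposure explained per causal variant
#'   (default 0.003, a typical lead-SNP value).
#' @param mediator_r2 variance in the mediator explained per mediator-own
#'   causal variant (defaults to `exposure_r2`).
#' @param pleiotropy list(fraction, mean, sd): share of exposure instruments
#'   receiving a direct (standardized) outcome effect drawn from
#'   N(mean, sd); mean 0 gives balanced, nonzero mean directional
#'   pleiotropy.
#' @param ld list(block_size, rho): AR(1) correlation within consecutive
#'   blocks (`r(i, j) = rho^|i-j|`), independence across blocks.
#' @param selection_threshold optional winner's-curse switch: observed
#'   exposure effects at causal variants are redrawn until genome-wide
#'   p < threshold.
#' @param overlap_rho correlation between exposure and outcome sampling
#'   noise (sample-overlap artifact switch).
#' @param seed integer seed; the whole draw is deterministic given the
#'   config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(m_snps = 120, j_causal = 30, maf_range = c(0.05, 0.5),
                       n_exposure = 8299, n_mediator = 8299, n_outcome = 244562,
                       beta_total = 0.2, a = NULL, b = NULL, c_prime = NULL,
                       j_causal_mediator = j_causal, exposure_r2 = 0.003,
                       mediator_r2 = exposure_r2,
                       pleiotropy = list(fraction = 0, mean = 0, sd = 0),
                       ld = list(block_size = 1, rho = 0),
                       selection_threshold = NULL, overlap_rho = 0,
                       seed = 1L) {
  chain <- !is.null(a) && !is.null(b) && !is.null(c_prime)
  cfg <- list(
    m_snps = m_snps, j_causal = j_causal, maf_range = maf_range,
    n_exposure = n_exposure, n_mediator = n_mediator, n_outcome = n_outcome,
    beta_total = beta_total, a = a, b = b, c_prime = c_prime, chain = chain,
    j_causal_mediator = if (chain) j_causal_mediator else 0L,
    exposure_r2 = exposure_r2, mediator_r2 = mediator_r2,
    pleiotropy = pleiotropy, ld = ld,
    selection_threshold = selection_threshold, overlap_rho = overlap_rho,
    seed = as.integer(seed)
  )
  n_blocks <- ceiling(m_snps / ld$block_size)
  if (j_causal > n_blocks) stop("j_causal exceeds the number of LD blocks")
  if (chain && j_causal + j_causal_mediator > n_blocks) {
    stop("j_causal + j_causal_mediator exceeds the number of LD blocks")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie in (0, 0.5]")
  }
  if (pleiotropy$fraction < 0 || pleiotropy$fraction > 1) stop("pleiotropy fraction in [0,1]")
  if (ld$rho < 0 || ld$rho >= 1) stop("ld rho must lie in [0, 1)")
  structure(cfg, class = "sim_config")
}

# observed per-allele summary stats for one trait given standardized truth
.observe_trait <- function(true_std, maf, n, noise_std) {
  scale <- sqrt(2 * maf * (1 - maf))
  beta <- (true_std + noise_std / sqrt(n)) / scale
  se <- 1 / (scale * sqrt(n))
  pval <- 2 * stats::pnorm(-abs(beta / se))
  list(beta = beta, se = se, pval = pmax(pval, .Machine$double.xmin))
}

#' Simulate an exposure/mediator/outcome summary-statistics triplet
#'
#' Draws MAFs, assigns standardized causal effects to LD-block leads,
#' propagates them through the AR(1) within-block correlation, optionally
#' adds pleiotropic direct effects on the outcome, and emits observed
#' per-allele summary statistics with allele codes, frequencies, p-values
#' and sample sizes, together with the LD matrix and the ground truth.
#'
#' @param config a [sim_config()].
#' @return list with elements `exposure`, `mediator` (NULL unless a chain
#'   was configured), `outcome` ([sumstats()] tables), `ld`
#'   ([ld_matrix()]), and `truth` (class `sim_truth`: standardized true
#'   effects, causal/pleiotropic variant ids, `total`, `indirect`,
#'   `direct`, `proportion`).
#' @export
simulate_triplet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  m <- cf$m_snps
  .with_seed(cf$seed, {
    ids <- sprintf("rs%05d", seq_len(m))
    maf <- stats::runif(m, cf$maf_range[1], cf$maf_range[2])
    block <- rep(seq_len(ceiling(m / cf$ld$block_size)), each = cf$ld$block_size)[seq_len(m)]
    pos_in_block <- stats::ave(seq_len(m), block, FUN = seq_along)
    lead_idx <- which(pos_in_block == 1)

    exp_lead <- lead_idx[seq_len(cf$j_causal)]
    med_lead <- if (cf$chain && cf$j_causal_mediator > 0) {
      lead_idx[cf$j_causal + seq_len(cf$j_causal_mediator)]
    } else {
      integer(0)
    }

    # standardized lead effects
    exp_std <- numeric(m)
    exp_std[exp_lead] <- sample(c(-1, 1), cf$j_causal, replace = TRUE) *
      sqrt(cf$exposure_r2)
    med_own_std <- numeric(m)
    if (length(med_lead)) {
      med_own_std[med_lead] <- sample(c(-1, 1), cf$j_causal_mediator, replace = TRUE) *
        sqrt(cf$mediator_r2)
    }

    # pleiotropic direct effects on the outcome, at a share of exposure leads
    n_pleio <- round(cf$pleiotropy$fraction * cf$j_causal)
    pleio_idx <- if (n_pleio > 0) sample(exp_lead, n_pleio) else integer(0)
    pleio_std <- numeric(m)
    if (n_pleio > 0) {
      pleio_std[pleio_idx] <- stats::rnorm(n_pleio, cf$pleiotropy$mean, cf$pleiotropy$sd)
    }

    total <- if (cf$chain) cf$c_prime + cf$a * cf$b else cf$beta_total
    med_std <- if (cf$chain) cf$a * exp_std + med_own_std else NULL
    out_std <- if (cf$chain) {
      cf$c_prime * exp_std + cf$b * med_std + pleio_std
    } else {
      cf$beta_total * exp_std + pleio_std
    }

    # AR(1) propagation: correlated neighbours carry r x the lead effect
    r_to_lead <- cf$ld$rho^(pos_in_block - 1)
    propagate <- function(std) std[lead_idx[block]] * r_to_lead
    exp_std <- propagate(exp_std)
    if (cf$chain) med_std <- propagate(med_std)
    out_std <- propagate(out_std)

    # correlated sampling noise emulates sample overlap when requested
    z_exp <- stats::rnorm(m)
    z_out_ind <- stats::rnorm(m)
    z_out <- cf$overlap_rho * z_exp + sqrt(1 - cf$overlap_rho^2) * z_out_ind

    obs_exp <- .observe_trait(exp_std, maf, cf$n_exposure, z_exp)
    obs_out <- .observe_trait(out_std, maf, cf$n_outcome, z_out)
    obs_med <- if (cf$chain) .observe_trait(med_std, maf, cf$n_mediator, stats::rnorm(m)) else NULL

    # winner's-curse switch: redraw causal exposure stats until significant
    if (!is.null(cf$selection_threshold)) {
      for (i in exp_lead) {
        tries <- 0
        while (obs_exp$pval[i] >= cf$selection_threshold && tries < 1000) {
          z <- stats::rnorm(1)
          scale <- sqrt(2 * maf[i] * (1 - maf[i]))
          obs_exp$beta[i] <- (exp_std[i] + z / sqrt(cf$n_exposure)) / scale
          obs_exp$pval[i] <- 2 * stats::pnorm(-abs(obs_exp$beta[i] / obs_exp$se[i]))
          tries <- tries + 1
        }
      }
    }

    allele_pairs <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"),
      c("A", "C"), c("G", "T"))
    ap <- allele_pairs[sample.int(length(allele_pairs), m, replace = TRUE)]
    ea <- vapply(ap, `[`, character(1), 1)
    oa <- vapply(ap, `[`, character(1), 2)

    make_table <- function(obs, n, trait_id, trait_class) {
      sumstats(
        data.frame(
          variant_id = ids, effect_allele = ea, other_allele = oa,
          eaf = maf, beta = obs$beta, se = obs$se, pval = obs$pval, n = n,
          stringsAsFactors = FALSE
        ),
        trait_id = trait_id, trait_class = trait_class
      )
    }

    # block AR(1) squared-correlation matrix
    r2 <- diag(m)
    for (bk in unique(block)) {
      idx <- which(block == bk)
      if (length(idx) > 1) {
        d <- abs(outer(pos_in_block[idx], pos_in_block[idx], "-"))
        r2[idx, idx] <- (cf$ld$rho^d)^2
      }
    }
    dimnames(r2) <- list(ids, ids)

    truth <- structure(list(
      beta_exposure_std = exp_std,
      beta_mediator_std = med_std,
      beta_outcome_std = out_std,
      causal_exposure = ids[exp_lead],
      causal_mediator = ids[med_lead],
      pleiotropic = ids[pleio_idx],
      a = cf$a, b = cf$b, c_prime = cf$c_prime,
      indirect = if (cf$chain) cf$a * cf$b else 0,
      total = total,
      direct = if (cf$chain) cf$c_prime else cf$beta_total,
      proportion = if (cf$chain && total != 0) 100 * cf$a * cf$b / total else NA_real_,
      maf = maf
    ), class = "sim_truth")

    list(
      exposure = make_table(obs_exp, cf$n_exposure, "sim_exposure", "gut_microbiota"),
      mediator = if (cf$chain) make_table(obs_med, cf$n_mediator, "sim_mediator", "immune_cell"),
      outcome = make_table(obs_out, cf$n_outcome, "sim_outcome", "disease"),
      ld = ld_matrix(r2),
      truth = truth
    )
  })
}

#' Simulate z-scores and LD scores for LD-score regression
#'
#' LD scores are drawn from a shifted gamma (minimum 1). Per variant the
#' pair `(z1_j, z2_j)` is bivariate normal with
#' `Var(z_i) = 1 + N_i h2_i l_j / M` and
#' `Cov = rg sqrt(h2_1 h2_2) sqrt(N1 N2) l_j / M` — the generative twin of
#' the regression model fitted by [ldsc_bivariate()].
#'
#' @param h2_1,h2_2 SNP heritabilities in \[0, 1\].
#' @param rg genetic correlation, |rg| <= 1.
#' @param N1,N2 GWAS sample sizes.
#' @param M number of variants.
#' @param seed integer seed.
#' @return list with `z1`, `z2`, `ld_scores`, `N1`, `N2`, `M`.
#' @export
simulate_ldsc_inputs <- function(h2_1, h2_2, rg, N1, N2, M, seed = 1L) {
  stopifnot(h2_1 >= 0, h2_1 <= 1, h2_2 >= 0, h2_2 <= 1, abs(rg) <= 1)
  .with_seed(seed, {
    l <- 1 + stats::rgamma(M, shape = 2, rate = 0.02)
    v1 <- 1 + N1 * h2_1 * l / M
    v2 <- 1 + N2 * h2_2 * l / M
    cv <- rg * sqrt(h2_1 * h2_2) * sqrt(N1 * N2) * l / M
    if (any(cv^2 >= v1 * v2)) stop("requested parameters give a non-PD covariance")
    x1 <- stats::rnorm(M)
    x2 <- stats::rnorm(M)
    z1 <- sqrt(v1) * x1
    z2 <- (cv / sqrt(v1)) * x1 + sqrt(v2 - cv^2 / v1) * x2
    list(z1 = z1, z2 = z2, ld_scores = l, N1 = N1, N2 = N2, M = M)
  })
}

#' Generate a toy pathway library with one planted enriched pathway
#'
#' Builds random pathways over a synthetic compound universe and a hit set
#' in which members of the planted pathway are over-sampled by
#' `enrichment_factor` (1 = no enrichment).
#'
#' @param n_pathways number of pathways.
#' @param size_range integer bounds on pathway sizes.
#' @param universe_size number of compounds in the universe.
#' @param n_hits size of the hit set.
#' @param enrichment_factor sampling-weight multiplier for planted-pathway
#'   members when drawing hits.
#' @param seed integer seed.
#' @return list with `library` (named list; the planted pathway is
#'   `"planted"`), `hits`, `universe`, `planted`.
#' @export
make_pathway_library <- function(n_pathways = 20, size_range = c(10, 40),
                                 universe_size = 500, n_hits = 30,
                                 enrichment_factor = 10, seed = 1L) {
  .with_seed(seed, {
    universe <- sprintf("C%05d", seq_len(universe_size))
    sizes <- size_range[1] - 1L +
      sample.int(size_range[2] - size_range[1] + 1L, n_pathways, replace = TRUE)
    lib <- lapply(sizes, function(s) sample(universe, s))
    names(lib) <- sprintf("pathway_%02d", seq_len(n_pathways))
    names(lib)[1] <- "planted"
    wts <- rep(1, universe_size)
    wts[universe %in% lib[["planted"]]] <- enrichment_factor
    hits <- sample(universe, n_hits, prob = wts)
    list(library = lib, hits = hits, universe = universe, planted = "planted")
  })
}
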