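# Shared fixtures built in code.

# A small, valid summary-stats data.frame with internally consistent p-values.
toy_sumstats_df <- function(n = 5, seed = 1) {
  set.seed(seed)
  beta <- rnorm(n, 0, 0.05)
  se <- runif(n, 0.01, 0.03)
  data.frame(
    variant_id = paste0("rs", seq_len(n)),
    effect_allele = rep(c("A", "C", "G", "T", "A"), length.out = n),
    other_allele = rep(c("G", "T", "A", "C", "C"), length.out = n),
    eaf = runif(n, 0.1, 0.45),
    beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)),
    n = 10000,
    stringsAsFactors = FALSE
  )
}

toy_sumstats <- function(n = 5, seed = 1, trait_id = "toy", trait_class = "disease") {
  sumstats(toy_sumstats_df(n, seed), trait_id = trait_id, trait_class = trait_class)
}

# Harmonized pair straight from effect vectors (bypasses tables).
toy_pair <- function(gamma, Gamma, se_gamma = rep(0.02, length(gamma)),
                     se_Gamma = rep(0.02, length(gamma)), ...) {
  mr_pair(gamma, se_gamma, Gamma, se_Gamma, ...)
}

# Pair drawn from the MR generative model: J instruments, true slope beta,
# optional additive pleiotropy vector (outcome-scale direct effects).
sim_pair <- function(J = 30, beta = 0.2, gamma_mean = 0.06, se_x = 0.005,
                     se_y = 0.005, pleiotropy = 0, n_exp = 50000, n_out = 50000) {
  gamma_true <- gamma_mean * sample(c(-1, 1), J, replace = TRUE)
  g <- rnorm(J, gamma_true, se_x)
  G <- rnorm(J, beta * gamma_true + pleiotropy, se_y)
  mr_pair(g, rep(se_x, J), G, rep(se_y, J),
    exposure_n = n_exp, outcome_n = n_out
  )
}

# Summary-level MR study generator mirroring the package's generative model:
# standardized per-variant effects (variance explained r2 each), per-allele
# observation noise 1/sqrt(2 maf (1-maf) n), optional direct (pleiotropic)
# outcome effects on a fraction of instruments.
study_pair <- function(J = 30, beta = 0.2, n_exp = 50000, n_out = 50000,
                       r2 = 0.003, pleio_frac = 0, pleio_mean = 0, pleio_sd = 0) {
  maf <- runif(J, 0.05, 0.5)
  scale <- sqrt(2 * maf * (1 - maf))
  # instruments oriented to the exposure-increasing allele (WLOG for
  # ratio-based estimators; directional pleiotropy is directional on this
  # orientation)
  g_std <- rep(sqrt(r2), J)
  pleio <- numeric(J)
  n_p <- round(pleio_frac * J)
  if (n_p > 0) pleio[sample.int(J, n_p)] <- rnorm(n_p, pleio_mean, pleio_sd)
  o_std <- beta * g_std + pleio
  se_x <- 1 / (scale * sqrt(n_exp))
  se_y <- 1 / (scale * sqrt(n_out))
  g <- (g_std + rnorm(J) / sqrt(n_exp)) / scale
  G <- (o_std + rnorm(J) / sqrt(n_out)) / scale
  mr_pair(g, se_x, G, se_y, exposure_n = n_exp, outcome_n = n_out)
}

# Independent weighted-regression oracle via stats::lm.
lm_ivw_oracle <- function(pair) {
  w <- 1 / pair$se_Gamma^2
  fit <- lm(pair$Gamma ~ 0 + pair$gamma, weights = w)
  s <- summary(fit)
  # unscale lm's residual-variance factor to get the fixed-effect SE
  list(
    beta = unname(coef(fit)[1]),
    se_fixed = unname(s$coefficients[1, 2] / s$sigma)
  )
}

lm_egger_oracle <- function(pair) {
  s <- ifelse(pair$gamma < 0, -1, 1)
  g <- pair$gamma * s
  G <- pair$Gamma * s
  w <- 1 / pair$se_Gamma^2
  fit <- lm(G ~ g, weights = w)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}
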