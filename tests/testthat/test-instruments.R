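test_that("p-value thresholds resolve by trait class and filter correctly", {
  expect_equal(resolve_p_threshold("auto", "gut_microbiota"), 1e-5)
  expect_equal(resolve_p_threshold("auto", "metabolite"), 1e-5)
  expect_equal(resolve_p_threshold("auto", "skin_microbiota"), 5e-5)
  expect_equal(resolve_p_threshold("auto", "immune_cell"), 5e-8)
  expect_equal(resolve_p_threshold("auto", "disease"), 5e-8)
  expect_equal(resolve_p_threshold(1e-6, "disease"), 1e-6)

  set.seed(42)
  n <- 100
  z <- c(rnorm(7, 9, 0.5), rnorm(93, 0, 1)) # 7 clearly genome-wide significant
  df <- data.frame(
    variant_id = sprintf("rs%03d", 1:n),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = z * 0.01, se = 0.01, pval = 2 * pnorm(-abs(z)), n = 50000
  )
  tab <- sumstats(df, "t", "disease")
  kept <- select_by_pvalue(tab, 5e-8)
  expect_equal(nrow(kept), 7)
})

test_that("greedy clumping keeps the strongest of correlated variants", {
  mk <- function(p) {
    z <- qnorm(p / 2, lower.tail = FALSE)
    data.frame(
      variant_id = paste0("v", seq_along(p)),
      effect_allele = "A", other_allele = "G", eaf = 0.3,
      beta = z * 0.01, se = 0.01, pval = p, n = 10000
    )
  }
  # independent variants: all kept
  r2 <- diag(3); dimnames(r2) <- list(paste0("v", 1:3), paste0("v", 1:3))
  tab <- sumstats(mk(c(1e-10, 1e-9, 1e-8)), "t")
  expect_equal(nrow(clump(tab, ld_matrix(r2), 0.001)), 3)

  # correlated pair: only the smaller p survives
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("v1", "v2"), c("v1", "v2")))
  tab <- sumstats(mk(c(1e-10, 1e-8)), "t")
  expect_equal(clump(tab, ld_matrix(r2), 0.001)$variant_id, "v1")

  # chain case: r2(1,2)=0.002, r2(2,3)=0.002, r2(1,3)=0.0005 -> keep {1,3}
  r2 <- diag(3)
  r2[1, 2] <- r2[2, 1] <- 0.002
  r2[2, 3] <- r2[3, 2] <- 0.002
  r2[1, 3] <- r2[3, 1] <- 0.0005
  dimnames(r2) <- list(paste0("v", 1:3), paste0("v", 1:3))
  tab <- sumstats(mk(c(1e-12, 1e-10, 1e-8)), "t")
  expect_equal(clump(tab, ld_matrix(r2), 0.001)$variant_id, c("v1", "v3"))

  expect_error(clump(tab, ld_matrix(diag(2), c("v1", "v2")), 0.001), "missing from LD matrix")
})

test_that("greedy clumping matches an enumerate-all-subsets oracle", {
  # the greedy-by-p rule has a deterministic oracle: iterate in p order and
  # check pairwise r2 against every kept predecessor by brute force
  set.seed(99)
  for (rep in 1:10) {
    m <- 8
    r <- matrix(runif(m * m, 0, 0.01), m)
    r2 <- (r + t(r)) / 2
    diag(r2) <- 1
    ids <- paste0("s", 1:m)
    dimnames(r2) <- list(ids, ids)
    p <- runif(m, 1e-12, 1e-6)
    tab <- sumstats(data.frame(
      variant_id = ids, effect_allele = "A", other_allele = "G", eaf = 0.3,
      beta = qnorm(p / 2, lower.tail = FALSE) * 0.01, se = 0.01, pval = p, n = 10000
    ), "t")
    thr <- 0.005
    kept <- clump(tab, ld_matrix(r2), thr)$variant_id
    # oracle: explicit loop
    oracle <- character(0)
    for (i in order(p, ids)) {
      if (!length(oracle) || all(r2[ids[i], oracle] < thr)) oracle <- c(oracle, ids[i])
    }
    expect_setequal(kept, oracle)
    # maximality: every dropped variant conflicts with some kept predecessor
    for (d in setdiff(ids, kept)) {
      expect_true(any(r2[d, kept] >= thr))
    }
  }
})

test_that("per-variant variance explained matches its closed forms", {
  expect_equal(
    r_squared_per_variant(beta = 0.1, eaf = 0.5, mode = "from_beta_eaf"),
    0.005
  )
  expect_equal(r_squared_per_variant(beta = 0, eaf = 0.3, mode = "from_beta_eaf"), 0)
  t <- qt(0.975, df = 998)
  expect_equal(
    r_squared_per_variant(pval = 0.05, n = 1000, mode = "from_pn"),
    t^2 / (t^2 + 998)
  )
  expect_equal(r_squared_per_variant(beta = 0, pval = 1, n = 1000, mode = "from_pn"), 0)
  expect_error(r_squared_per_variant(pval = 0.05, n = 2, mode = "from_pn"), "n > 2")
  expect_error(r_squared_per_variant(beta = 0.1, mode = "from_beta_eaf"), "eaf")
})

test_that("the F statistic follows the printed formula and is monotone", {
  expect_equal(f_statistic(0.01, 1000, 10), (0.01 * 989) / (10 * 0.99))
  expect_equal(f_statistic(0, 1000, 10), 0)
  expect_equal(f_statistic(0.038, 10000, 1), (0.038 * 9998) / (1 * 0.962))
  expect_error(f_statistic(1, 1000, 1), "R2")
  expect_error(f_statistic(0.1, 11, 10), "n > k")
  # monotone increasing in R2, decreasing in k
  r2s <- seq(0.001, 0.5, length.out = 20)
  expect_true(all(diff(f_statistic(r2s, 10000, 5)) > 0))
  ks <- 1:20
  expect_true(all(diff(vapply(ks, function(k) f_statistic(0.05, 10000, k), 1)) < 0))
})

test_that("weak-instrument filtering depends on sample size as expected", {
  # every variant causal at true per-variant r2 = 0.003:
  # F >> 10 at n = 50,000, F < 10 at n = 300
  strong <- simulate_triplet(sim_config(
    m_snps = 30, j_causal = 30, n_exposure = 50000, n_outcome = 50000,
    beta_total = 0.1, seed = 21
  ))
  pair <- harmonize(strong$exposure, strong$outcome)
  expect_equal(n_instruments(filter_weak(pair)), n_instruments(pair))

  weak <- simulate_triplet(sim_config(
    m_snps = 30, j_causal = 30, n_exposure = 300, n_outcome = 300,
    beta_total = 0.1, seed = 23
  ))
  pair_w <- harmonize(weak$exposure, weak$outcome)
  filtered <- filter_weak(pair_w)
  expect_equal(n_instruments(filtered), 0)
  expect_true(all(filtered$drop_log$reason == "weak_instrument"))
})

test_that("outcome-overlap exclusion applies the normal-approximation rule", {
  pair <- toy_pair(
    gamma = c(0.1, 0.1, 0.1),
    Gamma = c(2.5 * 0.02, 1.0 * 0.02, 0), # z = 2.5, 1.0, 0
    se_Gamma = rep(0.02, 3)
  )
  out <- exclude_outcome_associated(pair, 0.05)
  expect_equal(n_instruments(out), 2) # z=2.5 (p~0.0124) dropped
  expect_equal(out$drop_log$reason, "outcome_associated")
  # p_cut 0 drops nothing
  expect_equal(n_instruments(exclude_outcome_associated(pair, 0)), 3)
})

test_that("Steiger filtering drops variants better explained by the outcome", {
  n <- 50000
  z_exp <- c(10, 1, 5)
  z_out <- c(1, 10, 5) # variant 2 reversed, variant 3 exact tie
  pair <- mr_pair(
    gamma = z_exp * 0.01, se_gamma = rep(0.01, 3),
    Gamma = z_out * 0.01, se_Gamma = rep(0.01, 3),
    exposure_n = n, outcome_n = n
  )
  out <- steiger_filter(pair)
  expect_equal(n_instruments(out), 2)
  expect_equal(out$drop_log$reason, "steiger_reverse")
  expect_true(out$steiger_tie[out$variant_id == "snp_3"])
})

test_that("the composed instrument pipeline equals the manual filter order", {
  sim <- simulate_triplet(sim_config(
    m_snps = 60, j_causal = 20, n_exposure = 50000, n_outcome = 4000,
    beta_total = 0.3, ld = list(block_size = 3, rho = 0.5), seed = 31
  ))
  iset <- build_instrument_set(sim$exposure, sim$outcome, sim$ld,
    p_threshold = 5e-8
  )
  manual <- select_by_pvalue(sim$exposure, 5e-8)
  manual <- clump(manual, sim$ld, 0.001)
  pair <- harmonize(manual, sim$outcome)
  pair <- exclude_outcome_associated(pair, 0.05)
  pair <- filter_weak(pair, 10)
  pair <- steiger_filter(pair)
  expect_equal(iset$pair$variant_id, pair$variant_id)
  expect_equal(iset$pair$gamma, pair$gamma)
  expect_equal(iset$k, n_instruments(pair))
  expect_gt(iset$k, 0)
  # aggregate R2 is the sum of surviving per-variant r2
  expect_equal(
    iset$R2_total,
    sum(r_squared_per_variant(
      beta = pair$gamma, pval = pair$exposure_pval, n = pair$exposure_n,
      mode = "from_pn"
    ))
  )
})

test_that("LD matrices round-trip through TSV and validate their contract", {
  sim <- simulate_triplet(sim_config(
    m_snps = 12, j_causal = 3, ld = list(block_size = 4, rho = 0.6), seed = 2
  ))
  path <- tempfile(fileext = ".tsv")
  write_ld_matrix(sim$ld, path)
  back <- read_ld_matrix(path)
  expect_equal(unclass(back), unclass(sim$ld), tolerance = 1e-12)
  bad <- matrix(c(1, 0.5, 0.4, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(ld_matrix(bad), "symmetric")
  bad2 <- matrix(c(1, 0.5, 0.5, 0.9), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(ld_matrix(bad2), "diagonal")
})
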