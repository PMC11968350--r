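test_that("summary statistics round-trip exactly through write-then-read", {
  tab <- sumstats(
    data.frame(
      variant_id = c("rs1", "rs2", "rs3"),
      effect_allele = c("A", "C", "G"),
      other_allele = c("G", "T", "A"),
      eaf = c(0.25, 0.4, 0.1),
      beta = c(0.1, -0.05, 0.033),
      se = c(0.02, 0.01, 0.015),
      pval = 2 * pnorm(-abs(c(0.1, -0.05, 0.033) / c(0.02, 0.01, 0.015))),
      n = c(10000, 10000, 9500)
    ),
    trait_id = "t1", trait_class = "metabolite"
  )
  path <- tempfile(fileext = ".tsv")
  write_summary_stats(tab, path)
  back <- read_summary_stats(path, trait_id = "t1", trait_class = "metabolite")
  expect_equal(as.data.frame(back), as.data.frame(tab))
  # and a second round trip is byte-identical
  path2 <- tempfile(fileext = ".tsv")
  write_summary_stats(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("validation rejects bad rows with row-numbered messages", {
  df <- toy_sumstats_df(3)
  df$se[2] <- 0
  expect_error(sumstats(df, "t"), "row 2.*se must be > 0")
  df <- toy_sumstats_df(3)
  df$variant_id[3] <- "rs1"
  expect_error(sumstats(df, "t"), "duplicated variant_id: rs1")
  df <- toy_sumstats_df(3)
  df$effect_allele[1] <- "N"
  expect_error(sumstats(df, "t"), "row 1.*A/C/G/T")
  df <- toy_sumstats_df(3)
  df$other_allele[2] <- df$effect_allele[2]
  expect_error(sumstats(df, "t"), "equals other_allele")
  expect_error(
    sumstats(toy_sumstats_df(3)[, -5], "t"), # drop beta
    "missing required column"
  )
})

test_that("a p-value inconsistent with beta/se triggers a warning, not an error", {
  df <- toy_sumstats_df(3)
  df$pval[2] <- min(1, df$pval[2] * 2)
  expect_warning(sumstats(df, "t"), "normal approximation")
})

make_pair_tables <- function(outcome_df) {
  list(
    exposure = sumstats(
      data.frame(
        variant_id = c("rs1", "rs2", "rs9"),
        effect_allele = c("A", "A", "C"),
        other_allele = c("G", "T", "T"),
        eaf = c(0.2, 0.5, 0.3),
        beta = c(0.1, 0.08, 0.05),
        se = c(0.02, 0.02, 0.02),
        pval = NA, n = 8000
      ),
      "exp", "gut_microbiota"
    ),
    outcome = sumstats(outcome_df, "out", "disease")
  )
}

test_that("harmonization aligns swapped alleles by flipping the outcome beta", {
  tabs <- make_pair_tables(data.frame(
    variant_id = c("rs1", "rs2"),
    effect_allele = c("G", "A"),
    other_allele = c("A", "T"),
    eaf = c(0.75, 0.5),
    beta = c(-0.05, 0.01),
    se = c(0.02, 0.02),
    pval = NA, n = 20000
  ))
  pair <- harmonize(tabs$exposure, tabs$outcome)
  expect_equal(pair$variant_id, "rs1")
  expect_equal(pair$Gamma, 0.05) # -(-0.05): aligned to effect allele A
  expect_equal(pair$gamma, 0.1)
  # rs2 is palindromic with eaf 0.5 -> ambiguous; rs9 absent from outcome
  expect_setequal(
    pair$drop_log$reason[pair$drop_log$variant_id == "rs2"], "palindromic_ambiguous"
  )
  expect_setequal(
    pair$drop_log$reason[pair$drop_log$variant_id == "rs9"], "not_in_outcome"
  )
})

test_that("palindromic variants resolve only with concordant, informative eafs", {
  exp_tab <- sumstats(
    data.frame(
      variant_id = c("p1", "p2", "p3"),
      effect_allele = "A", other_allele = "T",
      eaf = c(0.2, 0.2, NA), beta = 0.1, se = 0.02, pval = NA, n = 5000
    ),
    "exp", "gut_microbiota"
  )
  out_tab <- sumstats(
    data.frame(
      variant_id = c("p1", "p2", "p3"),
      effect_allele = "A", other_allele = "T",
      eaf = c(0.25, 0.8, 0.2), beta = 0.05, se = 0.02, pval = NA, n = 5000
    ),
    "out", "disease"
  )
  pair <- harmonize(exp_tab, out_tab)
  # p1: both eafs < 0.42 -> kept; p2: opposite sides of 0.5 -> dropped;
  # p3: missing exposure eaf -> dropped
  expect_equal(pair$variant_id, "p1")
  expect_setequal(
    pair$drop_log$variant_id[pair$drop_log$reason == "palindromic_ambiguous"],
    c("p2", "p3")
  )
})

test_that("strand-complement outcome records harmonize to the same pair", {
  tabs <- make_pair_tables(data.frame(
    variant_id = "rs1", effect_allele = "T", other_allele = "C", # complement of A/G
    eaf = 0.2, beta = 0.05, se = 0.02, pval = NA, n = 20000
  ))
  pair <- harmonize(tabs$exposure, tabs$outcome)
  expect_equal(pair$variant_id, "rs1")
  expect_equal(pair$Gamma, 0.05)
})

test_that("harmonization is idempotent and double-flip is identity", {
  sim <- simulate_triplet(sim_config(m_snps = 20, j_causal = 10, seed = 11))
  base <- harmonize(sim$exposure, sim$outcome)
  # idempotence: feed the aligned pair back through as tables
  realigned <- sumstats(
    data.frame(
      variant_id = base$variant_id,
      effect_allele = sim$outcome$effect_allele[match(base$variant_id, sim$outcome$variant_id)],
      other_allele = sim$outcome$other_allele[match(base$variant_id, sim$outcome$variant_id)],
      eaf = base$eaf, beta = base$Gamma, se = base$se_Gamma,
      pval = NA, n = sim$outcome$n[1]
    ),
    "out", "disease"
  )
  again <- harmonize(sim$exposure, realigned)
  expect_equal(again$Gamma, base$Gamma)
  expect_equal(again$gamma, base$gamma)

  # double flip: swap alleles and negate beta in the outcome table
  flipped <- as.data.frame(sim$outcome)
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  flipped_tab <- sumstats(flipped, "out", "disease")
  pair_flip <- harmonize(sim$exposure, flipped_tab)
  expect_equal(pair_flip$Gamma, base$Gamma, tolerance = 1e-12)
  expect_equal(pair_flip$variant_id, base$variant_id)
})

test_that("every shared variant lands in the pair or the drop log", {
  sim <- simulate_triplet(sim_config(m_snps = 40, j_causal = 10, seed = 3))
  sub <- as.data.frame(sim$outcome)[1:30, ]
  out_tab <- sumstats(sub, "out", "disease")
  pair <- harmonize(sim$exposure, out_tab)
  shared <- intersect(sim$exposure$variant_id, out_tab$variant_id)
  in_log <- pair$drop_log$variant_id[pair$drop_log$variant_id %in% shared]
  expect_equal(length(shared), n_instruments(pair) + length(in_log))
  # exposure-only variants logged too
  expect_equal(
    sum(pair$drop_log$reason == "not_in_outcome"),
    length(setdiff(sim$exposure$variant_id, out_tab$variant_id))
  )
})
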