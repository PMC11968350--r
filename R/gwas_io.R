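#' mrscreen: two-sample Mendelian randomization screening
#'
#' Tools for causal screening from GWAS summary statistics: instrument
#' selection and QC, an MR estimator suite, sensitivity diagnostics,
#' FDR tiering, two-step mediation, lightweight LD-score regression,
#' hypergeometric pathway enrichment, and a synthetic summary-statistics
#' generator with known ground truth.
#'
#' @keywords internal
"_PACKAGE"

VALID_ALLELES <- c("A", "C", "G", "T")

TRAIT_CLASSES <- c(
  "gut_microbiota", "skin_microbiota", "metabolite", "wbc",
  "immune_cell", "inflammatory_protein", "inflammatory_cytokine", "disease"
)

.complement <- function(a) chartr("ACGT", "TGCA", a)

.is_palindromic <- function(ea, oa) oa == .complement(ea)

#' Canonical summary-statistics column mapping
#'
#' Maps the internal field names to the column names of the bundled TSV
#' dialect (a common layout for GWAS summary-statistic exports). Override
#' individual entries to read files with other headers.
#'
#' @param ... named overrides, e.g. `variant_id = "rsid"`.
#' @return named character vector mapping internal field -> file column.
#' @export
gwas_dialect <- function(...) {
  d <- c(
    variant_id = "SNP", effect_allele = "effect_allele",
    other_allele = "other_allele", eaf = "eaf", beta = "beta",
    se = "se", pval = "pval", n = "n"
  )
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(d))
    if (length(bad)) stop("unknown dialect fields: ", paste(bad, collapse = ", "))
    d[names(over)] <- over
  }
  d
}

#' Construct a validated summary-statistics table
#'
#' One row per variant: identifier, effect/other allele, effect-allele
#' frequency, effect estimate (log-odds for binary traits), its standard
#' error, p-value and sample size. Validation enforces the field contract;
#' rows violating it are reported by row number.
#'
#' @param data data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n` (`eaf`, `pval`, `n`
#'   may contain `NA`).
#' @param trait_id trait label.
#' @param trait_class one of `"gut_microbiota"`, `"skin_microbiota"`,
#'   `"metabolite"`, `"wbc"`, `"immune_cell"`, `"inflammatory_protein"`,
#'   `"inflammatory_cytokine"`, `"disease"`. Determines the automatic
#'   instrument p-value threshold (see [select_by_pvalue()]).
#' @param n_default sample size used where a row lacks `n`.
#' @return object of class `sumstats` (a data.frame with trait metadata
#'   attributes).
#' @export
sumstats <- function(data, trait_id, trait_class = "disease", n_default = NULL) {
  trait_class <- match.arg(trait_class, TRAIT_CLASSES)
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("eaf", "pval", "n")) if (is.null(data[[col]])) data[[col]] <- NA_real_
  data <- data.frame(
    variant_id = as.character(data$variant_id),
    effect_allele = toupper(as.character(data$effect_allele)),
    other_allele = toupper(as.character(data$other_allele)),
    eaf = as.numeric(data$eaf),
    beta = as.numeric(data$beta),
    se = as.numeric(data$se),
    pval = as.numeric(data$pval),
    n = as.numeric(data$n),
    stringsAsFactors = FALSE
  )
  if (!is.null(n_default)) data$n[is.na(data$n)] <- n_default
  .validate_sumstats_rows(data)
  structure(data,
    trait_id = trait_id, trait_class = trait_class,
    n_default = n_default, class = c("sumstats", "data.frame")
  )
}

.validate_sumstats_rows <- function(data) {
  problems <- character(0)
  row_msg <- function(rows, what) {
    if (any(rows, na.rm = TRUE)) {
      sprintf("row %s: %s", paste(which(rows), collapse = ","), what)
    } else {
      character(0)
    }
  }
  problems <- c(
    problems,
    row_msg(!data$effect_allele %in% VALID_ALLELES, "effect_allele not one of A/C/G/T"),
    row_msg(!data$other_allele %in% VALID_ALLELES, "other_allele not one of A/C/G/T"),
    row_msg(data$effect_allele == data$other_allele, "effect_allele equals other_allele"),
    row_msg(!is.finite(data$beta), "beta missing or non-finite"),
    row_msg(!is.finite(data$se) | data$se <= 0, "se must be > 0"),
    row_msg(!is.na(data$eaf) & (data$eaf <= 0 | data$eaf >= 1), "eaf outside (0,1)"),
    row_msg(!is.na(data$pval) & (data$pval <= 0 | data$pval > 1), "pval outside (0,1]"),
    row_msg(!is.na(data$n) & data$n <= 0, "n must be a positive count")
  )
  dup <- unique(data$variant_id[duplicated(data$variant_id)])
  if (length(dup)) {
    problems <- c(problems, paste0(
      "duplicated variant_id: ", paste(dup, collapse = ", ")
    ))
  }
  if (length(problems)) {
    stop("invalid summary statistics:\n  ", paste(problems, collapse = "\n  "))
  }
  # soft check: p should agree with the two-sided normal approximation of beta/se
  p_calc <- 2 * stats::pnorm(-abs(data$beta / data$se))
  have <- !is.na(data$pval) & p_calc > 0
  off <- have & abs(data$pval - p_calc) / p_calc > 0.10
  if (any(off)) {
    warning(sprintf(
      "row %s: pval differs from the normal approximation 2*pnorm(-|beta/se|) by >10%%",
      paste(which(off), collapse = ",")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf(
    "<sumstats> trait '%s' (%s), %d variants\n",
    attr(x, "trait_id"), attr(x, "trait_class"), nrow(x)
  ))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

trait_id <- function(x) attr(x, "trait_id")
trait_class <- function(x) attr(x, "trait_class")

.reclass_sumstats <- function(data, template) {
  structure(data,
    trait_id = attr(template, "trait_id"),
    trait_class = attr(template, "trait_class"),
    n_default = attr(template, "n_default"),
    class = c("sumstats", "data.frame")
  )
}

#' Read GWAS summary statistics from delimited text
#'
#' @param path file path to a delimited text file with a header row.
#' @param dialect column mapping from [gwas_dialect()].
#' @param trait_id,trait_class,n_default trait metadata, see [sumstats()].
#' @param sep field separator (tab by default).
#' @return validated [sumstats()] table.
#' @export
read_summary_stats <- function(path, dialect = gwas_dialect(), trait_id = basename(path),
                               trait_class = "disease", n_default = NULL, sep = "\t") {
  raw <- utils::read.table(path,
    header = TRUE, sep = sep, stringsAsFactors = FALSE,
    check.names = FALSE, comment.char = ""
  )
  needed <- dialect[c("variant_id", "effect_allele", "other_allele", "beta", "se")]
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  pick <- function(field) {
    col <- dialect[[field]]
    if (col %in% names(raw)) raw[[col]] else NA_real_
  }
  sumstats(
    data.frame(
      variant_id = pick("variant_id"),
      effect_allele = pick("effect_allele"),
      other_allele = pick("other_allele"),
      eaf = pick("eaf"), beta = pick("beta"), se = pick("se"),
      pval = pick("pval"), n = pick("n"),
      stringsAsFactors = FALSE
    ),
    trait_id = trait_id, trait_class = trait_class, n_default = n_default
  )
}

#' Write summary statistics in the canonical TSV dialect
#'
#' Numeric fields are written with full double precision so a
#' write-then-read round trip reproduces the table exactly.
#'
#' @param x a [sumstats()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  d <- gwas_dialect()
  fmt_num <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  out <- data.frame(
    a = x$variant_id, b = x$effect_allele, c = x$other_allele,
    d = fmt_num(x$eaf), e = fmt_num(x$beta), f = fmt_num(x$se),
    g = fmt_num(x$pval), h = fmt_num(x$n), stringsAsFactors = FALSE
  )
  names(out) <- unname(d)
  utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

# ---- harmonized exposure/outcome pairs --------------------------------------

#' Construct a harmonized exposure-outcome pair from effect vectors
#'
#' Low-level constructor for the allele-aligned container consumed by all
#' estimators: per-variant exposure effects (`gamma`) and outcome effects
#' (`Gamma`) referring to the same effect allele, with their standard errors.
#' Most users obtain one from [harmonize()].
#'
#' @param gamma,se_gamma exposure effects and standard errors.
#' @param Gamma,se_Gamma outcome effects and standard errors.
#' @param variant_id variant identifiers (defaults to `snp_1 ...`).
#' @param eaf aligned effect-allele frequencies (optional).
#' @param exposure_n,outcome_n GWAS sample sizes (scalar or per-variant).
#' @param exposure_pval,outcome_pval marginal p-values (optional; recomputed
#'   from the normal approximation when absent).
#' @param exposure_id,outcome_id trait labels.
#' @param drop_log data.frame of excluded variants with reasons.
#' @return object of class `harmonized_pair`.
#' @export
mr_pair <- function(gamma, se_gamma, Gamma, se_Gamma,
                    variant_id = NULL, eaf = NULL,
                    exposure_n = NA_real_, outcome_n = NA_real_,
                    exposure_pval = NULL, outcome_pval = NULL,
                    exposure_id = "exposure", outcome_id = "outcome",
                    drop_log = NULL) {
  J <- length(gamma)
  stopifnot(
    length(se_gamma) == J, length(Gamma) == J, length(se_Gamma) == J,
    all(se_gamma > 0), all(se_Gamma > 0)
  )
  if (is.null(variant_id)) variant_id <- if (J) paste0("snp_", seq_len(J)) else character(0)
  if (is.null(eaf)) eaf <- rep(NA_real_, J)
  p_exp <- 2 * stats::pnorm(-abs(gamma / se_gamma))
  p_out <- 2 * stats::pnorm(-abs(Gamma / se_Gamma))
  exposure_pval <- if (is.null(exposure_pval)) p_exp else ifelse(is.na(exposure_pval), p_exp, exposure_pval)
  outcome_pval <- if (is.null(outcome_pval)) p_out else ifelse(is.na(outcome_pval), p_out, outcome_pval)
  if (is.null(drop_log)) {
    drop_log <- data.frame(
      variant_id = character(0), reason = character(0),
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    variant_id = as.character(variant_id),
    gamma = as.numeric(gamma), se_gamma = as.numeric(se_gamma),
    Gamma = as.numeric(Gamma), se_Gamma = as.numeric(se_Gamma),
    eaf = as.numeric(eaf),
    exposure_n = rep_len(as.numeric(exposure_n), max(J, 1L))[seq_len(J)],
    outcome_n = rep_len(as.numeric(outcome_n), max(J, 1L))[seq_len(J)],
    exposure_pval = as.numeric(exposure_pval),
    outcome_pval = as.numeric(outcome_pval),
    exposure_id = exposure_id, outcome_id = outcome_id,
    steiger_tie = rep(FALSE, J),
    drop_log = drop_log
  ), class = "harmonized_pair")
}

#' Number of instruments in a harmonized pair
#' @param x a `harmonized_pair`.
#' @export
n_instruments <- function(x) length(x$gamma)

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf(
    "<harmonized_pair> %s -> %s: %d variants (%d dropped)\n",
    x$exposure_id, x$outcome_id, n_instruments(x), nrow(x$drop_log)
  ))
  invisible(x)
}

# Keep variants flagged TRUE; move the rest to drop_log with `reason`.
.pair_subset <- function(pair, keep, reason) {
  dropped <- pair$variant_id[!keep]
  if (length(dropped)) {
    pair$drop_log <- rbind(pair$drop_log, data.frame(
      variant_id = dropped, reason = reason, stringsAsFactors = FALSE
    ))
  }
  for (f in c(
    "variant_id", "gamma", "se_gamma", "Gamma", "se_Gamma", "eaf",
    "exposure_n", "outcome_n", "exposure_pval", "outcome_pval", "steiger_tie"
  )) {
    pair[[f]] <- pair[[f]][keep]
  }
  pair
}

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' For every variant present in both tables the outcome effect is aligned to
#' the exposure's effect allele: identical alleles are kept as-is, swapped
#' alleles flip the outcome beta (and eaf), and strand-complement matches are
#' resolved the same way. Palindromic variants (A/T or G/C) cannot be
#' resolved from alleles alone: they are kept only when both effect-allele
#' frequencies are on the same side of 0.5 and outside
#' `[0.5 - palindrome_eaf_window, 0.5 + palindrome_eaf_window]`; otherwise
#' (including missing eaf) they are dropped as `palindromic_ambiguous`.
#' Every input variant ends up either in the pair or in `drop_log`.
#'
#' @param exposure,outcome [sumstats()] tables.
#' @param palindrome_eaf_window half-width of the ambiguous frequency band
#'   around 0.5 (default 0.08, i.e. drop when eaf lies in \[0.42, 0.58\]).
#' @return a `harmonized_pair` (see [mr_pair()]).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  w <- palindrome_eaf_window
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  drop_log <- data.frame(variant_id = character(0), reason = character(0), stringsAsFactors = FALSE)
  add_drop <- function(ids, reason) {
    if (length(ids)) {
      rbind(drop_log, data.frame(variant_id = ids, reason = reason, stringsAsFactors = FALSE))
    } else {
      drop_log
    }
  }
  drop_log <- add_drop(setdiff(exposure$variant_id, shared), "not_in_outcome")
  drop_log <- add_drop(setdiff(outcome$variant_id, shared), "not_in_exposure")

  ei <- match(shared, exposure$variant_id)
  oi <- match(shared, outcome$variant_id)
  eea <- exposure$effect_allele[ei]
  eoa <- exposure$other_allele[ei]
  oea <- outcome$effect_allele[oi]
  ooa <- outcome$other_allele[oi]

  pal <- .is_palindromic(eea, eoa)
  ident <- oea == eea & ooa == eoa
  swapped <- oea == eoa & ooa == eea
  ident_c <- .complement(oea) == eea & .complement(ooa) == eoa
  swap_c <- .complement(oea) == eoa & .complement(ooa) == eea

  flip <- rep(NA, length(shared)) # NA -> allele mismatch
  flip[ident] <- FALSE
  flip[!ident & swapped] <- TRUE
  nonpal_more <- !pal & !ident & !swapped
  flip[nonpal_more & ident_c] <- FALSE
  flip[nonpal_more & !ident_c & swap_c] <- TRUE

  e_eaf <- exposure$eaf[ei]
  o_eaf_raw <- outcome$eaf[oi]
  o_eaf <- ifelse(!is.na(flip) & flip, 1 - o_eaf_raw, o_eaf_raw)

  reason <- rep(NA_character_, length(shared))
  reason[is.na(flip)] <- "allele_mismatch"
  pal_ok <- pal & !is.na(flip)
  unresolved <- pal_ok & (
    is.na(e_eaf) | is.na(o_eaf) |
      abs(e_eaf - 0.5) <= w | abs(o_eaf - 0.5) <= w |
      sign(e_eaf - 0.5) != sign(o_eaf - 0.5)
  )
  reason[unresolved] <- "palindromic_ambiguous"
  keep <- is.na(reason)

  for (r in unique(reason[!keep])) {
    drop_log <- add_drop(shared[!keep & reason == r], r)
  }

  Gamma <- ifelse(flip[keep], -outcome$beta[oi][keep], outcome$beta[oi][keep])
  exp_n <- exposure$n[ei][keep]
  out_n <- outcome$n[oi][keep]
  mr_pair(
    gamma = exposure$beta[ei][keep], se_gamma = exposure$se[ei][keep],
    Gamma = Gamma, se_Gamma = outcome$se[oi][keep],
    variant_id = shared[keep], eaf = e_eaf[keep],
    exposure_n = if (length(exp_n)) exp_n else NA_real_,
    outcome_n = if (length(out_n)) out_n else NA_real_,
    exposure_pval = exposure$pval[ei][keep],
    outcome_pval = outcome$pval[oi][keep],
    exposure_id = attr(exposure, "trait_id"),
    outcome_id = attr(outcome, "trait_id"),
    drop_log = drop_log
  )
}
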