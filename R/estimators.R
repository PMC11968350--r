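# MR estimator suite: Wald ratios, IVW, MR-Egger, weighted median,
# weighted mode, odds-ratio reporting.

Z95 <- stats::qnorm(0.975)

# Run `code` under `seed` without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

.new_mr_estimate <- function(method, beta, se, pval, nsnp, ci_low = NULL,
                             ci_high = NULL, extras = list()) {
  if (is.null(ci_low)) ci_low <- beta - Z95 * se
  if (is.null(ci_high)) ci_high <- beta + Z95 * se
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high, pval = pval, nsnp = nsnp,
    or_ = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
    extras = extras
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "<mr_estimate> %s: beta=%.4g (se %.4g), 95%% CI [%.4g, %.4g], p=%.3g, nsnp=%d\n",
    x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$nsnp
  ))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(
    method = x$method, nsnp = x$nsnp, beta = x$beta, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
    or_ = x$or_, or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
    stringsAsFactors = FALSE
  )
}

#' Per-variant Wald ratio estimates
#'
#' `beta_j = Gamma_j / gamma_j` with first-order standard error
#' `se_Gamma_j / |gamma_j|`. Variants with a zero exposure effect must have
#' been excluded upstream and raise an error here.
#'
#' @param pair a `harmonized_pair`.
#' @return data.frame with `variant_id`, `beta`, `se`, `weight`
#'   (inverse-variance weight of the ratio, normalized to sum 1).
#' @export
wald_ratios <- function(pair) {
  stopifnot(inherits(pair, "harmonized_pair"))
  zero <- pair$gamma == 0
  if (any(zero)) {
    stop(
      "zero exposure effect for variant(s): ",
      paste(pair$variant_id[zero], collapse = ", ")
    )
  }
  b <- pair$Gamma / pair$gamma
  se <- pair$se_Gamma / abs(pair$gamma)
  w <- 1 / se^2
  data.frame(
    variant_id = pair$variant_id, beta = b, se = se, weight = w / sum(w),
    stringsAsFactors = FALSE
  )
}

#' Inverse-variance-weighted estimate (primary method)
#'
#' Weighted least squares of outcome effects on exposure effects through
#' the origin with weights `1/se_Gamma^2`:
#' `beta = sum(w g G) / sum(w g^2)`, fixed-effect
#' `se = 1/sqrt(sum(w g^2))`. The default multiplicative random-effects
#' model scales the fixed SE by `max(1, sigma)` with
#' `sigma^2 = Q / (J - 1)`, so under-dispersion never shrinks the SE below
#' the fixed-effect value. P-values use the normal distribution.
#'
#' @param pair a `harmonized_pair` with at least 2 variants.
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return an `mr_estimate`; `extras` carries `Q`, `sigma` (residual
#'   scale), and the fixed-effect SE.
#' @export
mr_ivw <- function(pair, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  J <- n_instruments(pair)
  if (J < 2) stop("IVW requires at least 2 instruments, got ", J)
  g <- pair$gamma
  G <- pair$Gamma
  w <- 1 / pair$se_Gamma^2
  beta <- sum(w * g * G) / sum(w * g^2)
  se_fixed <- 1 / sqrt(sum(w * g^2))
  Q <- sum(w * (G - beta * g)^2)
  sigma <- sqrt(Q / (J - 1))
  se <- if (effects_model == "multiplicative_random") se_fixed * max(1, sigma) else se_fixed
  pval <- 2 * stats::pnorm(-abs(beta / se))
  .new_mr_estimate(
    method = if (effects_model == "fixed") "ivw_fe" else "ivw_re",
    beta = beta, se = se, pval = pval, nsnp = J,
    extras = list(Q = Q, sigma = sigma, se_fixed = se_fixed)
  )
}

# Closed-form weighted simple regression y ~ 1 + x with weights w.
# Returns coefficients and the unscaled covariance factor (X'WX)^{-1}.
.wls2 <- function(x, y, w) {
  W <- sum(w)
  Wx <- sum(w * x)
  Wxx <- sum(w * x^2)
  Wy <- sum(w * y)
  Wxy <- sum(w * x * y)
  D <- W * Wxx - Wx^2
  slope <- (W * Wxy - Wx * Wy) / D
  intercept <- (Wxx * Wy - Wx * Wxy) / D
  list(
    intercept = intercept, slope = slope,
    var_intercept = Wxx / D, var_slope = W / D,
    resid = y - intercept - slope * x
  )
}

#' MR-Egger regression
#'
#' After orienting every variant so the exposure effect is positive,
#' regresses outcome effects on exposure effects with a free intercept and
#' weights `1/se_Gamma^2`. The slope estimates the causal effect; the
#' intercept estimates average directional pleiotropy. Standard errors are
#' inflated by `max(1, sigma)` with `sigma^2 = Q_egger/(J-2)`; p-values
#' use the t distribution with `J - 2` degrees of freedom.
#'
#' @param pair a `harmonized_pair` with at least 3 variants.
#' @return an `mr_estimate`; `extras` carries `intercept`,
#'   `intercept_se`, `intercept_pval`, `Q`, `sigma`.
#' @export
mr_egger <- function(pair) {
  J <- n_instruments(pair)
  if (J < 3) stop("MR-Egger requires at least 3 instruments, got ", J)
  s <- ifelse(pair$gamma < 0, -1, 1)
  g <- pair$gamma * s
  G <- pair$Gamma * s
  w <- 1 / pair$se_Gamma^2
  fit <- .wls2(g, G, w)
  Q <- sum(w * fit$resid^2)
  sigma <- sqrt(Q / (J - 2))
  infl <- max(1, sigma)
  se_slope <- sqrt(fit$var_slope) * infl
  se_int <- sqrt(fit$var_intercept) * infl
  p_slope <- 2 * stats::pt(-abs(fit$slope / se_slope), df = J - 2)
  p_int <- 2 * stats::pt(-abs(fit$intercept / se_int), df = J - 2)
  .new_mr_estimate(
    method = "egger", beta = fit$slope, se = se_slope, pval = p_slope, nsnp = J,
    extras = list(
      intercept = fit$intercept, intercept_se = se_int, intercept_pval = p_int,
      Q = Q, sigma = sigma
    )
  )
}

.weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  S <- cumsum(w) - w / 2
  if (0.5 <= S[1]) return(b[1])
  if (0.5 >= S[length(S)]) return(b[length(b)])
  stats::approx(S, b, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap SE shared by weighted median / weighted mode:
# redraw gamma and Gamma from their sampling distributions and recompute
# the point estimate. n_boot = 0 skips the bootstrap (SE = NA).
.bootstrap_se <- function(pair, point_fun, n_boot, seed) {
  if (n_boot == 0) return(NA_real_)
  J <- n_instruments(pair)
  .with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      g <- stats::rnorm(J, pair$gamma, pair$se_gamma)
      G <- stats::rnorm(J, pair$Gamma, pair$se_Gamma)
      g[g == 0] <- .Machine$double.eps
      point_fun(G / g, g^2 / pair$se_Gamma^2)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted-median estimate
#'
#' Consistent when instruments contributing at least half the weight are
#' valid. Inverse-variance weights of the Wald ratios are normalized to
#' sum 1; ratios are sorted and the estimate interpolates the weighted
#' empirical median (cumulative midpoints crossing 0.5). The SE comes from
#' a parametric bootstrap redrawing both effect vectors.
#'
#' @param pair a `harmonized_pair` with at least 3 variants.
#' @param n_boot bootstrap replicates (default 1000; 0 skips the bootstrap
#'   and returns an NA standard error).
#' @param seed integer seed for the bootstrap stream.
#' @return an `mr_estimate`.
#' @export
mr_weighted_median <- function(pair, n_boot = 1000, seed = NULL) {
  J <- n_instruments(pair)
  if (J < 3) stop("weighted median requires at least 3 instruments, got ", J)
  wr <- wald_ratios(pair)
  beta <- .weighted_median_point(wr$beta, wr$weight)
  se <- .bootstrap_se(pair, .weighted_median_point, n_boot, seed)
  pval <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
  est <- .new_mr_estimate("weighted_median", beta, se, pval, J,
    ci_low = if (is.na(se)) NA_real_ else beta - Z95 * se,
    ci_high = if (is.na(se)) NA_real_ else beta + Z95 * se,
    extras = list(n_boot = n_boot, seed = seed)
  )
  est
}

.weighted_mode_point_factory <- function(phi) {
  function(b, w) {
    w <- w / sum(w)
    J <- length(b)
    spread <- min(stats::sd(b), stats::IQR(b) / 1.349)
    h <- phi * 0.9 * spread * J^(-1 / 5)
    if (!is.finite(h) || h <= 0) return(b[1]) # degenerate cluster
    dens <- vapply(b, function(x) sum(w * stats::dnorm(x, mean = b, sd = h)), numeric(1))
    b[which.max(dens)]
  }
}

#' Weighted-mode estimate
#'
#' Kernel-smoothed weighted empirical density of the Wald ratios (normal
#' kernel, bandwidth `phi * 0.9 * min(sd, IQR/1.349) * J^(-1/5)`) evaluated
#' at the ratio points; the estimate is the density argmax. Consistent when
#' the largest group of instruments sharing a ratio value is valid. SE from
#' the same parametric bootstrap as [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param phi bandwidth multiplier (default 1).
#' @return an `mr_estimate`; `extras` carries `phi`.
#' @export
mr_weighted_mode <- function(pair, phi = 1, n_boot = 1000, seed = NULL) {
  J <- n_instruments(pair)
  if (J < 3) stop("weighted mode requires at least 3 instruments, got ", J)
  point_fun <- .weighted_mode_point_factory(phi)
  wr <- wald_ratios(pair)
  beta <- point_fun(wr$beta, wr$weight)
  se <- .bootstrap_se(pair, point_fun, n_boot, seed)
  pval <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
  .new_mr_estimate("weighted_mode", beta, se, pval, J,
    ci_low = if (is.na(se)) NA_real_ else beta - Z95 * se,
    ci_high = if (is.na(se)) NA_real_ else beta + Z95 * se,
    extras = list(phi = phi, n_boot = n_boot, seed = seed)
  )
}

#' Report an estimate on the odds-ratio scale
#'
#' For binary outcomes whose effects are log-odds: `OR = exp(beta)` with
#' 95% CI `exp(beta +/- 1.96 * se)`.
#'
#' @param estimate an `mr_estimate`.
#' @return the estimate with `or_`, `or_ci_low`, `or_ci_high` populated.
#' @export
to_odds_ratio <- function(estimate) {
  stopifnot(inherits(estimate, "mr_estimate"))
  estimate$or_ <- exp(estimate$beta)
  estimate$or_ci_low <- exp(estimate$beta - 1.96 * estimate$se)
  estimate$or_ci_high <- exp(estimate$beta + 1.96 * estimate$se)
  estimate
}

#' Run the full estimator suite on one pair
#'
#' IVW (primary), MR-Egger, weighted median and weighted mode, as a tidy
#' table; methods whose minimum instrument count is not met are omitted.
#'
#' @param pair a `harmonized_pair`.
#' @param n_boot,seed bootstrap controls for median/mode.
#' @param odds_ratio also populate OR columns?
#' @return data.frame with one row per method.
#' @export
mr_all <- function(pair, n_boot = 1000, seed = NULL, odds_ratio = TRUE) {
  J <- n_instruments(pair)
  ests <- list()
  if (J >= 2) ests <- c(ests, list(mr_ivw(pair)))
  if (J >= 3) {
    ests <- c(ests, list(
      mr_egger(pair),
      mr_weighted_median(pair, n_boot = n_boot, seed = seed),
      mr_weighted_mode(pair, n_boot = n_boot, seed = seed)
    ))
  }
  if (!length(ests)) {
    return(data.frame())
  }
  if (odds_ratio) ests <- lapply(ests, to_odds_ratio)
  out <- do.call(rbind, lapply(ests, as.data.frame))
  out$exposure <- pair$exposure_id
  out$outcome <- pair$outcome_id
  out[, c("exposure", "outcome", setdiff(names(out), c("exposure", "outcome")))]
}
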