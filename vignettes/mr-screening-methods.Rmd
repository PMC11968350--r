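---
title: "Methods: two-sample MR screening, sensitivity analysis and mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening, sensitivity analysis and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of a
modifiable exposure (for example a gut bacterial abundance, a plasma
metabolite level, or an immune-cell trait) on a disease outcome using only
GWAS summary statistics from two non-overlapping samples. Genetic variants
serve as instrumental variables under three assumptions: they associate with
the exposure, they are independent of confounders, and they affect the
outcome only through the exposure. `mrscreen` implements a complete
screening workflow of this kind — many exposures against one binary outcome,
bidirectional checks, mediation through intermediate traits, and pathway
enrichment of the hits — together with a synthetic summary-statistics
generator so that every stage can be validated by parameter recovery without
any external data.

## The model

For variant $j$, let $\gamma_j$ (SE $\sigma_{xj}$) be its per-allele effect
on the exposure and $\Gamma_j$ (SE $\sigma_{yj}$) its effect on the outcome
(log-odds for a binary outcome). Under valid instruments each Wald ratio
$\Gamma_j/\gamma_j$ estimates the same causal effect $\beta$.

* **IVW (primary).** Weighted least squares of $\Gamma$ on $\gamma$ through
  the origin with weights $w_j = 1/\sigma_{yj}^2$:
  $\hat\beta = \sum w_j\gamma_j\Gamma_j / \sum w_j\gamma_j^2$. The default is
  a multiplicative random-effects model: the fixed-effect standard error
  $1/\sqrt{\sum w_j \gamma_j^2}$ is scaled by $\max(1, \hat\sigma)$ with
  $\hat\sigma^2 = Q/(J-1)$, so heterogeneity widens the interval but
  under-dispersion never narrows it below the fixed-effect value.
* **MR-Egger.** The same regression with a free intercept after orienting
  all variants to positive $\gamma$. The slope is the causal estimate robust
  to directional pleiotropy (under InSIDE); the intercept estimates the
  average direct effect, and its t-test (df $J-2$) is the pleiotropy
  diagnostic.
* **Weighted median.** The weighted empirical median of the Wald ratios
  (linear interpolation of the cumulative-weight midpoints at 0.5);
  consistent while at least half the weight comes from valid instruments.
* **Weighted mode.** The argmax of a normal-kernel-smoothed weighted density
  of the ratios, bandwidth $\varphi \cdot 0.9\min(\mathrm{sd},
  \mathrm{IQR}/1.349)J^{-1/5}$; consistent when the largest group of
  instruments sharing a ratio is valid.

Median and mode standard errors come from a parametric bootstrap that
redraws both $\gamma$ and $\Gamma$ from their sampling distributions
(default 1,000 replicates, explicit seed; `n_boot = 0` skips the bootstrap
when only point estimates are compared, as in the robustness simulations).
IVW p-values use the normal distribution, Egger p-values the t distribution
with $J-2$ df — the common conventions; the published analyses this package
mirrors do not state their choices, so ours are explicit and configurable.

## Instrument QC

Filters are applied in a fixed order, and every excluded variant is logged
with a machine-readable reason:

1. **P-value threshold** — genome-wide $5\times10^{-8}$, relaxed to
   $1\times10^{-5}$ for gut-microbiota and metabolite traits and
   $5\times10^{-5}$ for skin-microbiota traits, where genome-wide loci are
   scarce.
2. **LD clumping** at $r^2 < 0.001$, implemented as deterministic greedy
   selection against a supplied squared-correlation matrix (sorted by
   ascending p, ties broken by variant id). No genomic windows: the matrix
   defines correlation, which makes the operation exactly testable against
   a brute-force oracle.
3. **Allele harmonization** to the exposure's effect allele (swapped alleles
   flip the outcome beta; strand complements are retried). Palindromic
   variants are kept only when both effect-allele frequencies sit on the
   same side of 0.5 and outside $[0.42, 0.58]$ (window $w = 0.08$,
   configurable); missing frequency means the variant is dropped. These
   rules follow common harmonization practice; the source analyses do not
   state theirs.
4. **Outcome-overlap exclusion** — variants with outcome $p < 0.05$ (two-
   sided normal approximation $2\Phi(-|\Gamma/\sigma_y|)$, so it also works
   on tables lacking a p column) are removed. This threshold is unusually
   aggressive — under a genuine causal effect with strong instruments it
   removes true-signal variants and attenuates the estimate toward the null
   (our end-to-end screen recovers $\approx 0.24$ for a true effect of 0.3
   for exactly this reason) — but it is the printed rule, so it is the
   default, with the threshold configurable; `p_cut = 0` disables it.
5. **F filter** — $F = [R^2(n-k-1)]/[k(1-R^2)]$ with $R^2$ from the
   p-value/t-statistic route ($t^2/(t^2+n-2)$); per-variant ($k=1$) $F < 10$
   variants are dropped. Whether the original applied the filter per variant
   or per set is not stated; both are available, the pipeline defaults to
   per-variant and also reports the aggregate F of the surviving set (with
   aggregate $R^2$ as the sum of per-variant values — residual LD at
   $r^2 < 0.001$ is negligible).
6. **Steiger filter** — variants explaining more variance in the outcome
   than in the exposure are dropped; exact ties are kept but flagged.

## Sensitivity battery and remediation

Cochran's $Q$ about the IVW fit (df $J-1$; $Q = (J-1)\hat\sigma^2$ exactly)
and about the Egger fit (df $J-2$); the Egger intercept test; MR-PRESSO;
leave-one-out IVW; and a whole-set Steiger directionality test comparing
total variance explained, with a normal test on the difference of
Fisher-transformed correlations.

MR-PRESSO follows the residual-sum-of-squares construction: observed
$\mathrm{RSS} = \sum_j w_j(\Gamma_j - \hat\beta_{(-j)}\gamma_j)^2$ with
leave-one-out IVW fits, compared against `nb_sim` parametric replicates.
Three deliberate implementation choices: empirical p-values use
$(1+\text{hits})/(1+n_{\text{sim}})$ so they are never exactly zero (which
stabilizes downstream FDR); all random draws are keyed to variants sorted by
id, so input order cannot change results; and the distortion test permutes
the outlier labels rather than the original's under-specified bootstrap.
Note the resolution limit: with `nb_sim` replicates the smallest achievable
Bonferroni-adjusted outlier p is $J/(n_{\text{sim}}+1)$, so detecting
outliers among 30 instruments at $\alpha = 0.05$ needs
`nb_sim` $\geq$ 1000 — the default.

The screening remediation rule mirrors the source procedure: if the Egger
intercept or the PRESSO global test signals pleiotropy ($p < 0.05$), PRESSO
outliers are removed once and the pair re-estimated; if pleiotropy persists
the pair is marked `pleiotropy_unresolved` and excluded from headline
results.

## FDR tiering

Benjamini–Hochberg adjustment (via `stats::p.adjust`) is applied to the
primary IVW p-values within each exposure trait class — matching how
per-class result counts are conventionally reported; the family definition
is configurable. Tiers: *significant* if FDR < 0.1; *suggestive* if
$p_{IVW} < 0.05$ but FDR ≥ 0.1; otherwise *null*.

## Two-step mediation

With $a$ the exposure→mediator effect, $b$ the mediator→outcome effect
(univariable MR with the mediator's own instruments, not multivariable MR —
a known limitation of the two-step formulation) and $c$ the total effect:
indirect $= ab$, direct $= c - ab$, proportion mediated $= 100\,ab/c$ (%).
Delta-method standard errors assume the three estimates come from separate
samples, hence no covariance terms: $\mathrm{SE}(ab) =
\sqrt{a^2\mathrm{SE}_b^2 + b^2\mathrm{SE}_a^2}$. For the proportion both a
ratio-delta SE ($|\hat p|\sqrt{\mathrm{SE}_{ab}^2/(ab)^2 +
\mathrm{SE}_c^2/c^2}$) and a numerator-only SE ($100\,\mathrm{SE}_{ab}/|c|$)
are reported, since published intervals are sometimes computed either way.
Proportions outside $[0,100]$% and sign-inconsistent decompositions are
flagged, never truncated; totals within two SEs of zero are flagged
`unstable_total_effect`.

## LDSC-lite and enrichment

The bivariate LD-score regression is a deliberately minimal single-step
weighted least squares: $z_j^2$ (and $z_{1j}z_{2j}$) on the LD score
$\ell_j$ with weights $1/\max(\ell_j,1)$; slopes scale to $h^2$ and the
genetic covariance, $r_g = \rho_g/\sqrt{h^2_1 h^2_2}$. There is no block
jackknife and no two-step intercept constraint — it is built for recovery
testing on synthetic inputs (it recovers a planted $r_g = 0.5$ to within
±0.05 over replicate means), not as a substitute for the full published
LDSC methodology. $r_g$ is clamped to $[-1,1]$ only in the report column;
negative heritabilities are reported and flagged.

Pathway enrichment is the exact upper-tail hypergeometric test
(`stats::phyper`) of a hit set against a pathway library intersected with a
compound universe, BH-adjusted across pathways, significant at raw
$p < 0.01$. Library retrieval and compound-ID mapping against external
databases are out of scope; a toy library generator with a planted enriched
pathway stands in for testing.

## The synthetic generator

`simulate_triplet()` generates summary statistics directly at the summary
level: standardized per-variant effects with sampling noise
$1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$, which is orders of magnitude
faster than genotype-level simulation and sufficient for every contract in
this package. Design choices:

* Causal variants are LD-block leads; within an AR(1) block (parameter
  $\rho$) neighbours carry $\rho^{d}$ times the lead's standardized effect,
  and the emitted LD matrix is the squared AR(1) correlation.
* Each causal variant explains $r^2 = 0.003$ of the exposure by default (a
  typical lead-SNP value; at $n = 50{,}000$ this gives per-variant
  $F \approx 150$, at $n = 300$ the expected F is below 10 — the two ends
  of the weak-instrument simulation).
* The mediation chain plants $a$, $b$ and $c'$; the mediator receives its
  own causal variants (distinct block leads) in addition to the inherited
  $a\gamma$ signal, because without own instruments the mediator→outcome
  step of two-step MR is not identified.
* Pleiotropy is a direct standardized outcome effect
  $\mathcal N(\mu, \tau)$ on a configurable fraction of instruments
  ($\mu = 0$ balanced, $\mu \neq 0$ directional).
* Default sample sizes follow the scale of the motivating study design: a
  desk-sized exposure GWAS (~8,300, as for metabolite panels) against a
  large biobank case-control outcome (244,562). Simulation studies in the
  tests state their own sizes explicitly (mostly $n = 50{,}000$ per trait).
* What the generator does **not** emulate unless switched on: winner's
  curse (available as `selection_threshold`, which redraws causal exposure
  stats until significant) and sample overlap (`overlap_rho`, correlating
  exposure and outcome noise). There is no coalescent genealogy, no real
  LD panel, and no population stratification — so passing recovery tests
  demonstrates correctness of the estimators and plumbing under the assumed
  sampling model, not robustness to every artifact of real GWAS data.

## Numerical and degenerate-input choices

Zero exposure effects are a hard error in Wald ratios (they must be
filtered upstream). All-identical Wald ratios give $Q = 0$, $\hat\sigma =
0$ and the fixed-effect SE; a zero kernel bandwidth (all ratios equal)
returns that ratio. Clumping ties on p break lexicographically. Empirical
p-values are floored at $1/(n_{\text{sim}}+1)$. Harmonization with an empty
variant intersection is legal and returns an empty pair; screens never
abort on a degenerate exposure — the row is reported as
`skipped_no_instruments`.

## Problem sizes used in validation

The bundled studies use: 2,000 replicates for IVW calibration (type-I
error, recovery, coverage, Egger intercept calibration), 500 for the
robust-estimator contrast and mediation recovery, 200 for MR-PRESSO
operating characteristics and Steiger directionality, 50 for LDSC recovery
and 100 library draws for enrichment ranking — sizes at which the
Monte-Carlo error is comfortably below each assertion's margin, while the
full suite runs in well under a minute of simulation time.

## Known limitations

No multivariable MR, no proxy-variant lookup, no VCF parsing or liftover,
no real LD-panel clumping, and the LDSC implementation is the simplified
single-step variant described above. The outcome-overlap exclusion default
follows the printed rule even though it is aggressive; analysts comparing
against other toolchains should consider `outcome_p` explicitly. Binary
outcome effects are treated as log-odds throughout, with odds-ratio
conversion only at reporting.
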