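---
title: "Two-step Mendelian randomisation mediation analysis with mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step Mendelian randomisation mediation analysis with mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The problem

`mrmediate` implements two-sample Mendelian randomisation (MR) with a
two-step mediation extension, the design used to ask how much of the
effect of an early-life exposure (birth weight, in SD units) on adult
cardiovascular outcomes (on the log odds-ratio scale) is transmitted
through adult metabolic traits. It follows the analytical design of the
published birth-weight mediation study (Open Heart 2025;
doi:10.1136/openhrt-2025-003561), and its arithmetic conventions are
validated cell-for-cell against that study's mediation table.

The package covers the full workflow: reading and validating GWAS
summary statistics, instrument selection by p-value thresholding and
greedy LD clumping, allele harmonisation across studies, the univariable
and multivariable IVW estimators with the usual sensitivity analyses
(MR-Egger, weighted median, weighted mode, MR-PRESSO, leave-one-out,
Cochran's Q), the product-of-coefficients mediation decomposition, and a
config-driven study driver (`run_study()`) that executes the whole
screen-then-mediate funnel and writes report tables.

# The model

## Univariable MR

For variant $j$ with exposure association $\hat\beta_{Xj}$ (SE
$\sigma_{Xj}$) and outcome association $\hat\beta_{Yj}$ (SE
$\sigma_{Yj}$), the Wald ratio is
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$. The IVW estimate pools
ratios with weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$:

$$\hat\theta_{IVW} = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},
\qquad
\mathrm{SE}_{fixed} = \Big(\sum_j w_j\Big)^{-1/2}.$$

This is algebraically the zero-intercept weighted regression of
$\hat\beta_{Yj}$ on $\hat\beta_{Xj}$. The headline model is
*multiplicative random effects*: the fixed SE is inflated by
$\max\{1, \sqrt{Q/(n-1)}\}$ where
$Q = \sum_j w_j(\hat\theta_j - \hat\theta_{IVW})^2$ is Cochran's
heterogeneity statistic. The floor at 1 means the random-effects
interval never undercuts the fixed one. Identifying assumptions are the
usual three: instruments associate with the exposure, share no
confounder with the outcome, and affect the outcome only through the
exposure.

## Sensitivity estimators

- **MR-Egger** regresses $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with a
  free intercept (weights $1/\sigma_{Yj}^2$), after orienting every
  variant so $\hat\beta_{Xj} > 0$. The intercept estimates directional
  pleiotropy; the slope is consistent under the InSIDE assumption.
  Standard errors carry a multiplicative overdispersion factor
  $\max\{1, \sqrt{Q_E/(n-2)}\}$ and inference uses the $t_{n-2}$
  distribution.
- **Weighted median**: the value at cumulative weight one half of the
  ordered Wald ratios, with linear interpolation between adjacent order
  statistics; consistent when valid instruments carry at least half of
  the weight. The SE comes from a seeded parametric bootstrap that
  resamples both association vectors from their sampling distributions.
- **Weighted mode**: the maximiser of the IVW-weighted normal kernel
  density of the ratios, bandwidth
  $h = \phi \cdot 0.9\,\min(\mathrm{sd},\mathrm{mad})\,n^{-1/5}$ with
  `bandwidth_factor` $\phi$ defaulting to 1; consistent when the largest
  group of instruments sharing a causal effect is valid. SE again by
  seeded parametric bootstrap.
- **MR-PRESSO**: the observed weighted residual sum of squares around
  leave-one-out IVW slopes is compared against a seeded parametric null
  in which outcome effects are redrawn under the fitted model. The
  global p-value uses the add-one continuity correction
  $(1 + \#\{RSS_{sim} \ge RSS_{obs}\})/(1 + n_{sim})$, so it is bounded
  below by $1/(n_{sim}+1)$ and can never be exactly zero. Per-variant
  outlier p-values are Bonferroni-adjusted by the instrument count and
  flagged below 0.05; the outlier-corrected estimate refits IVW without
  the flagged variants, and the distortion test compares the observed
  slope change against random removals of the same size.

## Multivariable MR and the two-step decomposition

Step 2 estimates the mediator's effect on the outcome conditional on
the exposure by multivariable IVW: the no-intercept weighted regression

$$\hat\beta_{Yj} = \theta_X \hat\beta_{Xj} + \theta_M \hat\beta_{Mj} + \varepsilon_j,
\qquad w_j = 1/\sigma_{Yj}^2,$$

fitted over the union of both traits' instrument sets, pruned so no two
retained variants are close and correlated (the same greedy rule as
univariable clumping, prioritised by each variant's minimum p-value
across exposures). The mediated (indirect) effect is the product of
coefficients $\hat\beta_1\hat\beta_2$ (step 1: exposure on mediator by
univariable IVW; step 2: $\theta_M$ above), with the delta-method SE
$\sqrt{\hat\beta_1^2\mathrm{se}_2^2 + \hat\beta_2^2\mathrm{se}_1^2}$.
The proportion mediated is $100 \times$ indirect/total.

## Reporting conventions

Two deliberate conventions reproduce the published presentation
exactly, and are isolated in two small functions so they never leak
into estimation:

- `proportion_mediated(..., reporting = "table2_convention")` first
  rounds the indirect effect to two decimals, divides by the (printed)
  total effect, then rounds the percentage to two decimals using base
  R's `round()` (round-half-even). This is the convention under which
  every recomputable cell of the source table reproduces exactly —
  including a half-way case (15.625 printed as 15.62) that rules out
  round-half-away at that step. `reporting = "exact"` divides the
  unrounded quantities and is the right choice for simulations.
- Display strings (`format_effect()`, odds-ratio displays) use
  two-decimal round-half-away-from-zero, matching how the effect
  estimates themselves are printed.

Screening uses Bonferroni correction with strict inequality at three
layers: $0.05/16$ across outcomes, $0.05/24$ across mediators, and
$0.05/n$ across the $n$ mediator–outcome tests actually performed
(at the full design, $0.05/96$). The first two display as 0.0031 and
0.0021 after rounding to four decimals.

# Data handling

## Validation and harmonisation

`summary_stats()` enforces one row per variant, alleles in A/C/G/T,
allele frequencies in (0, 1), positive SEs and p-values in (0, 1], and
records a load report. `harmonise()` aligns an outcome panel to the
exposure's effect alleles row by row, with per-variant provenance
flags:

- `unchanged` — alleles already agree;
- `allele_flipped` — effect/other alleles swapped: the outcome beta
  changes sign and the frequency is complemented (strand complements,
  e.g. A/G vs T/C, are recognised and treated the same way);
- `dropped_palindromic` — A/T or C/G variants are aligned by comparing
  allele frequencies only when both frequencies sit outside the
  ambiguity band (0.40, 0.60); otherwise dropped;
- `dropped_missing`, `dropped_mismatch` — absent from the outcome
  panel, or alleles irreconcilable under swap and strand rules.

## Instrument selection

`select_instruments()` is greedy clumping: sort by p-value (ties broken
by variant ID for determinism), accept a variant unless it lies within
`window_kb` (default 10,000 kb, boundary inclusive) of an accepted
variant and either no LD matrix is supplied (distance-only rule) or
$r^2 \ge$ `r2_max` (default 0.001, boundary exclusive for retention).
The p-value threshold defaults to genome-wide significance
$5\times 10^{-8}$, strict inequality. Instrument strength is summarised
by the mean per-variant F statistic $(\hat\beta/\mathrm{se})^2$, with
the conventional weak-instrument warning at mean F $\le 10$.

# The synthetic generator

`simulate_triad()` draws a three-trait system (exposure, mediator,
binary outcome) with known causal structure
$\theta_{XM}, \theta_{MY}, \theta_{XY,direct}$, so that the true total
effect is $\theta_{XY,direct} + \theta_{XM}\theta_{MY}$ and the true
mediated proportion is known analytically. Per-variant effects follow
$\gamma_j \sim N(0, h^2_X / (2 m\, p_j(1-p_j)))$ for $m$ exposure
instruments at allele frequency $p_j$, giving expected instrument
strength $E[F] \approx 1 + N_X h^2_X / m$ (`expected_instrument_f()`).
Standard errors use the standard GWAS approximation
$1/\sqrt{2 N p_j (1-p_j)}$, with the effective sample size
$4/(1/N_{case} + 1/N_{control})$ for the binary outcome. Defaults
mirror the scale of the real application: exposure $N = 298{,}142$,
mediator $N = 450{,}243$, outcome $60{,}620$ cases / $970{,}216$
controls, $h^2_X = 0.02$ over 100 instruments.

Three features make the generator exercise the full pipeline rather
than just the estimators: a block of mediator-specific instruments
(without which the mediator's genetic effects would be exactly
proportional to the exposure's and multivariable MR would be
collinear by construction), a block of null variants (so thresholding
and screening do real work), and a 10% allele-swap rate in the
mediator and outcome panels (so harmonisation does real work).
Optional balanced pleiotropy adds $\alpha_j \sim N(0, \sigma_\alpha^2)$
directly to the outcome. `simulate_ld_block()` adds an AR(1)-style
$r^2$ decay structure for clumping tests.

What the generator does **not** emulate — so passing tests bound what
they show about real data: genotype-level LD beyond the synthetic
blocks, sample overlap between the three GWAS, population
stratification, winner's curse in instrument discovery, non-collapsible
odds ratios (the binary outcome is generated directly on the log-OR
scale), and directional (unbalanced) pleiotropy beyond what the
pleiotropy mean parameter injects.

# Numerical choices

- Weighted least squares is solved by the normal equations with an
  explicit rank check; rank deficiency raises an error naming the
  collinear design rather than silently dropping a column.
- All bootstrap/simulation SEs require an explicit seed and run under a
  local RNG scope that restores the caller's `.Random.seed`, so results
  are reproducible and functions have no RNG side effects.
- Overdispersion factors are floored at 1 (never deflate a SE).
- The 95% multiplier is fixed at 1.96 to match the printed-table
  presentation, not `qnorm(0.975)`.
- Degenerate inputs fail loudly: zero exposure effect in a Wald ratio,
  zero total effect in a proportion, fewer instruments than the
  estimator's minimum, an MVMR union no larger than the number of
  exposures (under-identified), and PRESSO flagging every instrument
  all raise errors; overlap exclusion that empties an instrument set
  returns a non-estimable result with a warning instead, because the
  study driver must continue past it.
- Problem sizes in the shipped tests are chosen for CI budgets
  (e.g. 2,000 coverage replicates, 500-draw bootstrap inside
  `run_study()`); they are the package's own defaults for validation,
  and all scale up through function arguments.

# Known limitations

- LD handling expects an externally supplied $r^2$ matrix; there is no
  reference-panel computation.
- The weighted mode's bootstrap SE is known to be conservative in small
  panels; the package reports it as-is.
- The mediation CI uses the delta method on the ratio of estimates and
  ignores the covariance between the total and indirect effects, as in
  the source design; for proportions near 0 or 1 the interval can
  escape [0, 100] and is truncated only in display strings.
- `table2_convention` reporting is a presentation-layer convention for
  matching printed tables; analyses on new data should prefer
  `"exact"`.
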