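#' Bonferroni significance layers of the study design
#'
#' The study screens 16 cardiovascular outcomes, 24 candidate metabolic
#' mediators and their mediator-outcome tests; each family gets its own
#' Bonferroni-corrected level.
#'
#' @param n_outcomes,n_mediators,n_pairs family sizes (defaults 16, 24, 96).
#' @return List with `alpha_outcomes`, `alpha_mediators`,
#'   `alpha_mediator_outcome`.
#' @export
bonferroni_layers <- function(n_outcomes = 16, n_mediators = 24,
                              n_pairs = 96) {
  stopifnot(n_outcomes >= 1, n_mediators >= 1, n_pairs >= 1)
  list(
    alpha_outcomes = 0.05 / n_outcomes,
    alpha_mediators = 0.05 / n_mediators,
    alpha_mediator_outcome = 0.05 / n_pairs
  )
}

#' Indirect (mediated) effect by the product of coefficients
#'
#' `indirect = beta1 * beta2` with the delta-method standard error
#' `sqrt(beta1^2 se2^2 + beta2^2 se1^2)` and a normal 95% CI.
#'
#' @param beta1 `mr_estimate` of the exposure-to-mediator effect.
#' @param beta2 `mr_estimate` of the mediator-to-outcome effect adjusted
#'   for the exposure.
#' @return List with `value`, `se`, `ci_low`, `ci_high`, `pvalue`.
#' @export
indirect_effect <- function(beta1, beta2) {
  stopifnot(is.finite(beta1$beta), is.finite(beta2$beta))
  value <- beta1$beta * beta2$beta
  se <- sqrt(beta1$beta^2 * beta2$se^2 + beta2$beta^2 * beta1$se^2)
  pvalue <- if (se == 0) as.numeric(value == 0) else
    2 * stats::pnorm(-abs(value / se))
  list(value = value, se = se,
       ci_low = value - Z95 * se, ci_high = value + Z95 * se,
       pvalue = pvalue)
}

#' Proportion of the total effect transmitted through a mediator
#'
#' `100 * indirect / total`. Two reporting modes: `"exact"` divides the
#' unrounded quantities; `"table2_convention"` first rounds the indirect
#' effect to 2 decimals, divides, and rounds the percentage to 2 decimals
#' (round-half-even, as base `round`) - the convention that reproduces the
#' published mediation table cell-for-cell. The CI is always the delta
#' method applied to the unrounded ratio of independent estimates.
#'
#' @param indirect result of [indirect_effect()].
#' @param total `mr_estimate` of the total effect (must be non-zero).
#' @param reporting `"table2_convention"` or `"exact"`.
#' @return List with `percentage`, `ci_low`, `ci_high` (percentage points)
#'   and `se` of the unrounded proportion (fraction scale).
#' @export
proportion_mediated <- function(indirect, total,
                                reporting = c("table2_convention", "exact")) {
  reporting <- match.arg(reporting)
  if (total$beta == 0) stop("undefined proportion: total effect is zero")
  ratio <- indirect$value / total$beta
  se_ratio <- sqrt(indirect$se^2 / total$beta^2 +
                   indirect$value^2 * total$se^2 / total$beta^4)
  pct <- if (reporting == "exact") {
    100 * ratio
  } else {
    round(100 * round(indirect$value, 2) / total$beta, 2)
  }
  list(percentage = pct,
       ci_low = 100 * (ratio - Z95 * se_ratio),
       ci_high = 100 * (ratio + Z95 * se_ratio),
       se = se_ratio)
}

#' Qualify a candidate mediator for one outcome
#'
#' Three criteria: (1) the exposure-to-mediator effect is significant at
#' the mediator layer; (2) the mediator-to-outcome effect, adjusted for the
#' exposure, is significant at the pair layer; (3) the indirect effect has
#' the same sign as the total effect.
#'
#' @param beta1,beta2,total `mr_estimate` objects.
#' @param layers significance layers from [bonferroni_layers()].
#' @return List with logical `qualified` and per-criterion `criteria`.
#' @export
qualify_mediator <- function(beta1, beta2, total, layers = bonferroni_layers()) {
  c1 <- beta1$pvalue < layers$alpha_mediators
  c2 <- beta2$pvalue < layers$alpha_mediator_outcome
  c3 <- sign(beta1$beta * beta2$beta) == sign(total$beta)
  list(qualified = c1 && c2 && c3,
       criteria = c(exposure_mediator = c1,
                    mediator_outcome = c2,
                    directional_consistency = c3))
}

#' Full two-step mediation analysis for one mediator-outcome pair
#'
#' Computes the total effect (IVW of exposure on outcome), step-1 effect
#' beta1 (IVW of exposure on mediator), step-2 effect beta2 (multivariable
#' IVW of the mediator on the outcome adjusted for the exposure, on the
#' union of both instrument sets), the product-of-coefficients indirect
#' effect, the mediated proportion, and the qualification verdict.
#'
#' @param exposure,mediator,outcome `summary_stats` objects.
#' @param p_threshold,r2_max,window_kb,ld instrument-selection controls.
#' @param layers Bonferroni layers, see [bonferroni_layers()].
#' @param reporting proportion reporting mode, see [proportion_mediated()].
#' @param exclude_variants variant IDs removed from both instrument sets
#'   before analysis (used by [overlap_sensitivity()]).
#' @return A `mediation_result` list: `outcome`, `mediator`, `total`,
#'   `beta1`, `beta2`, `indirect`, `proportion`, `qualified`, `criteria`,
#'   `n_excluded`, `estimable`.
#' @export
mediate_pair <- function(exposure, mediator, outcome, p_threshold = 5e-8,
                         r2_max = 0.001, window_kb = 10000, ld = NULL,
                         layers = bonferroni_layers(),
                         reporting = "table2_convention",
                         exclude_variants = character(0)) {
  drop_excluded <- function(ss) {
    restore_ss(as.data.frame(ss)[!(ss$variant_id %in% exclude_variants), ,
                                 drop = FALSE], ss)
  }
  exp_use <- drop_excluded(exposure)
  med_use <- drop_excluded(mediator)

  exp_iv <- select_instruments(exp_use, p_threshold, r2_max, window_kb, ld)
  med_iv <- select_instruments(med_use, p_threshold, r2_max, window_kb, ld)
  if (nrow(exp_iv) < 2L || nrow(med_iv) < 2L) {
    return(structure(list(
      outcome = attr(outcome, "trait_name"),
      mediator = attr(mediator, "trait_name"),
      total = NULL, beta1 = NULL, beta2 = NULL, indirect = NULL,
      proportion = NULL, qualified = FALSE, criteria = NULL,
      n_excluded = length(exclude_variants), estimable = FALSE
    ), class = "mediation_result"))
  }

  total <- mr_ivw(harmonise(exp_iv, outcome))
  beta1 <- mr_ivw(harmonise(exp_iv, mediator))
  mv <- assemble_mvmr(list(exp_use, med_use), outcome,
                      p_threshold = p_threshold, r2_max = r2_max,
                      window_kb = window_kb, ld = ld)
  beta2 <- mvmr_ivw(mv)[[attr(mediator, "trait_name")]]

  ind <- indirect_effect(beta1, beta2)
  prop <- proportion_mediated(ind, total, reporting = reporting)
  qual <- qualify_mediator(beta1, beta2, total, layers)

  structure(list(
    outcome = attr(outcome, "trait_name"),
    mediator = attr(mediator, "trait_name"),
    total = total, beta1 = beta1, beta2 = beta2,
    indirect = ind, proportion = prop,
    qualified = qual$qualified, criteria = qual$criteria,
    n_excluded = length(exclude_variants), estimable = TRUE
  ), class = "mediation_result")
}

#' Overlap-variant sensitivity analysis
#'
#' Repeats the full mediation analysis after removing every variant that is
#' genome-wide significant for both the exposure and the mediator, guarding
#' against shared instruments driving the decomposition.
#'
#' @inheritParams mediate_pair
#' @return A `mediation_result` with `n_excluded` set to the number of
#'   shared significant variants; `estimable = FALSE` when the exclusion
#'   empties an instrument set.
#' @export
overlap_sensitivity <- function(exposure, mediator, outcome,
                                p_threshold = 5e-8, r2_max = 0.001,
                                window_kb = 10000, ld = NULL,
                                layers = bonferroni_layers(),
                                reporting = "table2_convention") {
  sig_exp <- exposure$variant_id[exposure$pvalue < p_threshold]
  sig_med <- mediator$variant_id[mediator$pvalue < p_threshold]
  shared <- intersect(sig_exp, sig_med)
  res <- mediate_pair(exposure, mediator, outcome, p_threshold, r2_max,
                      window_kb, ld, layers, reporting,
                      exclude_variants = shared)
  if (!res$estimable) {
    warning("overlap exclusion left a degenerate instrument set for ",
            res$mediator, " -> ", res$outcome, call. = FALSE)
  }
  res$n_excluded <- length(shared)
  res
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s\n", x$mediator, x$outcome))
  if (!x$estimable) {
    cat("  non-estimable (degenerate instrument set after exclusions)\n")
    return(invisible(x))
  }
  cat(sprintf("  total %.3f, beta1 %.3f, beta2 %.3f, indirect %.3f\n",
              x$total$beta, x$beta1$beta, x$beta2$beta, x$indirect$value))
  cat(sprintf("  proportion mediated %.2f%% (%.2f%% to %.2f%%), qualified: %s\n",
              x$proportion$percentage, x$proportion$ci_low,
              x$proportion$ci_high, x$qualified))
  invisible(x)
}
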