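#' Configuration for a synthetic exposure-mediator-outcome triad
#'
#' Defaults emulate the study's flagship pathway: a standardised
#' birth-weight-like exposure (n about 298k, roughly 100 independent
#' instruments explaining 2% of variance, so the expected instrument F is
#' about 60), an appendicular-lean-mass-like mediator (n about 450k with
#' its own instruments), and an atrial-fibrillation-like binary outcome
#' (60 620 cases / 970 216 controls, effects on the log-OR scale). The
#' causal chain defaults give total effect 0.29 with 47% truly mediated.
#'
#' @param n_snps exposure instrument count.
#' @param n_med_snps mediator-specific instrument count (gives the mediator
#'   its own identification in multivariable fits).
#' @param n_null_snps background variants with no true effect on anything.
#' @param maf_range interval of minor-allele frequencies, within (0, 0.5].
#' @param n_exp,n_med GWAS sample sizes for exposure and mediator.
#' @param n_out outcome sample size: a single number for a continuous
#'   outcome, or `c(n_case, n_control)` for a binary one (effects then on
#'   the log-OR scale with effective-sample-size standard errors).
#' @param exposure_h2 variance of the exposure explained by its instruments.
#' @param mediator_h2 variance of the mediator explained by its own
#'   instruments (on top of what it inherits from the exposure).
#' @param theta_xm true exposure-to-mediator effect.
#' @param theta_my true mediator-to-outcome effect.
#' @param theta_xy_direct true direct exposure-to-outcome effect.
#' @param pleiotropy_mean,pleiotropy_sd distribution of direct
#'   variant-to-outcome effects added to the exposure instruments.
#' @param seed integer seed governing every random draw.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_snps = 100, n_med_snps = 100, n_null_snps = 100,
                       maf_range = c(0.05, 0.5),
                       n_exp = 298142, n_med = 450243,
                       n_out = c(60620, 970216),
                       exposure_h2 = 0.02, mediator_h2 = 0.03,
                       theta_xm = 0.47, theta_my = 0.29,
                       theta_xy_direct = 0.29 - 0.47 * 0.29,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       seed = NULL) {
  cfg <- list(n_snps = n_snps, n_med_snps = n_med_snps,
              n_null_snps = n_null_snps, maf_range = maf_range,
              n_exp = n_exp, n_med = n_med, n_out = n_out,
              exposure_h2 = exposure_h2, mediator_h2 = mediator_h2,
              theta_xm = theta_xm, theta_my = theta_my,
              theta_xy_direct = theta_xy_direct,
              pleiotropy_mean = pleiotropy_mean,
              pleiotropy_sd = pleiotropy_sd, seed = seed)
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(n_snps >= 1, "n_snps must be >= 1")
  chk(n_med_snps >= 0, "n_med_snps must be >= 0")
  chk(n_null_snps >= 0, "n_null_snps must be >= 0")
  chk(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
        maf_range[1] <= maf_range[2],
      "maf_range must be an interval within (0, 0.5]")
  chk(n_exp >= 1 && n_med >= 1 && all(n_out >= 1), "sample sizes must be >= 1")
  chk(length(n_out) %in% c(1L, 2L), "n_out must be scalar or case/control pair")
  chk(exposure_h2 > 0 && exposure_h2 < 1, "exposure_h2 must be in (0,1)")
  chk(mediator_h2 >= 0 && mediator_h2 < 1, "mediator_h2 must be in [0,1)")
  chk(pleiotropy_sd >= 0, "pleiotropy_sd must be >= 0")
  if (length(problems)) {
    stop("invalid simulation config: ", paste(problems, collapse = "; "))
  }
  structure(cfg, class = "sim_config")
}

#' Analytic ground truth implied by a simulation config
#'
#' @param cfg a `sim_config`.
#' @return A `triad_truth` list: `true_total`, `true_indirect`,
#'   `true_direct`, `true_proportion`.
#' @export
triad_truth <- function(cfg) {
  ind <- cfg$theta_xm * cfg$theta_my
  tot <- cfg$theta_xy_direct + ind
  structure(list(true_total = tot, true_indirect = ind,
                 true_direct = cfg$theta_xy_direct,
                 true_proportion = ind / tot),
            class = "triad_truth")
}

effective_n <- function(n) {
  if (length(n) == 2L) 4 / (1 / n[1] + 1 / n[2]) else n
}

# Chromosome/position layout placing every variant > 10,000 kb from the
# next on its chromosome, so distance-only pruning treats them as
# independent.
snp_positions <- function(n) {
  chrom <- as.character((seq_len(n) - 1L) %% 22L + 1L)
  pos <- 1e6 + ((seq_len(n) - 1L) %/% 22L) * 20000001
  list(chrom = chrom, pos = pos)
}

#' Simulate GWAS summary statistics for a causal triad
#'
#' Generates three summary-statistics tables (exposure, mediator, outcome)
#' over a shared variant panel with known causal structure. Exposure
#' instruments j carry effects `gamma_j` drawn so their variance
#' contribution sums to `exposure_h2`; their mediator effects are
#' `theta_xm * gamma_j` and their outcome effects
#' `(theta_xy_direct + theta_my * theta_xm) * gamma_j + alpha_j` with
#' pleiotropy `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)`.
#' Mediator-specific instruments affect the mediator directly and the
#' outcome through `theta_my`; null variants affect nothing. Observed
#' effects add sampling noise with `se = 1/sqrt(2 n maf (1-maf))` per trait
#' (effective n for case/control outcomes); p-values are two-sided normal.
#' Ten percent of mediator and outcome records are emitted with their
#' alleles swapped (and effects recoded accordingly) to exercise
#' harmonisation.
#'
#' @param cfg a `sim_config`; its `seed` must be set.
#' @return List with `exposure`, `mediator`, `outcome` (each
#'   `summary_stats`) and `truth` (a `triad_truth`).
#' @export
simulate_triad <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$seed)) stop("sim_config seed must be set to simulate")
  with_local_seed(cfg$seed, {
    n_total <- cfg$n_snps + cfg$n_med_snps + cfg$n_null_snps
    kind <- rep(c("exp", "med", "null"),
                c(cfg$n_snps, cfg$n_med_snps, cfg$n_null_snps))
    loc <- snp_positions(n_total)
    ids <- sprintf("rs%07d", seq_len(n_total))
    maf <- stats::runif(n_total, cfg$maf_range[1], cfg$maf_range[2])
    het <- 2 * maf * (1 - maf)  # per-variant genotype variance factor

    gamma <- numeric(n_total)
    is_exp <- kind == "exp"
    gamma[is_exp] <- stats::rnorm(cfg$n_snps,
                                  sd = sqrt(cfg$exposure_h2 / cfg$n_snps /
                                              het[is_exp]))
    gamma_m <- numeric(n_total)
    is_med <- kind == "med"
    if (cfg$n_med_snps > 0) {
      gamma_m[is_med] <- stats::rnorm(cfg$n_med_snps,
                                      sd = sqrt(cfg$mediator_h2 /
                                                  cfg$n_med_snps /
                                                  het[is_med]))
    }
    alpha <- numeric(n_total)
    alpha[is_exp] <- stats::rnorm(cfg$n_snps, cfg$pleiotropy_mean,
                                  cfg$pleiotropy_sd)

    true_exp <- gamma
    true_med <- cfg$theta_xm * gamma + gamma_m
    true_out <- (cfg$theta_xy_direct + cfg$theta_my * cfg$theta_xm) * gamma +
      cfg$theta_my * gamma_m + alpha

    make_trait <- function(true_beta, n, trait_name, unit, swap_frac = 0.1) {
      n_eff <- effective_n(n)
      se <- 1 / sqrt(2 * n_eff * maf * (1 - maf))
      beta <- stats::rnorm(n_total, true_beta, se)
      ea <- rep("A", n_total); oa <- rep("C", n_total)
      eaf <- maf
      swap <- stats::runif(n_total) < swap_frac
      ea[swap] <- "C"; oa[swap] <- "A"
      beta[swap] <- -beta[swap]; eaf[swap] <- 1 - eaf[swap]
      rec <- data.frame(
        variant_id = ids, chrom = loc$chrom, pos = loc$pos,
        effect_allele = ea, other_allele = oa, eaf = eaf,
        beta = beta, se = se,
        pvalue = 2 * stats::pnorm(-abs(beta / se)),
        n = sum(n), stringsAsFactors = FALSE
      )
      if (length(n) == 2L) { rec$n_case <- n[1]; rec$n_control <- n[2] }
      summary_stats(rec, trait_name = trait_name, unit = unit)
    }

    out_unit <- if (length(cfg$n_out) == 2L) "logOR" else "SD"
    list(
      exposure = make_trait(true_exp, cfg$n_exp, "exposure", "SD",
                            swap_frac = 0),
      mediator = make_trait(true_med, cfg$n_med, "mediator", "SD"),
      outcome = make_trait(true_out, cfg$n_out, "outcome", out_unit),
      truth = triad_truth(cfg)
    )
  })
}

#' Write a triad's ground truth as a plain-text sidecar
#'
#' @param truth a `triad_truth`.
#' @param path output path; written as `key: value` lines.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  lines <- sprintf("%s: %.10g",
                   c("true_total", "true_indirect", "true_direct",
                     "true_proportion"),
                   c(truth$true_total, truth$true_indirect,
                     truth$true_direct, truth$true_proportion))
  writeLines(lines, path)
  invisible(path)
}

#' Expected mean instrument F-statistic under a config
#'
#' The squared exposure z-score for instrument j has expectation
#' `1 + n_exp * E[gamma_j^2] / se_j^2 = 1 + n_exp * exposure_h2 / n_snps`,
#' independent of allele frequency.
#'
#' @param cfg a `sim_config`.
#' @return Expected mean F across exposure instruments.
#' @export
expected_instrument_f <- function(cfg) {
  1 + cfg$n_exp * cfg$exposure_h2 / cfg$n_snps
}

#' Simulate an LD block with geometric decay
#'
#' Squared correlations follow `r2(i,j) = decay_r2^|i-j|`; observed effects
#' are drawn with the matching correlation (signed correlation
#' `decay_r2^(|i-j|/2)`). Variants sit 100 kb apart on one chromosome, so
#' the whole block lies inside a standard 10,000 kb clumping window.
#'
#' @param n_snps block size.
#' @param decay_r2 nearest-neighbour squared correlation, in \[0,1).
#' @param seed integer seed.
#' @param beta_mean common true effect (default 0.1, genome-wide
#'   significant at the default standard error).
#' @param se per-variant standard error (default 0.01).
#' @return List with `ld` (an [ld_matrix()]) and `stats` (a
#'   `summary_stats` fragment).
#' @export
simulate_ld_block <- function(n_snps, decay_r2, seed, beta_mean = 0.1,
                              se = 0.01) {
  stopifnot(decay_r2 >= 0, decay_r2 < 1)
  ids <- sprintf("ld%04d", seq_len(n_snps))
  dist <- abs(outer(seq_len(n_snps), seq_len(n_snps), "-"))
  r2 <- decay_r2^dist
  if (decay_r2 == 0) r2[dist > 0] <- 0
  ld <- ld_matrix(ids, r2)
  corr <- sqrt(r2)
  z <- with_local_seed(seed, {
    drop(t(chol(corr)) %*% stats::rnorm(n_snps))
  })
  beta <- beta_mean + se * z
  rec <- data.frame(
    variant_id = ids, chrom = "1", pos = 1e6 + (seq_len(n_snps) - 1) * 1e5,
    effect_allele = "A", other_allele = "C", eaf = 0.3,
    beta = beta, se = se, pvalue = 2 * stats::pnorm(-abs(beta / se)),
    n = 100000, stringsAsFactors = FALSE
  )
  list(ld = ld, stats = summary_stats(rec, trait_name = "ld_block"))
}
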