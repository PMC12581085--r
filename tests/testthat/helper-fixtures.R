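# Shared fixture builders and independent oracles.

# Build a summary_stats object from vectors, filling in sensible defaults.
make_ss <- function(variant_id, beta, se,
                    pvalue = 2 * pnorm(-abs(beta / se)),
                    chrom = "1",
                    pos = seq_along(variant_id) * 30000000,
                    effect_allele = "A", other_allele = "C",
                    eaf = 0.3, n = 1e5, trait_name = "trait", unit = "SD") {
  summary_stats(data.frame(
    variant_id = variant_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n,
    stringsAsFactors = FALSE
  ), trait_name = trait_name, unit = unit)
}

# Build a harmonised_set directly from effect vectors.
make_hset <- function(beta_exp, se_exp, beta_out, se_out,
                      variant_id = sprintf("snp%03d", seq_along(beta_exp)),
                      exposure_name = "exposure", outcome_name = "outcome") {
  h <- data.frame(
    variant_id = variant_id, chrom = "1",
    pos = seq_along(beta_exp) * 30000000,
    effect_allele = "A", other_allele = "C",
    beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out,
    eaf = 0.3, flag = "unchanged", stringsAsFactors = FALSE
  )
  structure(h, class = c("harmonised_set", "data.frame"),
            exposure_name = exposure_name, outcome_name = outcome_name,
            provenance = data.frame(variant_id = variant_id,
                                    flag = "unchanged"))
}

# Generic weighted least-squares oracle via lm(), independent of wls_fit().
wls_oracle <- function(X, y, w, intercept = FALSE) {
  df <- as.data.frame(X)
  df$y <- y
  form <- if (intercept) y ~ . else y ~ . - 1
  fit <- lm(form, data = df, weights = w)
  list(coef = coef(fit), se = summary(fit)$coefficients[, "Std. Error"])
}

# Direct evaluation of the cumulative-weight weighted-median definition.
weighted_median_oracle <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  approx(cum, b, xout = 0.5, rule = 2)$y
}

# Density-maximum oracle on an explicit fine grid (normal kernel).
weighted_mode_oracle <- function(b, w, bw) {
  w <- w / sum(w)
  grid <- seq(min(b) - 4 * bw, max(b) + 4 * bw, length.out = 20000)
  dens <- vapply(grid, function(x) sum(w * dnorm(x, b, bw)), numeric(1))
  grid[which.max(dens)]
}

# Two exposures with disjoint significant variants plus shared nulls, and
# an outcome defined over every variant.
mvmr_fixture <- function(b1 = 0.3, b2 = 0.2, noise_sd = 0, seed = 1,
                         n_each = 8) {
  set.seed(seed)
  n <- 2 * n_each
  ids <- sprintf("mv%03d", 1:n)
  pos <- seq_len(n) * 3e7
  bx1 <- c(runif(n_each, 0.05, 0.12), runif(n_each, 0, 0.005))
  bx2 <- c(runif(n_each, 0, 0.005), runif(n_each, 0.05, 0.12))
  se1 <- rep(0.004, n); se2 <- rep(0.004, n)
  e1 <- make_ss(ids, bx1, se1, pos = pos, trait_name = "exp1")
  e2 <- make_ss(ids, bx2, se2, pos = pos, trait_name = "exp2")
  by <- b1 * bx1 + b2 * bx2 + rnorm(n, 0, noise_sd)
  out <- make_ss(ids, by, rep(0.01, n), pos = pos, trait_name = "outcome")
  list(e1 = e1, e2 = e2, out = out, ids = ids)
}

# A deterministic noisy instrument fixture used by several oracle tests.
noisy_hset <- function(n = 12, seed = 101, slope = 0.4) {
  set.seed(seed)
  bx <- runif(n, 0.02, 0.1)
  sx <- runif(n, 0.002, 0.006)
  sy <- runif(n, 0.005, 0.02)
  by <- slope * bx + rnorm(n, 0, sy)
  make_hset(bx, sx, by, sy)
}
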