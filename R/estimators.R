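Z95 <- 1.96  # fixed CI multiplier matching 95% presentation

#' Construct an MR estimate
#'
#' @param method label, one of `wald`, `ivw_fixed`, `ivw_random`,
#'   `egger_slope`, `weighted_median`, `weighted_mode`, `mvmr_ivw`.
#' @param beta causal effect (log-OR per exposure SD for binary outcomes).
#' @param se positive standard error.
#' @param pvalue two-sided p-value; computed from the normal approximation
#'   when omitted.
#' @param n_snp number of instruments behind the estimate.
#' @return An `mr_estimate` list with `beta`, `se`, `ci_low`, `ci_high`,
#'   `pvalue`, `n_snp`, `method`.
#' @export
mr_estimate <- function(method, beta, se, pvalue = NULL, n_snp = 1L) {
  stopifnot(is.finite(beta), is.finite(se), se >= 0)
  if (is.null(pvalue)) {
    pvalue <- if (se == 0) as.numeric(beta == 0) else
      2 * stats::pnorm(-abs(beta / se))
  }
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
    pvalue = pvalue, n_snp = as.integer(n_snp)
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (95%% CI %.4f to %.4f), se = %.4f, p = %.3g, n_snp = %d\n",
              x$method, x$beta, x$ci_low, x$ci_high, x$se, x$pvalue, x$n_snp))
  invisible(x)
}

#' Wald ratio for a single instrument
#'
#' The per-variant causal estimate: outcome effect divided by exposure
#' effect. The default standard error is the first-order delta
#' approximation `se_out/|beta_exp|`; `second_order = TRUE` adds the term
#' propagating exposure-side uncertainty.
#'
#' @param beta_exp,se_exp exposure association and SE.
#' @param beta_out,se_out outcome association and SE.
#' @param second_order use the second-order delta SE.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       second_order = FALSE) {
  if (beta_exp == 0) stop("undefined Wald ratio: exposure effect is zero")
  beta <- beta_out / beta_exp
  se <- if (second_order) {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  } else {
    se_out / abs(beta_exp)
  }
  mr_estimate("wald", beta, se, n_snp = 1L)
}

ivw_weights <- function(h) h$beta_exp^2 / h$se_out^2

wald_ratios <- function(h) h$beta_out / h$beta_exp

#' Inverse-variance weighted estimate
#'
#' Pools per-variant Wald ratios `r_j = beta_out/beta_exp` with weights
#' `w_j = beta_exp^2/se_out^2` (equivalent to the zero-intercept weighted
#' regression of outcome on exposure effects). The multiplicative
#' random-effects model inflates the fixed-effect SE by
#' `max(1, sqrt(Q/(n-1)))`.
#'
#' @param h a `harmonised_set` (>= 1 variant for fixed, >= 2 for random).
#' @param model `"random_multiplicative"` (headline) or `"fixed"`.
#' @return An `mr_estimate`.
#' @export
mr_ivw <- function(h, model = c("random_multiplicative", "fixed")) {
  model <- match.arg(model)
  n <- nrow(h)
  min_n <- if (model == "fixed") 1L else 2L
  if (n < min_n) stop("IVW (", model, ") requires at least ", min_n, " instruments")
  w <- ivw_weights(h)
  r <- wald_ratios(h)
  beta <- sum(w * r) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (model == "random_multiplicative") {
    q <- sum(w * (r - beta)^2)
    se <- se * max(1, sqrt(q / (n - 1)))
  }
  mr_estimate(if (model == "fixed") "ivw_fixed" else "ivw_random",
              beta, se, n_snp = n)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept (weights `1/se_out^2`), after orienting every variant so its
#' exposure effect is positive. A non-zero intercept indicates directional
#' horizontal pleiotropy. Standard errors use multiplicative overdispersion
#' floored at 1; inference is on the t distribution with `n - 2` df.
#'
#' @param h a `harmonised_set` with at least 3 variants.
#' @return List of class `egger_result` with `slope` (an `mr_estimate`) and
#'   `intercept` (`value`, `se`, `pvalue`), plus `Q` and `df`.
#' @export
mr_egger <- function(h) {
  n <- nrow(h)
  if (n < 3L) stop("MR-Egger requires at least 3 instruments")
  flip <- sign(h$beta_exp)
  x <- h$beta_exp * flip
  y <- h$beta_out * flip
  w <- 1 / h$se_out^2
  X <- cbind(intercept = 1, slope = x)
  fit <- wls_fit(X, y, w)
  phi <- max(1, sqrt(fit$rss_w / (n - 2)))
  se <- fit$se_unit * phi
  tval <- fit$coef / se
  pvals <- 2 * stats::pt(-abs(tval), df = n - 2)
  slope <- mr_estimate("egger_slope", fit$coef[["slope"]], se[["slope"]],
                       pvalue = pvals[["slope"]], n_snp = n)
  structure(list(
    slope = slope,
    intercept = list(value = fit$coef[["intercept"]],
                     se = se[["intercept"]],
                     pvalue = pvals[["intercept"]]),
    Q = fit$rss_w, df = n - 2L
  ), class = "egger_result")
}

# Weighted least squares via the normal equations; returns coefficients,
# weighted RSS and the unit-dispersion SEs sqrt(diag((X'WX)^-1)).
wls_fit <- function(X, y, w) {
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  qr_x <- qr(XtWX)
  if (qr_x$rank < ncol(X)) stop("rank-deficient design in weighted fit")
  coef <- drop(solve(XtWX, XtW %*% y))
  names(coef) <- colnames(X)
  resid <- y - drop(X %*% coef)
  inv <- solve(XtWX)
  se_unit <- sqrt(diag(inv))
  names(se_unit) <- colnames(X)
  list(coef = coef, rss_w = sum(w * resid^2), se_unit = se_unit, inv = inv)
}

# Weighted median of values `b` with weights `w` (normalised internally):
# value at cumulative weight 0.5 with linear interpolation between adjacent
# order statistics.
weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(b[1])
  if (cum[length(b)] <= 0.5) return(b[length(b)])
  below <- max(which(cum < 0.5))
  b[below] + (b[below + 1] - b[below]) * (0.5 - cum[below]) /
    (cum[below + 1] - cum[below])
}

#' Weighted-median MR estimate
#'
#' Weighted median of per-variant Wald ratios with inverse-variance weights;
#' consistent when instruments carrying at least half the weight are valid.
#' The SE comes from a seeded parametric bootstrap that resamples both
#' association vectors from their sampling distributions.
#'
#' @param h a `harmonised_set` with at least 3 variants.
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed integer seed (required: no hidden global randomness).
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 5000, seed) {
  n <- nrow(h)
  if (n < 3L) stop("weighted median requires at least 3 instruments")
  if (missing(seed)) stop("an explicit seed is required")
  w <- ivw_weights(h)
  est <- weighted_median_point(wald_ratios(h), w)
  se <- with_local_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(n, h$beta_exp, h$se_exp)
      by <- stats::rnorm(n, h$beta_out, h$se_out)
      weighted_median_point(by / bx, bx^2 / h$se_out^2)
    }, numeric(1))
    stats::sd(boots)
  })
  mr_estimate("weighted_median", est, se, n_snp = n)
}

# Mode of the inverse-variance weighted kernel density over ratios.
# Bandwidth: modified Silverman rule on the ratio spread,
# h = factor * 0.9 * min(sd, mad) * n^(-1/5).
weighted_mode_point <- function(b, w, bandwidth_factor = 1) {
  w <- w / sum(w)
  s <- min(stats::sd(b), stats::mad(b))
  if (s == 0) return(b[1])
  bw <- bandwidth_factor * 0.9 * s * length(b)^(-1 / 5)
  d <- stats::density(b, weights = w, bw = bw, n = 2048)
  d$x[which.max(d$y)]
}

#' Weighted-mode MR estimate
#'
#' The mode of the inverse-variance-weighted normal-kernel density of the
#' Wald ratios (bandwidth: modified Silverman rule on the ratio spread,
#' scaled by `bandwidth_factor`); consistent when the largest group of
#' instruments sharing a causal effect is valid. SE by seeded parametric
#' bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor multiplier on the rule-of-thumb bandwidth.
#' @return An `mr_estimate` with method `"weighted_mode"`.
#' @export
mr_weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 5000, seed) {
  n <- nrow(h)
  if (n < 3L) stop("weighted mode requires at least 3 instruments")
  if (missing(seed)) stop("an explicit seed is required")
  w <- ivw_weights(h)
  est <- weighted_mode_point(wald_ratios(h), w, bandwidth_factor)
  se <- with_local_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(n, h$beta_exp, h$se_exp)
      by <- stats::rnorm(n, h$beta_out, h$se_out)
      weighted_mode_point(by / bx, bx^2 / h$se_out^2, bandwidth_factor)
    }, numeric(1))
    stats::sd(boots)
  })
  mr_estimate("weighted_mode", est, se, n_snp = n)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (r_j - beta_pooled)^2` over per-variant Wald ratios, with
#' the IVW weights; p from the upper tail of chi-square on `n - 1` df
#' (`n - 2` is the caller's concern for Egger residual heterogeneity,
#' reported by [mr_egger()] itself).
#'
#' @param h a `harmonised_set` with at least 2 variants.
#' @param pooled the pooled `mr_estimate` the deviations are taken from
#'   (typically fixed-effects IVW).
#' @return List with `Q`, `df`, `pvalue` of class `heterogeneity_stats`.
#' @export
cochrans_q <- function(h, pooled) {
  n <- nrow(h)
  if (n < 2L) stop("Cochran's Q requires at least 2 instruments")
  w <- ivw_weights(h)
  r <- wald_ratios(h)
  q <- sum(w * (r - pooled$beta)^2)
  df <- n - 1L
  structure(list(Q = q, df = df,
                 pvalue = stats::pchisq(q, df, lower.tail = FALSE)),
            class = "heterogeneity_stats")
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the IVW estimate once per omitted variant, with the same model
#' settings as the headline fit.
#'
#' @param h a `harmonised_set` with at least 3 variants.
#' @param model IVW model passed through to [mr_ivw()].
#' @return Data frame with one row per omitted variant: `dropped`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `pvalue`.
#' @export
leave_one_out <- function(h, model = "random_multiplicative") {
  n <- nrow(h)
  if (n < 3L) stop("leave-one-out requires at least 3 instruments")
  rows <- lapply(seq_len(n), function(i) {
    e <- mr_ivw(h[-i, , drop = FALSE], model = model)
    data.frame(dropped = h$variant_id[i], beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  # nudge past binary representation error before taking the half-away floor
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Convert a log-odds-ratio estimate to the odds-ratio scale
#'
#' @param e an `mr_estimate` on the log-OR scale.
#' @return List with `or`, `ci_low`, `ci_high` (exact) and `display`, the
#'   2-decimal round-half-away presentation values.
#' @export
to_odds_ratio <- function(e) {
  or <- exp(e$beta); lo <- exp(e$ci_low); hi <- exp(e$ci_high)
  list(
    or = or, ci_low = lo, ci_high = hi,
    display = c(or = round_half_away(or), ci_low = round_half_away(lo),
                ci_high = round_half_away(hi))
  )
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
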