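test_that("Wald ratio matches the forced arithmetic and rejects a zero exposure effect", {
  e <- wald_ratio(1, 0.1, 0.5, 0.1)
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 0.1)
  expect_equal(wald_ratio(0.3, 0.01, 0, 0.05)$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.05), "zero")
})

test_that("second-order Wald SE matches a Monte-Carlo delta oracle", {
  bx <- 0.1; sx <- 0.01; by <- 0.02; sy <- 0.005
  e <- wald_ratio(bx, sx, by, sy, second_order = TRUE)
  # independent oracle: large-sample propagation of the ratio
  set.seed(2024)
  draws <- rnorm(2e6, by, sy) / rnorm(2e6, bx, sx)
  # the exact ratio sd exceeds the delta approximation at this noise level
  expect_equal(e$se, sd(draws), tolerance = 0.05)
  # and the closed form evaluated independently
  expect_equal(e$se, sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4), tolerance = 1e-12)
})

test_that("IVW reduces to the consensus ratio, the single-SNP Wald ratio, and the brute-force weighted mean", {
  # all variants share ratio c
  h <- make_hset(c(0.05, 0.1, 0.2), 0.01, c(0.05, 0.1, 0.2) * 0.3,
                 c(0.01, 0.02, 0.03))
  expect_equal(mr_ivw(h, "fixed")$beta, 0.3, tolerance = 1e-12)
  expect_equal(mr_ivw(h)$beta, 0.3, tolerance = 1e-12)

  h1 <- make_hset(0.05, 0.01, 0.02, 0.01)
  expect_equal(mr_ivw(h1, "fixed")$beta, wald_ratio(0.05, 0.01, 0.02, 0.01)$beta)
  expect_equal(mr_ivw(h1, "fixed")$se, wald_ratio(0.05, 0.01, 0.02, 0.01)$se)
  expect_error(mr_ivw(h1), "at least 2")

  h3 <- noisy_hset()
  w <- h3$beta_exp^2 / h3$se_out^2
  r <- h3$beta_out / h3$beta_exp
  brute <- sum(w * r) / sum(w)   # explicit loop-free weighted mean
  expect_equal(mr_ivw(h3, "fixed")$beta, brute, tolerance = 1e-12)
  expect_equal(mr_ivw(h3, "fixed")$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
})

test_that("multiplicative random-effects IVW never reports a smaller SE than fixed", {
  for (seed in 1:20) {
    h <- noisy_hset(seed = seed)
    expect_gte(mr_ivw(h)$se, mr_ivw(h, "fixed")$se)
  }
})

test_that("MR-Egger recovers exact lines and matches a weighted least-squares oracle", {
  bx <- c(0.02, 0.05, 0.08, 0.11)
  # line through the origin: intercept 0
  h0 <- make_hset(bx, 0.01, 0.4 * bx, c(0.01, 0.02, 0.015, 0.02))
  eg0 <- mr_egger(h0)
  expect_equal(eg0$intercept$value, 0, tolerance = 1e-10)
  expect_equal(eg0$slope$beta, 0.4, tolerance = 1e-10)
  # line with intercept 0.1, no noise
  h1 <- make_hset(bx, 0.01, 0.1 + 0.4 * bx, c(0.01, 0.02, 0.015, 0.02))
  eg1 <- mr_egger(h1)
  expect_equal(eg1$intercept$value, 0.1, tolerance = 1e-10)
  expect_equal(eg1$slope$beta, 0.4, tolerance = 1e-10)

  # noisy fixture vs generic WLS oracle (orientation: all beta_exp > 0)
  h <- noisy_hset(seed = 7)
  or <- wls_oracle(data.frame(x = h$beta_exp), h$beta_out,
                   1 / h$se_out^2, intercept = TRUE)
  eg <- mr_egger(h)
  expect_equal(eg$slope$beta, unname(or$coef["x"]), tolerance = 1e-8)
  expect_equal(eg$intercept$value, unname(or$coef["(Intercept)"]),
               tolerance = 1e-8)
  # lm()'s SEs already carry sqrt(RSS_w/(n-2)); equal when inflation > 1
  if (sqrt(eg$Q / eg$df) > 1) {
    expect_equal(eg$slope$se, unname(or$se["x"]), tolerance = 1e-8)
    expect_equal(eg$intercept$se, unname(or$se["(Intercept)"]),
                 tolerance = 1e-8)
  }
  expect_error(mr_egger(h[1:2, ]), "at least 3")
})

test_that("constraining the Egger intercept to zero reproduces the fixed-effects IVW slope", {
  h <- noisy_hset(seed = 13)
  or <- wls_oracle(data.frame(x = h$beta_exp), h$beta_out,
                   1 / h$se_out^2, intercept = FALSE)
  expect_equal(mr_ivw(h, "fixed")$beta, unname(or$coef["x"]), tolerance = 1e-10)
})

test_that("weighted median interpolates the cumulative-weight definition", {
  h <- make_hset(rep(1, 3), 0.01, c(1, 2, 9), rep(0.01, 3))
  # equalise weights: same beta_exp and se_out
  est <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(est$beta, 2)

  # weights (0.5, 0.25, 0.25) on ratios (1, 2, 3):
  # w = beta_exp^2/se_out^2, so beta_exp sqrt(2):1:1 at equal se
  bx <- c(sqrt(2), 1, 1) * 0.05
  h2 <- make_hset(bx, 0.01, bx * c(1, 2, 3), rep(0.01, 3))
  est2 <- mr_weighted_median(h2, n_boot = 50, seed = 1)
  expect_equal(est2$beta,
               weighted_median_oracle(c(1, 2, 3), c(0.5, 0.25, 0.25)))

  # randomised cases against the oracle
  for (seed in 1:10) {
    h3 <- noisy_hset(seed = seed)
    est3 <- mr_weighted_median(h3, n_boot = 50, seed = 1)
    expect_equal(est3$beta,
                 weighted_median_oracle(h3$beta_out / h3$beta_exp,
                                        h3$beta_exp^2 / h3$se_out^2))
  }
})

test_that("bootstrap SEs are deterministic under a seed and a seed is mandatory", {
  h <- noisy_hset()
  a <- mr_weighted_median(h, n_boot = 200, seed = 42)
  b <- mr_weighted_median(h, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
  expect_error(mr_weighted_median(h, n_boot = 10), "seed")
  m1 <- mr_weighted_mode(h, n_boot = 100, seed = 9)
  m2 <- mr_weighted_mode(h, n_boot = 100, seed = 9)
  expect_identical(m1$se, m2$se)
})

test_that("weighted mode sits in the majority cluster and ignores weight scaling", {
  # consensus
  h0 <- make_hset(rep(0.05, 4), 0.01, rep(0.05 * 0.3, 4), 0.01)
  expect_equal(mr_weighted_mode(h0, n_boot = 50, seed = 1)$beta, 0.3 * 0.05 / 0.05)

  # 5 ratios near 0.3 plus an outlier at 3.0 with comparable weights
  bx <- rep(0.05, 6)
  ratios <- c(0.28, 0.29, 0.3, 0.31, 0.32, 3.0)
  h <- make_hset(bx, 0.01, bx * ratios, rep(0.01, 6))
  est <- mr_weighted_mode(h, n_boot = 50, seed = 1)
  expect_gt(est$beta, 0.2)
  expect_lt(est$beta, 0.4)
  # grid oracle with the same rule-of-thumb bandwidth
  w <- bx^2 / 0.01^2
  s <- min(sd(ratios), mad(ratios))
  bw <- 0.9 * s * 6^(-1 / 5)
  expect_equal(est$beta, weighted_mode_oracle(ratios, w, bw), tolerance = 0.01)

  # doubling all weights leaves the estimate unchanged (scale by beta_exp
  # and outcome in proportion: w doubles, ratios unchanged)
  h2 <- make_hset(bx * sqrt(2), 0.01, bx * sqrt(2) * ratios, rep(0.01, 6))
  expect_equal(mr_weighted_mode(h2, n_boot = 50, seed = 1)$beta, est$beta)
})

test_that("Cochran's Q is zero for identical ratios, matches the two-term sum, and ignores order", {
  h0 <- make_hset(c(0.05, 0.1), 0.01, c(0.05, 0.1) * 0.4, c(0.01, 0.02))
  q0 <- cochrans_q(h0, mr_ivw(h0, "fixed"))
  expect_equal(q0$Q, 0, tolerance = 1e-20)
  expect_equal(q0$pvalue, 1)

  # equal weights, ratios 0 and 1, pooled 0.5: Q = 2 * w * 0.25 = w/2
  h1 <- make_hset(c(0.05, 0.05), 0.01, c(0, 0.05), c(0.01, 0.01))
  pooled <- mr_estimate("ivw_fixed", 0.5, 0.1, n_snp = 2)
  w <- 0.05^2 / 0.01^2
  expect_equal(cochrans_q(h1, pooled)$Q, w * 0.5)

  h2 <- noisy_hset()
  qa <- cochrans_q(h2, mr_ivw(h2, "fixed"))
  qb <- cochrans_q(h2[rev(seq_len(nrow(h2))), ], mr_ivw(h2, "fixed"))
  expect_equal(qa$Q, qb$Q)
  expect_error(cochrans_q(h2[1, ], pooled), "at least 2")
})

test_that("leave-one-out produces one estimate per omitted variant and isolates gross outliers", {
  # homogeneous: every LOO estimate equals the full estimate
  bx <- c(0.05, 0.1, 0.2, 0.15)
  h0 <- make_hset(bx, 0.01, bx * 0.3, c(0.01, 0.02, 0.03, 0.02))
  loo0 <- leave_one_out(h0)
  expect_equal(nrow(loo0), 4L)
  expect_true(all(abs(loo0$beta - mr_ivw(h0)$beta) < 1e-12))

  # one gross outlier: omitting it moves the estimate the most
  h1 <- noisy_hset(seed = 5)
  h1$beta_out[3] <- h1$beta_out[3] + 0.5
  loo1 <- leave_one_out(h1)
  full <- mr_ivw(h1)$beta
  shifts <- abs(loo1$beta - full)
  expect_equal(loo1$dropped[which.max(shifts)], h1$variant_id[3])
})

test_that("every estimator is sign-equivariant in the outcome effects", {
  h <- noisy_hset(seed = 21)
  hneg <- h; hneg$beta_out <- -h$beta_out
  expect_equal(mr_ivw(hneg)$beta, -mr_ivw(h)$beta)
  expect_equal(mr_ivw(hneg)$se, mr_ivw(h)$se)
  expect_equal(mr_ivw(hneg, "fixed")$se, mr_ivw(h, "fixed")$se)
  ea <- mr_egger(h); eb <- mr_egger(hneg)
  expect_equal(eb$slope$beta, -ea$slope$beta)
  expect_equal(eb$slope$se, ea$slope$se)
  expect_equal(eb$intercept$value, -ea$intercept$value)
  ma <- mr_weighted_median(h, n_boot = 100, seed = 3)
  mb <- mr_weighted_median(hneg, n_boot = 100, seed = 3)
  expect_equal(mb$beta, -ma$beta)
})

test_that("log-OR estimates convert to the published odds-ratio presentation", {
  e0 <- mr_estimate("ivw_random", 0, 0.01)
  expect_equal(unname(to_odds_ratio(e0)$display["or"]), 1.00)

  # atrial fibrillation: total effect 0.29 (0.19 to 0.39) -> OR 1.34 (1.21 to 1.48)
  af <- mr_estimate("ivw_random", 0.29, (0.39 - 0.19) / (2 * 1.96))
  expect_equal(unname(to_odds_ratio(af)$display),
               c(1.34, 1.21, 1.48))
  # aortic aneurysm: 0.38 (0.19 to 0.56) -> OR 1.46 (1.21 to 1.75)
  aa <- mr_estimate("ivw_random", 0.38, (0.56 - 0.19) / (2 * 1.96))
  expect_equal(unname(to_odds_ratio(aa)$display["or"]), 1.46)
})
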