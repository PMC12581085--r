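# Write a small synthetic study (one exposure, two outcomes, two mediators)
# to disk and return its study_config. Outcome/mediator 1 sit on a strong
# causal chain; outcome/mediator 2 are null.
write_small_study <- function(dir, seed = 123, null_total = FALSE) {
  cfg1 <- sim_config(seed = seed, n_snps = 60, n_med_snps = 60,
                     n_null_snps = 30,
                     theta_xm = if (null_total) 0 else 0.47,
                     theta_my = if (null_total) 0 else 0.29,
                     theta_xy_direct = if (null_total) 0 else 0.1537)
  tr1 <- simulate_triad(cfg1)
  cfg2 <- sim_config(seed = seed + 1, n_snps = 60, n_med_snps = 60,
                     n_null_snps = 30, theta_xm = 0, theta_my = 0,
                     theta_xy_direct = 0)
  tr2 <- simulate_triad(cfg2)

  paths <- list(
    exposure = file.path(dir, "exposure.tsv"),
    out1 = file.path(dir, "outcome1.tsv"), out2 = file.path(dir, "outcome2.tsv"),
    med1 = file.path(dir, "mediator1.tsv"), med2 = file.path(dir, "mediator2.tsv")
  )
  write_summary_stats(tr1$exposure, paths$exposure)
  write_summary_stats(tr1$outcome, paths$out1)
  write_summary_stats(tr2$outcome, paths$out2)
  write_summary_stats(tr1$mediator, paths$med1)
  write_summary_stats(tr2$mediator, paths$med2)

  list(cfg = study_config(
    exposure = list(name = "birth_weight", file = paths$exposure),
    outcomes = list(
      list(name = "outcome_strong", file = paths$out1, category = "other"),
      list(name = "outcome_null", file = paths$out2, category = "other")
    ),
    mediators = list(
      list(name = "mediator_strong", file = paths$med1,
           category = "body composition"),
      list(name = "mediator_null", file = paths$med2,
           category = "body composition")
    ),
    seed = 77
  ), truth = tr1$truth)
}

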