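#!/usr/bin/env Rscript

# Step 1: generate the synthetic study data.
#
# One exposure ("birth weight"), two binary outcomes and two continuous
# mediators, simulated as GWAS summary-statistic panels from a triad model
# with known causal structure: the strong arm carries total effect 0.29
# with 47% of it mediated (the atrial-fibrillation-like configuration);
# the null arm carries no causal effect at all. Tables are written under
# results/data/ together with the generating truth and a study
# configuration consumed by the later steps.

suppressPackageStartupMessages(library(mrmediate))

data_dir <- file.path("results", "data")
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

seed <- 20250101

cfg_strong <- sim_config(seed = seed, n_snps = 80, n_med_snps = 80,
                         n_null_snps = 40,
                         theta_xm = 0.47, theta_my = 0.29,
                         theta_xy_direct = 0.29 - 0.47 * 0.29)
cfg_null <- sim_config(seed = seed + 1, n_snps = 80, n_med_snps = 80,
                       n_null_snps = 40,
                       theta_xm = 0, theta_my = 0, theta_xy_direct = 0)

strong <- simulate_triad(cfg_strong)
null_arm <- simulate_triad(cfg_null)

write_summary_stats(strong$exposure, file.path(data_dir, "birth_weight.tsv"))
write_summary_stats(strong$outcome, file.path(data_dir, "outcome_af_like.tsv"))
write_summary_stats(strong$mediator, file.path(data_dir, "mediator_alm_like.tsv"))
write_summary_stats(null_arm$outcome, file.path(data_dir, "outcome_null.tsv"))
write_summary_stats(null_arm$mediator, file.path(data_dir, "mediator_null.tsv"))
write_truth(strong$truth, file.path(data_dir, "truth_strong.txt"))
write_truth(null_arm$truth, file.path(data_dir, "truth_null.txt"))

yaml::write_yaml(list(
  exposure = list(name = "birth_weight", file = "birth_weight.tsv",
                  unit = "SD"),
  outcomes = list(
    list(name = "outcome_af_like", file = "outcome_af_like.tsv",
         unit = "logOR", category = "arrhythmia"),
    list(name = "outcome_null", file = "outcome_null.tsv",
         unit = "logOR", category = "other")
  ),
  mediators = list(
    list(name = "mediator_alm_like", file = "mediator_alm_like.tsv",
         unit = "SD", category = "body composition"),
    list(name = "mediator_null", file = "mediator_null.tsv",
         unit = "SD", category = "other")
  ),
  seed = seed
), file.path(data_dir, "study.yaml"))

cat(sprintf("simulated study written to %s\n", data_dir))
cat(sprintf("  strong arm truth: total %.4f, indirect %.4f, proportion %.2f%%\n",
            strong$truth$true_total, strong$truth$true_indirect,
            100 * strong$truth$true_proportion))
cat(sprintf("  expected instrument F (exposure panel): %.1f\n",
            expected_instrument_f(cfg_strong)))
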