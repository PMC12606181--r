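#!/usr/bin/env Rscript
# Stage 6: ground-truth recovery across generator settings.
#
# Re-runs the full pipeline on cohorts with known planted structure --
# a strong familiarity contrast, a weak one, and the exchangeable null --
# and checks that each stage's estimate tracks its ground truth (reduced
# iteration counts; this is a sanity sweep, not the calibration study in
# the test suite).

suppressPackageStartupMessages(library(dyadseq))

configs <- list(
  strong = sim_config(seed = 301),
  weak = sim_config(adherence_stranger = 0.85, adherence_familiar = 0.75,
                    seed = 302),
  null = sim_config(escalation_mode = "homogeneous",
                    rate_pref = 0.05, rate_base = 0.05, rate_bonded = 0.05,
                    recur_moderate = 0.004, recur_high = 0.002, seed = 303)
)

rep <- recovery_suite(configs, n_iter_sequence_perm = 500,
                      n_iter_paired_perm = 2000,
                      chains = 2, iter = 3000, warmup = 1000)
rep$scenario <- names(configs)
print(rep, digits = 3)
write.csv(rep, "results/recovery_suite.csv", row.names = FALSE)

cat("\nreading the sweep:\n")
cat(" - strong/weak: the b_stranger CI should cover truth_log_odds and the\n")
cat("   paired test should reject (planted proximity preference)\n")
cat(" - null: permutation and paired p-values should be unremarkable and\n")
cat("   the CI should cover 0\n")
cat(" - caveat: when a stratum is observed with zero violations the\n")
cat("   familiarity contrast is quasi-separated and its posterior becomes\n")
cat("   diffuse and prior-driven; adherence settings near 1 invite this\n")
cat("wrote results/recovery_suite.csv\n")
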