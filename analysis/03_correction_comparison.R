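#!/usr/bin/env Rscript
# How does the below-LLQ substitution rule (none / M5 / M6 / M7) shape the
# posteriors recovered from synthetic data? Ten-point uniform schedule,
# additive noise SD 0.25, replicated with matched seeds across methods.

library(ocupkpd)
dir.create("results", showWarnings = FALSE)

cfg <- experiment_config(sigma_n = 0.25, n_replicates = 3, n_chains = 24,
                         n_iterations = 2000, seed = 5)
rep <- run_correction_comparison(cfg)

tab <- data.frame(method = names(rep$rmse),
                  rmse_rel_posterior_mean = as.numeric(rep$rmse),
                  kd_overlap_vs_none = as.numeric(rep$kd_overlap))
write.csv(tab, "results/correction_comparison.csv", row.names = FALSE)
print(tab)
cat(sprintf("Failures: %d\n", rep$n_failures))
cat("Zero-substitution (M7) should track the uncorrected reference most\n")
cat("closely, and the K_D posterior should be insensitive to the rule.\n")
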