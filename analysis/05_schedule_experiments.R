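#!/usr/bin/env Rscript
# Which part of the aqueous VEGF curve carries the information? Phase
# removal (P1 initial point, P2 suppression, P3 transition, P4 return to
# equilibrium) and transition-region data density (0/1/3/5 points), on
# low-noise synthetic data with the VEGF schedule varied and the antibody
# schedule held fixed. Observation SDs are fixed at the known generating
# value for these design studies.

library(ocupkpd)
dir.create("results", showWarnings = FALSE)

cfg <- experiment_config(sigma_n = 2.5e-3, n_replicates = 2,
                         n_chains = 20, n_iterations = 1200,
                         fix_sigma = TRUE, seed = 11)
rep <- run_schedule_experiments(cfg)

sds <- data.frame(kind = rownames(rep$posterior_sd), rep$posterior_sd,
                  row.names = NULL, check.names = FALSE)
write.csv(sds, "results/schedule_posterior_sds.csv", row.names = FALSE)
print(round(rep$posterior_sd[, c("kel_r", "kel_v", "kel_c", "kel_h")], 4))
cat(sprintf("Failures: %d\n", rep$n_failures))
cat("Expectation: removing the transition region (P3) hurts the\n")
cat("elimination-rate posteriors most; adding transition points\n")
cat("(N0 -> N5) progressively narrows them.\n")
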