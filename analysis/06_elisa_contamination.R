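#!/usr/bin/env Rscript
# Could the "free VEGF" ELISA be counting bound VEGF? Fit the adapted
# observation model mv = v + gamma*c + eta*h on base-model synthetic
# data, and profile the likelihood over gamma (eta = 0). On data with no
# contamination both fractions should concentrate at zero and the
# profile should fall as gamma rises.

library(ocupkpd)
dir.create("results", showWarnings = FALSE)

# low-noise regime: the contamination signature (bound VEGF is ~1 pM in
# the aqueous humor during suppression) must stand clear of the noise
ds <- generate_dataset(posterior_mean_params(), 2.5e-3,
                       make_schedule("uniform"), seed = 23)
ds <- list(vegf = apply_correction(ds$vegf, "M7"),
           ranibizumab = apply_correction(ds$ranibizumab, "M7"))

cfg <- experiment_config(sigma_n = 2.5e-3, n_chains = 24,
                         n_iterations = 1500, seed = 29,
                         priors = default_priors("adapted"))
fit <- fit_dataset(ds$vegf, ds$ranibizumab, correction = "none",
                   model_variant = "adapted", config = cfg,
                   n_predictive = 200)
s <- fit$summary
write.csv(s, "results/adapted_posterior_summary.csv", row.names = FALSE)
ge <- s[s$param %in% c("gamma", "eta"), ]
print(ge[, c("param", "mean", "sd", "skew", "q50")])
cat("Positive skew with mass near zero indicates no detectable\n")
cat("contamination of the free-VEGF measurement.\n")

prof <- profile_likelihood_gamma(ds, gamma_grid = seq(0, 1, 0.25),
                                 n_starts = 2, maxit = 250, seed = 31)
write.csv(prof, "results/profile_likelihood_gamma.csv", row.names = FALSE)
print(prof)
cat(sprintf("Profile argmax at gamma = %.2f\n",
            prof$gamma[which.max(prof$log_profile)]))
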