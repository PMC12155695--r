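# shared fixtures: the posterior-mean reference parameter set and a
# handful of cheap builders used across test files

theta_ref_params <- function() posterior_mean_params()

theta_ref_vec <- function(sigma = 0.25) {
  p <- posterior_mean_params()
  c(kel_r = p$kel_r, kel_v = p$kel_v, kel_c = p$kel_c, kel_h = p$kel_h,
    k_off = p$k_off, K_D = p$K_D, CL = p$CL, V_in = p$V_in,
    sigma_v = sigma, sigma_r = sigma)
}

# a small synthetic dataset at the reference parameters
make_test_dataset <- function(sigma_n = 0.25, seed = 42,
                              schedule = make_schedule("uniform"),
                              correction = "none") {
  ds <- generate_dataset(posterior_mean_params(), sigma_n, schedule,
                         seed = seed)
  if (correction != "none") {
    ds <- list(vegf = apply_correction(ds$vegf, correction),
               ranibizumab = apply_correction(ds$ranibizumab, correction))
  }
  ds
}

# build a chain_set from an [iteration, chain, parameter] array (for
# tests that need posterior containers without running the sampler)
fake_chain_set <- function(draws, params, burn_in = 0) {
  structure(list(draws = draws, log_post = NULL, params = params,
                 n_chains = dim(draws)[2], n_iterations = dim(draws)[1],
                 burn_in = burn_in, seed = 0, acceptance_rate = NA_real_),
            class = "chain_set")
}

fake_chain_set_from_matrix <- function(m, params, n_chains = 4) {
  n <- nrow(m)
  stopifnot(n %% n_chains == 0)
  draws <- array(NA_real_, c(n / n_chains, n_chains, ncol(m)),
                 dimnames = list(NULL, NULL, params))
  for (j in seq_len(ncol(m)))
    draws[, , j] <- matrix(m[, j], n / n_chains, n_chains)
  fake_chain_set(draws, params)
}
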