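#' Configuration for a synthetic-data inference experiment
#'
#' Collects the reference parameter set, the noise and schedule of the
#' synthetic protocol, the correction methods under comparison, and the
#' sampler settings. Per-replicate dataset seeds are derived as
#' `seed + replicate`, and the sampler seed for replicate `r` is
#' `seed + 1000 + r`, identical across correction methods and schedules so
#' comparisons are matched.
#'
#' @param theta_ref reference [ocular_params()] used to generate data.
#' @param sigma_n additive noise SD (per-series units; see
#'   [generate_dataset()]).
#' @param schedule a `schedule` (default 10 uniform points over 9 weeks).
#' @param correction_methods subset of `c("none","M5","M6","M7")`.
#' @param n_replicates replicate datasets per condition.
#' @param n_chains,n_iterations,burn_in,init_strategy DEMCMC settings; the
#'   experiment default initialization is the Laplace approximation (see
#'   [demcmc_sample()]), which reaches stationarity within desk-scale
#'   iteration budgets.
#' @param seed base seed (mandatory for reproducibility).
#' @param dose_mg injected dose, mg.
#' @param mc a [molecular_constants()] object.
#' @param priors a base-model [prior_spec()].
#' @param fix_sigma treat the observation-noise SDs as known constants
#'   equal to the generating `sigma_n` instead of inferring them. Used by
#'   the low-noise schedule design studies, where the near-degenerate noise
#'   posterior is irrelevant to the question and severely slows sampler
#'   convergence.
#' @param solver_opts solver settings for the likelihood evaluations; the
#'   experiment default relaxes `rtol` to 1e-6, which keeps the model error
#'   orders of magnitude below the smallest observation noise used in any
#'   experiment while roughly halving the cost of a likelihood call.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(theta_ref = posterior_mean_params(),
                              sigma_n = 0.25,
                              schedule = make_schedule("uniform"),
                              correction_methods = c("none", "M5", "M6",
                                                     "M7"),
                              n_replicates = 10, n_chains = 20,
                              n_iterations = 2500, burn_in = 0.5,
                              init_strategy = "laplace",
                              transform = "log", fix_sigma = FALSE,
                              seed = 1, dose_mg = 0.5,
                              mc = molecular_constants(),
                              priors = default_priors("base"),
                              solver_opts = list(rtol = 1e-6,
                                                 atol = 1e-10)) {
  stopifnot(n_replicates >= 1, !missing(seed) || !is.null(seed))
  structure(list(theta_ref = theta_ref, sigma_n = sigma_n,
                 schedule = schedule,
                 correction_methods = correction_methods,
                 n_replicates = n_replicates, n_chains = n_chains,
                 n_iterations = n_iterations, burn_in = burn_in,
                 init_strategy = init_strategy, transform = transform,
                 fix_sigma = fix_sigma,
                 seed = seed, dose_mg = dose_mg, mc = mc, priors = priors,
                 solver_opts = solver_opts),
            class = "experiment_config")
}

# reference values of the 10 free parameters implied by a config
theta_ref_vector <- function(config) {
  p <- config$theta_ref
  sn <- if (inherits(config$sigma_n, "noise_params"))
    c(config$sigma_n$sigma_v, config$sigma_n$sigma_r)
  else rep(config$sigma_n, 2)
  c(kel_r = p$kel_r, kel_v = p$kel_v, kel_c = p$kel_c, kel_h = p$kel_h,
    k_off = p$k_off, K_D = p$K_D, CL = p$CL, V_in = p$V_in,
    sigma_v = sn[1], sigma_r = sn[2])
}

run_one_inference <- function(data, config, sampler_seed) {
  priors <- config$priors
  fixed_sigma <- NULL
  if (isTRUE(config$fix_sigma)) {
    ref <- theta_ref_vector(config)
    fixed_sigma <- unname(ref[c("sigma_v", "sigma_r")])
    priors <- priors[!priors$param %in% c("sigma_v", "sigma_r"), ]
    class(priors) <- c("prior_spec", "data.frame")
  }
  lp <- make_log_posterior(data, priors, dose_mg = config$dose_mg,
                           mc = config$mc,
                           V_vit = config$theta_ref$V_vit,
                           V_aq = config$theta_ref$V_aq,
                           solver_opts = config$solver_opts,
                           fixed_sigma = fixed_sigma)
  demcmc_sample(lp, priors, n_chains = config$n_chains,
                n_iterations = config$n_iterations, seed = sampler_seed,
                init_strategy = config$init_strategy,
                transform = config$transform,
                burn_in = config$burn_in)
}

#' Compare below-LLQ correction techniques on synthetic data
#'
#' Generates `n_replicates` synthetic datasets at the reference parameters,
#' applies each correction method to each dataset, runs the DEMCMC
#' inference per replicate per method (matched sampler seeds), and
#' aggregates: replicate-averaged max-normalized posteriors per method, the
#' root-mean-square relative error of the posterior means to the reference
#' values, and the overlap of each method's dissociation-constant posterior
#' with the uncorrected reference posterior.
#'
#' @param config an [experiment_config()].
#' @return List of class `correction_report`: `rmse` (named per method),
#'   `avg_posteriors` (per method), `kd_overlap` (vs `"none"`),
#'   `summaries`, `n_failures`, `config`.
#' @export
run_correction_comparison <- function(config) {
  methods <- config$correction_methods
  chains <- stats::setNames(
    replicate(length(methods), list(), simplify = FALSE), methods)
  n_fail <- 0
  for (r in seq_len(config$n_replicates)) {
    ds <- generate_dataset(config$theta_ref, config$sigma_n,
                           config$schedule, config$dose_mg, config$mc,
                           seed = config$seed + r)
    for (m in methods) {
      cd <- list(vegf = apply_correction(ds$vegf, m),
                 ranibizumab = apply_correction(ds$ranibizumab, m))
      cs <- tryCatch(
        run_one_inference(cd, config, config$seed + 1000 + r),
        error = function(e) {
          warning("replicate ", r, " method ", m, " failed: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(cs)) n_fail <- n_fail + 1 else
        chains[[m]][[length(chains[[m]]) + 1]] <- cs
    }
  }
  ref <- theta_ref_vector(config)
  rmse <- vapply(methods, function(m) {
    if (length(chains[[m]]) == 0) return(NA_real_)
    errs <- vapply(chains[[m]], function(cs) {
      s <- summarize_posterior(cs)
      mean(((s$mean - ref[s$param]) / ref[s$param])^2)
    }, numeric(1))
    sqrt(mean(errs))
  }, numeric(1))
  avg <- lapply(chains, function(cl)
    if (length(cl) > 0) average_posteriors(cl) else NULL)
  kd_overlap <- rep(NA_real_, length(methods))
  names(kd_overlap) <- methods
  if ("none" %in% methods && !is.null(avg[["none"]])) {
    ref_kd <- avg[["none"]]$K_D
    for (m in methods) {
      if (is.null(avg[[m]])) next
      # common grid: re-evaluate both on the union range
      kd_overlap[m] <- overlap_on_common_grid(ref_kd, avg[[m]]$K_D)
    }
  }
  summaries <- lapply(chains, function(cl) lapply(cl, summarize_posterior))
  structure(list(rmse = rmse, avg_posteriors = avg,
                 kd_overlap = kd_overlap, summaries = summaries,
                 chains = chains, n_failures = n_fail, config = config),
            class = "correction_report")
}

# overlap of two max-normalized densities given on their own grids
overlap_on_common_grid <- function(a, b) {
  lo <- min(a$x[1], b$x[1]); hi <- max(max(a$x), max(b$x))
  grid <- seq(lo, hi, length.out = 512)
  fa <- stats::approx(a$x, a$y, xout = grid, yleft = 0, yright = 0)$y
  fb <- stats::approx(b$x, b$y, xout = grid, yleft = 0, yright = 0)$y
  overlap_coefficient(grid, fa, fb)
}

#' Sampling-schedule experiments
#'
#' Runs the phase-removal and transition-density experiments: for each
#' schedule variant, `n_replicates` synthetic datasets (matched dataset and
#' sampler seeds across variants) are generated and fitted, and the
#' posterior SDs and replicate-averaged posteriors aggregated. These
#' experiments are run in the low-noise regime (`sigma_n = 2.5e-3`) in
#' which schedule effects are isolated from observation noise. The phases
#' are features of the aqueous VEGF profile, so the schedule variants
#' alter the VEGF sampling only; the antibody series keeps the full base
#' schedule throughout. Schedule variants that resolve to identical
#' sampling times (transition density N0 coincides with removing the whole
#' transition region) are fitted once and shared.
#'
#' @param config an [experiment_config()]; its `sigma_n` should be the
#'   low-noise value (the default config is not modified here).
#' @param kinds schedule kinds to compare.
#' @param horizon_days schedule/simulation horizon.
#' @param correction below-LLQ correction applied to every generated
#'   dataset (`"none"` mirrors the raw synthetic protocol).
#' @return List of class `schedule_report`: `posterior_sd` (matrix
#'   kind x parameter, replicate-averaged), `avg_posteriors`, `summaries`,
#'   `n_failures`, `config`.
#' @export
run_schedule_experiments <- function(config,
                                     kinds = c("uniform",
                                               "phase_removed:P1",
                                               "phase_removed:P2",
                                               "phase_removed:P3",
                                               "phase_removed:P4",
                                               "phase_removed:P1P4",
                                               "transition_density:N0",
                                               "transition_density:N1",
                                               "transition_density:N3",
                                               "transition_density:N5"),
                                     horizon_days = 63,
                                     correction = "none") {
  ref_traj <- simulate_model(config$theta_ref, config$dose_mg, config$mc,
                             t_grid = seq(0, horizon_days, by = 0.1))
  base <- make_schedule("uniform", horizon_days = horizon_days)
  scheds <- lapply(kinds, make_schedule, horizon_days = horizon_days,
                   reference_traj = ref_traj)
  names(scheds) <- kinds
  keys <- vapply(scheds, function(s)
    paste(signif(s$times, 10), collapse = ","), character(1))
  chains <- stats::setNames(
    replicate(length(kinds), list(), simplify = FALSE), kinds)
  n_fail <- 0
  done <- list() # schedule key -> chain list, shared across aliases
  for (kind in kinds) {
    if (!is.null(done[[keys[kind]]])) {
      chains[[kind]] <- done[[keys[kind]]]
      next
    }
    for (r in seq_len(config$n_replicates)) {
      ds <- generate_dataset(config$theta_ref, config$sigma_n,
                             list(vegf = scheds[[kind]],
                                  ranibizumab = base),
                             config$dose_mg, config$mc,
                             seed = config$seed + r)
      ds <- list(vegf = apply_correction(ds$vegf, correction),
                 ranibizumab = apply_correction(ds$ranibizumab,
                                                correction))
      cs <- tryCatch(
        run_one_inference(ds, config, config$seed + 1000 + r),
        error = function(e) {
          warning("schedule ", kind, " replicate ", r, " failed: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(cs)) n_fail <- n_fail + 1 else
        chains[[kind]][[length(chains[[kind]]) + 1]] <- cs
    }
    done[[keys[kind]]] <- chains[[kind]]
  }
  params <- config$priors$param
  for (kind in kinds) {
    if (length(chains[[kind]]) > 0) {
      params <- chains[[kind]][[1]]$params
      break
    }
  }
  sds <- matrix(NA_real_, length(kinds), length(params),
                dimnames = list(kinds, params))
  summaries <- lapply(chains, function(cl) lapply(cl, summarize_posterior))
  for (kind in kinds) {
    if (length(summaries[[kind]]) == 0) next
    sd_mat <- vapply(summaries[[kind]], function(s) s$sd,
                     numeric(length(params)))
    sds[kind, ] <- rowMeans(sd_mat)
  }
  avg <- lapply(chains, function(cl)
    if (length(cl) > 0) average_posteriors(cl) else NULL)
  structure(list(posterior_sd = sds, avg_posteriors = avg,
                 summaries = summaries, chains = chains,
                 n_failures = n_fail, config = config),
            class = "schedule_report")
}

#' Full inference pipeline on an observation dataset
#'
#' Correct the series, run the DEMCMC inference, summarize, compute
#' posterior-predictive bands and the clearance--production regression.
#' Series can be passed as `observation_series` objects or CSV paths in the
#' canonical dialect. Convergence is reported per parameter against the
#' gate R-hat < 1.05.
#'
#' @param vegf,ranibizumab [observation_series()] or CSV paths.
#' @param correction correction method to apply (`"none"` to use as-is).
#' @param model_variant `"base"` or `"adapted"` (adds `gamma`, `eta`).
#' @param config an [experiment_config()] providing sampler settings,
#'   priors, dose and constants; its priors must match the variant.
#' @param n_predictive posterior-predictive draws.
#' @param t_grid predictive evaluation grid.
#' @return List of class `ocular_fit`: `chains`, `summary` (with a
#'   `converged` column), `predictive`, `regression`, `correction`,
#'   `variant`.
#' @export
fit_dataset <- function(vegf, ranibizumab, correction = "M7",
                        model_variant = c("base", "adapted"),
                        config = experiment_config(),
                        n_predictive = 1000,
                        t_grid = seq(0, 63, by = 0.5)) {
  model_variant <- match.arg(model_variant)
  if (is.character(vegf)) vegf <- read_series_csv(vegf)
  if (is.character(ranibizumab)) ranibizumab <- read_series_csv(ranibizumab)
  if (vegf$species[1] != "VEGF" || ranibizumab$species[1] != "ranibizumab")
    stop("series species labels do not match the expected inputs")
  if (correction != "none" || all(vegf$correction == "none")) {
    if (all(vegf$correction == "none"))
      vegf <- apply_correction(vegf, correction)
    if (all(ranibizumab$correction == "none"))
      ranibizumab <- apply_correction(ranibizumab, correction)
  }
  data <- list(vegf = vegf, ranibizumab = ranibizumab)
  priors <- config$priors
  if (model_variant == "adapted" && !"gamma" %in% priors$param)
    priors <- default_priors("adapted")
  fixed_sigma <- NULL
  if (isTRUE(config$fix_sigma) && model_variant == "base") {
    ref <- theta_ref_vector(config)
    fixed_sigma <- unname(ref[c("sigma_v", "sigma_r")])
    priors <- priors[!priors$param %in% c("sigma_v", "sigma_r"), ]
    class(priors) <- c("prior_spec", "data.frame")
  }
  lp <- make_log_posterior(data, priors, dose_mg = config$dose_mg,
                           mc = config$mc, model_variant = model_variant,
                           V_vit = config$theta_ref$V_vit,
                           V_aq = config$theta_ref$V_aq,
                           solver_opts = config$solver_opts,
                           fixed_sigma = fixed_sigma)
  chains <- demcmc_sample(lp, priors, n_chains = config$n_chains,
                          n_iterations = config$n_iterations,
                          seed = config$seed,
                          init_strategy = config$init_strategy,
                          transform = config$transform,
                          burn_in = config$burn_in)
  summ <- summarize_posterior(chains)
  summ$converged <- summ$rhat < 1.05
  n_pred <- min(n_predictive,
                nrow(pooled_draws(chains)))
  pred <- posterior_predictive(chains, n_draws = n_pred,
                               dose_mg = config$dose_mg, mc = config$mc,
                               t_grid = t_grid,
                               V_vit = config$theta_ref$V_vit,
                               V_aq = config$theta_ref$V_aq)
  reg <- regress_cl_vin(chains,
                        n_samples = min(1000, nrow(pooled_draws(chains))))
  structure(list(chains = chains, summary = summ, predictive = pred,
                 regression = reg, correction = correction,
                 variant = model_variant),
            class = "ocular_fit")
}

#' VEGF recovery time as a function of antibody hydrodynamic radius
#'
#' For a hypothetical anti-VEGF antibody of hydrodynamic radius `R_h` with
#' ranibizumab-like binding kinetics: the radius is inverted to a molecular
#' weight, the elimination rates of the antibody and of both complexes are
#' rescaled from the reference antibody rate by cube-root molecular-weight
#' scaling (the antibody weight replacing the reference weight in the
#' complex weights), the model is simulated, and the VEGF relaxation time
#' (PM2) extracted.
#'
#' @param params reference [ocular_params()] (its `kel_r` anchors the
#'   scaling; `kel_v` and all non-elimination parameters are reused).
#' @param mc a [molecular_constants()] object (reference weights).
#' @param radius_grid ascending hydrodynamic radii, nm.
#' @param dose_mg injected dose, mg.
#' @param horizon_days simulation horizon (long enough for recovery at the
#'   largest radius).
#' @param dt trajectory grid spacing, days.
#' @param f1,f2 [pk_metrics()] thresholds.
#' @return Data frame: `R_h_nm`, `MW`, `pm2_days`, `reached`.
#' @export
recovery_time_vs_radius <- function(params, mc = molecular_constants(),
                                    radius_grid = seq(2.0, 6.0, by = 0.25),
                                    dose_mg = 0.5, horizon_days = 210,
                                    dt = 0.25, f1 = 0.10, f2 = 0.90) {
  if (any(radius_grid <= 0) || any(diff(radius_grid) <= 0))
    stop("'radius_grid' must be positive and ascending")
  t_grid <- seq(0, horizon_days, by = dt)
  out <- data.frame(R_h_nm = radius_grid, MW = NA_real_,
                    pm2_days = NA_real_, reached = FALSE)
  for (i in seq_along(radius_grid)) {
    p <- radius_sweep_params(params, mc, radius_grid[i])
    pm <- tryCatch({
      traj <- simulate_model(p$params, dose_mg,
                             molecular_constants(MW_R = p$MW,
                                                 MW_V = mc$MW_V,
                                                 nu = mc$nu, N_A = mc$N_A),
                             t_grid = t_grid)
      pk_metrics(traj, p$params, f1 = f1, f2 = f2)
    }, error = function(e) NULL)
    out$MW[i] <- p$MW
    if (!is.null(pm) && pm$pm2_reached) {
      out$pm2_days[i] <- pm$pm2
      out$reached[i] <- TRUE
    }
  }
  out
}

#' Parameter set for a hypothetical antibody of given hydrodynamic radius
#'
#' @param params reference [ocular_params()].
#' @param mc reference [molecular_constants()].
#' @param R_h_nm antibody hydrodynamic radius, nm.
#' @return List with the rescaled `params` and the implied antibody `MW`.
#' @export
radius_sweep_params <- function(params, mc, R_h_nm) {
  MW_A <- mw_from_radius(R_h_nm, mc)
  kel_a <- scale_elimination_rate(params$kel_r, mc$MW_R, MW_A)
  kel_c <- scale_elimination_rate(params$kel_r, mc$MW_R, mc$MW_V + MW_A)
  kel_h <- scale_elimination_rate(params$kel_r, mc$MW_R,
                                  mc$MW_V + 2 * MW_A)
  p <- ocular_params(kel_r = kel_a, kel_v = params$kel_v, kel_c = kel_c,
                     kel_h = kel_h, k_off = params$k_off, K_D = params$K_D,
                     CL = params$CL, V_in = params$V_in,
                     V_vit = params$V_vit, V_aq = params$V_aq)
  list(params = p, MW = MW_A)
}
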