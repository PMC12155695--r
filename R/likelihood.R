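# lean solver for the inference hot path: returns the deSolve matrix
# (time + 8 species columns) or NULL on integration failure; all input
# checking is assumed done by the caller
solve_raw <- function(pv, y0, times, rtol = 1e-8, atol = 1e-10) {
  out <- tryCatch(
    suppressWarnings(
      deSolve::lsoda(y0, times, func = "ocular_derivs", parms = pv,
                     dllname = "ocupkpd", initfunc = "ocular_init",
                     rtol = rtol, atol = atol)),
    error = function(e) NULL)
  if (is.null(out) || nrow(out) < length(times) || anyNA(out)) return(NULL)
  out
}

# initial-condition vector for a free-parameter vector th (prior order)
# and a precomputed dose concentration increment (pM)
y0_from_theta <- function(th, dose_pM, V_vit) {
  c(th[8] / (th[2] * V_vit), dose_pM, 0, 0, th[8] / th[7], 0, 0, 0)
}

#' Gaussian observation log-likelihood of an aqueous humor dataset
#'
#' Simulates the model at `theta` and scores the two observation series with
#' independent additive Gaussian errors on each series' own observation
#' unit: VEGF residuals in pM against aqueous free VEGF (base variant) or
#' the adapted ELISA observation `v_aq + gamma c_aq + eta h_aq` (adapted
#' variant), with SD `sigma_v`; antibody residuals in uM against aqueous
#' antibody with SD `sigma_r`. Working on the linear concentration scale
#' makes zero-substituted (M7) censored points ordinary observations of 0;
#' points removed by M6 are simply absent from the sum.
#'
#' @param theta free-parameter vector in prior order (`kel_r, kel_v, kel_c,
#'   kel_h, k_off, K_D, CL, V_in, sigma_v, sigma_r`, plus `gamma`, `eta` for
#'   the adapted variant).
#' @param data list with `vegf` and `ranibizumab` [observation_series()]
#'   (already corrected, or uncorrected).
#' @param dose_mg injected dose, mg.
#' @param mc a [molecular_constants()] object.
#' @param model_variant `"base"` or `"adapted"`.
#' @param V_vit,V_aq fixed compartment volumes, mL.
#' @param solver_opts passed to [simulate_model()].
#' @param fixed_sigma optional length-2 vector `(sigma_v, sigma_r)`; when
#'   supplied the noise SDs are treated as known constants and `theta`
#'   carries only the 8 kinetic parameters (used by design studies where
#'   the synthetic noise level is known).
#' @return Log-likelihood; `-Inf` (with a warning) if the solver fails or
#'   `theta` is not a valid parameter set.
#' @export
log_likelihood <- function(theta, data, dose_mg = 0.5,
                           mc = molecular_constants(),
                           model_variant = c("base", "adapted"),
                           V_vit = 2.0, V_aq = 0.105,
                           solver_opts = list(), fixed_sigma = NULL) {
  model_variant <- match.arg(model_variant)
  fn <- make_log_likelihood(data, dose_mg = dose_mg, mc = mc,
                            model_variant = model_variant,
                            V_vit = V_vit, V_aq = V_aq,
                            solver_opts = solver_opts,
                            fixed_sigma = fixed_sigma)
  fn(theta)
}

# closure form of the likelihood with observation indices, initial dose
# and solver settings resolved once; this is the MCMC hot path
make_log_likelihood <- function(data, dose_mg = 0.5,
                                mc = molecular_constants(),
                                model_variant = "base",
                                V_vit = 2.0, V_aq = 0.105,
                                solver_opts = list(),
                                fixed_sigma = NULL) {
  if (!is.null(fixed_sigma) && !identical(model_variant, "base"))
    stop("'fixed_sigma' is only supported for the base variant")
  times <- sort(unique(c(0, data$vegf$time_days,
                         data$ranibizumab$time_days)))
  iv <- match(data$vegf$time_days, times)
  ir <- match(data$ranibizumab$time_days, times)
  obs_v <- data$vegf$value
  obs_r <- data$ranibizumab$value
  dose_pM <- dose_mg * 1e-3 / mc$MW_R / (V_vit * 1e-3) * 1e12
  opts <- utils::modifyList(list(rtol = 1e-8, atol = 1e-10), solver_opts)
  adapted <- identical(model_variant, "adapted")
  function(theta) {
    th <- unname(theta)
    if (adapted && length(th) < 12)
      stop("adapted variant needs gamma and eta in 'theta'")
    if (!is.null(fixed_sigma)) th <- c(th[1:8], fixed_sigma)
    if (any(!is.finite(th[1:10])) || any(th[c(1:7, 9, 10)] <= 0) ||
        th[8] < 0)
      return(-Inf)
    pv <- c(th[1:4], th[5] / th[6], th[5], th[7], th[8], V_vit, V_aq)
    out <- solve_raw(pv, y0_from_theta(th, dose_pM, V_vit), times,
                     rtol = opts$rtol, atol = opts$atol)
    if (is.null(out)) {
      warning("solver failure in likelihood; treating as zero likelihood",
              call. = FALSE)
      return(-Inf)
    }
    pred_v <- if (adapted) {
      if (th[11] < 0 || th[11] > 1 || th[12] < 0 || th[12] > 1)
        return(-Inf)
      out[iv, 6] + th[11] * out[iv, 8] + th[12] * out[iv, 9]
    } else {
      out[iv, 6]
    }
    sum(stats::dnorm(obs_v, pred_v, th[9], log = TRUE)) +
      sum(stats::dnorm(obs_r, out[ir, 7] * 1e-6, th[10], log = TRUE))
  }
}

#' Log posterior (unnormalized) for the aqueous humor dataset
#'
#' Convenience composition `log_prior(theta) + log_likelihood(theta)`; the
#' likelihood is skipped when the prior is `-Inf`, so the ODE is never
#' solved for out-of-bounds proposals.
#'
#' @inheritParams log_likelihood
#' @param priors a [prior_spec()].
#' @return A function `theta -> log posterior` suitable for
#'   [demcmc_sample()].
#' @export
make_log_posterior <- function(data, priors, dose_mg = 0.5,
                               mc = molecular_constants(),
                               model_variant = c("base", "adapted"),
                               V_vit = 2.0, V_aq = 0.105,
                               solver_opts = list(), fixed_sigma = NULL) {
  model_variant <- match.arg(model_variant)
  if (!is.null(fixed_sigma) && any(c("sigma_v", "sigma_r") %in%
                                     priors$param))
    stop("priors must not include the noise SDs when 'fixed_sigma' is set")
  ll_fn <- make_log_likelihood(data, dose_mg = dose_mg, mc = mc,
                               model_variant = model_variant,
                               V_vit = V_vit, V_aq = V_aq,
                               solver_opts = solver_opts,
                               fixed_sigma = fixed_sigma)
  # truncated-normal normalization constants are theta-independent
  log_z <- sum(log(stats::pnorm(priors$upper, priors$mean, priors$sd) -
                     stats::pnorm(priors$lower, priors$mean, priors$sd)))
  m <- priors$mean; s <- priors$sd
  lo <- priors$lower; hi <- priors$upper
  function(theta) {
    th <- theta_in_order(theta, priors)
    if (any(th < lo) || any(th > hi)) return(-Inf)
    lp <- sum(stats::dnorm(th, m, s, log = TRUE)) - log_z
    ll <- ll_fn(th)
    if (!is.finite(ll)) return(-Inf)
    lp + ll
  }
}
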