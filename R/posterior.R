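#' Posterior-predictive trajectory bands
#'
#' Simulates the model at each of the final `n_draws` posterior parameter
#' sets and returns the pointwise mean and SD of every species in both
#' compartments (8 bands). Draws at which the solver fails are dropped with
#' a warning and counted.
#'
#' @param chains a `chain_set` whose parameters start with the 8 kinetic
#'   parameters in canonical order.
#' @param n_draws number of parameter sets from the end of the run
#'   (default 1000).
#' @param dose_mg injected dose, mg.
#' @param mc a [molecular_constants()] object.
#' @param t_grid evaluation grid, days.
#' @param V_vit,V_aq fixed volumes, mL.
#' @param solver_opts passed to [simulate_model()].
#' @return List with `t_grid`, matrices `mean` and `sd`
#'   (`length(t_grid) x 8`, columns named by species), `n_used`,
#'   `n_dropped`.
#' @export
posterior_predictive <- function(chains, n_draws = 1000, dose_mg = 0.5,
                                 mc = molecular_constants(),
                                 t_grid = seq(0, 63, by = 0.5),
                                 V_vit = 2.0, V_aq = 0.105,
                                 solver_opts = list()) {
  pool <- pooled_draws(chains)
  if (n_draws > nrow(pool))
    stop("'n_draws' exceeds available post-burn-in draws")
  pool <- pool[seq.int(nrow(pool) - n_draws + 1, nrow(pool)), ,
               drop = FALSE]
  nt <- length(t_grid)
  s1 <- matrix(0, nt, 8); s2 <- matrix(0, nt, 8)
  used <- 0; dropped <- 0
  for (i in seq_len(nrow(pool))) {
    th <- pool[i, ]
    params <- tryCatch(
      ocular_params(kel_r = th[["kel_r"]], kel_v = th[["kel_v"]],
                    kel_c = th[["kel_c"]], kel_h = th[["kel_h"]],
                    k_off = th[["k_off"]], K_D = th[["K_D"]],
                    CL = th[["CL"]], V_in = th[["V_in"]],
                    V_vit = V_vit, V_aq = V_aq),
      error = function(e) NULL)
    traj <- if (is.null(params)) NULL else tryCatch(
      simulate_model(params, dose_mg, mc, t_grid = t_grid,
                     solver_opts = solver_opts),
      error = function(e) NULL)
    if (is.null(traj)) { dropped <- dropped + 1; next }
    m <- as.matrix(traj[STATE_NAMES])
    s1 <- s1 + m
    s2 <- s2 + m^2
    used <- used + 1
  }
  if (dropped > 0)
    warning(dropped, " posterior draw(s) dropped due to solver failure")
  if (used == 0) stop("no posterior draw could be simulated")
  mu <- s1 / used
  va <- s2 / used - mu^2
  va[va < 0] <- 0
  colnames(mu) <- colnames(va) <- STATE_NAMES
  list(t_grid = t_grid, mean = mu, sd = sqrt(va),
       n_used = used, n_dropped = dropped)
}

#' Profile likelihood over the ELISA contamination fraction gamma
#'
#' Fixes the singly-bound capture fraction `gamma` at each grid value (with
#' `eta = 0`), maximizes the adapted-model log posterior over the remaining
#' 10 free parameters, and returns the profile. The inner optimization is
#' multi-start bounded quasi-Newton (L-BFGS-B) seeded from the supplied
#' starting point (typically the base-model fit), prior draws, and - as the
#' grid is traversed in ascending order - the previous grid point's
#' optimum, which makes the profile smooth in practice.
#'
#' @param data list with `vegf` and `ranibizumab` [observation_series()].
#' @param gamma_grid values of `gamma` in `[0, 1]`.
#' @param dose_mg injected dose, mg.
#' @param mc a [molecular_constants()] object.
#' @param priors a base-model [prior_spec()] (10 parameters).
#' @param start optional starting vector (prior order); defaults to the
#'   prior means.
#' @param n_starts number of optimization starts per grid point.
#' @param seed RNG seed for the extra prior-draw starts.
#' @param maxit iteration cap per local optimization.
#' @return Data frame `gamma`, `log_profile` (maximized log posterior; `NA`
#'   where every start failed), `converged`.
#' @export
profile_likelihood_gamma <- function(data, gamma_grid = seq(0, 1, 0.2),
                                     dose_mg = 0.5,
                                     mc = molecular_constants(),
                                     priors = default_priors("base"),
                                     start = NULL, n_starts = 5, seed = 1,
                                     maxit = 300) {
  if (any(gamma_grid < 0 | gamma_grid > 1))
    stop("'gamma_grid' must lie in [0, 1]")
  set.seed(seed)
  d <- nrow(priors)
  if (is.null(start)) start <- priors$mean
  n_extra <- max(0, n_starts - 2)
  extra <- if (n_extra > 0) sample_prior(n_extra, priors) else
    matrix(numeric(0), 0, nrow(priors))
  eps <- 1e-9 * (priors$upper - priors$lower)
  lo <- pmax(priors$lower + eps, 1e-8)
  hi <- priors$upper - eps
  # the inner search runs on log coordinates so finite-difference steps
  # are scale-free across parameters spanning orders of magnitude
  lo_y <- log(lo); hi_y <- log(hi)
  ll_fn <- make_log_likelihood(data, dose_mg = dose_mg, mc = mc,
                               model_variant = "adapted")
  make_obj <- function(gam) {
    function(y) {
      th <- exp(y)
      lp <- log_prior(th, priors)
      if (!is.finite(lp)) return(1e10)
      ll <- ll_fn(c(th, gam, 0))
      if (!is.finite(ll)) return(1e10)
      -(lp + ll)
    }
  }
  polish <- function(obj, starts, maxit) {
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      fit <- tryCatch(
        stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                     lower = lo_y, upper = hi_y,
                     control = list(maxit = maxit)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) && fit$value < 1e9 &&
          (is.null(best) || fit$value < best$value))
        best <- fit
    }
    best
  }
  ord <- order(gamma_grid)
  res <- data.frame(gamma = gamma_grid, log_profile = NA_real_,
                    converged = FALSE)
  opts <- vector("list", length(gamma_grid))
  start_block <- log(pmin(pmax(start, lo), hi))
  if (nrow(extra) > 0) {
    clip <- pmin(pmax(extra, matrix(lo, nrow(extra), d, byrow = TRUE)),
                 matrix(hi, nrow(extra), d, byrow = TRUE))
    start_block <- rbind(start_block, log(clip))
  } else {
    start_block <- matrix(start_block, 1)
  }
  # ascending pass with warm starts from the previous grid point
  prev_opt <- NULL
  for (g in ord) {
    obj <- make_obj(gamma_grid[g])
    starts <- rbind(start_block, if (!is.null(prev_opt)) prev_opt)
    best <- polish(obj, starts, maxit)
    if (!is.null(best)) {
      res$log_profile[g] <- -best$value
      res$converged[g] <- TRUE
      opts[[g]] <- best$par
      prev_opt <- best$par
    }
  }
  # descending refinement pass: warm-start each point from its upper
  # neighbour so optimization quality is uniform along the grid (a
  # single ascending chain otherwise improves monotonically and can
  # tilt the profile)
  prev_opt <- NULL
  for (g in rev(ord)) {
    starts <- rbind(if (!is.null(opts[[g]])) opts[[g]],
                    if (!is.null(prev_opt)) prev_opt)
    if (is.null(starts)) next
    best <- polish(make_obj(gamma_grid[g]), starts, maxit)
    if (!is.null(best) &&
        (!res$converged[g] || -best$value > res$log_profile[g])) {
      res$log_profile[g] <- -best$value
      res$converged[g] <- TRUE
      opts[[g]] <- best$par
    }
    prev_opt <- opts[[g]]
  }
  res
}

#' Linear regression of VEGF production rate on clearance
#'
#' At steady state the pre-dose aqueous VEGF concentration ties production
#' to clearance (`v_aq* = V_in / CL`), so posterior draws of the pair lie
#' close to a line `V_in = lambda * CL - mu` whose slope estimates the
#' baseline aqueous VEGF. Ordinary least squares on the final `n_samples`
#' posterior draws.
#'
#' @param chains a `chain_set` containing parameters `CL` and `V_in`.
#' @param n_samples number of final draws to use (default 1000).
#' @return List of class `cl_vin_regression`: `lambda` (slope, pM), `mu`
#'   (negated intercept, pM mL/day), `r_squared`.
#' @export
regress_cl_vin <- function(chains, n_samples = 1000) {
  pool <- pooled_draws(chains)
  if (!all(c("CL", "V_in") %in% colnames(pool)))
    stop("chains must contain 'CL' and 'V_in'")
  if (n_samples > nrow(pool))
    stop("'n_samples' exceeds available post-burn-in draws")
  pool <- pool[seq.int(nrow(pool) - n_samples + 1, nrow(pool)), ]
  cl <- pool[, "CL"]; vin <- pool[, "V_in"]
  if (stats::var(cl) == 0) stop("zero variance in CL draws")
  fit <- stats::lm(vin ~ cl)
  structure(list(lambda = unname(stats::coef(fit)[2]),
                 mu = -unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared),
            class = "cl_vin_regression")
}

#' Replicate-averaged, maximum-normalized posterior densities
#'
#' For each parameter: a kernel density is estimated per replicate on a
#' shared grid spanning all replicates' draws, the densities are averaged
#' across replicates, and the average is normalized by its maximum (so the
#' peak is 1, the convention used to overlay posteriors from repeated
#' synthetic-data experiments).
#'
#' @param chain_sets list of `chain_set` objects with identical parameter
#'   vectors.
#' @param n_grid number of grid points per parameter.
#' @param burn_in burn-in fraction override.
#' @return List of class `averaged_posterior`: per parameter a list with
#'   `x` (grid) and `y` (max-normalized average density).
#' @export
average_posteriors <- function(chain_sets, n_grid = 512, burn_in = NULL) {
  if (length(chain_sets) < 1) stop("need at least one chain set")
  params <- chain_sets[[1]]$params
  for (cs in chain_sets)
    if (!identical(cs$params, params))
      stop("chain sets have incompatible parameter vectors")
  pools <- lapply(chain_sets, pooled_draws, burn_in = burn_in)
  out <- lapply(seq_along(params), function(j) {
    xs <- lapply(pools, function(p) p[, j])
    rng <- range(unlist(xs))
    if (diff(rng) == 0) rng <- rng + c(-1, 1) * max(1e-8, abs(rng[1]) * 1e-8)
    pad <- 0.05 * diff(rng)
    grid <- seq(rng[1] - pad, rng[2] + pad, length.out = n_grid)
    ys <- vapply(xs, function(x) {
      d <- stats::density(x, from = grid[1], to = grid[n_grid], n = n_grid)
      d$y
    }, numeric(n_grid))
    y <- rowMeans(ys)
    list(x = grid, y = y / max(y))
  })
  names(out) <- params
  class(out) <- "averaged_posterior"
  out
}

#' Overlap coefficient of two densities on a common grid
#'
#' Both curves are renormalized to integrate to 1, then
#' `OVL = integral of min(f, g)` is computed by the trapezoid rule; 1 means
#' identical distributions, 0 disjoint support.
#'
#' @param x common grid (increasing).
#' @param f,g non-negative density values on `x`.
#' @return Overlap coefficient in `[0, 1]`.
#' @export
overlap_coefficient <- function(x, f, g) {
  trap <- function(y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  f <- f / trap(f)
  g <- g / trap(g)
  trap(pmin(f, g))
}

#' Equal-tailed credible interval from pooled draws
#'
#' @param chains a `chain_set`.
#' @param param parameter name.
#' @param level interval mass (default 0.95).
#' @param burn_in burn-in fraction override.
#' @return Length-2 vector (lower, upper).
#' @export
credible_interval <- function(chains, param, level = 0.95,
                              burn_in = NULL) {
  pool <- pooled_draws(chains, burn_in = burn_in)
  a <- (1 - level) / 2
  stats::quantile(pool[, param], c(a, 1 - a), names = FALSE, type = 7)
}
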