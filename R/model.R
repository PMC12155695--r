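#' @useDynLib ocupkpd
NULL

# canonical state ordering used everywhere (vitreous then aqueous humor)
STATE_NAMES <- c("v_vit", "r_vit", "c_vit", "h_vit",
                 "v_aq", "r_aq", "c_aq", "h_aq")

param_vector <- function(params) {
  c(kel_r = params$kel_r, kel_v = params$kel_v, kel_c = params$kel_c,
    kel_h = params$kel_h, k_on = k_on(params), k_off = params$k_off,
    CL = params$CL, V_in = params$V_in,
    V_vit = params$V_vit, V_aq = params$V_aq)
}

#' Right-hand side of the two-compartment binding-kinetics system
#'
#' Reference (pure R) implementation of the mass-action ODE system: VEGF (v),
#' free antibody (r), singly bound complex (c = VR) and doubly bound complex
#' (h = RVR) in the vitreous and aqueous humor compartments. VEGF carries two
#' identical binding sites, so complex formation proceeds with statistical
#' factors 2*k_on (V + R -> VR) and k_off (VR -> V + R), and k_on
#' (R + VR -> RVR) and 2*k_off (RVR -> R + VR). Each species transfers
#' unidirectionally from vitreous to aqueous humor at its elimination rate
#' `kel_i` (amounts conserved via the volume ratio) and every aqueous species
#' is cleared at rate `CL / V_aq`.
#'
#' The compiled C implementation of the same system is what [simulate_model()]
#' integrates; this function is the human-readable form used for verification.
#'
#' @param state named numeric vector of the 8 concentrations (pM), names
#'   `v_vit, r_vit, c_vit, h_vit, v_aq, r_aq, c_aq, h_aq`.
#' @param params an [ocular_params()] object.
#' @return Named vector of time derivatives, pM/day.
#' @export
ode_rhs <- function(state, params) {
  state <- state[STATE_NAMES]
  if (anyNA(state)) stop("state must contain all 8 named components")
  tol <- 1e-8 * max(1, max(abs(state)))
  if (any(state < -tol)) stop("invalid state: negative concentrations")
  kon <- k_on(params)
  koff <- params$k_off
  ratio <- params$V_vit / params$V_aq
  kcl <- params$CL / params$V_aq
  vv <- state[["v_vit"]]; rv <- state[["r_vit"]]
  cv <- state[["c_vit"]]; hv <- state[["h_vit"]]
  va <- state[["v_aq"]]; ra <- state[["r_aq"]]
  ca <- state[["c_aq"]]; ha <- state[["h_aq"]]
  d <- c(
    v_vit = params$V_in / params$V_vit - 2 * kon * vv * rv + koff * cv -
      params$kel_v * vv,
    r_vit = -2 * kon * vv * rv + koff * cv - kon * rv * cv + 2 * koff * hv -
      params$kel_r * rv,
    c_vit = 2 * kon * vv * rv - koff * cv - kon * rv * cv + 2 * koff * hv -
      params$kel_c * cv,
    h_vit = kon * rv * cv - 2 * koff * hv - params$kel_h * hv,
    v_aq = -2 * kon * va * ra + koff * ca + params$kel_v * vv * ratio -
      kcl * va,
    r_aq = -2 * kon * va * ra + koff * ca - kon * ra * ca + 2 * koff * ha +
      params$kel_r * rv * ratio - kcl * ra,
    c_aq = 2 * kon * va * ra - koff * ca - kon * ra * ca + 2 * koff * ha +
      params$kel_c * cv * ratio - kcl * ca,
    h_aq = kon * ra * ca - 2 * koff * ha + params$kel_h * hv * ratio -
      kcl * ha
  )
  d
}

#' Drug-free steady state
#'
#' Before treatment the system sits at the fixed point with no antibody:
#' vitreous VEGF `V_in / (kel_v * V_vit)`, aqueous VEGF `V_in / CL`, and all
#' antibody-containing species at zero. At this state VEGF production exactly
#' balances aqueous clearance.
#'
#' @param params an [ocular_params()] object.
#' @return Named state vector (pM).
#' @export
drug_free_steady_state <- function(params) {
  s <- stats::setNames(numeric(8), STATE_NAMES)
  s["v_vit"] <- params$V_in / (params$kel_v * params$V_vit)
  s["v_aq"] <- params$V_in / params$CL
  s
}

#' Initial state after an intravitreal bolus
#'
#' The drug-free steady state plus the injected antibody, converted from
#' dose mass to vitreous concentration: `dose_mg / MW_R / V_vit` expressed
#' in pM (a 0.5 mg dose of a 48 kDa Fab in a 2 mL vitreous gives about
#' 5.2e6 pM).
#'
#' @param params an [ocular_params()] object.
#' @param dose_mg injected mass, mg.
#' @param mc a [molecular_constants()] object.
#' @return Named state vector (pM).
#' @export
initial_state <- function(params, dose_mg = 0.5, mc = molecular_constants()) {
  if (dose_mg < 0) stop("'dose_mg' must be >= 0")
  if (mc$MW_R <= 0) stop("antibody molecular weight must be positive")
  s <- drug_free_steady_state(params)
  # mg -> g -> mol -> mol/L (V in mL -> L) -> pM
  s["r_vit"] <- s[["r_vit"]] +
    dose_mg * 1e-3 / mc$MW_R / (params$V_vit * 1e-3) * 1e12
  s
}

#' Simulate the two-compartment model
#'
#' Integrates the mass-action system from [initial_state()] with a
#' stiff-capable solver (compiled derivatives via \pkg{deSolve}'s `lsoda` by
#' default). Small negative excursions within solver tolerance are clipped
#' to zero.
#'
#' @param params an [ocular_params()] object.
#' @param dose_mg injected antibody mass, mg.
#' @param mc a [molecular_constants()] object.
#' @param t_grid strictly increasing time grid in days, starting at 0.
#' @param solver_opts list of solver options: `method` (default `"lsoda"`),
#'   `rtol` (1e-8), `atol` (1e-10 pM), `compiled` (`TRUE` to use the C
#'   derivatives), `hmax`.
#' @param state0 optional explicit initial state overriding
#'   [initial_state()].
#' @return An object of class `ocular_trajectory`: a data frame with column
#'   `time_days` and the 8 species concentrations in pM.
#' @examples
#' traj <- simulate_model(posterior_mean_params(), t_grid = seq(0, 63, 0.5))
#' head(traj)
#' @export
simulate_model <- function(params, dose_mg = 0.5, mc = molecular_constants(),
                           t_grid = seq(0, 63, by = 0.25),
                           solver_opts = list(), state0 = NULL) {
  if (t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("'t_grid' must start at 0 and be strictly increasing")
  opts <- utils::modifyList(
    list(method = "lsoda", rtol = 1e-8, atol = 1e-10, compiled = TRUE,
         hmax = NULL), solver_opts)
  y0 <- if (is.null(state0)) initial_state(params, dose_mg, mc) else
    state0[STATE_NAMES]
  pv <- param_vector(params)
  out <- if (isTRUE(opts$compiled)) {
    deSolve::ode(y = y0, times = t_grid, func = "ocular_derivs",
                 parms = pv, dllname = "ocupkpd", initfunc = "ocular_init",
                 jacfunc = "ocular_jac", jactype = "fullusr",
                 method = opts$method, rtol = opts$rtol, atol = opts$atol,
                 hmax = opts$hmax)
  } else {
    rhs <- function(t, y, p) list(ode_rhs(y, params))
    deSolve::ode(y = y0, times = t_grid, func = rhs, parms = NULL,
                 method = opts$method, rtol = opts$rtol, atol = opts$atol,
                 hmax = opts$hmax)
  }
  if (nrow(out) < length(t_grid) || anyNA(out)) {
    stop(sprintf(
      "ODE integration failed at t ~ %.3g days (returned %d of %d steps)",
      out[nrow(out), 1], nrow(out), length(t_grid)))
  }
  df <- as.data.frame(out)
  names(df) <- c("time_days", STATE_NAMES)
  vals <- as.matrix(df[STATE_NAMES])
  allow <- 1e-8 * max(1, max(abs(vals)))
  if (any(vals < -allow))
    stop("integration produced negative concentrations beyond tolerance")
  vals[vals < 0] <- 0
  df[STATE_NAMES] <- vals
  class(df) <- c("ocular_trajectory", "data.frame")
  df
}

#' Elimination half-life from a first-order rate constant
#'
#' @param kel elimination rate constant, 1/day (vectorized).
#' @return Half-life `ln(2)/kel` in days.
#' @export
half_life <- function(kel) {
  if (any(!is.finite(kel)) || any(kel <= 0))
    stop("'kel' must be strictly positive")
  log(2) / kel
}

#' Scale an elimination rate constant by molecular weight
#'
#' Ocular elimination of a macromolecule is inversely proportional to its
#' hydrodynamic radius, which for a compact globular protein scales as the
#' cube root of molecular weight. Hence
#' `kel_target = kel_ref * (MW_ref / MW_target)^(1/3)`.
#'
#' @param kel_ref reference elimination rate, 1/day.
#' @param MW_ref reference molecular weight, g/mol.
#' @param MW_target target molecular weight, g/mol.
#' @return Scaled elimination rate, 1/day.
#' @export
scale_elimination_rate <- function(kel_ref, MW_ref, MW_target) {
  stopifnot(kel_ref > 0, MW_ref > 0, all(MW_target > 0))
  kel_ref * (MW_ref / MW_target)^(1 / 3)
}

#' Hydrodynamic radius of a globular protein
#'
#' Stokes--Einstein estimate treating the protein as a compact sphere of
#' partial specific volume `nu`: `R_h = (3 nu MW / (4 pi N_A))^(1/3)`,
#' returned in nm.
#'
#' @param MW molecular weight, g/mol (vectorized).
#' @param mc a [molecular_constants()] object supplying `nu` and `N_A`.
#' @return Radius in nm.
#' @export
hydrodynamic_radius <- function(MW, mc = molecular_constants()) {
  stopifnot(all(MW > 0))
  r_cm <- (3 * mc$nu * MW / (4 * pi * mc$N_A))^(1 / 3)
  r_cm * 1e7
}

#' Invert the hydrodynamic-radius relation
#'
#' @param R_h_nm radius in nm.
#' @param mc a [molecular_constants()] object.
#' @return Molecular weight in g/mol.
#' @export
mw_from_radius <- function(R_h_nm, mc = molecular_constants()) {
  stopifnot(all(R_h_nm > 0))
  r_cm <- R_h_nm * 1e-7
  4 * pi * mc$N_A * r_cm^3 / (3 * mc$nu)
}

#' Adapted ELISA observation of aqueous VEGF
#'
#' A sandwich ELISA targeting free VEGF binding sites can also capture
#' partially bound (one free site) and, through competitive binding, fully
#' bound VEGF. The measured aqueous VEGF is modelled as
#' `mv_aq(t) = v_aq(t) + gamma * c_aq(t) + eta * h_aq(t)`.
#'
#' @param traj an `ocular_trajectory`.
#' @param obs an [adapted_obs_params()] object.
#' @return Numeric vector of measured aqueous VEGF (pM) on the trajectory
#'   grid.
#' @export
adapted_observation <- function(traj, obs = adapted_obs_params()) {
  traj$v_aq + obs$gamma * traj$c_aq + obs$eta * traj$h_aq
}

# locate first upcrossing of `threshold` by series (t, v) at/after index
# i0, refined by interpolation within the bracketing interval (error
# O(dt^2), far below the 0.01-day contract on the default grids); returns
# NA if never crossed. `sustained`: require the series to stay at/above
# the threshold afterwards.
first_upcrossing <- function(t, v, threshold, i0, sustained = FALSE) {
  n <- length(t)
  i <- i0
  while (i < n) {
    j <- which(v[(i + 1):n] >= threshold)
    if (length(j) == 0) return(NA_real_)
    j <- i + j[1]
    if (sustained && any(v[j:n] < threshold)) {
      # rises above but dips back below: continue search after the dip
      i <- j
      next
    }
    if (v[j - 1] < threshold && v[j] > v[j - 1]) {
      return(t[j - 1] + (threshold - v[j - 1]) *
               (t[j] - t[j - 1]) / (v[j] - v[j - 1]))
    }
    return(t[j])
  }
  NA_real_
}

#' Pharmacokinetic output metrics of a simulated trajectory
#'
#' Three scalar summaries of the aqueous humor profiles:
#' \describe{
#'   \item{pm1}{time of the initial aqueous VEGF uplift: first time after the
#'     post-dose minimum at which `v_aq` recovers to `f1` of its pre-dose
#'     baseline `V_in / CL` (default `f1 = 0.10`).}
#'   \item{pm2}{VEGF relaxation (recovery) time: first time after the minimum
#'     at which `v_aq` reaches `f2` of baseline (default `f2 = 0.90`) and
#'     stays above it for the remainder of the horizon.}
#'   \item{pm3}{the antibody half-life: `ln(2)` over the magnitude of the
#'     terminal slope of `log(r_aq)` fitted over the final third of the
#'     horizon.}
#' }
#' Crossing times are refined by local spline interpolation and root
#' bracketing to well under 0.01 day. When a threshold is never reached the
#' metric is `NA` and the corresponding `reached` flag is `FALSE` (no
#' suppression event, e.g. a zero dose).
#'
#' @param traj an `ocular_trajectory`, ideally spanning at least 63 days.
#' @param params the [ocular_params()] used to generate it (for the
#'   baseline).
#' @param f1,f2 recovery thresholds as fractions of baseline aqueous VEGF.
#' @return List with `pm1`, `pm2`, `pm3` (days), `pm1_reached`,
#'   `pm2_reached` (logical), and `baseline_v_aq` (pM).
#' @export
pk_metrics <- function(traj, params, f1 = 0.10, f2 = 0.90) {
  baseline <- params$V_in / params$CL
  if (baseline <= 0) stop("baseline aqueous VEGF must be positive")
  pk_metrics_core(traj$time_days, traj$v_aq, traj$r_aq, baseline,
                  f1 = f1, f2 = f2)
}

# vector-level implementation shared with the sensitivity wrappers
pk_metrics_core <- function(t, v, r, baseline, f1 = 0.10, f2 = 0.90) {
  im <- which.min(v)
  th1 <- f1 * baseline
  th2 <- f2 * baseline
  pm1 <- if (v[im] < th1) first_upcrossing(t, v, th1, im) else NA_real_
  pm2 <- if (v[im] < th2)
    first_upcrossing(t, v, th2, im, sustained = TRUE) else NA_real_

  horizon <- t[length(t)]
  win <- t >= (2 / 3) * horizon & r > 0
  pm3 <- NA_real_
  if (sum(win) >= 3) {
    tw <- t[win]; lw <- log(r[win])
    slope <- stats::cov(tw, lw) / stats::var(tw)
    if (is.finite(slope) && slope < 0) pm3 <- log(2) / abs(slope)
  }
  list(pm1 = pm1, pm2 = pm2, pm3 = pm3,
       pm1_reached = !is.na(pm1), pm2_reached = !is.na(pm2),
       baseline_v_aq = baseline)
}

#' Write / read a trajectory as CSV
#'
#' Columns `time_days` then the 8 species concentrations in pM, with a
#' mandatory header and `.` as decimal separator; the reader restores the
#' `ocular_trajectory` class and round-trips values exactly.
#'
#' @param traj an `ocular_trajectory`.
#' @param path file path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns the trajectory.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  expected <- c("time_days", STATE_NAMES)
  if (!identical(names(df), expected))
    stop("trajectory CSV must have columns: ",
         paste(expected, collapse = ", "))
  class(df) <- c("ocular_trajectory", "data.frame")
  df
}
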