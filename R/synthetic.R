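#' Observation series container
#'
#' A measured concentration time series for one species, stored as a data
#' frame with the package's canonical columns: `time_days`, `value`, `unit`,
#' `species`, `below_llq` (0/1), `llq`, `correction`. Aqueous VEGF is
#' observed in pM and aqueous antibody in uM, so that the additive noise SDs
#' of both series are of order 0.1--0.3 on their own scales.
#'
#' @param times sampling times, days, strictly increasing.
#' @param values observed concentrations in the species' observation unit.
#' @param species `"VEGF"` or `"ranibizumab"`.
#' @param llq lower limit of quantification, same unit as `values`.
#' @param below_llq logical flags; defaults to `values < llq`.
#' @param correction correction tag: `"none"`, `"M5"`, `"M6"` or `"M7"`.
#' @return A data frame of class `observation_series`.
#' @export
observation_series <- function(times, values,
                               species = c("VEGF", "ranibizumab"),
                               llq, below_llq = values < llq,
                               correction = "none") {
  species <- match.arg(species)
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(values < 0)) stop("'values' must be non-negative")
  if (!is.finite(llq) || llq <= 0) stop("'llq' must be positive")
  if (!correction %in% c("none", "M5", "M6", "M7"))
    stop("unknown correction tag: ", correction)
  unit <- if (species == "VEGF") "pM" else "uM"
  df <- data.frame(time_days = times, value = values, unit = unit,
                   species = species, below_llq = as.integer(below_llq),
                   llq = llq, correction = correction,
                   stringsAsFactors = FALSE)
  class(df) <- c("observation_series", "data.frame")
  df
}

#' Build a sampling schedule
#'
#' Supported kinds:
#' \describe{
#'   \item{`"niwa"`}{the macaque study's schedule, days
#'     0, 1, 3, 7, 14, 21, 28, 35, 42, 49, 56.}
#'   \item{`"uniform"`}{`n_points` equally spaced days over `[0, horizon]`.}
#'   \item{`"phase_removed:<P>"`}{the uniform schedule with all points whose
#'     phase label (see [classify_phases()]) matches the named phase(s)
#'     removed; `<P>` is one of `P1`, `P2`, `P3`, `P4`, `P1P4`.}
#'   \item{`"transition_density:<Nk>"`}{the uniform schedule with its
#'     transition-region (P3) points replaced by exactly `k` equally spaced
#'     points strictly inside the P3 interval, `k` in 0, 1, 3, 5.}
#' }
#' Phase-based kinds require a noiseless reference trajectory.
#'
#' @param kind schedule kind tag (see Details).
#' @param n_points number of points for the uniform base schedule.
#' @param horizon_days schedule horizon, days.
#' @param reference_traj an `ocular_trajectory` used to locate the phases
#'   (required for phase-based kinds).
#' @param llq_v VEGF LLQ in pM used for phase classification.
#' @param f2 recovery threshold defining the P3/P4 boundary.
#' @return List of class `schedule` with elements `times` and `label`.
#' @export
make_schedule <- function(kind, n_points = 10, horizon_days = 63,
                          reference_traj = NULL,
                          llq_v = default_llq()$llq_v, f2 = 0.90) {
  if (horizon_days <= 0) stop("'horizon_days' must be positive")
  base <- seq(0, horizon_days, length.out = n_points)
  if (kind == "niwa") {
    return(structure(list(times = c(0, 1, 3, 7, 14, 21, 28, 35, 42, 49, 56),
                          label = "niwa"), class = "schedule"))
  }
  if (kind == "uniform") {
    return(structure(list(times = base, label = "uniform"),
                     class = "schedule"))
  }
  if (grepl("^phase_removed:", kind)) {
    tag <- sub("^phase_removed:", "", kind)
    phases <- if (tag == "P1P4") c("P1", "P4") else tag
    if (!all(phases %in% c("P1", "P2", "P3", "P4")))
      stop("unknown phase tag: ", tag)
    if (is.null(reference_traj))
      stop("phase-based schedules need 'reference_traj'")
    lab <- classify_phases(base, reference_traj, llq_v = llq_v, f2 = f2)
    return(structure(list(times = base[!lab %in% phases], label = kind),
                     class = "schedule"))
  }
  if (grepl("^transition_density:", kind)) {
    k <- as.integer(sub("^transition_density:N", "", kind))
    if (is.na(k) || k < 0) stop("unknown transition-density tag: ", kind)
    if (is.null(reference_traj))
      stop("phase-based schedules need 'reference_traj'")
    lab <- classify_phases(base, reference_traj, llq_v = llq_v, f2 = f2)
    keep <- base[lab != "P3"]
    iv <- transition_interval(reference_traj, llq_v = llq_v, f2 = f2)
    extra <- if (k > 0)
      seq(iv[1], iv[2], length.out = k + 2)[seq(2, k + 1)] else numeric(0)
    return(structure(list(times = sort(unique(c(keep, extra))),
                          label = kind), class = "schedule"))
  }
  stop("unknown schedule kind: ", kind)
}

# the transition (P3) time interval of a noiseless reference trajectory:
# from the post-minimum upcrossing of the VEGF LLQ to the sustained
# upcrossing of f2 * baseline
transition_interval <- function(reference_traj, llq_v, f2 = 0.90) {
  t <- reference_traj$time_days
  v <- reference_traj$v_aq
  baseline <- v[1]
  im <- which.min(v)
  lo <- first_upcrossing(t, v, llq_v, im)
  hi <- first_upcrossing(t, v, f2 * baseline, im, sustained = TRUE)
  if (is.na(lo) || is.na(hi) || hi <= lo)
    stop("reference trajectory has no identifiable transition region")
  c(lo, hi)
}

#' Label schedule times with the phases of the aqueous VEGF profile
#'
#' Phases are defined on the noiseless reference trajectory (labels are
#' therefore invariant to observation noise): `P1` is the pre-dose point
#' `t = 0`; `P2` (suppression) covers times where reference aqueous VEGF is
#' below the LLQ, and any pre-recovery descent points; `P3` (transition)
#' covers post-minimum times at or above the LLQ but below `f2` of baseline;
#' `P4` (return to equilibrium) covers post-minimum times at or above `f2`
#' of baseline. A trajectory with no suppression labels all non-zero times
#' `P4`.
#'
#' @param times schedule times (days) or a `schedule`.
#' @param reference_traj noiseless `ocular_trajectory` spanning the times.
#' @param llq_v VEGF LLQ, pM.
#' @param f2 recovery threshold fraction of baseline.
#' @return Character vector of labels (`"P1"`,...,`"P4"`), one per time.
#' @export
classify_phases <- function(times, reference_traj,
                            llq_v = default_llq()$llq_v, f2 = 0.90) {
  if (inherits(times, "schedule")) times <- times$times
  t <- reference_traj$time_days
  v <- reference_traj$v_aq
  if (max(times) > max(t) || min(times) < min(t))
    stop("reference trajectory does not span the schedule")
  baseline <- v[1]
  im <- which.min(v)
  t_min <- t[im]
  no_suppression <- v[im] >= f2 * baseline
  vi <- stats::approx(t, v, xout = times)$y
  lab <- character(length(times))
  for (i in seq_along(times)) {
    if (times[i] == 0) {
      lab[i] <- "P1"
    } else if (no_suppression) {
      lab[i] <- "P4"
    } else if (vi[i] < llq_v) {
      lab[i] <- "P2"
    } else if (times[i] <= t_min) {
      lab[i] <- "P2" # above LLQ but still on the descending limb
    } else if (vi[i] < f2 * baseline) {
      lab[i] <- "P3"
    } else {
      lab[i] <- "P4"
    }
  }
  lab
}

#' Generate a synthetic observation dataset
#'
#' Simulates the model at a reference parameter set, samples it on a
#' schedule, and adds independent additive Gaussian observation noise on
#' each series' own observation unit (VEGF in pM, antibody in uM). Negative
#' noisy draws are clipped to zero. Below-LLQ flags compare the noisy values
#' to each assay's limit, mirroring what an experimenter would see.
#'
#' @param params_ref reference [ocular_params()] (`theta_ref`).
#' @param sigma_n additive noise SD; a single value applied to both series
#'   on their own units, or a [noise_params()] object for per-series SDs.
#' @param schedule a `schedule` from [make_schedule()] applied to both
#'   series, or a list with elements `vegf` and `ranibizumab` holding a
#'   schedule each (the phase-removal experiments alter the VEGF sampling
#'   only).
#' @param dose_mg injected dose, mg.
#' @param mc a [molecular_constants()] object.
#' @param seed RNG seed (mandatory: datasets are reproducible by
#'   construction; replicate `r` of an experiment uses `seed + r`).
#' @param llq list with `llq_v` (pM) and `llq_r` (uM), as from
#'   [default_llq()].
#' @param solver_opts passed to [simulate_model()].
#' @return List with elements `vegf` and `ranibizumab`, each an
#'   [observation_series()].
#' @export
generate_dataset <- function(params_ref, sigma_n = 0.25, schedule,
                             dose_mg = 0.5, mc = molecular_constants(),
                             seed, llq = default_llq(mc),
                             solver_opts = list()) {
  if (missing(seed)) stop("'seed' must be supplied explicitly")
  if (inherits(sigma_n, "noise_params")) {
    sv <- sigma_n$sigma_v; sr <- sigma_n$sigma_r
  } else {
    if (sigma_n < 0) stop("'sigma_n' must be >= 0")
    sv <- sigma_n; sr <- sigma_n
  }
  if (inherits(schedule, "schedule")) {
    t_v <- schedule$times
    t_r <- schedule$times
  } else {
    t_v <- schedule$vegf$times
    t_r <- schedule$ranibizumab$times
  }
  grid <- sort(unique(c(0, t_v, t_r)))
  traj <- simulate_model(params_ref, dose_mg, mc, t_grid = grid,
                         solver_opts = solver_opts)
  v_true <- traj$v_aq[match(t_v, traj$time_days)]          # pM
  r_true <- pM_to_uM(traj$r_aq[match(t_r, traj$time_days)]) # uM
  set.seed(seed)
  v_obs <- pmax(0, v_true + stats::rnorm(length(t_v), 0, sv))
  r_obs <- pmax(0, r_true + stats::rnorm(length(t_r), 0, sr))
  list(
    vegf = observation_series(t_v, v_obs, "VEGF", llq = llq$llq_v),
    ranibizumab = observation_series(t_r, r_obs, "ranibizumab",
                                     llq = llq$llq_r)
  )
}

#' Write / read an observation series as CSV
#'
#' Canonical dialect: columns `time_days, value, unit, species, below_llq,
#' llq, correction`, header mandatory, `.` decimal separator. Numeric values
#' are written with 17 significant digits so the round trip is exact.
#'
#' @param series an [observation_series()].
#' @param path file path.
#' @return `write_series_csv()` returns `path` invisibly;
#'   `read_series_csv()` returns the series.
#' @export
write_series_csv <- function(series, path) {
  df <- as.data.frame(series)
  df$time_days <- format(df$time_days, digits = 17, trim = TRUE,
                         scientific = FALSE)
  df$value <- sprintf("%.17g", df$value)
  df$llq <- sprintf("%.17g", df$llq)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(time_days = "numeric",
                                       value = "numeric",
                                       llq = "numeric"))
  expected <- c("time_days", "value", "unit", "species", "below_llq",
                "llq", "correction")
  if (!identical(names(df), expected))
    stop("observation-series CSV must have columns: ",
         paste(expected, collapse = ", "))
  bad <- which(df$value < 0)
  if (length(bad) > 0)
    stop("negative concentration at row ", bad[1])
  bad <- which(diff(df$time_days) <= 0)
  if (length(bad) > 0)
    stop("times not strictly increasing at row ", bad[1] + 1)
  out <- observation_series(df$time_days, df$value,
                            species = df$species[1], llq = df$llq[1],
                            below_llq = df$below_llq == 1,
                            correction = df$correction[1])
  out
}
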