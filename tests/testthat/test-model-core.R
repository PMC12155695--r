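test_that("drug-free steady state is an exact fixed point of the RHS", {
  p <- theta_ref_params()
  ss <- drug_free_steady_state(p)
  expect_equal(ss[["v_vit"]], p$V_in / (p$kel_v * p$V_vit))
  expect_equal(ss[["v_aq"]], p$V_in / p$CL)
  expect_true(all(ss[c("r_vit", "c_vit", "h_vit", "r_aq", "c_aq",
                       "h_aq")] == 0))
  expect_lt(max(abs(ode_rhs(ss, p))), 1e-12)

  # production balances clearance exactly at the fixed point
  expect_equal(p$CL * ss[["v_aq"]], p$V_in)

  # no production -> the all-zero state
  p0 <- ocular_params(kel_r = 0.3, kel_v = 0.31, kel_c = 0.25,
                      kel_h = 0.21, k_off = 0.85, K_D = 1000, CL = 2.5,
                      V_in = 0)
  expect_true(all(drug_free_steady_state(p0) == 0))

  # Table 2 means: baseline aqueous VEGF is V_in / CL
  expect_equal(ss[["v_aq"]], 5.408 / 2.505, tolerance = 1e-12)
})

test_that("simulation from the steady state with no dose stays constant", {
  p <- theta_ref_params()
  traj <- simulate_model(p, dose_mg = 0, t_grid = seq(0, 63, 1))
  ss <- drug_free_steady_state(p)
  for (nm in c("v_vit", "v_aq"))
    expect_equal(traj[[nm]], rep(ss[[nm]], nrow(traj)), tolerance = 1e-7)
  expect_true(all(traj[c("r_vit", "c_vit", "h_vit", "r_aq", "c_aq",
                         "h_aq")] < 1e-8))
})

test_that("bolus initial state converts dose mass to concentration", {
  p <- theta_ref_params()
  mc <- molecular_constants()
  s <- initial_state(p, dose_mg = 0.5, mc = mc)
  # 0.5 mg of a 48 kDa Fab in 2 mL: 5.208e6 pM
  expect_equal(s[["r_vit"]], 0.5e-3 / 48000 / 2e-3 * 1e12,
               tolerance = 1e-12)
  expect_equal(s[["r_vit"]], 5.2083e6, tolerance = 1e-4)
  # zero dose reduces to the drug-free steady state
  expect_equal(initial_state(p, 0, mc), drug_free_steady_state(p))
  # linearity in dose
  s2 <- initial_state(p, 1.0, mc)
  expect_equal(s2[["r_vit"]], 2 * s[["r_vit"]], tolerance = 1e-12)
  expect_error(initial_state(p, -1, mc), "dose_mg")
})

test_that("VEGF-moiety mass balance holds for the stated RHS", {
  # d/dt of total VEGF amount (free + both complexes, both compartments)
  # must equal production minus clearance of aqueous VEGF species,
  # independent of the binding and transfer terms
  p <- theta_ref_params()
  set.seed(1)
  for (i in 1:25) {
    st <- stats::setNames(stats::runif(8, 0, 10)^3, names(ode_rhs(
      drug_free_steady_state(p), p)))
    d <- ode_rhs(st, p)
    lhs <- p$V_vit * (d[["v_vit"]] + d[["c_vit"]] + d[["h_vit"]]) +
      p$V_aq * (d[["v_aq"]] + d[["c_aq"]] + d[["h_aq"]])
    rhs <- p$V_in - p$CL * (st[["v_aq"]] + st[["c_aq"]] + st[["h_aq"]])
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("with binding off the RHS reduces to first-order decay", {
  p <- ocular_params(kel_r = 0.3, kel_v = 0.31, kel_c = 0.25, kel_h = 0.21,
                     k_off = 0.85, K_D = Inf, CL = 2.5, V_in = 0)
  expect_identical(k_on(p), 0)
  st <- stats::setNames(c(0, 1e6, 0, 0, 0, 0, 0, 0),
                        c("v_vit", "r_vit", "c_vit", "h_vit",
                          "v_aq", "r_aq", "c_aq", "h_aq"))
  d <- ode_rhs(st, p)
  expect_equal(d[["r_vit"]], -p$kel_r * 1e6)
  expect_equal(d[["c_vit"]], 0)
  expect_equal(d[["h_vit"]], 0)
})

test_that("binding-off simulation matches the two-compartment cascade
          closed form to 1e-6 relative error", {
  p <- ocular_params(kel_r = 0.293, kel_v = 0.575, kel_c = 0.259,
                     kel_h = 0.176, k_off = 1.669, K_D = Inf, CL = 2.505,
                     V_in = 0)
  mc <- molecular_constants()
  t_grid <- seq(0, 63, by = 0.25)
  traj <- simulate_model(p, dose_mg = 0.5, mc = mc, t_grid = t_grid,
                         solver_opts = list(rtol = 1e-10, atol = 1e-12))
  r0 <- initial_state(p, 0.5, mc)[["r_vit"]]
  k2 <- p$CL / p$V_aq
  expect_equal(traj$r_vit, r0 * exp(-p$kel_r * t_grid), tolerance = 1e-7)
  closed <- r0 * p$kel_r * (p$V_vit / p$V_aq) *
    (exp(-p$kel_r * t_grid) - exp(-k2 * t_grid)) / (k2 - p$kel_r)
  rel <- abs(traj$r_aq[-1] - closed[-1]) / closed[-1]
  expect_lt(max(rel), 1e-6)
})

test_that("stiff trajectory agrees with fixed-step RK4 integration", {
  # the initial binding transient relaxes at ~1.2e4 / day, so the
  # fixed-step oracle needs dt = 1e-4 day to sit inside RK4's stability
  # region (h * lambda < 2.8)
  p <- theta_ref_params()
  t_out <- seq(0, 63, by = 7)
  traj <- simulate_model(p, t_grid = t_out)
  y0 <- initial_state(p)
  pv <- c(p$kel_r, p$kel_v, p$kel_c, p$kel_h, k_on(p), p$k_off, p$CL,
          p$V_in, p$V_vit, p$V_aq)
  t_fine <- seq(0, 63, by = 1e-4)
  rk <- deSolve::ode(y0, t_fine, func = "ocular_derivs", parms = pv,
                     dllname = "ocupkpd", initfunc = "ocular_init",
                     method = "rk4")
  idx <- match(t_out, t_fine)
  for (j in 2:9) {
    ref <- rk[idx, j]
    scale <- pmax(abs(ref), 1e-6 * max(abs(ref)))
    expect_lt(max(abs(traj[[j]] - ref) / scale), 1e-5)
  }
})

test_that("simulated concentrations stay non-negative", {
  set.seed(7)
  rng <- default_efast_ranges(include_noise = FALSE,
                              include_dummy = FALSE)
  for (i in 1:10) {
    th <- rng$lower + stats::runif(nrow(rng)) * (rng$upper - rng$lower)
    names(th) <- rng$param
    p <- ocular_params(kel_r = th[["kel_r"]], kel_v = th[["kel_v"]],
                       kel_c = th[["kel_c"]], kel_h = th[["kel_h"]],
                       k_off = th[["k_off"]], K_D = th[["K_D"]],
                       CL = th[["CL"]], V_in = th[["V_in"]])
    traj <- simulate_model(p, t_grid = seq(0, 63, 0.5))
    expect_true(all(as.matrix(traj[-1]) >= 0))
  }
})

test_that("aqueous VEGF stays below its LLQ across days 1-21 at the
          posterior-mean parameters", {
  traj <- simulate_model(theta_ref_params(), t_grid = seq(0, 63, 0.25))
  llq_v <- default_llq()$llq_v
  win <- traj$time_days >= 1 & traj$time_days <= 21
  expect_true(all(traj$v_aq[win] < llq_v))
})

test_that("half-life transform is exact and order-reversing", {
  expect_equal(half_life(log(2)), 1.0)
  expect_equal(half_life(0.293), 2.3656, tolerance = 1e-4)
  expect_error(half_life(0), "positive")
  expect_error(half_life(-1), "positive")
  kels <- sort(stats::runif(20, 0.1, 2))
  expect_equal(order(half_life(kels)), rev(seq_along(kels)))
})

test_that("cube-root molecular-weight scaling reproduces the literature
          elimination rates", {
  mc <- molecular_constants()
  expect_equal(scale_elimination_rate(0.3, mc$MW_R, mc$MW_R), 0.3)
  # antibody 0.300/day anchors VEGF, VR and RVR rates
  expect_equal(scale_elimination_rate(0.300, mc$MW_R, mc$MW_H), 0.210,
               tolerance = 1e-3)
  kel_v <- scale_elimination_rate(0.300, mc$MW_R, mc$MW_V)
  expect_lt(abs(kel_v - 0.309) / 0.309, 0.02)
  kel_c <- scale_elimination_rate(0.300, mc$MW_R, mc$MW_C)
  expect_lt(abs(kel_c - 0.245) / 0.245, 0.02)
})

test_that("hydrodynamic radius follows the cube-root law", {
  mc <- molecular_constants()
  expect_equal(hydrodynamic_radius(48000, mc), 2.40, tolerance = 0.01)
  expect_equal(hydrodynamic_radius(8 * 48000, mc),
               2 * hydrodynamic_radius(48000, mc))
  # inversion round-trips
  expect_equal(mw_from_radius(hydrodynamic_radius(93000, mc), mc), 93000,
               tolerance = 1e-9)
  expect_equal(mc$nu, 0.73)
})

test_that("adapted ELISA observation is the stated linear combination", {
  df <- data.frame(time_days = 0:2, v_vit = 0, r_vit = 0, c_vit = 0,
                   h_vit = 0, v_aq = c(1, 1, 2), r_aq = 0,
                   c_aq = c(4, 0, 1), h_aq = c(7, 0, 3))
  class(df) <- c("ocular_trajectory", "data.frame")
  expect_equal(adapted_observation(df, adapted_obs_params(0, 0)), df$v_aq)
  expect_equal(adapted_observation(df, adapted_obs_params(1, 1)),
               df$v_aq + df$c_aq + df$h_aq)
  expect_equal(adapted_observation(df, adapted_obs_params(0.5, 0))[1], 3.0)
  expect_error(adapted_obs_params(-0.1, 0), "gamma")
  expect_error(adapted_obs_params(0, 1.5), "eta")
})

test_that("PK metrics: degenerate no-suppression case and binding-off
          half-life", {
  p <- theta_ref_params()
  traj0 <- simulate_model(p, dose_mg = 0, t_grid = seq(0, 63, 0.25))
  pm0 <- pk_metrics(traj0, p)
  expect_false(pm0$pm1_reached)
  expect_false(pm0$pm2_reached)
  expect_true(is.na(pm0$pm1) && is.na(pm0$pm2))

  pfree <- ocular_params(kel_r = 0.293, kel_v = 0.575, kel_c = 0.259,
                         kel_h = 0.176, k_off = 1.669, K_D = Inf,
                         CL = 2.505, V_in = 5.408)
  pmf <- pk_metrics(simulate_model(pfree, t_grid = seq(0, 63, 0.25)),
                    pfree)
  expect_lt(abs(pmf$pm3 - log(2) / 0.293) / (log(2) / 0.293), 0.01)
})

test_that("PK metric crossing times match a dense-grid scanning oracle", {
  p <- theta_ref_params()
  traj <- simulate_model(p, t_grid = seq(0, 63, 0.25))
  pm <- pk_metrics(traj, p)
  # brute force: scan a trajectory on a 0.001-day grid for the first
  # sustained upcrossing of f2 * baseline after the minimum
  fine <- simulate_model(p, t_grid = seq(0, 63, 0.001))
  v <- fine$v_aq
  base <- p$V_in / p$CL
  im <- which.min(v)
  above2 <- v >= 0.9 * base
  i2 <- which(above2 & rev(cumprod(rev(above2))) == 1)
  i2 <- i2[i2 > im][1]
  expect_lt(abs(pm$pm2 - fine$time_days[i2]), 0.01)
  above1 <- which(v >= 0.1 * base)
  i1 <- above1[above1 > im][1]
  expect_lt(abs(pm$pm1 - fine$time_days[i1]), 0.01)
})

test_that("trajectory CSV round-trips through the canonical dialect", {
  traj <- simulate_model(theta_ref_params(), t_grid = seq(0, 21, 1))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  back <- read_trajectory_csv(f)
  expect_s3_class(back, "ocular_trajectory")
  expect_equal(back$v_aq, traj$v_aq, tolerance = 1e-12)
  expect_equal(names(back), names(traj))
  writeLines("time_days,bogus\n0,1", f)
  expect_error(read_trajectory_csv(f), "columns")
  unlink(f)
})

test_that("parameter constructor enforces positivity and derives k_on", {
  expect_error(ocular_params(kel_r = -0.1, kel_v = 0.3, kel_c = 0.2,
                             kel_h = 0.2, k_off = 0.8, K_D = 100,
                             CL = 2, V_in = 5), "kel_r")
  expect_error(ocular_params(kel_r = 0.1, kel_v = 0.3, kel_c = 0.2,
                             kel_h = 0.2, k_off = 0.8, K_D = -5,
                             CL = 2, V_in = 5), "K_D")
  p <- literature_params()
  expect_equal(k_on(p), p$k_off / p$K_D)
  expect_equal(molecular_constants()$MW_H,
               molecular_constants()$MW_V + 2 * molecular_constants()$MW_R)
})
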