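test_that("replicate-averaged posteriors are max-normalized and behave
          under averaging", {
  set.seed(30)
  mk <- function(mu) fake_chain_set_from_matrix(
    cbind(stats::rnorm(2000, mu, 1)), "x")
  one <- average_posteriors(list(mk(0)))
  expect_equal(max(one$x$y), 1)
  two_same <- average_posteriors(list(mk(0), mk(0)))
  expect_equal(max(two_same$x$y), 1)

  # replicates centred at 0 and 5: a bimodal average with near-equal peaks
  bim <- average_posteriors(list(mk(0), mk(5)))
  y <- bim$x$y; x <- bim$x$x
  peak_lo <- max(y[x < 2.5]); peak_hi <- max(y[x > 2.5])
  expect_equal(peak_lo, peak_hi, tolerance = 0.1)
  expect_lt(min(y[x > 1.5 & x < 3.5]), 0.7 * peak_lo)

  bad <- fake_chain_set_from_matrix(cbind(stats::rnorm(100)), "z")
  expect_error(average_posteriors(list(mk(0), bad)), "incompatible")
})

test_that("overlap coefficient: identical, disjoint and partial
          densities", {
  x <- seq(-8, 8, length.out = 1001)
  f <- stats::dnorm(x, 0, 1)
  expect_equal(overlap_coefficient(x, f, f), 1, tolerance = 1e-6)
  g <- stats::dnorm(x, 40, 1) # effectively zero on the grid
  expect_lt(overlap_coefficient(x, f, g + 1e-300), 0.01)
  h <- stats::dnorm(x, 1, 1)
  # analytic overlap of unit normals one SD apart: 2*pnorm(-1/2)
  expect_equal(overlap_coefficient(x, f, h), 2 * stats::pnorm(-0.5),
               tolerance = 1e-3)
})

test_that("radius sweep parameters reproduce the base model at the
          reference radius", {
  p <- posterior_mean_params()
  mc <- molecular_constants()
  r_ref <- hydrodynamic_radius(mc$MW_R, mc)
  sw <- radius_sweep_params(p, mc, r_ref)
  expect_equal(sw$MW, mc$MW_R, tolerance = 1e-9)
  expect_equal(sw$params$kel_r, p$kel_r, tolerance = 1e-12)
  # complexes are anchored to the antibody rate by cube-root scaling
  expect_equal(sw$params$kel_c,
               p$kel_r * (mc$MW_R / mc$MW_C)^(1 / 3), tolerance = 1e-12)
  t_grid <- seq(0, 210, 0.25)
  pm_direct <- pk_metrics(simulate_model(sw$params, t_grid = t_grid),
                          sw$params)
  sweep1 <- recovery_time_vs_radius(p, mc, radius_grid = r_ref,
                                    horizon_days = 210)
  expect_equal(sweep1$pm2_days, pm_direct$pm2, tolerance = 1e-6)
})

test_that("dataset validation rejects malformed and mislabeled series", {
  ds <- make_test_dataset(seed = 4)
  cfg <- experiment_config(n_chains = 6, n_iterations = 20, seed = 1)
  expect_error(fit_dataset(ds$ranibizumab, ds$ranibizumab, config = cfg),
               "species")
  f <- tempfile(fileext = ".csv")
  write_series_csv(ds$vegf, f)
  txt <- readLines(f)
  txt[3] <- sub("^([0-9.]+),[0-9.eE+-]+", "\\1,-4", txt[3])
  writeLines(txt, f)
  expect_error(read_series_csv(f), "row")
  unlink(f)
})

test_that("correction comparison on a dataset with no censored points is
          method-invariant and reruns byte-identically", {
  # a recovery-window schedule with tiny noise keeps every observation
  # above both assay limits, so all methods see identical data
  p <- posterior_mean_params()
  # (no t = 0 point: pre-dose antibody is 0, i.e. below its own LLQ)
  sched <- structure(list(times = c(28, 35, 42), label = "late"),
                     class = "schedule")
  cfg <- experiment_config(theta_ref = p, sigma_n = 1e-7,
                           schedule = sched,
                           correction_methods = c("none", "M5", "M7"),
                           n_replicates = 1, n_chains = 8,
                           n_iterations = 60, seed = 99,
                           init_strategy = "prior")
  ds <- generate_dataset(p, 1e-7, sched, seed = 100)
  expect_true(all(ds$vegf$below_llq == 0))
  expect_true(all(ds$ranibizumab$below_llq == 0))
  rep1 <- suppressWarnings(run_correction_comparison(cfg))
  expect_equal(rep1$rmse[["M5"]], rep1$rmse[["none"]], tolerance = 1e-12)
  expect_equal(rep1$rmse[["M7"]], rep1$rmse[["none"]], tolerance = 1e-12)
  expect_equal(rep1$kd_overlap[["M7"]], 1, tolerance = 1e-9)

  rep2 <- suppressWarnings(run_correction_comparison(cfg))
  expect_identical(rep1$rmse, rep2$rmse)
  expect_identical(rep1$summaries, rep2$summaries)
})

test_that("fitting near-noiseless synthetic data recovers the generating
          parameters", {
  sched <- make_schedule("uniform")
  ds <- generate_dataset(posterior_mean_params(), 1e-4, sched, seed = 55)
  cfg <- experiment_config(sigma_n = 1e-4, n_chains = 12,
                           n_iterations = 250, seed = 7,
                           fix_sigma = TRUE)
  fit <- suppressWarnings(
    fit_dataset(ds$vegf, ds$ranibizumab, correction = "none",
                config = cfg, n_predictive = 50,
                t_grid = seq(0, 63, 3.5)))
  s <- fit$summary
  ref <- theta_ref_vec()
  for (pa in c("kel_r", "CL", "V_in")) {
    est <- s$mean[s$param == pa]
    expect_lt(abs(est - ref[[pa]]) / ref[[pa]], 0.05)
  }
  expect_s3_class(fit$chains, "chain_set")
  expect_true(all(c("lambda", "mu", "r_squared") %in%
                    names(fit$regression)))
  expect_equal(dim(fit$predictive$mean), c(length(seq(0, 63, 3.5)), 8))
})

test_that("chain CSV export writes draws long with a metadata sidecar", {
  pr <- prior_spec(c("a", "b"), c(0, 0), c(1, 1), c(-5, -5), c(5, 5))
  cs <- demcmc_sample(function(th) sum(stats::dnorm(th, log = TRUE)),
                      pr, n_chains = 4, n_iterations = 50, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_chains_csv(cs, f)
  df <- utils::read.csv(f)
  expect_equal(names(df), c("chain", "iteration", "a", "b"))
  expect_equal(nrow(df), 200)
  expect_equal(df$a[df$chain == 3 & df$iteration == 17],
               unname(cs$draws[17, 3, "a"]))
  meta <- readLines(paste0(f, ".meta"))
  expect_true(any(grepl("^seed: 2", meta)))
  unlink(c(f, paste0(f, ".meta")))
})
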