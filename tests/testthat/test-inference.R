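test_that("truncated-normal log prior: bounds, mode and wide-bound
          limit", {
  pr <- default_priors("base")
  th <- pr$mean
  expect_true(is.finite(log_prior(th, pr)))
  th_bad <- th; th_bad[1] <- -0.01
  expect_identical(log_prior(th_bad, pr), -Inf)
  th_bad2 <- th; th_bad2[6] <- 40000
  expect_identical(log_prior(th_bad2, pr), -Inf)

  # effectively untruncated: matches the plain normal log density
  wide <- prior_spec("x", mean = 1.3, sd = 0.7, lower = -1e8, upper = 1e8)
  x <- 2.2
  expect_equal(log_prior(x, wide), stats::dnorm(x, 1.3, 0.7, log = TRUE),
               tolerance = 1e-6)

  # adapted variant appends the contamination fractions
  pa <- default_priors("adapted")
  expect_equal(pa$param[11:12], c("gamma", "eta"))
  expect_identical(log_prior(c(pr$mean, 0.5, 1.2), pa), -Inf)
})

test_that("prior sampling respects bounds and hits the right moments", {
  pr <- default_priors("base")
  set.seed(3)
  X <- sample_prior(4000, pr)
  for (j in seq_len(nrow(pr))) {
    expect_true(all(X[, j] >= pr$lower[j] & X[, j] <= pr$upper[j]))
  }
  # a nearly untruncated component recovers its normal moments
  wide <- prior_spec("x", 2, 0.5, -20, 20)
  set.seed(4)
  x <- sample_prior(20000, wide)
  expect_equal(mean(x), 2, tolerance = 0.02)
  expect_equal(stats::sd(x), 0.5, tolerance = 0.02)
})

test_that("log likelihood equals an independently coded Gaussian sum", {
  ds <- make_test_dataset(sigma_n = 0.25, seed = 31, correction = "M7")
  pr <- default_priors("base")
  set.seed(11)
  thetas <- sample_prior(100, pr)
  mc <- molecular_constants()
  times <- sort(unique(c(0, ds$vegf$time_days, ds$ranibizumab$time_days)))
  pv_of <- function(th) c(th[1:4], th[5] / th[6], th[5], th[7], th[8],
                          2.0, 0.105)
  oracle <- function(th) {
    y0 <- c(th[8] / (th[2] * 2), 0.5e-3 / mc$MW_R / 2e-3 * 1e12, 0, 0,
            th[8] / th[7], 0, 0, 0)
    out <- deSolve::lsoda(y0, times, func = "ocular_derivs",
                          parms = pv_of(th), dllname = "ocupkpd",
                          initfunc = "ocular_init",
                          rtol = 1e-8, atol = 1e-10)
    ll <- 0
    for (i in seq_len(nrow(ds$vegf))) {
      mu <- out[match(ds$vegf$time_days[i], times), 6]
      r <- ds$vegf$value[i] - mu
      ll <- ll - log(th[9] * sqrt(2 * pi)) - r^2 / (2 * th[9]^2)
    }
    for (i in seq_len(nrow(ds$ranibizumab))) {
      mu <- out[match(ds$ranibizumab$time_days[i], times), 7] * 1e-6
      r <- ds$ranibizumab$value[i] - mu
      ll <- ll - log(th[10] * sqrt(2 * pi)) - r^2 / (2 * th[10]^2)
    }
    ll
  }
  for (i in seq_len(25)) {
    th <- unname(thetas[i, ])
    got <- log_likelihood(th, ds)
    want <- unname(oracle(th))
    if (is.finite(want)) expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("hand-computed two-point Gaussian example", {
  # build a dataset whose predictions are exactly known: zero-noise
  # values at theta_ref, then perturb two VEGF observations by +0.1/-0.2
  p <- posterior_mean_params()
  sched <- structure(list(times = c(0, 49), label = "uniform"),
                     class = "schedule")
  ds <- generate_dataset(p, 0, sched, seed = 1)
  ds$vegf$value <- ds$vegf$value + c(0.1, -0.2)
  th <- theta_ref_vec(sigma = 0.25)
  got <- log_likelihood(th, ds)
  want_v <- -2 * log(0.25 * sqrt(2 * pi)) - (0.01 + 0.04) / (2 * 0.0625)
  want_r <- -2 * log(0.25 * sqrt(2 * pi)) # zero residuals
  expect_equal(got, want_v + want_r, tolerance = 1e-6)
})

test_that("adapted likelihood with zero contamination equals the base
          likelihood; fixed-sigma variant matches", {
  ds <- make_test_dataset(sigma_n = 0.25, seed = 8)
  th <- theta_ref_vec()
  base <- log_likelihood(th, ds)
  adapted <- log_likelihood(c(th, gamma = 0, eta = 0), ds,
                            model_variant = "adapted")
  expect_equal(adapted, base, tolerance = 1e-12)
  fixed <- log_likelihood(th[1:8], ds, fixed_sigma = c(0.25, 0.25))
  expect_equal(fixed, base, tolerance = 1e-12)
})

test_that("zero-noise data at the generating parameters gives the
          Gaussian normalization constant", {
  ds <- make_test_dataset(sigma_n = 0, seed = 2)
  th <- theta_ref_vec(sigma = 0.25)
  n <- nrow(ds$vegf) + nrow(ds$ranibizumab)
  expect_equal(log_likelihood(th, ds), -n * log(0.25 * sqrt(2 * pi)),
               tolerance = 1e-4)
})

test_that("DEMCMC recovers a known two-dimensional normal target", {
  pr <- prior_spec(c("a", "b"), mean = c(0, 0), sd = c(5, 5),
                   lower = c(-50, -50), upper = c(50, 50))
  target <- function(th) sum(stats::dnorm(th, 0, 1, log = TRUE))
  cs <- demcmc_sample(target, pr, n_chains = 10, n_iterations = 5000,
                      seed = 1234)
  s <- summarize_posterior(cs)
  expect_lt(max(abs(s$mean)), 0.1)
  expect_lt(max(abs(s$sd - 1) / 1), 0.15)
  expect_lt(max(s$rhat), 1.1)
  expect_error(demcmc_sample(target, pr, n_chains = 2,
                             n_iterations = 10, seed = 1), "3 chains")
})

test_that("with a flat likelihood DEMCMC reproduces the truncated-normal
          prior", {
  pr <- prior_spec(c("u", "v", "w"), mean = c(0.3, 5, 1),
                   sd = c(0.1, 2, 0.5), lower = c(0, 0, 0),
                   upper = c(2, 30, 10))
  lp <- function(th) log_prior(th, pr)
  cs <- demcmc_sample(lp, pr, n_chains = 12, n_iterations = 4000,
                      seed = 77)
  s <- summarize_posterior(cs)
  big <- sample_prior(100000, pr)
  for (j in 1:3) {
    expect_lt(abs(s$mean[j] - mean(big[, j])) / stats::sd(big[, j]), 0.1)
    expect_lt(abs(s$sd[j] - stats::sd(big[, j])) / stats::sd(big[, j]),
              0.1)
  }
  # draws respect the prior box
  pool <- pooled_draws(cs)
  expect_true(all(pool >= matrix(pr$lower, nrow(pool), 3, byrow = TRUE)))
  expect_true(all(pool <= matrix(pr$upper, nrow(pool), 3, byrow = TRUE)))
})

test_that("a population initialized at a single point cannot disperse", {
  pr <- prior_spec(c("a", "b"), mean = c(0, 0), sd = c(1, 1),
                   lower = c(-10, -10), upper = c(10, 10))
  target <- function(th) sum(stats::dnorm(th, 3, 1, log = TRUE))
  init <- matrix(0, nrow = 8, ncol = 2)
  cs <- demcmc_sample(target, pr, n_chains = 8, n_iterations = 200,
                      seed = 5, init = init, jitter_scale = 0)
  # with no jitter, proposals are differences of identical states: the
  # population can never leave the starting point
  expect_true(all(cs$draws == 0))
  # with jitter on, differential evolution amplifies the perturbations
  # and the population escapes (why dispersed initialization is standard)
  cs2 <- demcmc_sample(target, pr, n_chains = 8, n_iterations = 200,
                       seed = 5, init = init)
  expect_gt(max(abs(cs2$draws)), 0.1)
})

test_that("rank-normalized split R-hat separates mixed from unmixed
          chains", {
  set.seed(42)
  good <- matrix(stats::rnorm(2000 * 4), 2000, 4)
  expect_lt(rank_normalized_rhat(good), 1.01)

  shifted <- good
  shifted[, 1] <- shifted[, 1] + 10
  expect_gt(rank_normalized_rhat(shifted), 1.5)

  # deliberately unconverged: each chain stuck in its own mode
  modes <- matrix(rep(c(-5, 0, 5, 10), each = 500), 500, 4) +
    0.01 * stats::rnorm(2000)
  expect_gt(rank_normalized_rhat(modes), 1.1)

  expect_identical(rank_normalized_rhat(matrix(1, 100, 4)), 1)
  expect_error(rank_normalized_rhat(matrix(1, 2, 4)), "4 draws")
  # heavy-tailed draws do not break the diagnostic (rank normalization)
  heavy <- matrix(stats::rcauchy(4000), 1000, 4)
  expect_lt(rank_normalized_rhat(heavy), 1.02)
})

test_that("posterior summaries: moments, skewness and quartile
          conventions", {
  x <- c(1, 2, 3, 4, 10)
  expect_equal(skewness_g1(x), 36 / 10^1.5, tolerance = 1e-12)
  expect_equal(skewness_g1(c(-2, -1, 0, 1, 2)), 0)

  m <- matrix(rep(1:100, 2), 100, 2)
  cs <- fake_chain_set(array(m, c(100, 2, 1), list(NULL, NULL, "x")),
                       params = "x")
  s <- summarize_posterior(cs, burn_in = 0)
  expect_equal(c(s$q25, s$q50, s$q75), c(25.75, 50.5, 75.25))
  expect_equal(s$mean, 50.5)
  expect_error(summarize_posterior(cs, burn_in = 1), "burn_in")
})

test_that("clearance-production regression recovers exact and noisy
          slopes", {
  cl <- seq(1, 3, length.out = 1000)
  vin <- 2 * cl - 1
  cs <- fake_chain_set_from_matrix(cbind(cl, vin), c("CL", "V_in"))
  # exact collinearity makes lm warn about a perfect fit; that is the point
  r <- suppressWarnings(regress_cl_vin(cs, n_samples = 1000))
  expect_equal(r$lambda, 2, tolerance = 1e-10)
  expect_equal(r$mu, 1, tolerance = 1e-9)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)

  set.seed(6)
  cl2 <- stats::rnorm(1000, 2.5, 0.4)
  vin2 <- 2.16 * cl2 - 0.46 + stats::rnorm(1000, 0, 0.1)
  cs2 <- fake_chain_set_from_matrix(cbind(cl2, vin2), c("CL", "V_in"))
  r2 <- regress_cl_vin(cs2, n_samples = 1000)
  se <- 0.1 / (0.4 * sqrt(1000))
  expect_lt(abs(r2$lambda - 2.16), 3 * se)
  expect_gt(r2$r_squared, 0.9)

  degenerate <- fake_chain_set_from_matrix(
    cbind(rep(2, 100), stats::rnorm(100)), c("CL", "V_in"))
  expect_error(regress_cl_vin(degenerate, 100), "variance")
})

test_that("posterior-predictive bands collapse for a point-mass
          posterior", {
  th <- theta_ref_vec()
  draws <- array(rep(th, each = 40), c(10, 4, 10),
                 dimnames = list(NULL, NULL, names(th)))
  cs <- fake_chain_set(draws, names(th))
  pp <- posterior_predictive(cs, n_draws = 5, t_grid = seq(0, 63, 7))
  # zero up to floating cancellation at ~1e6 pM concentrations
  expect_lt(max(pp$sd), 1e-4)
  traj <- simulate_model(posterior_mean_params(),
                         t_grid = seq(0, 63, 7))
  expect_equal(pp$mean[, "v_aq"], traj$v_aq, tolerance = 1e-6)
  expect_equal(pp$n_dropped, 0)
  expect_error(posterior_predictive(cs, n_draws = 100), "exceeds")
})
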