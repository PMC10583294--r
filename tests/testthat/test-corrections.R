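test_that("CC time correction inverts the apparent-rate relation exactly", {
  r <- params_from_observables(0.3, 50)
  set.seed(41)
  for (i in 1:20) {
    theta <- runif(1, 0, 45)
    TR <- runif(1, 0.3, 5)
    app <- apparent_params(r, theta, TR)
    expect_lt(rel_err(cc_correct_time(app$tau, theta, TR), 50), 1e-12)
  }
  expect_equal(cc_correct_time(14.5, 0, 2), 14.5)
})

test_that("CC corrections reproduce the worked experimental examples", {
  # DNP-juice experiment: theta 7.1 deg, TR 1 s, eps' 106, tau' 24 s
  tau <- cc_correct_time(24, 7.1, 1)
  expect_lt(rel_err(cc_correct_amplitude(106, 24, tau), 130), 0.02)
  # natural-abundance experiment: theta 4.7 deg, TR 1 s, eps' 149, tau' 47 s
  tau2 <- cc_correct_time(47, 4.7, 1)
  expect_lt(rel_err(tau2, 56), 0.02)
  expect_lt(rel_err(cc_correct_amplitude(149, 47, tau2), 177), 0.02)
  # apparent 25 deg / TR 2 build-up time inverts back to ~50
  expect_lt(rel_err(cc_correct_time(14.5, 25, 2), 50), 0.02)
  # theta = 0 leaves the amplitude untouched (tau = tau')
  expect_equal(cc_correct_amplitude(0.3, 50, 50), 0.3)
})

test_that("non-physical CC corrections raise a classed error", {
  # RF depletion far faster than the apparent decay rate
  expect_error(cc_correct_time(20, 24.7, 0.5),
               class = "dnpcorr_nonphysical_correction")
  expect_error(cc_correct_time(367, 36.9, 2),
               class = "dnpcorr_nonphysical_correction")
  # message names the two competing rates
  expect_error(cc_correct_time(20, 24.7, 0.5), "depletion rate")
})

test_that("iterative correction is the identity at theta = 0", {
  r <- params_from_observables(0.3, 50)
  ts <- simulate_buildup(r, pulse_scheme(0, 2, duration = 200))
  res <- iterative_correct(ts, rate_sum = 0.02)
  expect_equal(res$series$signal, ts$signal, tolerance = 1e-14)
})

test_that("iterative correction recovers the RF-free build-up", {
  r <- params_from_observables(0.3, 50)
  for (theta in c(7, 25, 37)) {
    for (TR in c(1, 2)) {
      ts <- simulate_buildup(r, pulse_scheme(theta, TR, duration = 300))
      app <- apparent_params(r, theta, TR)
      res <- iterative_correct(ts, rate_sum = 1 / 50)
      truth <- polarization_at(ts$time, r)
      expect_lt(max(abs(res$series$signal - truth) / pmax(truth, 0.01)),
                0.02)
      # first point is exact without any correction
      expect_identical(res$series$signal[1], ts$signal[1])
      # over-injection terms are recorded for every step
      expect_length(res$delta, nrow(ts) - 1)
      expect_true(all(res$delta >= 0))
    }
  }
})

test_that("iterative and cos-power decay corrections agree without noise", {
  d <- simulate_decay(rate_params(0, 1 / 173),
                      pulse_scheme(7, 1, duration = 400), P_init = 0.3)
  it <- iterative_correct(d, rate_sum = 1 / 173)
  cp <- cos_power_correct(d)
  expect_lt(max(rel_err(it$series$signal, cp$series$signal)), 0.005)
})

test_that("cos-power correction is exact on noiseless pulsed decays", {
  set.seed(43)
  for (i in 1:10) {
    kR <- runif(1, 1e-3, 0.05)
    theta <- runif(1, 1, 37)
    TR <- runif(1, 0.5, 3)
    d <- simulate_decay(rate_params(0, kR), pulse_scheme(theta, TR, 60),
                        P_init = 0.4)
    cp <- cos_power_correct(d)
    expect_equal(cp$series$signal, 0.4 * exp(-kR * d$time),
                 tolerance = 1e-12)
    expect_lt(rel_err(cp$tau, 1 / kR), 1e-6)
  }
  # refuses build-ups, where the factor diverges
  b <- simulate_buildup(params_from_observables(0.3, 50),
                        pulse_scheme(7, 2, duration = 100))
  expect_error(cos_power_correct(b), "decays")
  # theta = 0 and single-point series are identities
  d0 <- simulate_decay(rate_params(0, 0.01), pulse_scheme(0, 1, 50), 0.3)
  expect_equal(cos_power_correct(d0)$series$signal, d0$signal)
})

test_that("the full pipeline recovers the ground truth", {
  r <- params_from_observables(0.3, 50)
  # theta = 0: everything reduces to the uncorrected fit
  ts0 <- simulate_buildup(r, pulse_scheme(0, 2, duration = 300))
  res0 <- correct_experiment(ts0)
  expect_lt(rel_err(res0$tau, 50), 1e-6)
  expect_lt(rel_err(res0$P0, 0.3), 1e-6)

  # noiseless 25 deg / TR 2 build-up: both parameters within 2 %
  ts <- simulate_buildup(r, pulse_scheme(25, 2, duration = 300))
  for (m in c("iterative", "cc")) {
    res <- correct_experiment(ts, method = m)
    expect_lt(rel_err(res$tau, 50), 0.02)
    # the CC amplitude relation is approximate at large flip angles
    expect_lt(rel_err(res$P0, 0.3), if (m == "cc") 0.08 else 0.02)
    # corrected parameters always exceed the apparent ones
    expect_gt(res$tau, res$uncorrected$estimate[["tau"]])
    expect_gt(res$P0, res$uncorrected$estimate[["P0"]])
  }

  # noisy at SNR ~40: within 10 % of the truth
  tsn <- simulate_buildup(r, pulse_scheme(25, 2, duration = 300),
                          noise_sigma = 3.2e-4, seed = 8)
  resn <- correct_experiment(tsn)
  expect_lt(rel_err(resn$tau, 50), 0.10)
  expect_lt(rel_err(resn$P0, 0.3), 0.10)
})

test_that("CC amplitude error grows with flip angle; iterative beats it at 25 deg", {
  r <- params_from_observables(0.3, 50)
  err <- function(theta, method) {
    ts <- simulate_buildup(r, pulse_scheme(theta, 2, duration = 300))
    rel_err(correct_experiment(ts, method = method)$P0, 0.3)
  }
  e_cc <- vapply(c(7, 12.5, 25), err, numeric(1), method = "cc")
  expect_lt(e_cc[1], 0.01)   # ~0.4 % at 7 deg
  expect_lt(e_cc[2], 0.02)   # ~1.2 % at 12.5 deg
  expect_lt(e_cc[3], 0.08)   # several % at 25 deg
  expect_true(all(diff(e_cc) > 0))
  expect_lt(err(25, "iterative"), e_cc[3])
})

test_that("the refinement loop records its trace and is honestly flagged", {
  r <- params_from_observables(0.3, 50)
  # gentle RF load: the fixed point sits next to the single-pass result
  ts_soft <- simulate_buildup(r, pulse_scheme(2.5, 2, duration = 300))
  res_soft <- correct_experiment(ts_soft, refine = TRUE)
  expect_true(res_soft$converged)
  expect_lt(rel_err(res_soft$tau, 50), 0.02)

  # heavy RF load with noise: the self-consistent rate sum drifts away
  # from the CC value; the loop must cap and flag rather than pretend
  ts <- simulate_buildup(r, pulse_scheme(25, 2, duration = 300),
                         noise_sigma = 3.2e-4, seed = 12)
  res <- correct_experiment(ts, refine = TRUE, max_iter = 10)
  expect_equal(nrow(res$trace), res$iterations)
  expect_lte(res$iterations, 10)
  if (!res$converged) expect_equal(res$iterations, 10L)
  # the single CC-rate pass remains the accurate default
  res1 <- correct_experiment(ts)
  expect_equal(res1$iterations, 1L)
  expect_lt(rel_err(res1$tau, 50), 0.10)
})

test_that("pipeline survives a non-physical decay correction via flags", {
  # measured decay faster than RF depletion alone can explain:
  # sin(theta)/TR >> 1/tau', as in strongly pulsed experimental decays
  t <- seq(0.5, 30, by = 0.5)
  d <- pol_series(t, 0.3 * exp(-t / 20), theta = 24.7, TR = 0.5,
                  mode = "decay")
  for (m in c("cc", "iterative")) {
    res <- correct_experiment(d, method = m)
    expect_false(res$converged)
    expect_true("nonphysical_cc_correction" %in% res$flags)
    expect_true(is.na(res$tau))
    # the uncorrected fit is still reported
    expect_true(res$uncorrected$converged)
    expect_lt(rel_err(res$uncorrected$estimate[["tau"]], 20), 0.01)
  }
})

test_that("non-uniform sampling is rejected by the recursion", {
  t <- c(1, 2, 3.5, 4)
  ts <- pol_series(t, rep(0.1, 4), theta = 7, TR = 1)
  expect_error(iterative_correct(ts, rate_sum = 0.02), "uniform")
})
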