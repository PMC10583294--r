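test_that("theta = 0 simulation coincides with the closed form", {
  r <- params_from_observables(0.3, 50)
  s <- pulse_scheme(0, 2, duration = 300)
  ts <- simulate_buildup(r, s)
  expect_equal(ts$signal, polarization_at(ts$time, r),
               tolerance = 1e-12)
  d <- simulate_decay(rate_params(0.006, 1 / 173),
                      pulse_scheme(0, 1, n_pulses = 200), P_init = 0.3)
  expect_equal(d$signal, 0.3 * exp(-d$time / 173), tolerance = 1e-12)
})

test_that("pre-pulse samples obey the geometric recurrence oracle", {
  set.seed(21)
  for (i in 1:12) {
    P0 <- runif(1, 0.05, 0.6)
    tau <- runif(1, 10, 200)
    theta <- runif(1, 0.5, 37)
    TR <- runif(1, 0.3, 5)
    P_init <- runif(1, 0, 0.5) * P0
    r <- params_from_observables(P0, tau)
    s <- pulse_scheme(theta, TR, n_pulses = 60)
    ts <- simulate_buildup(r, s, P_init = P_init)
    expect_equal(ts$signal,
                 oracle_pulsed_buildup(P0, tau, theta, TR, 60, P_init),
                 tolerance = 1e-12)
  }
})

test_that("long pulsed build-up settles at the reference apparent steady state", {
  r <- params_from_observables(0.3, 50)
  ts <- simulate_buildup(r, pulse_scheme(25, 2, duration = 400))
  expect_lt(rel_err(tail(ts$signal, 1), 0.091), 0.01)
})

test_that("pulsed decay follows its closed form exactly", {
  set.seed(22)
  for (i in 1:10) {
    kR <- runif(1, 1e-3, 0.1)
    theta <- runif(1, 0, 40)
    TR <- runif(1, 0.3, 5)
    P_init <- runif(1, 0.05, 0.9)
    d <- simulate_decay(rate_params(0, kR), pulse_scheme(theta, TR, 80),
                        P_init = P_init)
    expect_equal(d$signal, oracle_pulsed_decay(P_init, kR, theta, TR, 80),
                 tolerance = 1e-12)
  }
  # no relaxation: pure geometric pulse depletion
  g <- simulate_decay(rate_params(0.01, 0), pulse_scheme(10, 1, 30),
                      P_init = 0.5)
  expect_equal(g$signal, 0.5 * cos(10 * pi / 180)^(0:29),
               tolerance = 1e-12)
})

test_that("noise is Gaussian, reproducible and honest about its size", {
  r <- params_from_observables(0.3, 50)
  s <- pulse_scheme(2.5, 2, duration = 300)
  clean <- simulate_buildup(r, s)
  expect_identical(add_noise(clean, 0)$signal, clean$signal)

  n1 <- simulate_buildup(r, s, noise_sigma = 3.2e-4, seed = 99)
  n2 <- simulate_buildup(r, s, noise_sigma = 3.2e-4, seed = 99)
  expect_identical(n1$signal, n2$signal)

  big <- pol_series(seq_len(1e5), rep(0, 1e5), theta = 0, TR = 1)
  noisy <- add_noise(big, 0.02, seed = 5)
  expect_lt(abs(sd(noisy$signal - big$signal) - 0.02) / 0.02, 0.02)
})

test_that("noise amplitude is defined on the transverse signal", {
  # polarization-scale scatter must be sigma / sin(theta)
  r <- params_from_observables(0.3, 50)
  s <- pulse_scheme(25, 2, n_pulses = 5000)
  ts <- simulate_buildup(r, s, noise_sigma = 3.2e-4, seed = 7)
  clean <- simulate_buildup(r, s)
  expect_lt(abs(sd(ts$signal - clean$signal) -
                  3.2e-4 / sin(25 * pi / 180)) /
              (3.2e-4 / sin(25 * pi / 180)), 0.05)
  tv <- as_transverse(ts)
  expect_equal(tv$signal, ts$signal * sin(25 * pi / 180))
  expect_equal(as_polarization(tv)$signal, ts$signal, tolerance = 1e-15)
})

test_that("build-up from zero stays within physical bounds and orders by RF load", {
  r <- params_from_observables(0.3, 50)
  schemes <- list(c(2.5, 2), c(2.5, 1), c(7, 2), c(12.5, 2), c(25, 2))
  late <- vapply(schemes, function(sc) {
    ts <- simulate_buildup(r, pulse_scheme(sc[1], sc[2], duration = 300))
    expect_true(all(ts$signal >= 0 & ts$signal <= 0.3 + 1e-12))
    ts$signal[which.min(abs(ts$time - 290))]
  }, numeric(1))
  # stronger pulses or shorter TR sit lower at fixed late time
  expect_true(all(diff(late) < 0))
})

test_that("pre-pulse samples are exactly mono-exponential in time", {
  r <- params_from_observables(0.3, 50)
  ts <- simulate_buildup(r, pulse_scheme(12.5, 2, duration = 300))
  app <- apparent_params(r, 12.5, 2)
  model <- app$P0 * (1 - exp(-ts$time / app$tau))
  expect_lt(max(abs(ts$signal - model)), 1e-13)
})

test_that("time slicing converges to the analytic propagator", {
  r <- params_from_observables(0.3, 50)
  s <- pulse_scheme(25, 2, duration = 120)
  ana <- simulate_buildup(r, s)
  fine <- slice_integrate(r, s, dt = 2 / 1000)
  expect_lt(max(abs(fine$signal - ana$signal)), 1e-4)
  # first-order convergence: halving the step roughly halves the error
  e1 <- max(abs(slice_integrate(r, s, dt = 2 / 250)$signal - ana$signal))
  e2 <- max(abs(slice_integrate(r, s, dt = 2 / 500)$signal - ana$signal))
  expect_gt(e1 / e2, 1.5)
  expect_lt(e1 / e2, 3)
  # decay limit without injection
  d <- slice_integrate(rate_params(0.01, 0.02), pulse_scheme(0, 1, 50),
                       dt = 1 / 200, mode = "decay", P_init = 0.4)
  expect_equal(d$signal, 0.4 * exp(-0.02 * d$time), tolerance = 1e-4)
  expect_warning(slice_integrate(r, s, dt = 1), "coarser")
})

test_that("scheme construction checks its preconditions", {
  expect_error(pulse_scheme(25, 2, duration = 1), "empty series")
  expect_error(pulse_scheme(95, 2, n_pulses = 5), "theta")
  expect_error(pulse_scheme(25, 0, n_pulses = 5), "TR")
  expect_error(pulse_scheme(25, 2), "exactly one")
  expect_equal(pulse_scheme(25, 2, duration = 300)$n_pulses, 150L)
})
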