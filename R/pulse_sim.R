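#' RF readout scheme
#'
#' Describes a train of readout pulses: flip angle \code{theta}, fixed
#' repetition time \code{TR} and either the number of pulses or a total
#' duration.  Pulses occur at t = t0, t0 + TR, ... and the recorded sample
#' is the polarization immediately \emph{before} each pulse; afterwards
#' the longitudinal state is multiplied by cos(theta).  The default first
#' pulse time \code{t0 = TR} places samples at t = n TR.
#'
#' @param theta Flip angle in degrees, 0 <= theta < 90.
#' @param TR Repetition time (time units), > 0.
#' @param n_pulses Number of pulses (>= 1).  Give either this or
#'   \code{duration}.
#' @param duration Total acquisition time; the number of pulses is the
#'   largest n with t0 + (n-1) TR <= duration.
#' @param t0 Time of the first pulse, default \code{TR}.
#' @return An object of class \code{"pulse_scheme"}.
#' @export
#' @examples
#' pulse_scheme(theta = 25, TR = 2, duration = 300)
pulse_scheme <- function(theta, TR, n_pulses = NULL, duration = NULL,
                         t0 = TR) {
  check_theta(theta)
  check_TR(TR)
  if (is.null(n_pulses) == is.null(duration))
    stop("give exactly one of n_pulses or duration", call. = FALSE)
  if (!is.finite(t0) || t0 <= 0)
    stop("first-pulse time t0 must be positive", call. = FALSE)
  if (is.null(n_pulses)) {
    if (duration < t0)
      stop("empty series: duration shorter than the first pulse time",
           call. = FALSE)
    n_pulses <- floor((duration - t0) / TR) + 1
  }
  n_pulses <- as.integer(n_pulses)
  if (n_pulses < 1) stop("n_pulses must be >= 1", call. = FALSE)
  structure(list(theta = theta, TR = TR, n_pulses = n_pulses, t0 = t0),
            class = "pulse_scheme")
}

#' @export
print.pulse_scheme <- function(x, ...) {
  cat(sprintf(
    "Pulse scheme: theta = %g deg, TR = %g, %d pulses (t0 = %g)\n",
    x$theta, x$TR, x$n_pulses, x$t0))
  invisible(x)
}

#' Sampled polarization time series
#'
#' A data frame (columns \code{time}, \code{signal}) carrying acquisition
#' metadata as attributes: flip angle, repetition time, mode (build-up or
#' decay), signal scale, noise level and seed.  On the
#' \code{"polarization"} scale the signal is the longitudinal polarization
#' reconstructed from the measurement (transverse signal divided by
#' sin(theta)); on the \code{"transverse"} scale it is the measured
#' quantity sin(theta) P.
#'
#' @param time Strictly increasing sample times.
#' @param signal Signal values, same length as \code{time}.
#' @param theta Flip angle in degrees.
#' @param TR Repetition time.
#' @param mode \code{"buildup"} or \code{"decay"}.
#' @param scale \code{"polarization"} or \code{"transverse"}.
#' @param noise_sigma Standard deviation of the additive noise on the
#'   transverse (measured) signal; 0 for noiseless data.
#' @param seed RNG seed used to generate the noise, or NULL.
#' @param time_unit Opaque unit label carried through, never converted.
#' @return An object of classes \code{"pol_series"} and
#'   \code{"data.frame"}.
#' @export
pol_series <- function(time, signal, theta, TR, mode = "buildup",
                       scale = "polarization", noise_sigma = 0,
                       seed = NULL, time_unit = "a.u.") {
  if (length(time) != length(signal))
    stop("time and signal must have equal length", call. = FALSE)
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("sample times must be strictly increasing", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  mode <- match.arg(mode, c("buildup", "decay"))
  scale <- match.arg(scale, c("polarization", "transverse"))
  structure(data.frame(time = time, signal = signal),
            theta = theta, TR = TR, mode = mode, scale = scale,
            noise_sigma = noise_sigma, seed = seed, time_unit = time_unit,
            class = c("pol_series", "data.frame"))
}

series_meta <- function(ts) {
  list(theta = attr(ts, "theta"), TR = attr(ts, "TR"),
       mode = attr(ts, "mode"), scale = attr(ts, "scale"),
       noise_sigma = attr(ts, "noise_sigma"), seed = attr(ts, "seed"),
       time_unit = attr(ts, "time_unit"))
}

#' @export
print.pol_series <- function(x, ...) {
  m <- series_meta(x)
  cat(sprintf(
    "Polarization series: %d samples, %s, theta = %g deg, TR = %g %s\n",
    nrow(x), m$mode, m$theta, m$TR, m$time_unit))
  cat(sprintf("  scale = %s, noise_sigma = %g%s\n", m$scale, m$noise_sigma,
              if (is.null(m$seed)) "" else sprintf(", seed = %d", m$seed)))
  NextMethod()
}

#' @export
plot.pol_series <- function(x, ...) {
  m <- series_meta(x)
  args <- list(x = x$time, y = x$signal,
               xlab = sprintf("time (%s)", m$time_unit),
               ylab = if (m$scale == "polarization") "polarization"
                      else "transverse signal",
               main = sprintf("%s, theta = %g deg, TR = %g",
                              m$mode, m$theta, m$TR))
  do.call(graphics::plot, modifyList(args, list(...)))
  invisible(x)
}

#' Convert a series between polarization and transverse scale
#'
#' Multiplies or divides by sin(theta).  A theta = 0 series has no
#' transverse signal and is refused.
#'
#' @param ts A [pol_series()].
#' @return The converted series.
#' @export
as_transverse <- function(ts) {
  stopifnot(inherits(ts, "pol_series"))
  m <- series_meta(ts)
  if (m$scale == "transverse") return(ts)
  if (m$theta == 0)
    stop("a theta = 0 series has no transverse signal", call. = FALSE)
  out <- ts
  out$signal <- ts$signal * sin(deg2rad(m$theta))
  attr(out, "scale") <- "transverse"
  out
}

#' @rdname as_transverse
#' @export
as_polarization <- function(ts) {
  stopifnot(inherits(ts, "pol_series"))
  m <- series_meta(ts)
  if (m$scale == "polarization") return(ts)
  out <- ts
  out$signal <- ts$signal / sin(deg2rad(m$theta))
  attr(out, "scale") <- "polarization"
  out
}

# Noiseless pre-pulse samples of the pulsed rate-equation dynamics.
# Between pulses the state follows the closed form of polarization_at();
# each pulse multiplies the state by cos(theta).
pulsed_samples <- function(params, scheme, P_init, kW_zero = FALSE) {
  obs <- observables_from_params(params)
  P0 <- if (kW_zero) 0 else obs$P0
  tau <- if (kW_zero) 1 / max(params$kR, .Machine$double.xmin) else obs$tau
  ct <- cos(deg2rad(scheme$theta))
  n <- scheme$n_pulses
  times <- scheme$t0 + (seq_len(n) - 1) * scheme$TR
  P <- numeric(n)
  if (kW_zero && params$kR == 0) {
    # pure pulse depletion, no relaxation
    P <- P_init * ct^(seq_len(n) - 1)
    return(list(times = times, P = P))
  }
  e0 <- exp(-scheme$t0 / tau)
  eTR <- exp(-scheme$TR / tau)
  p <- P0 + (P_init - P0) * e0
  for (i in seq_len(n)) {
    P[i] <- p
    p <- P0 + (p * ct - P0) * eTR
  }
  list(times = times, P = P)
}

# Turn clean polarization samples into a measured series, optionally
# adding Gaussian noise of sd `noise_sigma` on the transverse signal
# (directly on the polarization if theta = 0, where no transverse channel
# exists).
measure_samples <- function(times, P, scheme, mode, noise_sigma, seed) {
  st <- sin(deg2rad(scheme$theta))
  signal <- P
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    eps <- rnorm(length(P), mean = 0, sd = noise_sigma)
    signal <- if (scheme$theta > 0) (st * P + eps) / st else P + eps
  }
  pol_series(times, signal, theta = scheme$theta, TR = scheme$TR,
             mode = mode, scale = "polarization",
             noise_sigma = noise_sigma, seed = seed)
}

#' Simulate a pulsed build-up experiment
#'
#' Exact piecewise-analytic propagation of the rate equation with readout
#' pulses: between pulses the closed-form solution advances the state, at
#' each pulse time the pre-pulse polarization is recorded and the state is
#' multiplied by cos(theta).  At theta = 0 the samples coincide with the
#' unperturbed closed form.  Optional Gaussian noise (standard deviation
#' \code{noise_sigma}) is added on the transverse signal sin(theta) P; the
#' returned series is on the polarization scale.
#'
#' @param params A [rate_params()] object.
#' @param scheme A [pulse_scheme()].
#' @param P_init Initial polarization, default 0.
#' @param noise_sigma Noise standard deviation (transverse signal units).
#' @param seed RNG seed for the noise, or NULL to use the current RNG
#'   state.
#' @return A [pol_series()] on the polarization scale.
#' @export
#' @examples
#' r <- params_from_observables(0.3, 50)
#' s <- pulse_scheme(25, 2, duration = 300)
#' ts <- simulate_buildup(r, s)
#' tail(ts$signal, 1)  # apparent steady state ~0.091
simulate_buildup <- function(params, scheme, P_init = 0, noise_sigma = 0,
                             seed = NULL) {
  stopifnot(inherits(params, "rate_params"),
            inherits(scheme, "pulse_scheme"))
  if (P_init < 0 || P_init > params$A)
    stop("P_init must lie in [0, A]", call. = FALSE)
  sim <- pulsed_samples(params, scheme, P_init)
  measure_samples(sim$times, sim$P, scheme, "buildup", noise_sigma, seed)
}

#' Simulate a pulsed decay experiment
#'
#' As [simulate_buildup()] but with the injection term removed
#' (\code{kW = 0}), so the underlying dynamics are a pure exponential
#' relaxation punctuated by pulse depletion.  The pre-pulse sample n obeys
#' the closed form \code{P_init cos^(n-1)(theta) exp(-kR t_n)}.
#'
#' @inheritParams simulate_buildup
#' @param params A [rate_params()] object; only \code{kR} is used, any
#'   \code{kW} is ignored.
#' @param P_init Initial polarization, > 0 (the polarization created
#'   before the decay measurement).
#' @return A [pol_series()] with mode \code{"decay"}.
#' @export
#' @examples
#' d <- simulate_decay(rate_params(0, 1/173), pulse_scheme(7, 1, 100), 0.3)
simulate_decay <- function(params, scheme, P_init, noise_sigma = 0,
                           seed = NULL) {
  stopifnot(inherits(params, "rate_params"),
            inherits(scheme, "pulse_scheme"))
  if (!is.finite(P_init) || P_init <= 0)
    stop("decay requires a positive initial polarization", call. = FALSE)
  sim <- pulsed_samples(params, scheme, P_init, kW_zero = TRUE)
  measure_samples(sim$times, sim$P, scheme, "decay", noise_sigma, seed)
}

#' Add measurement noise to a series
#'
#' Adds independent Gaussian noise in the units of the series' current
#' scale.  Identical seeds give bitwise-identical output; \code{sigma = 0}
#' returns the input unchanged.
#'
#' @param ts A [pol_series()].
#' @param sigma Noise standard deviation (units of the current scale).
#' @param seed RNG seed, or NULL.
#' @return The noisy series; \code{noise_sigma} metadata is updated (noise
#'   on a polarization-scale series is recorded as the equivalent
#'   transverse amplitude sin(theta) sigma when theta > 0).
#' @export
add_noise <- function(ts, sigma, seed = NULL) {
  stopifnot(inherits(ts, "pol_series"))
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(ts)
  if (!is.null(seed)) set.seed(seed)
  m <- series_meta(ts)
  out <- ts
  out$signal <- ts$signal + rnorm(nrow(ts), 0, sigma)
  sigma_t <- if (m$scale == "polarization" && m$theta > 0)
    sigma * sin(deg2rad(m$theta)) else sigma
  attr(out, "noise_sigma") <- m$noise_sigma + sigma_t
  attr(out, "seed") <- seed
  out
}

#' Fixed-step time-slicing integration of the pulsed dynamics
#'
#' Explicit Euler integration of the rate equation between pulses,
#' mirroring a time-slicing simulation; the analytic propagator of
#' [simulate_buildup()] is the reference this cross-validates.  The step
#' is rounded so that an integer number of slices fits into each TR
#' interval.
#'
#' @inheritParams simulate_buildup
#' @param dt Integration step; should be <= TR/10, coarser steps are
#'   accepted but flagged in the result metadata.
#' @param mode \code{"buildup"} or \code{"decay"} (the latter forces
#'   \code{kW = 0}).
#' @return A [pol_series()]; attribute \code{dt_warning} is TRUE when the
#'   requested step was coarser than TR/10.
#' @export
slice_integrate <- function(params, scheme, dt, P_init = 0,
                            mode = c("buildup", "decay")) {
  stopifnot(inherits(params, "rate_params"),
            inherits(scheme, "pulse_scheme"))
  mode <- match.arg(mode)
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  coarse <- dt > scheme$TR / 10
  if (coarse)
    warning("integration step coarser than TR/10; result flagged")
  kW <- if (mode == "decay") 0 else params$kW
  kR <- params$kR
  A <- params$A
  ct <- cos(deg2rad(scheme$theta))
  step_to <- function(p, interval) {
    nstep <- max(1L, as.integer(round(interval / dt)))
    h <- interval / nstep
    for (i in seq_len(nstep)) p <- p + ((A - p) * kW - kR * p) * h
    p
  }
  n <- scheme$n_pulses
  times <- scheme$t0 + (seq_len(n) - 1) * scheme$TR
  P <- numeric(n)
  p <- step_to(P_init, scheme$t0)
  for (i in seq_len(n)) {
    P[i] <- p
    p <- step_to(p * ct, scheme$TR)
  }
  out <- pol_series(times, P, theta = scheme$theta, TR = scheme$TR,
                    mode = mode, scale = "polarization")
  attr(out, "dt") <- dt
  attr(out, "dt_warning") <- coarse
  out
}
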