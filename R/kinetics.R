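#' Rate-equation parameters of the hyperpolarization model
#'
#' The single-compartment model describes the nuclear polarization P by
#' \deqn{dP/dt = (A - P) k_W - k_R P,}
#' where \code{A} is the polarization capacity (the total density of states
#' available to the hyperpolarization process, bounded by the thermal
#' electron polarization in DNP), \code{kW} the polarization injection rate
#' constant and \code{kR} the relaxation rate constant.
#'
#' @param kW Injection rate constant (1/time), >= 0.
#' @param kR Relaxation rate constant (1/time), >= 0.
#' @param A Polarization capacity, in (0, 1].  Defaults to 1 for pure
#'   simulations; for DNP experiments the thermal electron polarization
#'   (see [thermal_polarization()]) is the physically motivated value.
#' @return An object of class \code{"rate_params"}.
#' @seealso [params_from_observables()], [observables_from_params()]
#' @export
#' @examples
#' rate_params(kW = 0.006, kR = 0.014)
rate_params <- function(kW, kR, A = 1) {
  stopifnot(is.numeric(kW), is.numeric(kR), is.numeric(A),
            length(kW) == 1, length(kR) == 1, length(A) == 1)
  if (!is.finite(A) || A <= 0 || A > 1)
    stop("capacity A must lie in (0, 1]", call. = FALSE)
  if (!is.finite(kW) || kW < 0) stop("kW must be >= 0", call. = FALSE)
  if (!is.finite(kR) || kR < 0) stop("kR must be >= 0", call. = FALSE)
  if (kW + kR <= 0)
    stop("degenerate model: kW + kR must be positive", call. = FALSE)
  structure(list(A = A, kW = kW, kR = kR), class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat(sprintf("Rate-equation parameters: A = %g, kW = %g, kR = %g\n",
              x$A, x$kW, x$kR))
  obs <- observables_from_params(x)
  cat(sprintf("  (steady state P0 = %.6g, build-up tau = %.6g)\n",
              obs$P0, obs$tau))
  invisible(x)
}

#' Convert measured observables to rate constants
#'
#' Inverts the steady-state and time-constant relations of the rate
#' equation: \code{kW = P0 / (A tau)} and \code{kR = (1 - P0/A) / tau}.
#'
#' @param P0 Steady-state polarization, 0 < P0 < A.
#' @param tau Build-up time constant, > 0.
#' @param A Polarization capacity, see [rate_params()].
#' @return A [rate_params()] object.
#' @export
#' @examples
#' params_from_observables(P0 = 0.3, tau = 50, A = 1)
params_from_observables <- function(P0, tau, A = 1) {
  stopifnot(length(P0) == 1, length(tau) == 1, length(A) == 1)
  if (!is.finite(tau) || tau <= 0)
    stop("tau must be positive", call. = FALSE)
  if (!is.finite(P0) || P0 < 0)
    stop("P0 must be non-negative", call. = FALSE)
  if (P0 >= A)
    stop("invalid observables: P0 >= A would force kR < 0", call. = FALSE)
  rate_params(kW = P0 / (A * tau), kR = (1 - P0 / A) / tau, A = A)
}

#' Steady state and build-up time constant of a rate-parameter set
#'
#' Computes the phenomenological observables \code{P0 = A kW / (kW + kR)}
#' and \code{tau = 1 / (kW + kR)} that a mono-exponential fit of the
#' unperturbed build-up recovers.
#'
#' @param params A [rate_params()] object.
#' @return A list of class \code{"phenom_params"} with elements \code{P0}
#'   and \code{tau}.
#' @export
#' @examples
#' observables_from_params(rate_params(0.006, 0.014))
observables_from_params <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  ksum <- params$kW + params$kR
  if (ksum <= 0) stop("degenerate model: kW + kR = 0", call. = FALSE)
  structure(list(P0 = params$A * params$kW / ksum, tau = 1 / ksum),
            class = "phenom_params")
}

#' @export
print.phenom_params <- function(x, ...) {
  cat(sprintf("Phenomenological parameters: P0 = %.6g, tau = %.6g\n",
              x$P0, x$tau))
  invisible(x)
}

#' Closed-form polarization at time t
#'
#' Exact solution of the rate equation from an arbitrary initial
#' polarization: \code{P(t) = P0 + (P_init - P0) exp(-(kW + kR) t)}, with
#' \code{P0} the steady state.  With \code{kW = 0} this reduces to the
#' exponential decay \code{P_init exp(-kR t)}.
#'
#' @param t Time(s), >= 0.  Vectorized.
#' @param params A [rate_params()] object.
#' @param P_init Initial polarization in [0, A], default 0.
#' @return Polarization value(s), same length as \code{t}.
#' @export
#' @examples
#' polarization_at(c(0, 50, 1e6), params_from_observables(0.3, 50))
polarization_at <- function(t, params, P_init = 0) {
  stopifnot(inherits(params, "rate_params"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and non-negative", call. = FALSE)
  if (P_init < 0 || P_init > params$A)
    stop("P_init must lie in [0, A]", call. = FALSE)
  obs <- observables_from_params(params)
  obs$P0 + (P_init - obs$P0) * exp(-t / obs$tau)
}

#' Thermal equilibrium polarization of a spin-1/2 species
#'
#' Spin-1/2 closed form \code{P_eq = tanh(h f / (2 k_B T))} with Planck and
#' Boltzmann constants in SI units.  At the field of a 299 MHz 1H system
#' and 3.3 K the electron polarization evaluates to 0.89, the capacity
#' relevant for DNP.
#'
#' @param frequency Larmor frequency in Hz, > 0.
#' @param temperature Temperature in K, > 0.
#' @return Equilibrium polarization in (0, 1).
#' @seealso [electron_frequency()]
#' @export
#' @examples
#' thermal_polarization(electron_frequency(299e6), 3.3)  # ~0.89
thermal_polarization <- function(frequency, temperature) {
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    stop("frequency must be positive", call. = FALSE)
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("temperature must be positive", call. = FALSE)
  tanh(PLANCK_H * frequency / (2 * BOLTZMANN_K * temperature))
}

#' Electron Larmor frequency at the field of a given 1H frequency
#'
#' Scales a proton Larmor frequency by the magnitude of the
#' electron-to-proton gyromagnetic ratio (658.21).
#'
#' @param proton_frequency 1H Larmor frequency in Hz.
#' @return Electron Larmor frequency in Hz.
#' @export
electron_frequency <- function(proton_frequency) {
  proton_frequency * ELECTRON_PROTON_RATIO
}

#' Convert between enhancement and absolute polarization
#'
#' The enhancement of a hyperpolarized signal is defined relative to the
#' thermal equilibrium polarization, \code{eps = P_hyp / P_eq}.
#'
#' @param eps Enhancement, >= 0.
#' @param P_eq Thermal equilibrium polarization in (0, 1).
#' @return Absolute polarization \code{eps * P_eq}.
#' @export
#' @examples
#' enhancement_to_polarization(133, thermal_polarization(299e6, 3.3))
enhancement_to_polarization <- function(eps, P_eq) {
  if (any(eps < 0)) stop("enhancement must be >= 0", call. = FALSE)
  if (any(P_eq <= 0) || any(P_eq >= 1))
    stop("P_eq must lie in (0, 1)", call. = FALSE)
  eps * P_eq
}

#' @rdname enhancement_to_polarization
#' @param P Absolute polarization.
#' @export
polarization_to_enhancement <- function(P, P_eq) {
  if (any(P_eq <= 0) || any(P_eq >= 1))
    stop("P_eq must lie in (0, 1)", call. = FALSE)
  P / P_eq
}

#' Apparent (RF-perturbed) build-up parameters
#'
#' Analytic fixed point of the pulse-and-relax recurrence.  Sampling the
#' polarization immediately before each pulse (pulses at t = n TR,
#' depletion by cos(theta)) yields a sequence that is exactly
#' mono-exponential with
#' \deqn{\tau' = \left(1/\tau - \ln\cos\theta / T_R\right)^{-1}}
#' and pre-pulse steady state
#' \deqn{P_0' = P_0 \frac{1 - e^{-T_R/\tau}}{1 - \cos\theta\, e^{-T_R/\tau}}.}
#' A fit of the build-up ansatz to noiseless pulsed samples recovers these
#' values exactly; they are the analytic oracle for the simulator and the
#' inverse of the CC time-constant correction.
#'
#' @param params A [rate_params()] object.
#' @param theta Flip angle in degrees, 0 <= theta < 90.
#' @param TR Repetition time, > 0.
#' @return A \code{"phenom_params"} list with apparent \code{P0} and
#'   \code{tau}.
#' @export
#' @examples
#' apparent_params(params_from_observables(0.3, 50), theta = 25, TR = 2)
apparent_params <- function(params, theta, TR) {
  check_theta(theta)
  check_TR(TR)
  obs <- observables_from_params(params)
  if (theta == 0) return(obs)
  ct <- cos(deg2rad(theta))
  e <- exp(-TR / obs$tau)
  structure(list(
    P0 = obs$P0 * (1 - e) / (1 - ct * e),
    tau = 1 / (1 / obs$tau - log(ct) / TR)
  ), class = "phenom_params")
}

#' Apparent relaxation rate of an RF readout scheme
#'
#' The heuristic depletion scale \code{sin(theta) / TR}: the rate at which
#' a readout scheme consumes polarization, comparable to a relaxation rate
#' constant.  Useful for ordering experiments by the severity of the RF
#' perturbation.
#'
#' @inheritParams apparent_params
#' @return Rate in 1/time units.
#' @export
#' @examples
#' rf_relaxation_rate(7.1, 1)   # ~0.12 per second
rf_relaxation_rate <- function(theta, TR) {
  check_theta(theta)
  check_TR(TR)
  sin(deg2rad(theta)) / TR
}

check_theta <- function(theta) {
  if (length(theta) != 1 || !is.finite(theta) || theta < 0 || theta >= 90)
    stop("flip angle theta must lie in [0, 90) degrees", call. = FALSE)
  invisible(theta)
}

check_TR <- function(TR) {
  if (length(TR) != 1 || !is.finite(TR) || TR <= 0)
    stop("repetition time TR must be positive", call. = FALSE)
  invisible(TR)
}
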