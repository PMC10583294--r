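# dnpcorr

Rate-equation modelling and RF-pulse correction for hyperpolarized NMR.

## The problem

Monitoring the build-up or decay of hyperpolarization — in dynamic
nuclear polarization (DNP), spin-exchange optical pumping, para-hydrogen
techniques — requires radio-frequency readout pulses, and every pulse of
flip angle θ converts part of the longitudinal polarization into signal,
leaving only cos θ of it behind. The measurement therefore perturbs the
dynamics it observes: fitted build-up/decay curves report an *apparent*
steady state P₀′ and time constant τ′ that can underestimate the true
values severely (a 25° readout every 2 time units turns τ = 50 into
τ′ ≈ 14.5 and P₀ = 0.30 into P₀′ ≈ 0.09).

`dnpcorr` is for experimentalists who want to use intermediate flip
angles (better SNR, faster measurements) and correct the perturbation
afterwards.

## The model and the corrections

The polarization P obeys a single-compartment rate equation with an
injection term (rate constant k_W, capacity A) and a relaxation term
(k_R):

    dP/dt = (A − P) k_W − k_R P

whose solution is mono-exponential with steady state
P₀ = A·k_W/(k_W + k_R) and time constant τ = 1/(k_W + k_R); setting
k_W = 0 gives the decay experiment, τ_decay = 1/k_R. Under pulsed
readout (pre-pulse sampling at t = n·TR, depletion by cos θ) the sampled
sequence is still exactly mono-exponential, with

    1/τ′ = 1/τ − ln(cos θ)/TR
    P₀′  = P₀ (1 − e^(−TR/τ)) / (1 − cos θ · e^(−TR/τ))

Three corrections recover the unperturbed parameters from measured data:

* **CC (analytical)** — treat RF pulsing as an apparent relaxation
  channel: τ = (1/τ′ + ln(cos θ)/TR)⁻¹ and P₀ = P₀′·τ/τ′ (exact for τ,
  approximate for P₀ at large θ).
* **Iterative (per point)** — reconstruct the RF-free curve sample by
  sample, restoring the pulse depletion and removing the DNP
  over-injection term Δ = (P̃ − cos θ·P)(k_W + k_R)·TR at every step,
  then refit.
* **1/cosⁿ⁻¹ (decays only)** — multiply the n-th point by cos^−(n−1) θ;
  exact without noise, noise-amplifying with it.

## Worked example

```r
library(dnpcorr)

# how strongly does readout perturb the observables?
reproduce_table1()
#>   theta TR tau_apparent P0_apparent
#> 1   2.5  2     48.83739  0.29316293
#> 2   2.5  1     47.72761  0.28650159
#> 3   7.0  2     42.12143  0.25366887
#> 4  12.5  2     31.25515  0.18977411
#> 5  25.0  2     14.45334  0.09102573

# correct a strongly pulsed build-up back to the truth (P0 = 0.3, tau = 50)
r  <- params_from_observables(P0 = 0.3, tau = 50, A = 1)
ts <- simulate_buildup(r, pulse_scheme(theta = 25, TR = 2, duration = 300))
correct_experiment(ts)
#> RF correction (iterative)
#>   uncorrected: P0' = 0.0910257, tau' = 14.4533
#>   corrected:   P0  = 0.295752, tau  = 49.1108
#>   rate sum kW + kR = 0.02 (1/time)

# analytical correction of a measured enhancement
# (7.1 deg pulses every 1 s; uncorrected enhancement 106, tau' 24 s)
tau <- cc_correct_time(24, theta = 7.1, TR = 1)   # 29.44 s
cc_correct_amplitude(106, 24, tau)                # 130.02

# the thermal electron polarization that bounds A in DNP at 7 T, 3.3 K
thermal_polarization(electron_frequency(299e6), 3.3)
#> [1] 0.8918881
```

The apparent 14.45/0.091 become 49.1/0.296 after the iterative
correction — within 2 % of the true 50/0.30; the analytical correction
turns the measured enhancement 106 into 130.

## Command line

```sh
inst/cli/dnpcorr simulate --theta 7 --tr 2 --noise 3.2e-4 --seed 1 --out buildup.csv
inst/cli/dnpcorr correct --in buildup.csv --json report.json
inst/cli/dnpcorr study --study minsnr --seed 1 --out minsnr.csv
```

`correct` reports uncorrected, CC and iterative (and, for decays,
1/cosⁿ⁻¹) parameters side by side as JSON, with full provenance (seed,
version, config hash). Input CSVs carry their metadata in `#` header
comments; command-line flags override them.

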