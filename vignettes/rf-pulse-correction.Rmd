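---
title: "Correcting RF-pulse effects in hyperpolarization measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting RF-pulse effects in hyperpolarization measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

`dnpcorr` describes the nuclear polarization $P$ of a hyperpolarized
sample by a single-compartment rate equation

$$\frac{dP}{dt} = (A - P)\,k_W - k_R\,P,$$

with three parameters: the polarization capacity $A$ (the total density
of states available to the hyperpolarization process — in DNP bounded by
the thermal electron polarization), the injection rate constant $k_W$
and the relaxation rate constant $k_R$. The solution is
mono-exponential; comparing it with the phenomenological ansatz
$P_{\mathrm{exp}}(t) = P_0(1 - e^{-t/\tau})$ identifies

$$P_0 = A\,\frac{k_W}{k_W + k_R}, \qquad \tau^{-1} = k_W + k_R,$$

inverted by `params_from_observables()`. Removing the injection term
($k_W = 0$) gives the decay experiment, $\tau_{\mathrm{decay}}^{-1} =
k_R$. The relaxation constant during a decay need not equal the one
during the build-up (microwaves off versus on), which is why the two
modes are fitted and corrected independently.

Assumptions inherited from the model: a *single* compartment (one pool
of spins with one injection and one relaxation channel — samples with
multi-exponential build-ups violate this and will be corrected
wrongly); thermal equilibrium polarization negligible against the
hyperpolarization; rate constants stationary over the measurement.

Flip angles are accepted in **degrees** at every public boundary; time
units are an opaque label (`"a.u."`, `"s"`) carried through and never
converted. $A$ defaults to 1 in pure simulations; for DNP work the
physically motivated value is the thermal electron polarization,
`thermal_polarization(electron_frequency(f_1H), T)`, the spin-1/2
closed form $\tanh(hf/2k_BT)$ with exact SI constants (0.89 at the
field of a 299 MHz proton system and 3.3 K).

## Pulsed readout and the sampling convention

A readout pulse of flip angle $\theta$ produces the measured transverse
signal $\sin\theta\,M_z$ and leaves $\cos\theta\,P$ longitudinal.
`simulate_buildup()`/`simulate_decay()` propagate the closed-form
solution between pulses and apply the $\cos\theta$ depletion at every
pulse — a piecewise-*analytic* propagator, so there is no hidden
step-size parameter. `slice_integrate()`, a fixed-step Euler slicer,
exists purely as a cross-validation oracle for that propagator (the
test suite checks first-order convergence of one to the other).

The recorded sample is the polarization **immediately before** each
pulse, with pulses at $t = n\,T_R$. This convention matters: the
pre-pulse sequence has the fixed point

$$P_0' = P_0\,\frac{1 - e^{-T_R/\tau}}{1 - \cos\theta\,e^{-T_R/\tau}},
\qquad \frac{1}{\tau'} = \frac{1}{\tau} - \frac{\ln\cos\theta}{T_R},$$

(`apparent_params()`), and it is this pair that noiseless pulsed
simulations plus mono-exponential fits reproduce to machine precision —
the pre-pulse sequence is *exactly* exponential in $n$, which is what
justifies using the mono-exponential ansatz on pulsed data at all.
Post-pulse sampling produces a different (lower) amplitude and does not
match the apparent steady states the model predicts.

Fits operate on the polarization scale (measured signal divided by
$\sin\theta$) so amplitudes are comparable across flip angles;
`as_transverse()`/`as_polarization()` convert a series between scales.

## Noise model and seeds

Noise is additive, homoscedastic and Gaussian on the **transverse**
(measured) signal, standard deviation `noise_sigma`; on the
polarization scale the scatter is therefore $\sigma/\sin\theta$. The
canonical noisy condition ($\sigma = 3.2\times10^{-4}$ with a
2.5° readout of the $P_0 = 0.3$, $\tau = 50$ model) corresponds to a
steady-state SNR near 40, where SNR is defined as
$\sin\theta\,P_0'/\sigma$ (`estimate_snr()`). A $\theta = 0$ series has
no transverse channel; it is treated as an idealized direct record of
the polarization and noise applies to it directly.

Every stochastic function takes an explicit seed. Study replicates
derive their seeds from a master seed via `child_seed()` (exact integer
arithmetic below $2^{53}$, values in $[1, 2^{31}-2]$), so studies are
reproducible bit for bit and individual replicates can be regenerated
in isolation.

## Estimation

`fit_buildup()`/`fit_decay()` minimize least squares with
Levenberg–Marquardt (`minpack.lm::nls.lm`) using analytic Jacobians.
Starting values are deterministic and derivative-free: the amplitude
from the last (build-up) or first (decay) decile mean, the time
constant from a log-linear regression of $\max(P) - P$ (build-up) or of
the positive signals (decay) on time, with fall-back
$\max(t)/6$. The time constant is bounded positive during
optimization. Gradient-orthogonality termination (the normal exit for
zero-residual problems) counts as convergence; iteration-limit exits
are flagged `not_converged`, numerical failures return an NA result
flagged `fit_failed` — never a silent value. Records shorter than one
fitted time constant are flagged `short_series` rather than refused.

Confidence intervals are linearized 95 % intervals from the fit
covariance — the convention for nonlinear least squares; profile
intervals would be more faithful at very low SNR but the corrections
themselves dominate the error budget there.

An optional additive offset (`with_offset = TRUE`) accommodates
experimental records whose first point is acquired late (spectrometer
loading delays): it stabilizes fits of real data at the cost of wider
intervals. Simulated data need no offset, so it defaults off in the
library and on in the command-line `correct` mode, which targets
spectrometer exports.

## The three corrections and their numerical behaviour

**CC (analytical).** `cc_correct_time()` removes the RF channel
$-\ln(\cos\theta)/T_R$ from the apparent rate — the exact inverse of
the apparent-rate relation above, so the $\tau$ round-trip is exact to
machine precision. `cc_correct_amplitude()` rescales $P_0 =
P_0'\,\tau/\tau'$; this rests on the injection rate being undisturbed
by pulsing and is *approximate*: the recovery error on noiseless data
grows from ~0.4 % at 7° to several per cent at 25° (the test suite
pins these bounds). When the RF depletion rate reaches the apparent
rate the corrected rate would be non-positive; this is a real failure
mode of strongly pulsed decay measurements, and the package signals it
as a classed condition (`dnpcorr_nonphysical_correction`) that the
pipeline converts into a flagged result, not a crash.

**Iterative.** `iterative_correct()` reconstructs the RF-free curve
point by point: add the measured increment, restore the pulse
depletion, subtract the over-injection caused by the RF-lowered
polarization, $\Delta = (\tilde P - \cos\theta\,P)(k_W+k_R)T_R$. The
first point needs no correction. The recursion assumes uniform spacing
at $T_R$ (non-uniform series are rejected, not approximated) and its
$\Delta$ term is a first-order rectangle rule in $T_R$, which is why
recovered parameters carry a residual error of order 1–2 % at the
largest flip angles. Noise-wise the recursion is benign: each corrected
point mixes a few measured points, unlike the divergent single-point
cos-power factor. Negative corrected values under noise are retained —
clipping would bias the refit.

**Rate sum.** The recursion needs $k_W + k_R = 1/\tau$.
`correct_experiment()` takes it from the CC-corrected time constant of
the uncorrected fit — a single pass, which already matches the
analytical correction on noiseless data. An optional fixed-point outer
loop (`refine = TRUE`, capped at 20 iterations, relative tolerance
$10^{-6}$) updates the rate sum from the refit of the corrected series.
At small flip angles the loop converges immediately; at large flip
angles its self-consistent fixed point inherits the recursion's
first-order bias and drifts a few per cent *away* from the single-pass
result before stalling at the iteration cap, which the result then
reports honestly (`converged = FALSE`, full trace). That drift is the
reason the single CC-rate pass is the default and the loop is an
explicitly requested refinement.

**1/cos^(n−1).** Decays only — on build-ups the factor diverges and the
function refuses to run. On noiseless pulsed decays the correction is
exact (the pulsed decay is $P_1\cos^{n-1}\theta\,e^{-k_R nT_R}$); under
noise the exponentially growing factor amplifies late-time scatter,
which is the documented reason fit-based methods are preferred at low
SNR.

All corrections are amplitude-scale invariant, so they apply to
enhancements exactly as to absolute polarizations;
`enhancement_to_polarization()` converts when a thermal reference is
available.

## The simulation studies

`reproduce_table1()` runs the noiseless scheme sweep (duration 300,
canonical model $P_0 = 0.3$, $\tau = 50$, $A = 1$) and tabulates the
apparent parameters per readout scheme.

`monte_carlo_accuracy()` simulates `n_rep` noisy experiments per grid
cell and summarizes mean, spread and relative bias of the corrected
parameters per method. The desk-scale default is 200 replicates per
cell — enough to resolve biases of a fraction of a per cent at SNR 40 —
with the replicate count exposed for full-scale (several-thousand
replicate) parity runs. At the canonical noise level both the CC and
the iterative correction recover $\tau$ and $P_0$ with biases well
inside the ±10 % accuracy scale at all tested flip angles; their
precisions are indistinguishable, while their small systematic
amplitude residuals differ in sign (CC high, iterative low) and grow
with flip angle, consistent with the approximation each method makes.

`min_snr_map()` sweeps steady state (10 steps, 0.01–0.1) and noise (10
steps, $3.2\times10^{-5}$–$3.2\times10^{-3}$; logarithmic, so the
resulting SNR axis is sampled evenly across its decades), corrects 100
noisy build-ups per cell, and reports per flip angle and method the
smallest uncorrected steady-state SNR from which every higher-SNR cell
keeps the corrected parameters within 10 % of the truth.

Two deviation measures are offered, and the choice is consequential.
The default, `"replicate"`, is the mean absolute relative deviation of
the per-replicate corrected parameters — the accuracy a *single*
corrected measurement can expect. With it, the packaged study finds a
minimum usable SNR of about 5 at small flip angles (2.5°, 7°) and a
substantially higher one at 25°, where the short apparent build-up
leaves few informative points per record. The alternative,
`"average"`, measures the deviation of the replicate-*averaged*
parameters; averaging cancels most of the scatter, so thresholds drop
to SNR ≈ 1.5 — true for a protocol that averages a hundred build-ups,
but misleading as a guideline for a single measurement, which is why it
is not the default.

## What the generator does and does not emulate

The simulator is the package's own fixture factory: every test input is
generated from the model. It reproduces the features that drive the
corrections — exact pulsed dynamics, pre-pulse sampling, homoscedastic
Gaussian detection noise at a controlled SNR. It does **not** emulate:
acquisition-start offsets (first point acquired late — handled at fit
time via the offset parameter, not simulated), drifts in microwave
power or temperature, flip-angle miscalibration, non-exponential
(multi-compartment) dynamics, $T_2^*$/FID structure, or dead-time
artefacts. Green tests therefore demonstrate correctness of the model
arithmetic and the corrections *under the model's assumptions*; on real
data the single-compartment assumption and stationarity must hold for
the corrected parameters to be trustworthy.

## Degenerate inputs and tie-breaks

Capacity outside $(0,1]$, $P_0 \ge A$, non-positive $\tau$ or $T_R$,
flip angles outside $[0°, 90°)$ and decreasing time columns are
errors. $\theta = 0$ is the exact identity everywhere (simulator,
corrections, pipeline). A duration shorter than one $T_R$ is an
empty-series error. Too few points for the requested parameter count is
an input error; a short-but-fittable record yields a flagged result.
The Euler slicer accepts steps coarser than $T_R/10$ but flags them in
the result metadata.

## Known limitations

Single compartment only; fixed flip angle and repetition time within a
record (variable-flip-angle schedules are out of scope); corrections
assume the same $\theta$, $T_R$ metadata that produced the data;
linearized confidence intervals; the decay-mode corrections degrade
earlier than build-up corrections as the RF depletion rate approaches
the relaxation rate, ultimately hitting the non-physical-correction
regime that the package flags rather than extrapolates.
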