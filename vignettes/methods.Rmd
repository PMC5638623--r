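---
title: "Grid-pattern formation from adaptation and STDP: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-pattern formation from adaptation and STDP: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, the numerical
choices, and what the synthetic benchmarks do and do not show.

## The model

A single output neuron receives `N` excitatory inputs whose rates are
spatial tuning curves evaluated along the trajectory of a virtual rat.
All spike trains are inhomogeneous Poisson processes. The output rate is
linear in the input spikes filtered by a biphasic adaptation kernel

$$K(t) = \frac{1}{\tau_S}e^{-t/\tau_S} - \frac{\mu}{\tau_L}e^{-t/\tau_L},
\qquad t \ge 0,$$

a brief excitation followed by a slow hyperpolarization — a band-pass
filter with DC gain $1-\mu$ and, for the defaults
($\tau_S = 0.1$ s, $\tau_L = 0.16$ s, $\mu = 1.06$), a resonance at
1.23 cycles/s. There is no reset after output spikes; adaptation is the
only intrinsic dynamics.

Synapses obey a symmetric exponential STDP window $W$ (integral
$W_{tot}$, width $\tau_W$) plus a local normalization term
$\eta(\beta - \alpha w_i)$ applied at every presynaptic spike, and a hard
non-negativity bound. Averaging the rule over spike statistics and over
the exploration gives the deterministic drift

$$\eta^{-1}\frac{d\bar w_i}{dt} = \sum_j C_{ij}\bar w_j - a\bar w_i + b,
\qquad \bar w_i \ge 0,$$

where $a = r_{av}[\alpha - \int W(s)K(-s)\,ds]$ and
$b = r_{av}(W_{tot} r_0 + \beta)$, both evaluated in closed form, and
$C_{ij}$ integrates the spatial cross-correlation of the tuning curves
over circles of radius $\tau v$, weighted by $K(\tau)$ — valid when
trajectories are smooth on the kernel's support and the arena is covered
ergodically.

For single-field Gaussian inputs on an even lattice, $C$ is translation
invariant and the linearized dynamics diagonalizes in Fourier space:

$$\lambda(k) = \rho W_{tot}\frac{4\pi^2}{L^2}\tilde G^2(k)
\tilde K_{sp}(k) - a,$$

with $\tilde G$ and $\tilde K_{sp}$ zeroth-order Hankel transforms and
$K_{sp}(r) = K(r/v)/(rv)$ the kernel mapped into space by the running
speed. A positive maximum at $k_{max} > 0$ is the Turing condition; modes
grow as $e^{\eta\lambda(k)t}$, so structure appears on the time scale
$\tau_{str} = 1/(\eta\lambda_{max})$. The defaults give
$k_{max} \approx 2.91$ cycles/m, $\lambda_{max} \approx 1.0$ s$^{-1}$ and,
with $\eta = 2\cdot10^{-5}$, $\tau_{str} \approx 5\cdot10^4$ s. The
linear theory is agnostic about which planform wins; the non-negativity
clamp is the nonlinearity that selects the triangular lattice, and the
package tests this directly by disabling it.

For spatially irregular inputs (each neuron summing $M$ Gaussian fields
with uniform random centers and amplitudes, normalized to a common mean
rate), the expected spectrum is the regular one attenuated by
$\Phi(M) = \frac{\pi}{3M}(\frac{4}{\pi} + \frac{1}{3M})$ for
$|k| > 1/L$, derived from Rayleigh statistics of the random phasor sum
(numerator) and Irwin–Hall moments of the amplitude sum (denominator).
The critical frequency is unchanged; only the growth rate shrinks.

## Frequency and sign conventions

All spatial frequencies are in **cycles per meter** and temporal
frequencies in cycles per second; every Fourier, Bessel and Hankel kernel
therefore carries the angular factor $2\pi k$ internally, e.g.
$\tilde K_{sp}(k) = \int_0^\infty K(\tau) J_0(2\pi k v \tau)\,d\tau$.
This is the only convention that reproduces $k_{max} = 3$ cycles/m and
$\lambda_{max} \approx 1$ s$^{-1}$ with the documented parameters. The
Bessel argument in the Gaussian closed form for $C(u)$ is evaluated as
$I_0(|u|\tau v / 2\sigma^2)$; $I_0$ is even, so the sign printed in some
renderings is immaterial. For the irregular spectrum we use the
$\Phi$-scaled positive term minus $a$ directly rather than any rearranged
"constant offset" form, whose sign is ambiguous across renderings.

## Numerical choices

* **Kernel quadrature horizon.** $|K(t)| < 0.01|K(0)|$ beyond
  $\tau_{max} = 5\tau_L$, and $\tau_{max}$ is the right truncation for
  raster/convolution purposes. The *integral* of the tail is not
  negligible, however: the kernel integral $1-\mu = -0.06$ is itself
  small, and the tail beyond $5\tau_L$ carries about 11% of it. All
  correlation quadratures therefore integrate to $50\tau_L$
  (Gauss–Legendre, 200 nodes on $(0, 5\tau_L]$ plus 120 on the tail),
  which reproduces the discrete normalization quantities
  ($\tau_{av} = 5.13\cdot10^3$ s, $w_{av}^\infty = 0.050$) to three
  digits.
* **Correlation operator, three routes.** (i) the Gaussian closed form
  (radial quadrature with scaled Bessel $I_0$ for numerical stability);
  (ii) the general correlogram route: periodic FFT cross-correlograms,
  circle-averaged at 256 angles by periodic bilinear interpolation;
  (iii) a Fourier-mode Gram factorization
  $C = A^H \mathrm{diag}(d) A$ built from the *analytic* torus Fourier
  coefficients of the tuning curves and the closed-form
  $\tilde K_{sp}$ — mathematically identical to (ii) with no gridding
  error, and cheap enough to integrate $N = 3600$ irregular ensembles.
  Routes are cross-checked against each other in the tests (<1%).
* **Integration.** Projected forward Euler with the documented 50 s step
  (stability is checked against $\eta\,dt\,|\lambda|$); the weight clamp
  is applied after each step. On regular lattices $C$ is block-circulant
  and $Cw$ is computed by 2D FFT; the mode-Gram route stores only a
  (modes × N) factor, with conjugate half-plane reduction and a
  $|k| \le 8$ cycles/m cut-off (Gaussian tuning leaves $<10^{-4}$
  relative power beyond it).
* **Spiking simulator.** 1 ms steps, zero-order-hold rates between 10 ms
  walk updates, at most one spike per channel per step (Bernoulli, error
  $O((r\,dt)^2)$), exact exponential traces for the two kernel components
  and for all-to-all STDP pairing (exact for an exponential window), and
  the update order Hebbian → normalization → clamp, which makes the
  $\eta \to 0$ limit match the averaged drift. Output rates are rectified
  at 0 before the Poisson draw; with the default baseline $r_0$
  rectification is rare and the linear analysis applies.
* **Output rate maps.** The spatial kernel $K_{sp}$ has an integrable
  $1/r$ singularity; the output map convolution is evaluated spectrally
  with its exact Hankel transform, so the singularity never needs
  rasterizing.
* **Gridness.** Torus (periodic) Pearson autocorrelograms, consistent
  with the model's periodic boundaries. Rotational correlations are
  computed on annuli (inner radius $R/2$, outer $R$, 24 candidate $R$
  between $0.7/k_{max}$ and $2.5/k_{max}$ — lengths in meters) sampled on
  a polar grid with radii spaced uniformly *in area*, matching the
  pixel-ring construction of the standard score; rotations are then
  exact in angle. Calibration: ideal triangular fixture ≈ 1.6, square
  lattice < 0, white noise ≈ 0. The triangular fixture places its
  *lattice axis* (peak direction) at the requested orientation; wave
  vectors lie 30° away.
* **OU speed.** The Ornstein–Uhlenbeck speed process is reflected at 0
  (the process is silent about negative excursions; reflection keeps
  speed physical and preserves the documented mean 0.25 m/s and s.d.
  0.02 m/s).
* **Initial weights.** Normal around $5\cdot10^{-3}$ (s.d. $10^{-4}$ for
  spiking runs, $10^{-3}$ for averaged runs), clamped at 0. The initial
  mean is exposed as a parameter because the documented target level and
  the documented initialization differ by an order of magnitude across
  configurations; $5\cdot10^{-3}$ is the default.

## Benchmark problem sizes

The deterministic analytic suite runs in seconds. The two stochastic
pattern-formation benchmarks are sized so the whole suite completes on a
single CPU in well under half an hour while remaining deep in the
nonlinear regime:

* *Regular inputs*: the robust published configuration ($L = 2$ m,
  $N = 3600$, $\sigma = 6.25$ cm, $\tau_L = 0.16$ s, $a = 4$, $b = 1.23$,
  $\eta = 5\cdot10^{-5}$, $t = 10^6$ s $\approx 36\,\tau_{str}$) with 10
  random initializations, integrated by FFT. A smaller desk variant that
  was considered ($N = 400$ on a 1 m arena with the 1 m-arena rates)
  is *not* used: at density 400 m$^{-2}$ the spectrum's positive term
  peaks below $a$ and no pattern can form — preserving the published
  density is essential when scaling down.
* *Irregular inputs*: the published configuration ($N = 3600$, $M = 10$,
  $L = 1$ m, $r_{av} = 0.8$ s$^{-1}$, $a = 2.5$, $b = 2.8$,
  $t = 10^6$ s) with 5 input realizations instead of 100. In a 10-seed
  pilot, 7/10 realizations exceeded gridness 0.5 with ensemble mean
  0.84, consistent with the documented 73/100 success rate and mean
  0.77; five realizations keep the majority/mean checks well-powered
  without dominating the suite's run time.

Full-scale presets (`parameterPreset()`, `scale = "full"`) expose the
original durations and ensemble designs unchanged.

## Tolerances in the validation suite

Deterministic closed forms are checked to $10^{-6}$ or better against
independent quadrature oracles. Stochastic checks use Monte-Carlo
standard errors (typically 4 SE) plus, where the *prediction itself* is
an approximation, an explicit systematic margin: the spiking-drift check
allows 10% because the averaged drift neglects the learning-window
smoothing (relative error of order $\tau_W v/\sigma \approx 0.2$) and
uses the smooth-trajectory circle approximation; the $\Phi(M)$ check
allows a $1/M$ relative margin because the closed form drops the
amplitude/path-length covariance, an $O(1/M)$-relative remainder (the
Monte-Carlo estimator is separately validated, to pure MC error, against
the exact identity
$\Phi = \mathbb{E}[\sum_m A_m^2 / (\sum_m A_m)^2]$ that holds under
uniform phases).

## What the synthetic benchmarks do not show

The generator emulates the model's own idealizations: periodic
boundaries, circular Gaussian fields covering the arena evenly, constant
(or OU-modulated) speed, and stationary input statistics. Passing tests
therefore demonstrate internal consistency of theory, simulation and
metrics — not that real entorhinal circuits learn grids this way. Border
effects (non-periodic arenas), non-circular or reward-biased fields,
recurrent connectivity, and biophysical adaptation mechanisms are out of
scope. Orientation statistics in particular depend strongly on the
boundary conditions: on a torus, grid orientations cluster according to
the pattern scale relative to the arena, so no claim about experimental
orientation distributions follows from these simulations.
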