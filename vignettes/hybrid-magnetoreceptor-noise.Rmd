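---
title: "Noise limits of a nanoparticle-amplified magnetoreceptor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise limits of a nanoparticle-amplified magnetoreceptor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnoise)
```

# The question

The avian magnetic compass is disrupted by broadband radio-frequency
magnetic noise of extremely low amplitude. Within the radical-pair
mechanism (RPM), an external field can only alter the singlet/triplet
yield if its spectral power density is comparable to that of the internal
random hyperfine fields already relaxing the electron spins. This package
quantifies that comparison, then asks whether a superparamagnetic
nanocrystal placed next to the cryptochrome could bridge the gap by
amplifying the external field — and shows that its own magnetization noise
forbids it. Everything is desk-scale arithmetic plus stochastic
simulation; there are no external data.

# Models

## Internal versus external field densities

Spin relaxation in an organic radical is characterised by the
zero-frequency inverse spectral density $J(0)^{-1}$ of the internal
hyperfine fields, in time units. With the electron gyromagnetic ratio
$\gamma_e = 176\ \mathrm{rad\,s^{-1}\,nT^{-1}}$,

$$ b^2_{int} = \frac{2\pi}{\gamma_e^2\, J(0)^{-1}} \quad [\mathrm{nT^2/Hz}]. $$

The factor $2\pi$ is a deliberate convention choice: spectral densities
quoted "per Hz" are $2\pi$ times the same two-sided density per rad/s.
Only with this factor does $J(0)^{-1} = 1\ \mu s$ reproduce the accepted
$\approx 200\ \mathrm{nT^2/Hz}$ (the raw rad/s route gives $\approx 32$).
The conversion lives in one place (`angular_psd_to_per_hz()`) and is
applied exactly once.

Applied broadband fields are assumed spectrally flat in band, so a
spectral amplitude $b$ within a functional window $\Delta f$ gives
$b^2_{ext} = b^2/\Delta f$, and an integral rms amplitude over a band
$[f_1, f_2]$ gives $b^2_{ext} = b_{rms}^2/(f_2 - f_1)$. The behavioural
sensitivity threshold, 1 nT within 10 kHz, is $10^{-4}\ \mathrm{nT^2/Hz}$
— six orders below $b^2_{int}$ (`psd_orders_of_magnitude()`).

One loose end is deliberately preserved. Lifting the external density to
10% of the internal one needs an amplitude amplification of
$\sqrt{0.1 \cdot b^2_{int}/b^2_{ext}} \approx 450$, yet the benchmark
commonly quoted for this scenario — and the one the feasibility analysis
adopts — is $k \approx 300$. The two are not reconcilable from the printed
inputs, so `compare_rpm()` reports both (`k_computed`, `k_adopted`)
instead of forcing agreement.

## The particle as amplifier

Above its blocking temperature a single-domain particle of volume $V$ and
saturation magnetization $M_s$ shows the Curie susceptibility and, in CGS,
the relative permeability

$$ \chi = \frac{V M_s^2}{3 k_B T}, \qquad k = 1 + 4\pi\chi . $$

Inverting for the smallest volume reaching a target $k$ gives
$V = 3k_BT(k-1)/(4\pi M_s^2)$; at $k = 300$, $M_s = 500$ G, $T = 310$ K
this is $1.22\times10^{-17}\ \mathrm{cm^3}$, a 23 nm cube. "Biological
temperatures" is not a number; 310 K is the standard physiological choice,
and printed-value comparisons carry a ±15% band to absorb it (the quoted
$1.3\times10^{-17}\ \mathrm{cm^3}$ corresponds to a slightly warmer or
slightly weaker particle). Material presets: 500 G as a generous upper
bound, 475 G for magnetite (midpoint of 470–480 G), 240 G for greigite.

Superparamagnetism is encoded purely as a volume bound,
$V < 10^{-16}\ \mathrm{cm^3}$ (a 46 nm cube), the boundary for magnetite
crystals of small aspect ratio. The comparison is strict: a particle
exactly at the bound counts as blocked. The bound is a parameter, not a
constant, and the blocking temperature itself is not modelled — the
quantitative argument never needs it.

## The particle as noise source

The magnitude of the moment, $\mu = M_s V$, is pinned by exchange; its
direction fluctuates thermally with relaxation time $\tau$, so the
projection on any axis has

$$ \langle\mu_z(0)\mu_z(t)\rangle = \langle\mu_z^2\rangle e^{-|t|/\tau},
\qquad
S(\omega) = \langle\mu_z^2\rangle \frac{2\tau}{1+\omega^2\tau^2}, $$

with $\langle\mu_z^2\rangle = \mu^2/\eta$: $\eta = 3$ for an isotropic (or
cubic) particle, $\eta = 1$ under strong uniaxial anisotropy. The
fluctuation-dissipation theorem fixes the dissipative response,
$\alpha''(\omega) = \omega S(\omega)/2k_BT$, and Kramers–Kronig fixes the
real part, $\alpha'(\omega) = (\langle\mu_z^2\rangle/k_BT)/(1+\omega^2\tau^2)$.
The noise-equivalent power of the particle-as-antenna is the ratio

$$ b^2_{NEP} = \frac{S(\omega)}{|\alpha(\omega)|^2}
 = \frac{2(k_BT)^2\tau}{\langle\mu_z^2\rangle}
 = \frac{2\eta (k_BT)^2 \tau}{M_s^2 V^2} \quad [\mathrm{G^2/Hz}], $$

frequency independent because numerator and denominator share the same
Lorentzian. Both closed forms are implemented (`nep()` methods for
`noise_spectrum` and `particle`) and the test suite asserts their identity
and the $S/|\alpha|^2$ route at several frequencies, rather than trusting
any single algebraic path. NEP is always reported in G²/Hz and nT²/Hz side
by side: the radical-pair comparison is naturally quoted in nT²/Hz and the
feasibility threshold in G²/Hz, and the $10^{10}$ factor between them is
an easy trap.

## The feasibility map

`build_feasibility_map()` sweeps a log-spaced $V \times \tau$ grid
(defaults: $[10^{-18}, 10^{-15}]\ \mathrm{cm^3}$, $[1.3\times10^{-12},
10^{-7}]$ s, 200×200) and evaluates three masks: permeable ($k \ge 300$),
superparamagnetic ($V < 10^{-16}\ \mathrm{cm^3}$), and quiet (NEP at or
below $10^{-14}\ \mathrm{G^2/Hz}$, the threshold at which robins were
disoriented). The $\tau$ lower bound is the shortest relaxation time
reported for magnetite nanoparticles, $1.3\times10^{-12}$ s; ~1 ns is more
realistic. Since NEP is increasing in $\tau$ and decreasing in $V$, the
minimum over the admissible band sits at its largest-volume shortest-time
corner — the tests assert this monotonicity, that every cell equals a
from-scratch scalar recomputation, and that the emptiness verdict is
stable under grid refinement. With the defaults the verdict is empty: the
quietest admissible particle is still a factor of several hundred above
the threshold. `viable_region_empty()` returns that diagnostic rather than
a bare boolean, so a non-overlap conclusion is always accompanied by how
far from overlap the system is.

# Synthetic dynamics

The analytic layer assumes only the exponential autocorrelation; no
microscopic dynamics is prescribed. The generator therefore implements the
*minimal* pair of processes consistent with that ACF and detailed balance,
not a claim about the micromagnetism:

* **Random telegraph** (`simulate_telegraph()`): the strong-uniaxial
  picture, $\mu_z = \pm\mu$, with Arrhenius-split flip rates
  $r_{\pm} = (2\tau)^{-1} e^{\mp \mu B/k_BT}$. The symmetric split makes
  the zero-field relaxation rate exactly $1/\tau$ and detailed balance
  gives $\langle\mu_z\rangle = \mu\tanh(\mu B/k_BT)$, whose linear regime
  reproduces the static susceptibility $\mu^2/k_BT$.
* **Ornstein–Uhlenbeck** (`simulate_ou()`): Gaussian surrogate for one
  Cartesian component of an isotropic particle, with the stationary
  variance supplied directly.

Both use exact per-step updates — flip probabilities $1 - e^{-r\,dt}$ and
the exact OU discretization $x_{n+1} = \rho x_n + \sqrt{(1-\rho^2)\sigma^2}\,\xi$
— so the only discretization artefact is the grid itself, and the grid is
policed ($dt \le \tau/20$). Each trajectory is driven by R's RNG under a
caller-supplied seed, recorded in the output, and leaves the caller's RNG
stream untouched; identical parameters and seed give identical samples.

The estimators close the loop: `estimate_acf()` (biased sample
autocovariance, log-linear exponential fit over the leading positive run
above 5% of the variance, with an `resolved` flag when the decay is at the
grid scale), `estimate_psd()` (segment-averaged periodogram rescaled to the
two-sided angular convention, Parseval-consistent with the sample
variance), and `estimate_response()` (sinusoidal drive in the linear
regime $\mu b/k_BT \le 0.2$, quadrature projection over at least 200
periods). The package's core end-to-end validation is the
fluctuation-dissipation closure $\hat\alpha''(\omega) \approx \omega
\hat S(\omega)/2k_BT$ at $\omega\tau \in \{0.3, 1, 3\}$, with both sides
estimated from independent simulations, and the stochastic NEP recovery
$\hat S/|\hat\alpha|^2$ against the closed form.

What the generator does *not* emulate: full three-component
Landau–Lifshitz–Gilbert dynamics, field dependence of $\tau$ itself,
temperature sweeps across the blocking transition, particle ensembles and
interparticle fields, and any coupling back from the radical pair. Passing
tests therefore show the analytic pipeline is internally consistent and
correctly implemented — not that real magnetite obeys a single-$\tau$
Lorentzian at all frequencies.

# Numerical choices

* **Units.** Gaussian CGS internally (G, cm, erg, s, emu); conversions to
  nT and Hz at the interface only, and involutive to machine precision.
  $k_B = 1.380649\times10^{-16}$ erg/K; $\gamma_e = 176$ exactly, as the
  working value of the field.
* **Tie-breaks.** Strict inequality at the superparamagnetic bound;
  `quiet` uses $\le$ at the threshold (a particle exactly at threshold is
  not ruled out by noise).
* **Quadratures.** Parseval closure of the Lorentzian uses adaptive
  quadrature (`integrate`) at $10^{-10}$ relative tolerance. The
  Kramers–Kronig check in the tests is an independent principal-value
  quadrature with the singularity removed by subtraction, on a log grid
  spanning six decades either side of the evaluation point; it reproduces
  $\alpha'$ to well under 1% mid-band.
* **Simulation scales.** Test runs use $\tau$-normalised durations of
  $10^4\,\tau$ for equilibrium moments, $10^5\,\tau$ for spectra and
  driven responses, and up to $4\times10^5\,\tau$ for the static
  susceptibility, with $dt = \tau/20$ to $\tau/50$ — chosen so that the
  three-standard-error statistical bands are comfortably inside the stated
  10–25% stochastic tolerances while each run completes in well under a
  minute on one core. The compiled telegraph kernel makes the per-step
  loop cheap; all surrounding arithmetic is vectorised R.
* **Degenerate inputs.** Zero-width bands, non-positive physical
  parameters, inverted grid ranges, sub-Nyquist `dt`, out-of-linear-regime
  drive amplitudes, and overflow-prone $|\mu B/k_BT| > 30$ are rejected
  with informative errors rather than propagated.

# Known limitations

The argument is deliberately conservative where it can be: the 500 G
saturation magnetization is an upper estimate, the $1.3\times10^{-12}$ s
relaxation-time floor is the most extreme value on record, and the quiet
mask uses the particle's NEP alone — any transduction chain after the
antenna only adds noise. Limitations that could move the conclusion are
structural rather than parametric: multi-domain or multi-grain
architectures are not modelled (their permeability/noise trade-off is an
open question), the electric component of the applied fields is not
modelled, and behavioural threshold metrology (peak-amplitude versus
power-density recording, conductive test arenas) is taken at face value as
a $10^{-14}\ \mathrm{G^2/Hz}$ threshold. Within the single-particle,
single-relaxation-time model, the non-overlap verdict is robust across the
entire parameter ranges exposed.
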