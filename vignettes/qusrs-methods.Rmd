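---
title: "Methods: entangled-photon stimulated Raman spectroscopy of exciton aggregates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entangled-photon stimulated Raman spectroscopy of exciton aggregates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qusrs)
```

## The problem

Ultrafast stimulated Raman scattering probes excited-state dynamics of
molecules by jointly scattering a pump (s) and a probe (i) field off the
Raman polarizability. With classical pulses the spectral resolution of
the Raman lines and the temporal resolution of the gate are conjugate:
one pulse bandwidth controls both. A time-frequency *entangled* photon
pair breaks that conjugation: the pair's two-photon amplitude carries a
narrow distribution of the difference frequency `ws - wi` (set by the
entangling pump bandwidth `sigma0`) while each photon individually is a
short wavepacket of duration `tau0` set by the group-velocity delay in
the entangling crystal. Coincidence counting of the transmitted pair
then yields a Raman spectrum whose lines have width `~ sigma0` while the
molecular dynamics are gated by a window of width `~ tau0` — scales that
are independent knobs.

A second quantum effect matters: the stimulated Raman signal is a sum of
a *parametric* and a *dissipative* pathway (the two orderings of the
six-point field correlator). For any state with exactly one photon per
arm, the dissipative ordering annihilates the lone s photon before the
s-arm number operator acts, so that pathway vanishes identically — a
Hong–Ou–Mandel (HOM) type destructive two-photon interference. Classical
fields commute, the two orderings coincide, and the selectivity is lost.
This package implements the full chain and verifies each of these
statements numerically.

## Molecular model

The aggregate is a chain of `N` two-level chromophores with site
energies `w_n` (eV) and nearest-neighbour dipole coupling `J`, i.e. a
one-exciton Frenkel Hamiltonian: tridiagonal, `-J` on the
off-diagonals. The reference system is a trimer with
`w = (2.25, 2.1, 2.1)` eV and `J = 30` meV:

```{r}
spec <- aggregate_spec(c(2.25, 2.1, 2.1), coupling_J = 0.03)
basis <- diagonalize(build_hamiltonian(spec))
basis$eigenvalues
```

Eigenstates are labelled ascending: `e1` is the lowest exciton, the sink
of the downhill population transfer. The exciton gaps — 0.0591, 0.1294
and 0.1886 eV — are the Raman shifts at which every spectral feature
below appears. Only the one-exciton manifold is modelled; multi-exciton
states are outside the scope of the signal expressions used here.

### Relaxation

Coupling of each site to a dense set of vibrations is reduced, after
tracing the bath, to thermal jumps between exciton eigenstates: each
pair `j > i` contributes a downward Lindblad channel `|e_i><e_j|` with
rate `gamma_ji (nbar + 1)` and an upward channel with `gamma_ji nbar`,
where `nbar` is the Bose occupation of the gap. This enforces detailed
balance, so the stationary state of the dissipator is the Boltzmann
distribution over the exciton energies at the bath temperature (a
property the test suite checks against the Liouvillian null space).

A note on the jump-operator coefficients: contracting the modal matrix
with its inverse over sites, `sum_n (P^-1)_jn P_ni`, is exactly
`delta_ji` for the orthogonal modal matrix of a symmetric Hamiltonian,
which would leave no inter-state jumps at all. The package therefore
uses unit jump operators between eigenstates and carries all bath
physics in the rates `gamma_ji ∝ D(w_ji)`, which is the standard secular
form and the only reading under which the dissipator is nonzero.

The spectral density is Ohmic with exponential cutoff,
`D(w) = w exp(-w/wc)`. The proportionality constant of
`gamma_ji ∝ D(w_ji)` is not fixed by the model, so it is exposed as
`gamma0`, defined as the downward rate at a gap equal to the cutoff.

### Parameter defaults and why

| parameter | default | unit | role |
|---|---|---|---|
| `site_energies` | 2.25, 2.1, 2.1 | eV | reference trimer |
| `coupling_J` | 0.03 | eV | sets the exciton splittings |
| `cutoff` (wc) | 0.2 | eV | Ohmic peak near the large gaps |
| `gamma0` | 1.3e-3 | fs^-1 | top exciton relaxes on ~400 fs |
| `temperature` | 300 | K | room-temperature detailed balance |
| `pure_dephasing` | 0 | fs^-1 | optional extra coherence decay |
| `sigma0` | 0.001 | eV | Raman line HWHM (narrowband pump) |
| `tau0` | 25 | fs | gate window / HOM envelope scale |
| `omega_plus` | 0.3 | eV | fixed sum frequency of the pair |

`gamma0 = 1.3e-3 fs^-1` makes the total outgoing rate of the top
exciton `~ 1/(400 fs)`, so its population decays substantially within a
700 fs observation window while the middle exciton rises on a ~100 fs
scale — a regime in which the downhill transfer is clearly resolved
inside a 700 fs observation window. The
resulting coherence dephasing rates, `hbar (Gamma_e + Gamma_e')/2 ~
1–2 meV`, keep the 0.124 and 0.129 eV lines resolvable. These choices
were made once, from the physics, and are fully configurable. Energies
are always in eV and times in fs, with `hbar = 0.6582119569 eV fs`
entering only through phase factors `exp(-i w t / hbar)`.

### Initial condition

The model itself does not fix the post-pump state. The default is a
pure excitation of the highest-energy site transformed into the exciton
basis: a resonant short pump excites the local transition, and the
transform produces both populations (mostly the top exciton) and
inter-exciton coherences, which is what makes the oscillatory coherence
side peaks visible at early times. `initial_state()` also accepts a
single eigenstate or any custom positive trace-one matrix.

### Propagation

The Liouvillian `L vec(rho) = vec(-(i/hbar)[H, rho] + W rho)` is a
complex `N^2 x N^2` matrix; `propagate()` exponentiates `L dt` once by
scaling-and-squaring (Padé 6,6 — none of the installed matrix libraries
exponentiate complex matrices) and reapplies the step propagator.
Defaults: `dt = 0.25 fs`, span 0–1000 fs. The suite checks trace,
Hermiticity and positivity along 2000-step trajectories at 1e-8, agreement
with an adaptive complex ODE integrator (`deSolve::zvode`) at 1e-8, and
convergence to the Boltzmann state.

## Photon states

Fourier conventions: the two-photon time wavepacket is
`Phi~(t1,t2) = (1/4pi^2) \int\int Phi(w1,w2) e^{-i(w1 t1 + w2 t2)/hbar} dw1 dw2`,
and the one-dimensional `phi~(t) = (1/2pi) \int e^{-ivt} phi(v) dv`.
Absolute normalisation is a declared convention — every spectrum is
reported in arbitrary units normalised to unit maximum.

* **Entangled pair**: `Phi = A(ws - wi - w_-) phi(ws + wi - w_+)
  e^{ikL/2}` with a Lorentzian pump envelope `A` of HWHM `sigma0`, the
  phase-matching amplitude `phi(v) = (2i/tau0)/(v + 2i/tau0)`, and the
  linear phase `kL/2 = (ws + wi - w_+) tau0 / 2` for equal group delays
  `tau_s = tau_i = tau0`. The `|Phi|` ridge lies along `ws - wi = w_-`:
  the photons are *positively* frequency correlated. In closed form the
  wavepacket factorises into a difference-time envelope
  `e^{-sigma0 |t1 - t2| / 2 hbar}`, a one-sided sum-time exponential
  gated at `tau0`, and carrier phases; the tests verify this against
  direct quadrature of the defining transform.
* **Uncorrelated pair**: `Phi = A(ws - ws0) A(wi - wi0)` with each
  photon's bandwidth `sigma~0 = hbar/(2 tau0) ~ 13 meV`. Exactly
  separable (Schmidt rank 1).
* **Classical pulses**: c-number fields
  `eps(t) = e^{i(w + i sigma~0) t / hbar}`, switched on at the pulse
  centre in signal integrals.

`phi~(u)` is the one-sided exponential `(2/tau0) e^{-2u}` for `u > 0`
(contour integral over the single pole), with the Fourier half-weight at
the jump `u = 0`. The HOM overlap window
`W(u) = phi~*(u) phi~(u + DeltaT/tau0)` integrates to
`exp(-2|DeltaT|/tau0)` relative to zero delay, which is the envelope of
every delay scan.

## Correlators and the HOM cancellation

`correlators_fock()` is a brute-force oracle: it discretises each arm
into frequency bins, builds the two-photon state in a Fock space
truncated at total photon number two (exact for pair states), applies
the parametric and dissipative operator strings literally, and takes
inner products. `correlators_analytic()` evaluates the same quantities
by Wick contraction. On matched grids the two agree to round-off, and
the dissipative pathway is *exactly* zero — for the entangled pair and
for the uncorrelated product pair alike, since the cancellation is an
operator-algebra fact for any one-photon-per-arm state. What
distinguishes uncorrelated pairs is resolution (their 13 meV single
photon bandwidth), not pathway selectivity. For classical fields both
orderings are the same product of four c-numbers, so `C_I = C_II`
exactly.

## The Raman signal

Every signal is a triple sum over `(e, e', e'')`: the monitored
density-matrix element `rho_ee'`, an intermediate state `e''`, and the
polarizability weight `alpha[e',e''] alpha[e'',e]`. The polarizability
has no diagonal elements (it is a sum of inter-state couplings plus
Hermitian conjugate), so there is no Rayleigh line at zero shift; by
default all couplings are 1 and the matrix is configurable.

### Analytic narrowband form

`signal_narrowband()` evaluates, per term, a complex Lorentzian of
HWHM `sigma0 + hbar gamma_e''e'` centred at
`w_- = -(E(e'') - E(e')) + (E(e) - E(e'))/2`, weighted by the
time-gated integral of `rho_ee'(t)` through the window
`W((2t - 2Ti - tau0)/tau0)` and multiplied by the delay prefactor
`e^{-i (w_+ + w_-) DeltaT / 2 hbar}`. Populations therefore produce
lines at their *signed* gaps `E(e) - E(e'')`: the lowest exciton at
-0.059 and -0.189 eV, the middle one at -0.129 and +0.059 eV, the top
one at +0.129 and +0.189 eV, and the `rho_e2e3` coherence side peaks at
+0.124 eV. Each spectral position is thus owned by a single
density-matrix element, which is what makes the spectrum a readout of
the exciton dynamics. The
Lorentzian is implemented as the one-sided time integral
`1/(gamma + sigma0/hbar + i(...)/hbar)`, which is what the double-time
expression reduces to; it has the same line positions and widths as the
conventional `i/(w_- + i sigma0 - ...)` writing and keeps the numeric
and analytic routes phase-consistent.

**Branch calibration.** The formal `s <-> i` exchange term maps
`w_- -> -w_-` and `Ts <-> Ti`. Including it at equal weight would make
the zero-delay spectrum exactly symmetric in `w_-`, which contradicts
the signed single-branch population assignments above and would erase
the pathway selectivity that distinguishes entangled from classical
driving. The package therefore computes the parametric branch by
default and exposes the mirror via `include_exchange = TRUE`; the one
place the mirror is used is the `-0.124 eV` image of the coherence side
peak. With the single branch, the HOM beat frequency is
`|w_+ + w_-|/2` at every shift, which on the Stokes side
(`w_- < 0`) equals `|w_+ - |w_-||/2` — both reported beat laws are one
expression.

### Direct double-time quadrature

`signal_double_time()` integrates the double-time expression without
the narrowband approximation. In coordinates `u = t - tau >= 0` (time
ordering retained; without it the `tau > t` half-plane diverges
whenever `gamma > sigma0/hbar`, and the analytic form corresponds to the
one-sided integral anyway) and `v = t + tau`, each term becomes an
exponential-kernel convolution of the trajectory element over `u`,
evaluated exactly by a one-step recurrence, followed by the `tau0` gate
over `v`. This makes a 1 meV-resolution map over dozens of arrival
times tractable in seconds. The route supports `DeltaT = 0`; delay
scans go through the analytic form, which is also how they are defined
in the narrowband regime.

The two routes agree to 0.03% (normalised) on the stationary
lowest-exciton state of the reference trimer — the regime where the
narrowband reduction is controlled. They *should not* agree on fast
transients: the analytic form samples `rho(t)` at the gate, while the
exact integral convolves it over the Raman-coherence memory
`1/(sigma0/hbar + gamma) ~ 300 fs`. With relaxation on a 400 fs scale
this produces genuinely different transient profiles; the cross-method
check is therefore performed on stationary and near-stationary states,
and the discrepancy on transients is a property of the approximation,
not of the implementation.

### Population limit and rate read-back

`signal_population()` is the zero-delay, population-only limit: a
sum of Lorentzians of HWHM `sigma0 + hbar gamma` weighted by the
populations gated through `|phi~|^2` over `Ts <= t <= Ts + tau0`. For a
frozen population it coincides with the analytic form to round-off, and
for a relaxing two-level system a log-linear fit of the signal versus
arrival time recovers the population decay rate to well within 5% —
the package's stand-in for absolute-intensity comparisons, which are
not reproducible (arbitrary units, unspecified polarizability
magnitudes and spectral-density constant).

### Classical and uncorrelated signals

For classical pulses the six-point correlators collapse to c-number
products and the molecular part becomes the commutator — the response
function. Its product with the real classical field factor has
identically vanishing real part (verified numerically: the real
quadrature of a population-only classical signal is zero at double
precision), so the observable classical spectrum is the other
quadrature, and `signal_classical()` returns it. The result is exactly
symmetric in `w_-`: Stokes and anti-Stokes lines appear with equal
magnitude at every gap, with no way to tell which population produced
which line — the selectivity loss of classical light. Uncorrelated
pairs run through the same double-time machinery with the factorised
wavepacket; their signal retains the quantum detection phases (real
part) but the 13 meV bandwidth blurs the 59 meV-spaced line structure.

## What the simulations do and do not show

The synthetic study emulates: a small exciton manifold with secular
Markovian relaxation and detailed balance, ideal lossless twin-photon
states with Lorentzian spectra, noiseless coincidence detection, and
arbitrary-unit spectra. It does not emulate inhomogeneous broadening,
non-Markovian bath memory, photon loss or detector jitter, multi-pair
emission from the source, or absolute signal strengths. Passing tests
therefore demonstrate the internal consistency of the theory chain and
its stated limits, not instrument-level predictions.

## Numerical choices

* Trajectory step 0.25 fs (phase per step < 0.2 rad for all gaps);
  quadrature by trapezoid on uniform grids; the numeric signal route
  offers a step-halving (`richardson`) check at 2%.
* Eigenvector sign fixed by making the largest-magnitude component
  positive; degenerate site energies are allowed (the eigen-gaps of the
  reference trimer are distinct, which resolves all lines).
* Lorentzian line fits by least squares from moment starts; peak
  finding by interior local maxima above a 2% floor; beat frequencies
  by FFT argmax (resolution one bin).
* Stationary states for cross-method checks start at negative times
  (`t0 <= -6 hbar/sigma0`... in practice -1800 fs) so the Raman
  coherence integral is fully accumulated at `T = 0`.
* Problem sizes used by the shipped checks: 441-point shift grids at
  1 meV, up to 21 arrival times, 3600-step trajectories, Fock grids of
  10 bins per arm (the oracle caps at 64).

## Limitations

Single-exciton manifold only; secular Lindblad relaxation (no
coherence-population mixing terms); the `DeltaT != 0` numeric route and
unequal group delays (`tau_s != tau_i`) are not implemented; the
uncorrelated-signal engine is zero-delay only. The classical-signal
quadrature and the parametric-branch calibration are declared
conventions, documented above, chosen once so that each exciton
population owns a single signed set of spectral lines.
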