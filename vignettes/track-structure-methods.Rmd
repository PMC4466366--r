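---
title: "Track-structure physics in trackmc: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Track-structure physics in trackmc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackmc)
```

## What the package computes

`trackmc` is an event-by-event (track-structure) Monte Carlo library for
charged particles in liquid water. Unlike condensed-history transport, which
averages many collisions into a single step, track structure simulates every
inelastic collision individually — the resolution needed to study radiation
damage at sub-cellular scales, where the spatial pattern of ionisations
matters more than the average dose.

The package has two layers:

1. **Cross-section models** — semiempirical and dielectric-theory
   differential cross-sections (DCS, `dσ/dW` in m²/eV) for electron-impact
   ionisation and excitation, proton-impact ionisation, and heavy-ion
   ionisation by charge scaling. Models are organised into two switchable
   *model chains* that mirror the physics lists of two production
   track-structure codes: `ritracks_like` (Rudd + Seltzer ionisation,
   Kaplan-Sukhonosov + Kutcher-Green excitation, Rudd protons everywhere)
   and `geant4dna_like` (dielectric Born machinery for electrons, Rudd
   protons below 500 keV and Born above).
2. **Transport** — a compiled event loop that alternates exponential free
   flights, boundary checks, channel selection and energy-loss sampling in a
   cubic water target (7 µm default), spawning and transporting every
   secondary electron, with exact per-history energy bookkeeping.

## The medium

Liquid water at 1.0 g/cm³ (molar mass 18.015 g/mol, number density
N ≈ 3.343 × 10²² cm⁻³) with five ionisable molecular orbitals
(1b1, 3a1, 1b2, 2a1, 1a1) and five discrete excitation levels. Each orbital
carries an occupancy `N_i = 2`, a binding energy `B_i ≡ I_i` (11.50 to
539.7 eV), a mean orbital kinetic energy `U_i`, and a mean radius `⟨r⟩_i`
(stored for completeness; no implemented formula uses it). All of this lives
in an editable YAML configuration (`default_config_path()`); nothing is
hard-coded.

```{r medium}
med <- load_medium()
med
```

## Ionisation models

**Rudd electron-impact ionisation** (used by `ritracks_like` below 50 keV):
a binary-encounter form in the scaled variables `t = T/I_i`, `ω = W/I_i`,
with the prefactor `S_i = 4π a0² N_i (ℜ/I_i)²` and two fitted energy
functions `F_k(t) = A_k ln(t)/(t + B_k)` (one constant set for outer
"liquid" shells, one for the oxygen K shell). Because the two outgoing
electrons are indistinguishable, the slower one is the secondary:
`W ≤ (T − I_i)/2`. A note on units: the prefactor `S_i/I_i` already carries
m²/eV, so the scaled form is per unit secondary energy as written — a
dimensional-analysis point that the package's tests pin against the
literature cross-section scale.

**Seltzer electron-impact ionisation** (above 50 keV): the sum of a
close-collision (Møller-like binary encounter with the binary-encounter
factor `T/(T+B_i+U_i)` and the `G_i` orbital term) and a distant-collision
term proportional to the orbital photoelectric cross-section
`σ_PE^i(E = W + B_i)`. The photoelectric curve is not part of the
track-structure models proper; it enters through a provider interface
(`photo_xs_provider()`), whose packaged default is a hydrogenic
`(B_i/E)³` fall-off with a configurable threshold value. The
virtual-photon intensity `I(E)` multiplying `σ_PE` uses the standard
leading-log form. Tests exercise the close term against hand
transcriptions and synthetic providers (including `σ_PE ≡ 0`).

**Rudd proton-impact ionisation**: per-orbital DCS
`(S_i/I_i)(F_1(υ) + ω F_2(υ)) / {(1+ω)³ [1 + exp(α(ω − ω_c)/υ)]}` in the
scaled velocity `υ = √(T/I_i)`, `T = E_p m/M_p`. The fitted functions
`F_1, F_2` use the high-/low-velocity component forms of the semiempirical
proton model with per-shell-class parameters in the configuration; the
spectral cutoff is `ω_c = 4υ² − 2υ − ℜ/(4I_i)`. Above a configurable
threshold (500 keV default) the relativistic substitution
`υ² = (mc²/2I_i)[1 − (1 + T/mc²)⁻²]` replaces `T/I_i`; the two agree to
0.1% below 500 keV and the substitution saturates at `mc²/(2I_i)`.

**Born dielectric machinery** (the `geant4dna_like` electron models and its
protons above 500 keV): the double-differential inverse mean free path
`d²Σ/dE dq = Im(−1/ε(E,q)) / (π a0 T q)` inside the kinematic window
`q_± = √(2M)(√τ ± √(τ−E))`, `E ≤ τ`, with `T = (m/M)τ`. The q-integral is
done by Simpson's rule in `ln q`, which is exact for the `1/q` kernel — a
momentum-independent energy-loss function (ELF) reproduces the
`ln(q_+/q_−)/(π a0 T)` closed form to machine precision, which is how the
implementation is anchored in the tests.

The ELF itself is pluggable. The packaged default is a single-Drude
parameterisation with quadratic momentum dispersion
`E_0(q) = E_0 + q²/2m`, amplitude fixed by the f-sum rule at the nominal
plasmon energy of liquid water (21.46 eV at unit density), peak 21.4 eV and
width 13 eV chosen to match the measured optical ELF peak height (≈1.4).
These choices were made once, from the dielectric-theory literature, and
give inelastic mean free paths and stopping powers at the right scale
(e.g. ≈ 2 nm IMFP for 1 keV electrons; ≈ 34 keV/µm effective stopping for
1 MeV protons in the transport loop, vs the ≈ 27 keV/µm Bethe value).

Energy transfers are partitioned between ionisation and excitation by an
ionisation quantum efficiency that ramps linearly from 0 at the 11.5 eV
threshold to 1 at a configurable 18 eV — liquid water's photoionisation
yield saturates a few eV above threshold, and without the ramp the Born
chain converts deposited energy into ionisations at an unphysically low
energy per ion pair. Electron projectiles additionally carry the same
indistinguishability restriction `W ≤ (τ−B_i)/2` as the Rudd and Seltzer
conventions.

## Excitation models

The discrete levels carry Gaussian strength functions `f_i(W)`. The
high-energy form (Kutcher-Green, above 100 eV) is
`(ρ(W)/W) f_i(W) ln(4T/Q_min)` with the Rutherford free-electron kernel
`ρ(W) = 4π a0² ℜ²/(T W²)` and
`Q_min = 2T(1 − W/2T − √(1 − W/T))`. The low-energy form
(Kaplan-Sukhonosov/Cobut) replaces the logarithm by `ln(α T/W)` with
`α = 4 − 3 exp[−(W − W_{0,i})/α_i]`, `α_i = 4 E_min/ln 2` and
`E_min = 7.34` eV the minimum excitation transfer. Both are clamped to zero
wherever the logarithm argument does not exceed one (the models are silent
about the negative-log region, and a total, non-negative DCS is required
for sampling).

The level energies and strengths are *not* fixed by the track-structure
formulations this package implements. The defaults place the five levels at
the optical excitation bands of liquid water (8.4–14.1 eV) with amplitudes
giving excitation totals of order 10⁻²¹–10⁻²⁰ m² near 100 eV, the magnitude
range of the excitation-model literature; they are flagged as editable,
extra-model defaults in the configuration comments, and every correctness
test uses synthetic levels so that nothing depends on them.

## Heavy ions

An ion of charge `Z` moving at the velocity of a proton of energy `τ`
(i.e. with kinetic energy `E_ion = (M/M_p)τ`) ionises with exactly
`Z²` times the proton DCS. At low velocity electron capture reduces the
acting charge: the Booth-Grant effective charge
`Z*/Z = 1 − exp(−1.316x + 0.112x² − 0.0650x³)`, `x = 100β Z^{−2/3}`, is
applied (squared) below a configurable 0.2 MeV/u, with an explicit
override. `β` is computed relativistically from the ion energy and mass,
a mapping the source formulations leave unstated. The `Z²` multiplication
is exact at the bit level, and is tested as such.

## Sampling and transport

Energy losses are drawn by inverse-CDF tabulation (512-point log-spaced
grids, trapezoid CDF, linear interpolation), not rejection: the DCS shapes
here are smooth, steep (`~W⁻²` with soft cutoffs) and cheap to tabulate,
and tabulation gives deterministic cost. Free paths are exponential with
mean `1/(Nσ_tot)`; channels are selected proportional to their
cross-sections. Every stochastic operation runs through a seedable stream;
each transport history derives its own stream from
`history_seed(master, index)`, so histories are reproducible independently
of execution order.

The transport loop itself is compiled (Rcpp) and table-driven, the way
production codes precompute their physics: per species, a log-uniform
energy grid (96 points by default) of per-channel cross-sections and
128-node quantile tables. Two numerical choices matter and are worth
stating:

* interpolation is linear in `log E` for cross-sections and linear between
  quantile nodes for energy losses, with the energy-loss table taken from
  the nearest grid energy;
* the stored quantiles are capped at the `1 − 10⁻⁴` probability point.
  Linear interpolation across an unbounded last bin would inflate the
  sampled tail of the steep secondary spectra — in testing this single
  artefact doubled the effective stopping power.

Geometry is a cube (7 µm default) entered at the centre of one face along
the axis. All particles travel in straight lines: elastic scattering is out
of scope, and the observable — ionisation counts in a micron-scale box —
is governed by inelastic mean free paths that are orders of magnitude
shorter than the box. Secondary electrons are emitted isotropically
(configurable to forward). Per ionisation the projectile loses `W + B_i`
(binding deposited locally, `W` carried by the secondary); per excitation
it loses `W`. Particles terminate on exit or below the tracking cutoffs
(10 eV electrons, 100 eV protons), depositing the remainder; there is no
thermalisation model. The bookkeeping identity
`initial = deposited + sub-cutoff + exited` holds to ~10⁻¹⁴ relative and
is asserted over a thousand mixed histories per test run.

```{r history}
tab <- build_physics_tables(load_config(), model_chain("ritracks_like"),
                            n_energy = 48)
h <- run_history(1e6, tab, sim_config(seed = 1), "proton")
h
energy_residual(h)
```

## The counting experiment

`ionisation_yield_scan()` reproduces the protocol of firing one proton into
the cube per history and recording the total number of ionisation events
(primary plus all secondary generations), averaged over histories with the
standard error from the history-to-history spread. Counts only ionisations,
not excitations. The acceptance runs use 10 log-spaced energies from
10⁻² to 10² MeV with 100 histories each — sizes chosen so a scan completes
in minutes on one core while keeping the standard errors a few percent of
the means.

What the two chains do with this experiment is instructive, and the
package reports it honestly rather than asserting a curve: below ~0.1 MeV
the proton stops inside the cube and both chains bind the *same* proton
Rudd model, so the count is energy-budget-limited and the chains agree to
within ~10–20% (set by their different electron-cascade energy-per-ion-pair
values). Above ~1 MeV the proton crosses the cube and the fast δ-rays
escape after a handful of collisions, so the count becomes proportional to
the electron ionisation cross-sections — where the printed Rudd form and
the dielectric Born model genuinely differ by a factor ~2 in the keV range.
Mechanisms that drive the large low-energy discrepancy between the real
codes (charge transfer, low-energy Coulomb corrections, version-specific
cutoffs) are explicitly out of scope here.

## What the synthetic fixtures do and do not show

`generate_fixtures()` produces analytic toy objects — power-law and uniform
DCS with closed-form totals and CDFs, constant and Drude toy ELFs, zero and
constant photoelectric providers, random positive parameter sets — and
`toy_physics_tables()` builds constant-cross-section transport tables whose
event counts are exactly Poisson. These anchor the machinery (quadrature,
inverse-CDF sampling, free flights, channel selection, bookkeeping) to
closed forms. They do not validate the fitted physics against experiment:
passing tests show the equations are transcribed and sampled correctly, not
that liquid water behaves like any particular parameterisation. The
editable configuration is the contract for the latter.

## Known limitations

* No elastic scattering, charge transfer, or sub-excitation (vibrational /
  rotational) channels; no chemistry stage; no proton excitation channel.
* The Born machinery is used as given down to its chain boundaries; the
  low-energy Coulomb-field correction applied by the real dielectric-model
  code has no published formula in the sources this package follows and is
  not implemented.
* The excitation-level strengths, photoelectric curve and ELF are
  documented extra-model defaults, not fitted constants of the
  implemented formulations.
* Cross-section interpolation (96-point log grids) and nearest-grid
  energy-loss tables introduce percent-level transport discretisation,
  deliberately traded for deterministic table-driven cost.
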