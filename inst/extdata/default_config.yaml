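# Default liquid-water configuration for trackmc.
#
# Energies in eV, lengths in m unless a key says otherwise.  Every fitted or
# literature-sourced number used by the physics models lives here and can be
# edited; nothing below is hard-coded in the package.

constants:
  bohr_radius_m: 5.29177210903e-11
  rydberg_eV: 13.605693122994
  # value as conventionally used in the Seltzer close-collision prefactor
  classical_electron_radius_m: 2.817e-15
  electron_rest_energy_eV: 510998.95
  electron_proton_mass_ratio: 5.44617021487e-4
  vacuum_permittivity_si: 8.8541878128e-12

medium:
  mass_density_g_cm3: 1.0
  molar_mass_g_mol: 18.015

# The five ionisable molecular orbitals of water: electron count N_i, binding
# energy B_i (= I_i), mean orbital kinetic energy U_i, mean orbital radius.
# <r>_i is informational only; no implemented formula consumes it.
orbitals:
  - {index: 1, label: 1b1, n_electrons: 2, binding_eV: 11.50, kinetic_eV: 30.0,  r_mean_angstrom: 0.833, shell_class: outer}
  - {index: 2, label: 3a1, n_electrons: 2, binding_eV: 11.75, kinetic_eV: 40.0,  r_mean_angstrom: 0.867, shell_class: outer}
  - {index: 3, label: 1b2, n_electrons: 2, binding_eV: 13.51, kinetic_eV: 50.0,  r_mean_angstrom: 0.901, shell_class: outer}
  - {index: 4, label: 2a1, n_electrons: 2, binding_eV: 16.0,  kinetic_eV: 60.0,  r_mean_angstrom: 0.906, shell_class: outer}
  - {index: 5, label: 1a1, n_electrons: 2, binding_eV: 539.7, kinetic_eV: 700.0, r_mean_angstrom: 0.129, shell_class: inner}

# Five discrete electronic excitation states.  Band energies follow the
# optical excitation spectrum of liquid water (A1B1, B1A1, Ryd A+B, Ryd C+D,
# diffuse bands).  The Gaussian strength amplitudes are NOT constrained by the
# track-structure sources this package implements; they are editable defaults
# calibrated to give excitation cross-sections of order 1e-21..1e-20 m^2 near
# 100 eV, consistent with the magnitude reported in the excitation-model
# literature.  W_0 links the low- and high-energy excitation models.
excitation_levels:
  e_min_eV: 7.34
  levels:
    - {index: 1, label: A1B1,     w0_eV: 8.4,   center_eV: 8.4,   width_eV: 1.0, amplitude: 0.80}
    - {index: 2, label: B1A1,     w0_eV: 10.1,  center_eV: 10.1,  width_eV: 1.0, amplitude: 0.70}
    - {index: 3, label: RydAB,    w0_eV: 11.26, center_eV: 11.26, width_eV: 1.0, amplitude: 0.40}
    - {index: 4, label: RydCD,    w0_eV: 11.93, center_eV: 11.93, width_eV: 1.2, amplitude: 1.90}
    - {index: 5, label: diffuse,  w0_eV: 14.1,  center_eV: 14.1,  width_eV: 2.0, amplitude: 2.60}

# Fitted constants of the electron-impact Rudd model, one set per shell class.
rudd_electron:
  liquid: {A1: 0.94, A2: 1.13, B1: 2.30, B2: 22.0}
  inner:  {A1: 1.31, A2: 0.37, B1: 0.00, B2: 0.00}

# Velocity-dependent fitted functions F1(v), F2(v) of the proton Rudd model:
# F1 = L1 + H1, H1 = A1 ln(1+v^2)/(v^2 + B1/v^2), L1 = C1 v^D1/(1 + E1 v^(D1+4)),
# F2 = L2 H2/(L2 + H2), H2 = A2/v^2 + B2/v^4, L2 = C2 v^D2.
# Parameter values from the cited semiempirical proton-impact literature
# (outer/inner shells of water); every number is editable, and correctness
# tests use synthetic sets.  The spectral cutoff is w_c = 4v^2 - 2v - R/(4 I_i).
rudd_proton:
  outer: {A1: 0.97, B1: 82.0, C1: 0.40, D1: -0.30, E1: 0.38, A2: 1.04, B2: 17.3, C2: 0.76, D2: 0.04, alpha: 0.64}
  inner: {A1: 1.25, B1: 0.50, C1: 1.00, D1: 1.00,  E1: 3.00, A2: 1.10, B2: 1.30, C2: 1.00, D2: 0.00, alpha: 0.66}
  # above this proton kinetic energy the relativistic scaled-velocity
  # substitution replaces v^2 = T/I
  relativistic_threshold_eV: 5.0e+05
  # secondary-energy support cap, in units of the free-electron kinematic
  # maximum 4T (T = electron-equivalent energy)
  w_max_factor: 4.0

# Dielectric energy-loss function Im(-1/eps) for the Born chain.
# Single-Drude parameterisation with quadratic momentum dispersion:
#   Im(-1/eps)(E,q) = Ep^2 g E / ((E^2 - E0(q)^2)^2 + (g E)^2),
#   E0(q) = E0 + q^2/(2 m).
# Amplitude Ep is the nominal plasmon energy of liquid water at unit density
# (f-sum-rule normalisation); E0 and g reproduce the measured optical ELF
# peak (height ~1.4 at ~21 eV).  Extra-paper provenance; fully editable.
born_elf:
  model: drude
  plasmon_energy_eV: 21.46
  peak_eV: 21.4
  width_eV: 13.0
  dispersion: quadratic
  # ionisation quantum efficiency: fraction of the dielectric strength at
  # energy transfer E that ionises (rather than excites) ramps linearly
  # from 0 at the first ionisation threshold to 1 here (liquid water's
  # photoionisation yield saturates a few eV above threshold)
  ionisation_full_above_eV: 18.0

# Per-orbital photoelectric cross-section table for the Seltzer distant term,
# log-log interpolated in photon energy; sigma in m^2.  A hydrogenic
# (B_i/E)^3 fall-off anchored at sigma_b m^2 just above each orbital
# threshold.  Extra-paper provenance (the distant-collision source does not
# travel with this package); editable.
photoeffect:
  sigma_at_threshold_m2: 1.0e-22
  exponent: 3.0

# Model-chain dispatch boundaries (energy in eV).
chains:
  electron_ionisation_split_eV: 5.0e+04   # Rudd below, Seltzer above (ritracks_like)
  excitation_split_eV: 100.0            # Kaplan below, Kutcher-Green above
  proton_born_split_eV: 5.0e+05           # Rudd below, Born above (geant4dna_like)
  electron_born_max_eV: 1.0e+06

# Transport defaults: a cubic water target, tracking cutoffs per species.
transport:
  box_um: 7.0
  cutoff_electron_eV: 10.0
  cutoff_proton_eV: 100.0
  secondary_emission: isotropic   # or "forward"
  energy_grid_points: 96
  quantile_points: 128

# Heavy-ion table: charge and mass ratio to the proton.
ions:
  - {name: "H",  Z: 1,  mass_ratio: 1.0}
  - {name: "He", Z: 2,  mass_ratio: 3.9726}
  - {name: "Li", Z: 3,  mass_ratio: 6.9455}
  - {name: "Be", Z: 4,  mass_ratio: 8.9347}
  - {name: "B",  Z: 5,  mass_ratio: 10.9646}
  - {name: "C",  Z: 6,  mass_ratio: 11.9178}
  - {name: "N",  Z: 7,  mass_ratio: 13.9029}
  - {name: "O",  Z: 8,  mass_ratio: 15.8668}
  - {name: "Si", Z: 14, mass_ratio: 27.7697}
  - {name: "Fe", Z: 26, mass_ratio: 55.4672}

# Effective-charge correction default: on below this specific energy (eV per
# nucleon), off above, unless overridden per call.
effective_charge:
  auto_below_eV_per_u: 2.0e+05
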