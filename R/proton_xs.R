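## Proton (and generic charged-particle) ionisation cross-sections:
## semiempirical Rudd model with relativistic velocity substitution, and the
## first-Born double-differential inverse mean free path with a pluggable
## dielectric response.

#' Squared scaled velocity of a heavy charged particle
#'
#' The proton Rudd model works in the scaled velocity
#' \eqn{\upsilon = \sqrt{T/I_i}}, where \eqn{T = E_p\, m/M_p} is the kinetic
#' energy of an electron moving with the proton's velocity.  In the
#' relativistic range the substitution
#' \deqn{\upsilon^2 = \frac{mc^2}{2 I_i}\left[1 -
#'   \frac{1}{(1 + T/mc^2)^2}\right]}
#' replaces the classical \eqn{T/I_i}; the two agree to better than 0.1%
#' below proton energies of 500 keV and the relativistic form saturates at
#' \eqn{mc^2/(2I_i)}.
#'
#' @param E_p Proton kinetic energy (eV), vectorised.
#' @param I_i Orbital binding energy (eV).
#' @param mode `"classical"` or `"relativistic"`.
#' @param constants A `physical_constants` object.
#' @return \eqn{\upsilon^2}, dimensionless.
#' @export
scaled_velocity_sq <- function(E_p, I_i, mode = c("classical",
                                                  "relativistic"),
                               constants = physical_constants()) {
  mode <- match.arg(mode)
  if (any(!is.finite(E_p)) || any(E_p <= 0) || I_i <= 0) {
    stop("E_p and I_i must be strictly positive", call. = FALSE)
  }
  T_eV <- E_p * constants$m_over_Mp
  if (mode == "classical") {
    T_eV / I_i
  } else {
    (constants$mc2 / (2 * I_i)) * (1 - 1 / (1 + T_eV / constants$mc2)^2)
  }
}

#' Velocity-dependent fitted functions of the proton Rudd model
#'
#' \eqn{F_1 = L_1 + H_1} and \eqn{F_2 = L_2 H_2/(L_2 + H_2)} with
#' \eqn{H_1 = A_1 \ln(1+\upsilon^2)/(\upsilon^2 + B_1/\upsilon^2)},
#' \eqn{L_1 = C_1 \upsilon^{D_1}/(1 + E_1 \upsilon^{D_1+4})},
#' \eqn{H_2 = A_2/\upsilon^2 + B_2/\upsilon^4},
#' \eqn{L_2 = C_2 \upsilon^{D_2}}.
#'
#' @param v Scaled velocity \eqn{\upsilon > 0}, vectorised.
#' @param params One shell-class parameter set (`A1`,`B1`,`C1`,`D1`,`E1`,
#'   `A2`,`B2`,`C2`,`D2`,`alpha`).
#' @return List with components `F1` and `F2`.
#' @export
rudd_proton_F <- function(v, params) {
  p <- params
  H1 <- p$A1 * log(1 + v^2) / (v^2 + p$B1 / v^2)
  L1 <- p$C1 * v^p$D1 / (1 + p$E1 * v^(p$D1 + 4))
  H2 <- p$A2 / v^2 + p$B2 / v^4
  L2 <- p$C2 * v^p$D2
  den <- L2 + H2
  F2 <- ifelse(den > 0, L2 * H2 / den, 0)
  list(F1 = H1 + L1, F2 = F2)
}

#' Rudd differential cross-section for proton-impact ionisation
#'
#' Semiempirical per-orbital DCS for ejection of a secondary electron of
#' energy `W` by a proton of energy `E_p`; in scaled variables
#' \eqn{\omega = W/I_i}, \eqn{\upsilon} per [scaled_velocity_sq()]:
#' \deqn{d\sigma/dW = \frac{S_i}{I_i}\,
#'   \frac{F_1(\upsilon) + \omega F_2(\upsilon)}
#'        {(1+\omega)^3\,[1 + \exp(\alpha(\omega - \omega_c)/\upsilon)]}}
#' with the spectral cutoff \eqn{\omega_c = 4\upsilon^2 - 2\upsilon -
#' \Re/(4 I_i)}.  The exponential Fermi factor truncates the spectrum near
#' the free-electron kinematic maximum.
#'
#' @param E_p Proton kinetic energy (eV).
#' @param W_eV Secondary electron energy (eV), vectorised.
#' @param orbital A `molecular_orbital`.
#' @param params One shell-class set of fitted constants (see
#'   [rudd_proton_F()]), plus `alpha`.
#' @param mode Velocity mode passed to [scaled_velocity_sq()].
#' @param constants A `physical_constants` object.
#' @param w_max_factor Secondary-energy support cap in units of the
#'   free-electron kinematic maximum \eqn{4T}.
#' @return DCS in m\eqn{^2}/eV.
#' @export
proton_rudd_dcs <- function(E_p, W_eV, orbital, params,
                            mode = c("classical", "relativistic"),
                            constants = physical_constants(),
                            w_max_factor = 4.0) {
  mode <- match.arg(mode)
  check_energy_args(E_p, W_eV)
  I <- orbital$binding_eV
  v2 <- scaled_velocity_sq(E_p, I, mode, constants)
  v <- sqrt(v2)
  S <- orbital_prefactor(orbital, constants)
  Ff <- rudd_proton_F(v, params)
  T_eV <- E_p * constants$m_over_Mp
  w_max <- w_max_factor * 4 * T_eV
  w <- W_eV / I
  wc <- 4 * v2 - 2 * v - constants$rydberg / (4 * I)
  x <- params$alpha * (w - wc) / v
  fermi <- ifelse(x > 700, Inf, 1 + exp(x))
  val <- (S / I) * (Ff$F1 + w * Ff$F2) / ((1 + w)^3 * fermi)
  val[W_eV > w_max] <- 0
  pmax(val, 0)
}

#' Dielectric energy-loss-function provider from the configuration
#'
#' Builds the callable \eqn{(E, q) \mapsto \mathrm{Im}(-1/\varepsilon(E,q))}
#' used by the Born inverse mean free path.  The packaged default is a
#' single-Drude parameterisation with quadratic momentum dispersion,
#' \deqn{\mathrm{Im}(-1/\varepsilon) = \frac{E_p^2\, \gamma E}
#'   {(E^2 - E_0(q)^2)^2 + (\gamma E)^2}, \qquad
#'   E_0(q) = E_0 + \frac{q^2}{2 mc^2},}
#' with the amplitude fixed by the f-sum rule (nominal plasmon energy of
#' liquid water) and \eqn{q} in energy-equivalent momentum units.
#'
#' @param config A `trackmc_config`.
#' @return A function `(E_eV, q_eV) -> dimensionless`, elementwise
#'   vectorised, non-negative, zero for `E <= 0`.
#' @export
elf_provider <- function(config = load_config()) {
  spec <- config$born_elf
  if (is.null(spec)) {
    stop("config error: Born model requested but no 'born_elf' section is ",
         "configured", call. = FALSE)
  }
  if (!identical(spec$model, "drude")) {
    stop(sprintf("config error: unknown ELF model '%s'", spec$model),
         call. = FALSE)
  }
  Ep2 <- need_positive(spec$plasmon_energy_eV,
                       "born_elf.plasmon_energy_eV")^2
  E0 <- need_positive(spec$peak_eV, "born_elf.peak_eV")
  g <- need_positive(spec$width_eV, "born_elf.width_eV")
  mc2 <- config$constants$mc2
  disperse <- !identical(spec$dispersion, "none")
  function(E_eV, q_eV) {
    n <- max(length(E_eV), length(q_eV))
    E <- rep_len(E_eV, n)
    q <- rep_len(q_eV, n)
    E0q <- if (disperse) E0 + q^2 / (2 * mc2) else rep_len(E0, n)
    val <- Ep2 * g * E / ((E^2 - E0q^2)^2 + (g * E)^2)
    val[E <= 0] <- 0
    val
  }
}

## Saturation energy of the ionisation quantum-efficiency ramp.
born_eta_full <- function(config) {
  v <- config$born_elf$ionisation_full_above_eV
  if (is.null(v)) 18 else v
}

#' Kinematic momentum-transfer window of the Born approximation
#'
#' \eqn{q_\pm = \sqrt{2M}\,(\sqrt{\tau} \pm \sqrt{\tau - E})} in
#' energy-equivalent momentum units (masses and energies in eV, so that
#' \eqn{q^2/2M} is an energy).  Satisfies \eqn{q_+ q_- = 2 M E} exactly.
#'
#' @param tau Particle kinetic energy \eqn{\tau} (eV).
#' @param E Energy transfer (eV), vectorised; must satisfy
#'   \eqn{0 \le E \le \tau}.
#' @param mass_eV Particle rest mass \eqn{Mc^2} (eV).
#' @return List with components `q_minus`, `q_plus` (eV).
#' @export
born_q_bounds <- function(tau, E, mass_eV) {
  if (any(!is.finite(E)) || any(E < 0) || any(E > tau)) {
    stop("born_q_bounds requires 0 <= E <= tau", call. = FALSE)
  }
  root <- sqrt(2 * mass_eV)
  st <- sqrt(tau)
  se <- sqrt(pmax(tau - E, 0))
  list(q_minus = root * (st - se), q_plus = root * (st + se))
}

#' Born double-differential inverse mean free path
#'
#' \deqn{\frac{d^2\Sigma}{dE\,dq} = \frac{1}{\pi a_0 T q}\,
#'   \mathrm{Im}\!\left(\frac{-1}{\varepsilon(E,q)}\right)
#'   \theta(q - q_-)\,\theta(q_+ - q)\,\theta(\tau - E)}
#' with \eqn{T = (m/M)\tau} the electron-equivalent kinetic energy; zero
#' outside the kinematic window.
#'
#' @inheritParams born_q_bounds
#' @param q Momentum transfer (eV-equivalent units), vectorised with `E`.
#' @param elf ELF provider `(E, q) -> Im(-1/eps)`.
#' @param constants A `physical_constants` object.
#' @return Inverse length per (eV energy \eqn{\times} eV momentum),
#'   i.e. m\eqn{^{-1}}eV\eqn{^{-2}}.
#' @export
born_ddcs <- function(tau, E, q, mass_eV, elf,
                      constants = physical_constants()) {
  T_eV <- (constants$mc2 / mass_eV) * tau
  n <- max(length(E), length(q))
  E <- rep_len(E, n)
  q <- rep_len(q, n)
  out <- numeric(n)
  inside <- E > 0 & E <= tau
  if (any(inside)) {
    qb <- born_q_bounds(tau, E[inside], mass_eV)
    win <- q[inside] >= qb$q_minus & q[inside] <= qb$q_plus
    idx <- which(inside)[win]
    if (length(idx)) {
      val <- elf(E[idx], q[idx])
      if (any(val < 0)) {
        stop("ELF provider returned a negative value", call. = FALSE)
      }
      out[idx] <- val / (pi * constants$a0 * T_eV * q[idx])
    }
  }
  out
}

#' q-integrated Born inverse mean free path, differential in energy transfer
#'
#' Integrates [born_ddcs()] over the kinematic momentum window
#' \eqn{[q_-, q_+]} with a composite Simpson rule in \eqn{\ln q} (exact for
#' the \eqn{1/q} kernel, so a momentum-independent ELF reproduces the
#' closed form \eqn{\ln(q_+/q_-)/(\pi a_0 T)} to machine precision).
#'
#' @inheritParams born_ddcs
#' @param n_q Number of quadrature nodes (odd; default 65).
#' @return \eqn{d\Sigma/dE} in m\eqn{^{-1}}eV\eqn{^{-1}}, vectorised in `E`.
#' @export
born_sdcs <- function(tau, E, mass_eV, elf,
                      constants = physical_constants(), n_q = 65L) {
  if (n_q %% 2L == 0L) n_q <- n_q + 1L
  T_eV <- (constants$mc2 / mass_eV) * tau
  out <- numeric(length(E))
  inside <- which(E > 0 & E < tau)
  if (!length(inside)) return(out)
  qb <- born_q_bounds(tau, E[inside], mass_eV)
  lo <- log(qb$q_minus)
  hi <- log(qb$q_plus)
  # Simpson weights in u = ln q; integrand elf(E, e^u) since dq/q = du
  wts <- c(1, rep(c(4, 2), length.out = n_q - 2L), 1)
  frac <- seq(0, 1, length.out = n_q)
  for (k in seq_along(inside)) {
    u <- lo[k] + (hi[k] - lo[k]) * frac
    f <- elf(E[inside[k]], exp(u))
    if (any(f < 0)) {
      stop("ELF provider returned a negative value", call. = FALSE)
    }
    h <- (hi[k] - lo[k]) / (n_q - 1L)
    out[inside[k]] <- sum(wts * f) * h / 3 / (pi * constants$a0 * T_eV)
  }
  out
}

## Ionisation quantum efficiency of an energy transfer E: the fraction of
## the dielectric strength at E that leads to ionisation rather than
## discrete excitation.  Zero below the first ionisation threshold, rising
## linearly to one at eta_full_eV (liquid water's photoionisation yield
## saturates a few eV above threshold).
ionisation_efficiency <- function(E_eV, medium, eta_full_eV = 18) {
  b_min <- min(vapply(medium$orbitals, `[[`, 0, "binding_eV"))
  pmin(pmax((E_eV - b_min) / (eta_full_eV - b_min), 0), 1)
}

## Internal: Born ionisation DCS per orbital in secondary-energy space.
## E = W + B_i; the energy transfer is apportioned among the orbitals that
## are energetically open (weights proportional to occupancy) and weighted
## by the ionisation quantum efficiency.  For electron projectiles the
## exchange convention restricts the secondary to W <= (tau - B_i)/2.
born_ionisation_dcs <- function(tau, W_eV, orbital, medium, elf, constants,
                                mass_eV, eta_full_eV = 18,
                                exchange = FALSE) {
  out <- numeric(length(W_eV))
  E <- W_eV + orbital$binding_eV
  ok <- W_eV >= 0 & E < tau
  if (exchange) ok <- ok & W_eV <= (tau - orbital$binding_eV) / 2
  if (!any(ok)) return(out)
  bind_all <- vapply(medium$orbitals, `[[`, 0, "binding_eV")
  n_all <- vapply(medium$orbitals, `[[`, 0, "n_electrons")
  Ek <- E[ok]
  wsum <- vapply(Ek, function(e) sum(n_all[bind_all < e]), 0)
  weight <- ifelse(wsum > 0, orbital$n_electrons / wsum, 0) *
    ionisation_efficiency(Ek, medium, eta_full_eV)
  sd <- born_sdcs(tau, Ek, mass_eV, elf, constants)
  out[ok] <- weight * sd / medium$number_density_m3
  out
}

#' Proton ionisation differential cross-section under a model chain
#'
#' Dispatches to the Rudd model or the Born dielectric model according to the
#' chain binding at `E_p` (Geant4-DNA-like: Rudd below 500 keV, Born above;
#' RITRACKS-like: Rudd throughout, with the relativistic velocity
#' substitution above the configured threshold) and sums over the five
#' molecular orbitals.
#'
#' @param E_p Proton kinetic energy (eV).
#' @param W_eV Secondary electron energy (eV), vectorised.
#' @param config A `trackmc_config`.
#' @param chain A `model_chain`.
#' @return DCS in m\eqn{^2}/eV, with attribute `"model"` recording the bound
#'   model identifier.
#' @export
proton_ionisation_dcs <- function(E_p, W_eV, config = load_config(),
                                  chain = model_chain("ritracks_like",
                                                      config)) {
  model <- chain_model_for(chain, "proton_ionisation", E_p)
  med <- config$medium
  cst <- config$constants
  if (model == "rudd") {
    mode <- if (E_p > config$rudd_proton$relativistic_threshold_eV) {
      "relativistic"
    } else {
      "classical"
    }
    val <- Reduce(`+`, lapply(med$orbitals, function(orb) {
      cls <- if (orb$shell_class == "inner") "inner" else "outer"
      proton_rudd_dcs(E_p, W_eV, orb, config$rudd_proton[[cls]], mode, cst,
                      config$rudd_proton$w_max_factor)
    }))
  } else if (model == "born") {
    elf <- elf_provider(config)
    mass_eV <- cst$mc2 / cst$m_over_Mp
    eta_full <- born_eta_full(config)
    val <- Reduce(`+`, lapply(med$orbitals, function(orb) {
      born_ionisation_dcs(E_p, W_eV, orb, med, elf, cst, mass_eV, eta_full)
    }))
  } else {
    stop(sprintf("unknown proton ionisation model '%s'", model),
         call. = FALSE)
  }
  attr(val, "model") <- model
  val
}

#' Total proton ionisation cross-section
#'
#' @inheritParams proton_ionisation_dcs
#' @param rel_tol Quadrature relative tolerance.
#' @return Total cross-section in m\eqn{^2}.
#' @export
proton_tics <- function(E_p, config = load_config(),
                        chain = model_chain("ritracks_like", config),
                        rel_tol = 1e-6) {
  T_eV <- E_p * config$constants$m_over_Mp
  w_hi <- config$rudd_proton$w_max_factor * 4 * T_eV
  model <- chain_model_for(chain, "proton_ionisation", E_p)
  if (model == "born") {
    w_hi <- E_p - min(vapply(config$medium$orbitals, `[[`, 0, "binding_eV"))
  }
  dcs <- function(W) {
    v <- proton_ionisation_dcs(E_p, W, config, chain)
    attributes(v) <- NULL
    v
  }
  total_cross_section(dcs, c(0, w_hi), rel_tol)
}
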