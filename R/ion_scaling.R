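## Heavy-ion ionisation cross-sections by velocity matching and charge
## scaling: an ion of charge Z and mass M interacting at the velocity of a
## proton of energy tau has Z^2 times the proton cross-section, reduced at
## low velocity by the Booth-Grant effective charge.

#' Construct an ion specification
#'
#' @param name Ion name.
#' @param Z Nuclear charge (integer \eqn{\ge 1}).
#' @param mass_ratio Ion-to-proton mass ratio \eqn{M/M_p}.
#' @return An object of class `ion_spec`.
#' @export
ion_spec <- function(name, Z, mass_ratio) {
  if (!is.numeric(Z) || Z < 1 || Z != round(Z)) {
    stop("Z must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(mass_ratio) || mass_ratio <= 0) {
    stop("mass_ratio must be > 0", call. = FALSE)
  }
  structure(list(name = name, Z = as.integer(Z),
                 mass_ratio = as.numeric(mass_ratio)),
            class = "ion_spec")
}

#' Packaged heavy-ion table
#'
#' @param config A `trackmc_config`.
#' @return Named list of `ion_spec` objects (H through Fe by default).
#' @export
ion_table <- function(config = load_config()) {
  ions <- lapply(config$ions, function(x) {
    ion_spec(x$name, x$Z, x$mass_ratio)
  })
  names(ions) <- vapply(ions, `[[`, "", "name")
  ions
}

#' Kinetic energy of an ion moving at a matched proton velocity
#'
#' \eqn{E_{ion} = (M/M_p)\,\tau}: valid relativistically and classically,
#' since equal velocity means equal kinetic energy per unit mass.
#'
#' @param ion An `ion_spec`.
#' @param tau_proton Proton kinetic energy (eV).
#' @return Ion kinetic energy (eV).
#' @export
matched_ion_energy <- function(ion, tau_proton) {
  stopifnot(inherits(ion, "ion_spec"))
  if (any(tau_proton <= 0)) {
    stop("tau_proton must be > 0", call. = FALSE)
  }
  ion$mass_ratio * tau_proton
}

#' Booth-Grant effective charge fraction
#'
#' Low-velocity ions capture electrons and act with a reduced charge
#' \eqn{Z^*}:
#' \deqn{Z^*/Z = 1 - \exp(-1.316 x + 0.112 x^2 - 0.0650 x^3), \qquad
#'   x = 100\,\beta\, Z^{-2/3},}
#' clamped to \eqn{[0, 1]}.  The correction is a few percent for protons
#' near 0.2 MeV and vanishes as \eqn{\beta \to 0}.
#'
#' @param Z Nuclear charge.
#' @param beta Particle speed in units of c, \eqn{0 \le \beta < 1};
#'   vectorised.
#' @return \eqn{Z^*/Z \in [0, 1]}.
#' @export
effective_charge_ratio <- function(Z, beta) {
  if (any(beta < 0) || any(beta >= 1)) {
    stop("beta must satisfy 0 <= beta < 1", call. = FALSE)
  }
  x <- 100 * beta * Z^(-2 / 3)
  ratio <- 1 - exp(-1.316 * x + 0.112 * x^2 - 0.0650 * x^3)
  pmin(pmax(ratio, 0), 1)
}

## Relativistic beta from kinetic energy and rest mass (both eV).
beta_from_energy <- function(E_kin, mass_eV) {
  sqrt(pmax(1 - 1 / (1 + E_kin / mass_eV)^2, 0))
}

#' Heavy-ion ionisation differential cross-section
#'
#' Evaluates the proton DCS at the velocity-matched proton energy
#' \eqn{\tau = E_{ion}/(M/M_p)} and scales it by \eqn{Z^2} (or by
#' \eqn{Z^{*2}} when the effective-charge flag is on; by default the
#' correction switches on automatically below the configured specific
#' energy).
#'
#' @param ion An `ion_spec`.
#' @param E_ion Ion kinetic energy (eV).
#' @param W_eV Secondary electron energy (eV), vectorised.
#' @param config A `trackmc_config`.
#' @param chain A `model_chain` used for the underlying proton DCS.
#' @param use_effective_charge `TRUE`, `FALSE`, or `"auto"` (default:
#'   effective charge applied below `effective_charge.auto_below_eV_per_u`).
#' @return DCS in m\eqn{^2}/eV with attributes `"model"` and `"z_eff"`.
#' @export
ion_ionisation_dcs <- function(ion, E_ion, W_eV, config = load_config(),
                               chain = model_chain("ritracks_like", config),
                               use_effective_charge = "auto") {
  stopifnot(inherits(ion, "ion_spec"))
  if (E_ion <= 0) stop("E_ion must be > 0", call. = FALSE)
  tau <- E_ion / ion$mass_ratio
  mass_eV <- ion$mass_ratio * config$constants$mc2 /
    config$constants$m_over_Mp
  if (identical(use_effective_charge, "auto")) {
    per_u <- E_ion / ion$mass_ratio
    use_effective_charge <-
      per_u < config$effective_charge$auto_below_eV_per_u
  }
  z <- if (isTRUE(use_effective_charge)) {
    beta <- beta_from_energy(E_ion, mass_eV)
    ion$Z * effective_charge_ratio(ion$Z, beta)
  } else {
    as.numeric(ion$Z)
  }
  base <- proton_ionisation_dcs(tau, W_eV, config, chain)
  model <- attr(base, "model")
  attributes(base) <- NULL
  val <- z^2 * base
  attr(val, "model") <- model
  attr(val, "z_eff") <- z
  val
}
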