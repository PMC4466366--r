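## Electron-impact inelastic cross-sections in liquid water.
##
## Ionisation: semiempirical Rudd model (low energy) and Seltzer
## close+distant collision model (high energy).  Excitation: Kutcher-Green
## (high energy) and Kaplan-Sukhonosov/Cobut (low energy).  All differential
## cross-sections are per unit secondary / transferred energy, in m^2/eV.

check_energy_args <- function(T_eV, W_eV) {
  if (any(!is.finite(T_eV)) || any(T_eV < 0)) {
    stop("primary energy T must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(W_eV)) || any(W_eV < 0)) {
    stop("energy transfer W must be finite and non-negative", call. = FALSE)
  }
}

#' Rudd differential cross-section for electron-impact ionisation
#'
#' Semiempirical binary-encounter form for the ejection of a secondary
#' electron of energy `W` by a primary of energy `T` from one molecular
#' orbital.  Because the two outgoing electrons are indistinguishable, the
#' faster one is taken as the primary, restricting the secondary spectrum to
#' \eqn{W \le (T - I_i)/2}.  In scaled variables \eqn{t = T/I_i},
#' \eqn{\omega = W/I_i}:
#' \deqn{d\sigma/d\omega = (S_i/I_i)\,[F_1(t) g_1(t,\omega) +
#'       F_2(t) g_2(t,\omega)]}
#' with \eqn{g_1 = (1+\omega)^{-3} + (t-\omega)^{-3} -
#' (1+\omega)^{-3/2}(t-\omega)^{-3/2}}, \eqn{g_2 = (1+\omega)^{-2} +
#' (t-\omega)^{-2} - (1+\omega)^{-1}(t-\omega)^{-1}} and
#' \eqn{F_k(t) = A_k \ln(t)/(t + B_k)}.  The prefactor \eqn{S_i/I_i}
#' already carries m\eqn{^2}/eV, so the value is per unit secondary energy
#' as written.
#'
#' @param T_eV Primary electron kinetic energy (eV).
#' @param W_eV Secondary (ejected) electron energy (eV); vectorised.
#' @param orbital A `molecular_orbital`.
#' @param params List with `A1`, `A2`, `B1`, `B2` (one shell-class set of the
#'   fitted constants).
#' @param constants A `physical_constants` object.
#' @return Differential cross-section in m\eqn{^2}/eV; 0 below threshold or
#'   outside the secondary-energy support.
#' @export
rudd_electron_dcs <- function(T_eV, W_eV, orbital, params,
                              constants = physical_constants()) {
  check_energy_args(T_eV, W_eV)
  I <- orbital$binding_eV
  t <- T_eV / I
  out <- numeric(length(W_eV))
  if (t <= 1) return(out)
  S <- orbital_prefactor(orbital, constants)
  w <- W_eV / I
  ok <- W_eV <= (T_eV - I) / 2
  if (!any(ok)) return(out)
  w <- w[ok]
  F1 <- params$A1 * log(t) / (t + params$B1)
  F2 <- params$A2 * log(t) / (t + params$B2)
  u1 <- 1 + w
  u2 <- t - w
  g1 <- 1 / u1^3 + 1 / u2^3 - 1 / (u1^1.5 * u2^1.5)
  g2 <- 1 / u1^2 + 1 / u2^2 - 1 / (u1 * u2)
  # S_i/I_i already carries m^2/eV: the scaled form is per unit energy
  val <- (S / I) * (F1 * g1 + F2 * g2)
  out[ok] <- pmax(val, 0)
  out
}

#' Photoelectric cross-section provider from the configuration
#'
#' Returns the callable used by the Seltzer distant-collision term: a
#' function `(orbital, E_eV)` giving the photoelectric cross-section of that
#' molecular orbital for photon energy `E_eV`, zero below the orbital binding
#' energy.  The packaged default is a hydrogenic power-law fall-off anchored
#' at the configured threshold value; its parameters live in the
#' `photoeffect` config section and carry no constraint from the
#' track-structure models themselves.
#'
#' @param config A `trackmc_config`.
#' @return A function `(orbital, E_eV) -> m^2`, vectorised in `E_eV`.
#' @export
photo_xs_provider <- function(config = load_config()) {
  s0 <- config$photoeffect$sigma_at_threshold_m2
  p <- config$photoeffect$exponent
  function(orbital, E_eV) {
    B <- orbital$binding_eV
    ifelse(E_eV >= B, s0 * (B / E_eV)^p, 0)
  }
}

## Virtual-photon intensity per unit photon energy for the distant-collision
## term (leading-log form; the source that ships sigma_PE does not travel
## with the package, so this factor is documented as an editable convention).
virtual_photon_intensity <- function(E_eV, beta2, gamma2, mc2) {
  arg <- 2 * beta2 * gamma2 * mc2 / E_eV
  val <- ifelse(arg > 1, (log(arg) - beta2) / (137.035999 * pi * beta2 * E_eV),
                0)
  pmax(val, 0)
}

#' Seltzer differential cross-section for electron-impact ionisation
#'
#' High-energy ionisation DCS as the sum of a close-collision (binary
#' encounter, Moller-corrected) term and a distant-collision term driven by
#' the orbital photoelectric cross-section.  With \eqn{E = W + B_i},
#' \eqn{\tau = T/mc^2}, \eqn{\beta^2 = 1 - (1+\tau)^{-2}}, \eqn{y = W/U_i}:
#' \deqn{d\sigma_c/dW = \frac{2\pi r_e^2 mc^2 N_i\, T}{\beta^2 (T + B_i + U_i)}
#'   \left[\frac{1}{E^2} + \frac{1}{(T-W)^2} +
#'   \frac{1}{T^2}\Big(\frac{\tau}{\tau+1}\Big)^2 -
#'   \frac{2\tau+1}{(\tau+1)^2}\frac{1}{E(T-W)} + G_i\right]}
#' \deqn{G_i = \frac{8 U_i}{3\pi}\left[\frac{1}{E^3} +
#'   \frac{1}{(T-W)^3}\right]\left[\tan^{-1}\sqrt{y} +
#'   \frac{\sqrt{y}(y-1)}{(y+1)^2}\right]}
#' and \eqn{d\sigma_d/dW = N_i\, I(E)\, \sigma_{PE}^i(E)} with \eqn{I(E)} the
#' virtual-photon intensity.
#'
#' @inheritParams rudd_electron_dcs
#' @param pe Photoelectric provider `(orbital, E_eV) -> m^2`; use a function
#'   returning 0 to obtain the close-collision term alone.
#' @return DCS in m\eqn{^2}/eV, zero outside \eqn{0 \le W \le (T-B_i)/2}.
#' @export
seltzer_dcs <- function(T_eV, W_eV, orbital, pe = function(orbital, E) 0,
                        constants = physical_constants()) {
  check_energy_args(T_eV, W_eV)
  B <- orbital$binding_eV
  U <- orbital$kinetic_eV
  N <- orbital$n_electrons
  out <- numeric(length(W_eV))
  if (T_eV <= B) return(out)
  ok <- W_eV <= (T_eV - B) / 2
  if (!any(ok)) return(out)
  W <- W_eV[ok]
  mc2 <- constants$mc2
  tau <- T_eV / mc2
  gamma2 <- (1 + tau)^2
  beta2 <- 1 - 1 / gamma2
  E <- W + B
  TmW <- T_eV - W
  y <- W / U
  G <- (8 * U / (3 * pi)) * (1 / E^3 + 1 / TmW^3) *
    (atan(sqrt(y)) + sqrt(y) * (y - 1) / (y + 1)^2)
  bracket <- 1 / E^2 + 1 / TmW^2 +
    (1 / T_eV^2) * (tau / (tau + 1))^2 -
    (2 * tau + 1) / (tau + 1)^2 / (E * TmW) + G
  # binary-encounter factor T/(T+B+U): restores the Moller 1/W^2 limit at
  # high T and keeps the close term dimensionally consistent
  close_term <- 2 * pi * constants$r_e^2 * mc2 * N * T_eV /
    (beta2 * (T_eV + B + U)) * bracket
  pe_val <- pe(orbital, E)
  if (any(pe_val < 0)) {
    stop("photoelectric provider returned a negative cross-section",
         call. = FALSE)
  }
  distant <- N * virtual_photon_intensity(E, beta2, gamma2, mc2) * pe_val
  out[ok] <- pmax(close_term + distant, 0)
  out
}

#' Minimum energy transfer in a free-electron collision
#'
#' \eqn{Q_{\min} = 2T\,(1 - W/(2T) - \sqrt{1 - W/T})}: the smallest energy a
#' charged particle of energy `T` can transfer to a free electron at rest
#' while losing total energy `W`.
#'
#' @param T_eV Primary energy (eV).
#' @param W_eV Energy lost (eV), vectorised; must satisfy \eqn{W \le T}.
#' @return \eqn{Q_{\min}} in eV.
#' @export
q_min <- function(T_eV, W_eV) {
  check_energy_args(T_eV, W_eV)
  if (any(W_eV > T_eV)) {
    stop("q_min requires W <= T", call. = FALSE)
  }
  x <- W_eV / T_eV
  pmax(2 * T_eV * (1 - x / 2 - sqrt(1 - x)), 0)
}

#' Rutherford free-electron collision kernel
#'
#' \eqn{\rho(W) = 4\pi a_0^2\, \Re^2 / (T W^2)}: the differential
#' cross-section for energy transfer `W` from a charged particle of energy
#' `T` to a free electron at rest.
#'
#' @inheritParams q_min
#' @param constants A `physical_constants` object.
#' @return \eqn{\rho(W)} in m\eqn{^2}/eV.
#' @export
rho_free <- function(T_eV, W_eV, constants = physical_constants()) {
  check_energy_args(T_eV, W_eV)
  if (any(W_eV > T_eV)) {
    stop("rho_free requires W <= T", call. = FALSE)
  }
  4 * pi * constants$a0^2 * constants$rydberg^2 / (T_eV * W_eV^2)
}

#' Kutcher-Green differential cross-section for electron excitation
#'
#' High-energy (intended \eqn{T > 100} eV) excitation DCS:
#' \eqn{(\rho(W)/W)\, f_i(W)\, \ln(4T/Q_{\min})}, clamped to zero wherever
#' the logarithm argument does not exceed one.
#'
#' @inheritParams rho_free
#' @param level An `excitation_level` supplying the Gaussian strength
#'   function \eqn{f_i(W)}.
#' @return DCS in m\eqn{^2}/eV.
#' @export
kutcher_green_dcs <- function(T_eV, W_eV, level,
                              constants = physical_constants()) {
  check_energy_args(T_eV, W_eV)
  out <- numeric(length(W_eV))
  ok <- W_eV > 0 & W_eV <= T_eV
  if (!any(ok)) return(out)
  W <- W_eV[ok]
  qm <- q_min(T_eV, W)
  arg <- ifelse(qm > 0, 4 * T_eV / qm, Inf)
  val <- rho_free(T_eV, W, constants) / W * level_strength(level, W) *
    log(pmax(arg, 1))
  out[ok] <- pmax(val, 0)
  out
}

#' Kaplan-Sukhonosov differential cross-section for electron excitation
#'
#' Low-energy (intended \eqn{T < 100} eV) excitation DCS:
#' \eqn{(\rho(W)/W)\, f_i(W)\, \ln(\alpha T/W)} with the interpolating factor
#' \eqn{\alpha = 4 - 3\exp[-(W - W_{0,i})/\alpha_i]},
#' \eqn{\alpha_i = 4E_{\min}/\ln 2} and \eqn{E_{\min} = 7.34} eV the minimum
#' energy transfer by excitation.  Clamped to zero wherever the logarithm
#' argument does not exceed one; zero below \eqn{E_{\min}}.
#'
#' @inheritParams kutcher_green_dcs
#' @return DCS in m\eqn{^2}/eV.
#' @export
kaplan_dcs <- function(T_eV, W_eV, level, constants = physical_constants()) {
  check_energy_args(T_eV, W_eV)
  out <- numeric(length(W_eV))
  ok <- W_eV >= level$e_min_eV & W_eV <= T_eV
  if (!any(ok)) return(out)
  W <- W_eV[ok]
  alpha <- 4 - 3 * exp(-(W - level$w0_eV) / level$alpha_i)
  arg <- alpha * T_eV / W
  val <- ifelse(arg > 1,
                rho_free(T_eV, W, constants) / W *
                  level_strength(level, W) * log(arg),
                0)
  out[ok] <- pmax(val, 0)
  out
}

#' Integrate a differential cross-section over its energy-transfer support
#'
#' Adaptive quadrature of a non-negative W-differential cross-section.
#'
#' @param dcs Function of `W` (vectorised) returning m\eqn{^2}/eV.
#' @param support Numeric length-2, the integration interval in eV.
#' @param rel_tol Relative tolerance (default `1e-6`).
#' @return Total cross-section in m\eqn{^2}; 0 for an empty support.
#' @export
total_cross_section <- function(dcs, support, rel_tol = 1e-6) {
  lo <- support[1L]
  hi <- support[2L]
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) return(0)
  # steep (~W^-2) integrands over wide supports: integrate decade by decade
  breaks <- c(lo, hi)
  if (hi > 100 * max(lo, 1)) {
    inner <- 10^seq(ceiling(log10(max(lo, 1))), floor(log10(hi)))
    breaks <- sort(unique(c(lo, inner[inner > lo & inner < hi], hi)))
  }
  total <- 0
  for (k in seq_len(length(breaks) - 1L)) {
    res <- stats::integrate(dcs, breaks[k], breaks[k + 1L],
                            rel.tol = rel_tol, subdivisions = 2000L,
                            stop.on.error = FALSE)
    if (res$message != "OK") {
      cond <- simpleError(sprintf(
        "quadrature did not converge (%s); achieved estimate %.6e",
        res$message, total + res$value))
      cond$estimate <- total + res$value
      stop(cond)
    }
    total <- total + res$value
  }
  max(total, 0)
}

## Secondary-energy support of an electron ionisation channel.
electron_ion_support <- function(T_eV, orbital) {
  c(0, max((T_eV - orbital$binding_eV) / 2, 0))
}

#' Total electron-impact ionisation cross-section
#'
#' Sums the per-orbital totals of the model the chain binds at `T_eV`
#' (Rudd, Seltzer or Born depending on the chain).
#'
#' @param T_eV Primary electron energy (eV).
#' @param config A `trackmc_config`.
#' @param chain A `model_chain` (default RITRACKS-like).
#' @param rel_tol Quadrature relative tolerance.
#' @return Total ionisation cross-section in m\eqn{^2}.
#' @export
electron_tics <- function(T_eV, config = load_config(),
                          chain = model_chain("ritracks_like", config),
                          rel_tol = 1e-6) {
  sum(vapply(seq_along(config$medium$orbitals), function(i) {
    ch <- electron_ion_channel_dcs(T_eV, config, chain, i)
    total_cross_section(ch$dcs, ch$support, rel_tol)
  }, 0))
}

#' Per-channel electron differential cross-sections under a model chain
#'
#' Dispatches every ionisation (orbital) and excitation (level) channel to
#' the model bound by the chain at energy `T_eV` and evaluates the DCS at
#' `W_eV`, recording the model identifier per channel.
#'
#' @param T_eV Primary electron energy (eV).
#' @param W_eV Energy transfer / secondary energy (eV), scalar.
#' @param config A `trackmc_config`.
#' @param chain A `model_chain`.
#' @return A data.frame with columns `channel`, `process`, `index`, `model`,
#'   `dcs_m2_eV`.
#' @export
electron_channel_dcs <- function(T_eV, W_eV, config = load_config(),
                                 chain = model_chain("ritracks_like",
                                                     config)) {
  med <- config$medium
  rows <- list()
  for (i in seq_along(med$orbitals)) {
    ch <- electron_ion_channel_dcs(T_eV, config, chain, i)
    rows[[length(rows) + 1L]] <- data.frame(
      channel = med$orbitals[[i]]$label, process = "ionisation",
      index = i, model = ch$model, dcs_m2_eV = ch$dcs(W_eV),
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(med$excitation_levels)) {
    ch <- electron_exc_channel_dcs(T_eV, config, chain, i)
    rows[[length(rows) + 1L]] <- data.frame(
      channel = med$excitation_levels[[i]]$label, process = "excitation",
      index = i, model = ch$model, dcs_m2_eV = ch$dcs(W_eV),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## Internal: one electron ionisation channel (orbital i) under a chain.
## Returns list(dcs = function(W), support = c(lo, hi), model = id).
electron_ion_channel_dcs <- function(T_eV, config, chain, i) {
  med <- config$medium
  orb <- med$orbitals[[i]]
  cst <- config$constants
  model <- chain_model_for(chain, "electron_ionisation", T_eV)
  if (model == "rudd") {
    cls <- if (orb$shell_class == "inner") "inner" else "liquid"
    par <- config$rudd_electron[[cls]]
    list(dcs = function(W) rudd_electron_dcs(T_eV, W, orb, par, cst),
         support = electron_ion_support(T_eV, orb), model = model)
  } else if (model == "seltzer") {
    pe <- photo_xs_provider(config)
    list(dcs = function(W) seltzer_dcs(T_eV, W, orb, pe, cst),
         support = electron_ion_support(T_eV, orb), model = model)
  } else if (model == "born") {
    elf <- elf_provider(config)
    list(dcs = function(W) born_ionisation_dcs(T_eV, W, orb, med, elf,
                                               cst, mass_eV = cst$mc2,
                                               eta_full_eV =
                                                 born_eta_full(config),
                                               exchange = TRUE),
         support = electron_ion_support(T_eV, orb), model = model)
  } else {
    stop(sprintf("unknown electron ionisation model '%s'", model),
         call. = FALSE)
  }
}

## Internal: one electron excitation channel (level i) under a chain.
electron_exc_channel_dcs <- function(T_eV, config, chain, i) {
  med <- config$medium
  lev <- med$excitation_levels[[i]]
  cst <- config$constants
  model <- chain_model_for(chain, "electron_excitation", T_eV)
  hi <- function() min(T_eV, lev$center_eV + 8 * lev$width_eV)
  if (model == "kutcher_green") {
    list(dcs = function(W) kutcher_green_dcs(T_eV, W, lev, cst),
         support = c(med$e_min_eV, hi()), model = model)
  } else if (model == "kaplan") {
    list(dcs = function(W) kaplan_dcs(T_eV, W, lev, cst),
         support = c(med$e_min_eV, hi()), model = model)
  } else if (model == "born_excitation") {
    elf <- elf_provider(config)
    eta_full <- born_eta_full(config)
    # dielectric machinery weighted by the non-ionising fraction of the
    # strength (1 - eta), split evenly across the five levels
    list(dcs = function(W) {
      inside <- W >= med$e_min_eV & W < min(eta_full, T_eV)
      out <- numeric(length(W))
      if (any(inside)) {
        frac <- 1 - ionisation_efficiency(W[inside], med, eta_full)
        out[inside] <- frac *
          born_sdcs(T_eV, W[inside], mass_eV = cst$mc2, elf = elf,
                    constants = cst) /
          med$number_density_m3 / length(med$excitation_levels)
      }
      out
    },
    support = c(med$e_min_eV, min(eta_full, T_eV)), model = model)
  } else {
    stop(sprintf("unknown electron excitation model '%s'", model),
         call. = FALSE)
  }
}
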