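#' Path to the packaged default liquid-water configuration
#'
#' @return Path to the YAML configuration shipped with the package.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "trackmc",
              mustWork = TRUE)
}

#' Load and validate a full trackmc configuration
#'
#' Reads the YAML configuration (constants, medium, orbital and
#' excitation-level tables, fitted model parameters, dielectric response,
#' chain boundaries, transport defaults) and validates every section.  All
#' physics functions in the package draw their parameters from the object
#' returned here; none hard-code a fitted number.
#'
#' @param path Path to a YAML configuration file, or `NULL` for the packaged
#'   default.
#' @return An object of class `trackmc_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) path <- default_config_path()
  raw <- yaml::read_yaml(path)
  cfg <- validate_config(raw)
  cfg$source_path <- path
  class(cfg) <- "trackmc_config"
  cfg
}

config_error <- function(field, msg) {
  stop(sprintf("config validation error in '%s': %s", field, msg),
       call. = FALSE)
}

need_positive <- function(x, field) {
  if (is.null(x) || !is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x <= 0) {
    config_error(field, "must be a single strictly positive number")
  }
  as.numeric(x)
}

validate_config <- function(raw) {
  for (sec in c("constants", "medium", "orbitals", "excitation_levels",
                "rudd_electron", "rudd_proton", "born_elf")) {
    if (is.null(raw[[sec]])) config_error(sec, "section missing")
  }
  cfg <- raw
  cfg$constants <- do.call(physical_constants, raw$constants)
  cfg$medium <- build_medium(raw)
  cfg$rudd_electron <- validate_rudd_electron(raw$rudd_electron)
  cfg$rudd_proton <- validate_rudd_proton(raw$rudd_proton)
  cfg
}

#' Physical constants used by the cross-section models
#'
#' @param bohr_radius_m Bohr radius \eqn{a_0} (m).
#' @param rydberg_eV Rydberg energy \eqn{\Re} (eV).
#' @param classical_electron_radius_m Classical electron radius \eqn{r_e} (m).
#' @param electron_rest_energy_eV Electron rest energy \eqn{mc^2} (eV).
#' @param electron_proton_mass_ratio \eqn{m/M_p}, dimensionless.
#' @param vacuum_permittivity_si \eqn{\varepsilon_0} (SI units).
#' @return An object of class `physical_constants`.
#' @export
physical_constants <- function(bohr_radius_m = 5.29177210903e-11,
                               rydberg_eV = 13.605693122994,
                               classical_electron_radius_m = 2.817e-15,
                               electron_rest_energy_eV = 510998.95,
                               electron_proton_mass_ratio = 5.44617021487e-4,
                               vacuum_permittivity_si = 8.8541878128e-12) {
  cst <- list(
    a0 = need_positive(bohr_radius_m, "constants.bohr_radius_m"),
    rydberg = need_positive(rydberg_eV, "constants.rydberg_eV"),
    r_e = need_positive(classical_electron_radius_m,
                        "constants.classical_electron_radius_m"),
    mc2 = need_positive(electron_rest_energy_eV,
                        "constants.electron_rest_energy_eV"),
    m_over_Mp = need_positive(electron_proton_mass_ratio,
                              "constants.electron_proton_mass_ratio"),
    eps0 = need_positive(vacuum_permittivity_si,
                         "constants.vacuum_permittivity_si"))
  class(cst) <- "physical_constants"
  cst
}

valid_orbital_labels <- c("1b1", "3a1", "1b2", "2a1", "1a1")

validate_orbital <- function(o, where) {
  for (f in c("index", "label", "n_electrons", "binding_eV", "kinetic_eV",
              "r_mean_angstrom", "shell_class")) {
    if (is.null(o[[f]])) config_error(paste0(where, ".", f), "field missing")
  }
  o$n_electrons <- need_positive(o$n_electrons, paste0(where, ".n_electrons"))
  o$binding_eV <- need_positive(o$binding_eV, paste0(where, ".binding_eV"))
  o$kinetic_eV <- need_positive(o$kinetic_eV, paste0(where, ".kinetic_eV"))
  if (!o$shell_class %in% c("outer", "inner")) {
    config_error(paste0(where, ".shell_class"), "must be 'outer' or 'inner'")
  }
  class(o) <- "molecular_orbital"
  o
}

validate_level <- function(l, e_min, where) {
  for (f in c("index", "label", "w0_eV", "center_eV", "width_eV",
              "amplitude")) {
    if (is.null(l[[f]])) config_error(paste0(where, ".", f), "field missing")
  }
  l$w0_eV <- need_positive(l$w0_eV, paste0(where, ".w0_eV"))
  l$width_eV <- need_positive(l$width_eV, paste0(where, ".width_eV"))
  if (l$amplitude < 0) {
    config_error(paste0(where, ".amplitude"), "must be non-negative")
  }
  l$e_min_eV <- e_min
  # linking scale of the low-energy excitation model
  l$alpha_i <- 4 * e_min / log(2)
  class(l) <- "excitation_level"
  l
}

build_medium <- function(raw) {
  med <- raw$medium
  density <- need_positive(med$mass_density_g_cm3,
                           "medium.mass_density_g_cm3")
  molar <- need_positive(med$molar_mass_g_mol, "medium.molar_mass_g_mol")

  orbs <- raw$orbitals
  if (length(orbs) != 5L) {
    config_error("orbitals", sprintf(
      "exactly 5 molecular orbitals required, got %d", length(orbs)))
  }
  orbs <- lapply(seq_along(orbs), function(i) {
    validate_orbital(orbs[[i]], sprintf("orbitals[%d]", i))
  })
  labels <- vapply(orbs, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    config_error("orbitals", sprintf("duplicate orbital label '%s'",
                                     labels[duplicated(labels)][1L]))
  }

  exc <- raw$excitation_levels
  e_min <- need_positive(exc$e_min_eV, "excitation_levels.e_min_eV")
  levels <- exc$levels
  if (length(levels) != 5L) {
    config_error("excitation_levels.levels", sprintf(
      "exactly 5 excitation levels required, got %d", length(levels)))
  }
  levels <- lapply(seq_along(levels), function(i) {
    validate_level(levels[[i]], e_min,
                   sprintf("excitation_levels.levels[%d]", i))
  })

  avogadro <- 6.02214076e23
  n_cm3 <- density * avogadro / molar
  spec <- list(
    mass_density_g_cm3 = density,
    molar_mass_g_mol = molar,
    number_density_cm3 = n_cm3,
    number_density_m3 = n_cm3 * 1e6,
    e_min_eV = e_min,
    orbitals = orbs,
    excitation_levels = levels)
  class(spec) <- "medium_spec"
  spec
}

#' Load a validated water-medium specification
#'
#' Builds the `medium_spec` (number density, the five molecular orbitals, the
#' five excitation levels) from a configuration.  Accepts a path to a YAML
#' file, a raw configuration list, or an already loaded `trackmc_config`.
#'
#' @param config A `trackmc_config`, a YAML path, a raw config list, or `NULL`
#'   for the packaged default.
#' @return An object of class `medium_spec`.
#' @examples
#' med <- load_medium()
#' med$orbitals[[1]]$binding_eV   # 11.50 eV for the 1b1 orbital
#' @export
load_medium <- function(config = NULL) {
  if (is.null(config)) config <- load_config()
  if (is.character(config)) config <- load_config(config)
  if (inherits(config, "trackmc_config")) return(config$medium)
  if (is.list(config)) return(build_medium(config))
  stop("config must be a trackmc_config, a path or a list", call. = FALSE)
}

#' Serialise a medium specification back to a config fragment
#'
#' Writes a YAML file whose `medium`, `orbitals` and `excitation_levels`
#' sections reproduce `medium` bit-exactly when read back with
#' [load_medium()].
#'
#' @param medium A `medium_spec`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_medium_yaml <- function(medium, path) {
  stopifnot(inherits(medium, "medium_spec"))
  strip <- function(x, drop) {
    x <- unclass(x)
    x[setdiff(names(x), drop)]
  }
  out <- list(
    medium = list(mass_density_g_cm3 = medium$mass_density_g_cm3,
                  molar_mass_g_mol = medium$molar_mass_g_mol),
    orbitals = lapply(medium$orbitals, strip, drop = character()),
    excitation_levels = list(
      e_min_eV = medium$e_min_eV,
      levels = lapply(medium$excitation_levels, strip,
                      drop = c("e_min_eV", "alpha_i"))))
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' Orbital interaction prefactor
#'
#' The geometric prefactor \eqn{S_i = 4\pi a_0^2 N_i (\Re/I_i)^2} shared by
#' the semiempirical ionisation models: the Rutherford scale \eqn{4\pi a_0^2}
#' weighted by the orbital occupancy and by the squared ratio of the Rydberg
#' energy to the orbital binding energy.
#'
#' @param orbital A `molecular_orbital`.
#' @param constants A `physical_constants` object.
#' @return Cross-section scale \eqn{S_i} in m\eqn{^2}.
#' @export
orbital_prefactor <- function(orbital, constants = physical_constants()) {
  stopifnot(inherits(orbital, "molecular_orbital"))
  4 * pi * constants$a0^2 * orbital$n_electrons *
    (constants$rydberg / orbital$binding_eV)^2
}

#' Construct a molecular orbital (mainly for tests and synthetic studies)
#'
#' @param label Orbital label.
#' @param n_electrons Occupancy \eqn{N_i}.
#' @param binding_eV Binding energy \eqn{B_i = I_i} (eV).
#' @param kinetic_eV Mean orbital kinetic energy \eqn{U_i} (eV).
#' @param shell_class `"outer"` or `"inner"`.
#' @param index Orbital index.
#' @param r_mean_angstrom Mean orbital radius (informational).
#' @return A `molecular_orbital`.
#' @export
molecular_orbital <- function(label, n_electrons, binding_eV, kinetic_eV,
                              shell_class = "outer", index = 1L,
                              r_mean_angstrom = 1.0) {
  validate_orbital(list(index = index, label = label,
                        n_electrons = n_electrons, binding_eV = binding_eV,
                        kinetic_eV = kinetic_eV,
                        r_mean_angstrom = r_mean_angstrom,
                        shell_class = shell_class),
                   sprintf("orbital '%s'", label))
}

#' Construct an excitation level (mainly for tests and synthetic studies)
#'
#' @param label Level label.
#' @param w0_eV Linking energy \eqn{W_{0,i}} (eV).
#' @param center_eV,width_eV,amplitude Gaussian strength-function parameters.
#' @param e_min_eV Minimum excitation energy transfer (eV).
#' @param index Level index.
#' @return An `excitation_level`.
#' @export
excitation_level <- function(label, w0_eV, center_eV, width_eV, amplitude,
                             e_min_eV = 7.34, index = 1L) {
  validate_level(list(index = index, label = label, w0_eV = w0_eV,
                      center_eV = center_eV, width_eV = width_eV,
                      amplitude = amplitude),
                 e_min_eV, sprintf("level '%s'", label))
}

#' Gaussian strength function of an excitation level
#'
#' @param level An `excitation_level`.
#' @param W Energy transfer (eV), vectorised.
#' @return \eqn{f_i(W) \ge 0}.
#' @export
level_strength <- function(level, W) {
  level$amplitude * exp(-(W - level$center_eV)^2 / (2 * level$width_eV^2))
}

#' @export
print.medium_spec <- function(x, ...) {
  cat("Liquid-water medium specification\n")
  cat(sprintf("  density %.4g g/cm^3, N = %.4g molecules/cm^3\n",
              x$mass_density_g_cm3, x$number_density_cm3))
  cat(sprintf("  %d molecular orbitals: %s\n", length(x$orbitals),
              paste(vapply(x$orbitals, `[[`, "", "label"), collapse = ", ")))
  cat(sprintf("  %d excitation levels, E_min = %.3g eV\n",
              length(x$excitation_levels), x$e_min_eV))
  invisible(x)
}

#' @export
print.trackmc_config <- function(x, ...) {
  cat("trackmc configuration (", x$source_path, ")\n", sep = "")
  print(x$medium)
  invisible(x)
}

validate_rudd_electron <- function(p) {
  for (cls in c("liquid", "inner")) {
    if (is.null(p[[cls]])) config_error(paste0("rudd_electron.", cls),
                                        "parameter set missing")
    for (f in c("A1", "A2", "B1", "B2")) {
      v <- p[[cls]][[f]]
      if (is.null(v) || !is.numeric(v) || v < 0) {
        config_error(paste0("rudd_electron.", cls, ".", f),
                     "must be a non-negative number")
      }
    }
  }
  p
}

validate_rudd_proton <- function(p) {
  for (cls in c("outer", "inner")) {
    if (is.null(p[[cls]])) config_error(paste0("rudd_proton.", cls),
                                        "parameter set missing")
    for (f in c("A1", "B1", "C1", "D1", "E1", "A2", "B2", "C2", "D2",
                "alpha")) {
      v <- p[[cls]][[f]]
      if (is.null(v) || !is.numeric(v) || !is.finite(v)) {
        config_error(paste0("rudd_proton.", cls, ".", f),
                     "must be a finite number")
      }
    }
  }
  if (is.null(p$relativistic_threshold_eV)) p$relativistic_threshold_eV <- 5e5
  if (is.null(p$w_max_factor)) p$w_max_factor <- 4.0
  p
}
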