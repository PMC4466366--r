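## Table-driven physics for the transport loop: per-species energy grids of
## channel cross-sections and inverse-CDF energy-loss quantile tables,
## built once per (chain, configuration) and handed to the compiled
## event loop.

## Internal: one proton ionisation channel (orbital i) under a chain.
proton_ion_channel_dcs <- function(E_p, config, chain, i) {
  med <- config$medium
  orb <- med$orbitals[[i]]
  cst <- config$constants
  model <- chain_model_for(chain, "proton_ionisation", E_p)
  T_eV <- E_p * cst$m_over_Mp
  if (model == "rudd") {
    cls <- if (orb$shell_class == "inner") "inner" else "outer"
    mode <- if (E_p > config$rudd_proton$relativistic_threshold_eV) {
      "relativistic"
    } else {
      "classical"
    }
    par <- config$rudd_proton[[cls]]
    list(dcs = function(W) proton_rudd_dcs(E_p, W, orb, par, mode, cst,
                                           config$rudd_proton$w_max_factor),
         support = c(0, config$rudd_proton$w_max_factor * 4 * T_eV),
         model = model)
  } else if (model == "born") {
    elf <- elf_provider(config)
    mass_eV <- cst$mc2 / cst$m_over_Mp
    list(dcs = function(W) born_ionisation_dcs(E_p, W, orb, med, elf, cst,
                                               mass_eV),
         support = c(0, max(E_p - orb$binding_eV, 0)), model = model)
  } else {
    stop(sprintf("unknown proton ionisation model '%s'", model),
         call. = FALSE)
  }
}

## Internal: the channel list for one species under a chain.
## Each element: function(E) -> list(dcs, support, model), plus metadata.
species_channels <- function(species, config, chain, ion = NULL) {
  med <- config$medium
  chans <- list()
  if (species == "electron") {
    for (i in seq_along(med$orbitals)) {
      local({
        ii <- i
        chans[[length(chans) + 1L]] <<- list(
          label = med$orbitals[[ii]]$label, process = 1L,
          binding = med$orbitals[[ii]]$binding_eV,
          at = function(E) electron_ion_channel_dcs(E, config, chain, ii))
      })
    }
    for (i in seq_along(med$excitation_levels)) {
      local({
        ii <- i
        chans[[length(chans) + 1L]] <<- list(
          label = med$excitation_levels[[ii]]$label, process = 2L,
          binding = 0,
          at = function(E) electron_exc_channel_dcs(E, config, chain, ii))
      })
    }
  } else if (species == "proton") {
    for (i in seq_along(med$orbitals)) {
      local({
        ii <- i
        chans[[length(chans) + 1L]] <<- list(
          label = med$orbitals[[ii]]$label, process = 1L,
          binding = med$orbitals[[ii]]$binding_eV,
          at = function(E) proton_ion_channel_dcs(E, config, chain, ii))
      })
    }
  } else if (species == "ion") {
    if (is.null(ion)) stop("ion species requires an ion_spec", call. = FALSE)
    for (i in seq_along(med$orbitals)) {
      local({
        ii <- i
        chans[[length(chans) + 1L]] <<- list(
          label = med$orbitals[[ii]]$label, process = 1L,
          binding = med$orbitals[[ii]]$binding_eV,
          at = function(E) {
            tau <- E / ion$mass_ratio
            base <- proton_ion_channel_dcs(tau, config, chain, ii)
            z <- as.numeric(ion$Z)
            if (tau < config$effective_charge$auto_below_eV_per_u) {
              mass_eV <- ion$mass_ratio * config$constants$mc2 /
                config$constants$m_over_Mp
              z <- z * effective_charge_ratio(ion$Z,
                                              beta_from_energy(E, mass_eV))
            }
            list(dcs = function(W) z^2 * base$dcs(W),
                 support = base$support, model = base$model)
          })
      })
    }
  } else {
    stop(sprintf("unknown species '%s'", species), call. = FALSE)
  }
  chans
}

#' Build table-driven physics for the transport loop
#'
#' Tabulates, for every interaction channel of every species, the total
#' cross-section and the inverse-CDF energy-loss quantiles on a log-uniform
#' energy grid under the given model chain.  The transport loop interpolates
#' these tables rather than re-evaluating the differential cross-sections at
#' every collision, the way production track-structure codes precompute
#' their physics.
#'
#' @param config A `trackmc_config`.
#' @param chain A `model_chain` (or chain name).
#' @param species Character vector; tables are built for each (the electron
#'   table is always included, since every ionisation spawns electrons).
#' @param e_range_proton,e_range_electron Energy-grid ranges (eV).
#' @param n_energy Grid points per species (default from config).
#' @param n_quantile Energy-loss quantile nodes (default from config).
#' @param ion An `ion_spec`, required when `"ion"` is in `species`.
#' @return An object of class `physics_tables`.
#' @export
build_physics_tables <- function(config = load_config(),
                                 chain = model_chain("ritracks_like",
                                                     config),
                                 species = c("electron", "proton"),
                                 e_range_proton = c(1e2, 1.2e8),
                                 e_range_electron = c(8, 1e6),
                                 n_energy = NULL, n_quantile = NULL,
                                 ion = NULL) {
  if (is.character(chain)) chain <- model_chain(chain, config)
  if (is.null(n_energy)) n_energy <- config$transport$energy_grid_points
  if (is.null(n_quantile)) n_quantile <- config$transport$quantile_points
  species <- unique(c("electron", species))
  tabs <- list()
  for (sp in species) {
    rng <- if (sp == "electron") e_range_electron else e_range_proton
    tabs[[sp]] <- build_species_table(sp, config, chain, rng, n_energy,
                                      n_quantile, ion)
  }
  structure(list(tables = tabs, species_names = names(tabs),
                 number_density_m3 = config$medium$number_density_m3,
                 chain_name = chain$name),
            class = "physics_tables")
}

build_species_table <- function(species, config, chain, e_range, n_energy,
                                n_quantile, ion = NULL) {
  chans <- species_channels(species, config, chain, ion)
  nC <- length(chans)
  loge <- seq(log10(e_range[1L]), log10(e_range[2L]),
              length.out = n_energy)
  egrid <- 10^loge
  sigma <- matrix(0, n_energy, nC)
  qtab <- array(1e-3, dim = c(n_energy, nC, n_quantile))
  model_names <- character()
  model_code <- matrix(1L, n_energy, nC)
  # cap the stored quantiles at the 1 - 1e-4 point: linear interpolation
  # across an unbounded last bin would grossly inflate the sampled tail of
  # steep (~W^-2 with soft cutoff) spectra
  probs <- seq(0, 1, length.out = n_quantile) * (1 - 1e-4)
  for (e in seq_len(n_energy)) {
    for (c in seq_len(nC)) {
      ch <- chans[[c]]$at(egrid[e])
      if (!ch$model %in% model_names) {
        model_names <- c(model_names, ch$model)
      }
      model_code[e, c] <- match(ch$model, model_names)
      smp <- build_sampler(ch$dcs, ch$support, grid_points = 256L,
                           T_eV = egrid[e], channel = chans[[c]]$label)
      if (!smp$empty) {
        sigma[e, c] <- smp$sigma_tot
        qtab[e, c, ] <- sampler_quantile(smp, probs)
      }
    }
  }
  list(species = species,
       loge = loge,
       sigma = sigma,
       chan_process = vapply(chans, `[[`, 0L, "process"),
       chan_binding = vapply(chans, `[[`, 0, "binding"),
       chan_label = vapply(chans, `[[`, "", "label"),
       model_code = model_code,
       model_names = model_names,
       qtab = as.numeric(qtab),
       n_quantile = as.integer(n_quantile))
}

#' Hand-built constant-cross-section physics tables (for verification runs)
#'
#' Builds a `physics_tables` object with a single toy channel of constant
#' cross-section and fixed energy loss for the primary species, and a
#' zero-cross-section electron table.  With these tables the number of
#' interactions of a primary crossing a box of side L is exactly Poisson
#' with mean \eqn{N \sigma L}, which anchors the transport loop to a closed
#' form.
#'
#' @param sigma_m2 Constant channel cross-section (m\eqn{^2}).
#' @param W_eV Fixed energy loss per event (eV).
#' @param process `"ionisation"` or `"excitation"`.
#' @param binding_eV Binding energy deposited per ionisation (eV).
#' @param number_density_m3 Molecular number density (m\eqn{^{-3}}).
#' @param species Primary species name (default `"proton"`).
#' @return A `physics_tables` object.
#' @export
toy_physics_tables <- function(sigma_m2, W_eV,
                               process = c("ionisation", "excitation"),
                               binding_eV = 0,
                               number_density_m3 = 3.3428e28,
                               species = "proton") {
  process <- match.arg(process)
  proc_code <- if (process == "ionisation") 1L else 2L
  nQ <- 4L
  toy <- function(sig, proc, bind) {
    list(species = species, loge = c(0, 9),
         sigma = matrix(sig, 2, 1),
         chan_process = proc, chan_binding = bind,
         chan_label = "toy",
         model_code = matrix(1L, 2, 1), model_names = "toy",
         qtab = rep(W_eV, 2 * nQ), n_quantile = nQ)
  }
  tabs <- list(electron = toy(0, 2L, 0))
  tabs[[species]] <- toy(sigma_m2, proc_code, binding_eV)
  structure(list(tables = tabs, species_names = names(tabs),
                 number_density_m3 = number_density_m3,
                 chain_name = "toy"),
            class = "physics_tables")
}

#' @export
print.physics_tables <- function(x, ...) {
  cat(sprintf("Physics tables (chain '%s', N = %.4g m^-3)\n",
              x$chain_name, x$number_density_m3))
  for (sp in x$species_names) {
    t <- x$tables[[sp]]
    cat(sprintf("  %-9s %d channels, %d energies [%.3g, %.3g] eV\n", sp,
                ncol(t$sigma), length(t$loge), 10^t$loge[1L],
                10^t$loge[length(t$loge)]))
  }
  invisible(x)
}
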