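## Event-by-event Monte Carlo of a primary particle and its
## secondary-electron cascade in a cubic water target.

#' Simulation configuration for the transport experiment
#'
#' @param box_um Cube edge length (micrometres; default 7).
#' @param cutoff_electron_eV Electron tracking cutoff (eV; default 10).
#'   Electrons below it deposit their remaining energy locally.
#' @param cutoff_proton_eV Proton/ion tracking cutoff (eV; default 100).
#' @param n_histories Number of independent primary histories.
#' @param seed Master seed; each history re-seeds its own stream through
#'   [history_seed()].
#' @param chain Chain name (`"ritracks_like"` or `"geant4dna_like"`).
#' @param secondary_emission `"isotropic"` or `"forward"` emission of
#'   secondary electrons.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(box_um = 7, cutoff_electron_eV = 10,
                       cutoff_proton_eV = 100, n_histories = 100L,
                       seed = 1L, chain = "ritracks_like",
                       secondary_emission = c("isotropic", "forward")) {
  secondary_emission <- match.arg(secondary_emission)
  if (!is.numeric(box_um) || box_um <= 0) {
    stop("box edge length must be > 0", call. = FALSE)
  }
  if (cutoff_electron_eV < 0 || cutoff_proton_eV < 0) {
    stop("tracking cutoffs must be >= 0", call. = FALSE)
  }
  if (!is.numeric(n_histories) || n_histories < 1) {
    stop("n_histories must be >= 1", call. = FALSE)
  }
  structure(list(box_um = box_um,
                 cutoff_electron_eV = cutoff_electron_eV,
                 cutoff_proton_eV = cutoff_proton_eV,
                 n_histories = as.integer(n_histories),
                 seed = as.integer(seed), chain = chain,
                 secondary_emission = secondary_emission),
            class = "sim_config")
}

species_cutoffs <- function(tables, sim) {
  vapply(tables$species_names, function(sp) {
    if (sp == "electron") sim$cutoff_electron_eV else sim$cutoff_proton_eV
  }, 0)
}

#' Transport one primary particle and its full secondary cascade
#'
#' Fires a single primary into the water cube from the centre of the
#' `x = 0` face, directed inward along the box axis (unless overridden),
#' alternating exponential free flights, boundary checks, channel selection
#' and energy-loss sampling.  Every ionisation spawns a secondary electron
#' that is transported identically; particles terminate on exit or when
#' their energy falls below the species cutoff (booked as a sub-cutoff
#' deposit).
#'
#' @param E0_eV Primary kinetic energy (eV).
#' @param tables A `physics_tables` object (see [build_physics_tables()]).
#' @param sim A `sim_config`.
#' @param species Primary species name; must have a table.
#' @param seed Stream seed for this history (default derives from
#'   `sim$seed` and history index 1).
#' @param record_events Keep the per-event table (position, channel, model,
#'   energy transfer)?
#' @param direction Unit 3-vector initial direction.
#' @param start Start position (m), default centre of the `x = 0` face.
#' @return An object of class `mc_history` with the event list, ionisation
#'   and excitation counts and exact energy bookkeeping
#'   (`initial = deposited + sub_cutoff + exited`).
#' @export
run_history <- function(E0_eV, tables, sim = sim_config(),
                        species = "proton",
                        seed = history_seed(sim$seed, 1L),
                        record_events = TRUE,
                        direction = c(1, 0, 0), start = NULL) {
  stopifnot(inherits(tables, "physics_tables"))
  if (!species %in% tables$species_names) {
    stop(sprintf("no physics table for species '%s'", species),
         call. = FALSE)
  }
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-12) {
    stop("direction must be a unit vector", call. = FALSE)
  }
  L <- sim$box_um * 1e-6
  if (is.null(start)) start <- c(0, L / 2, L / 2)
  sp0 <- match(species, tables$species_names)
  el <- match("electron", tables$species_names)
  res <- cpp_run_history(E0_eV, sp0, unname(tables$tables), el, L,
                         species_cutoffs(tables, sim),
                         tables$number_density_m3, seed, record_events,
                         identical(sim$secondary_emission, "isotropic"),
                         start, direction)
  hist <- list(
    primary = list(species = species, energy_eV = E0_eV),
    n_ionisation = res$n_ionisation,
    n_excitation = res$n_excitation,
    energy = list(initial_eV = E0_eV,
                  deposited_eV = res$deposited_eV,
                  sub_cutoff_eV = res$sub_cutoff_eV,
                  exited_eV = res$exited_eV),
    seed = seed,
    chain = tables$chain_name)
  if (record_events) {
    ev <- res$events
    ev$species <- tables$species_names[ev$species]
    hist$events <- ev
  }
  class(hist) <- "mc_history"
  hist
}

#' @export
print.mc_history <- function(x, ...) {
  cat(sprintf("History: %s primary at %.4g eV (chain %s)\n",
              x$primary$species, x$primary$energy_eV, x$chain))
  cat(sprintf("  %d ionisations, %d excitations\n",
              x$n_ionisation, x$n_excitation))
  e <- x$energy
  cat(sprintf(
    "  energy: deposited %.4g eV, sub-cutoff %.4g eV, exited %.4g eV\n",
    e$deposited_eV, e$sub_cutoff_eV, e$exited_eV))
  invisible(x)
}

#' Energy-bookkeeping residual of a history
#'
#' @param history An `mc_history`.
#' @return Relative residual of
#'   `initial - (deposited + sub_cutoff + exited)`.
#' @export
energy_residual <- function(history) {
  e <- history$energy
  (e$initial_eV - (e$deposited_eV + e$sub_cutoff_eV + e$exited_eV)) /
    e$initial_eV
}

#' Ionisation yield versus primary energy
#'
#' Reproduces the single-primary counting experiment: for each energy on
#' the grid, `n_histories` independent primaries are fired into the cube
#' and the total number of ionisation events (primary plus all secondary
#' generations) is recorded; the mean and its standard error over histories
#' are reported per energy.
#'
#' @param energy_grid_eV Sorted ascending vector of primary energies (eV).
#' @param tables A `physics_tables`.
#' @param sim A `sim_config` (supplies `n_histories` and the master seed).
#' @param species Primary species.
#' @return A data.frame with columns `energy_eV`, `mean_ionisations`, `se`,
#'   `n_histories`, `chain`.
#' @export
ionisation_yield_scan <- function(energy_grid_eV, tables,
                                  sim = sim_config(), species = "proton") {
  if (!length(energy_grid_eV)) {
    stop("energy grid must not be empty", call. = FALSE)
  }
  if (is.unsorted(energy_grid_eV)) {
    stop("energy grid must be sorted ascending", call. = FALSE)
  }
  n <- sim$n_histories
  rows <- lapply(seq_along(energy_grid_eV), function(k) {
    counts <- vapply(seq_len(n), function(i) {
      h <- run_history(energy_grid_eV[k], tables, sim, species,
                       seed = history_seed(sim$seed, (k - 1L) * n + i),
                       record_events = FALSE)
      h$n_ionisation
    }, 0)
    data.frame(energy_eV = energy_grid_eV[k],
               mean_ionisations = mean(counts),
               se = if (n > 1) stats::sd(counts) / sqrt(n) else 0,
               n_histories = n, chain = tables$chain_name,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
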