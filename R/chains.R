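## Model chains: ordered assignments of physics models to processes over
## energy ranges, mirroring the published physics lists of the two
## track-structure codes the package emulates.

#' Construct a model chain
#'
#' A model chain binds one physics model to each (process, energy range)
#' pair, with strict half-open intervals `[lo, hi)` and no blending at the
#' boundaries.  Two chains ship with the package:
#'
#' * `ritracks_like` — electron ionisation by the Rudd model below the
#'   configured split (default 50 keV) and the Seltzer model above; electron
#'   excitation by Kaplan-Sukhonosov below 100 eV and Kutcher-Green above;
#'   proton ionisation by the Rudd model at all energies (relativistic
#'   velocity substitution above the configured threshold).
#' * `geant4dna_like` — electron ionisation and excitation through the Born
#'   dielectric machinery; proton ionisation by the Rudd model below the
#'   configured split (default 500 keV) and the Born model above.
#'
#' @param name `"ritracks_like"` or `"geant4dna_like"`.
#' @param config A `trackmc_config` supplying the boundary energies.
#' @return An object of class `model_chain` with a `bindings` data.frame
#'   (`process`, `model`, `e_lo_eV`, `e_hi_eV`).
#' @export
model_chain <- function(name, config = load_config()) {
  bnd <- config$chains
  e_split <- bnd$electron_ionisation_split_eV
  x_split <- bnd$excitation_split_eV
  p_split <- bnd$proton_born_split_eV
  bindings <- switch(
    name,
    ritracks_like = data.frame(
      process = c("electron_ionisation", "electron_ionisation",
                  "electron_excitation", "electron_excitation",
                  "proton_ionisation"),
      model = c("rudd", "seltzer", "kaplan", "kutcher_green", "rudd"),
      e_lo_eV = c(0, e_split, 0, x_split, 0),
      e_hi_eV = c(e_split, Inf, x_split, Inf, Inf),
      stringsAsFactors = FALSE),
    geant4dna_like = data.frame(
      process = c("electron_ionisation", "electron_excitation",
                  "proton_ionisation", "proton_ionisation"),
      model = c("born", "born_excitation", "rudd", "born"),
      e_lo_eV = c(0, 0, 0, p_split),
      e_hi_eV = c(Inf, Inf, p_split, Inf),
      stringsAsFactors = FALSE),
    stop(sprintf("unknown model chain '%s'", name), call. = FALSE))
  chain <- structure(list(name = name, bindings = bindings),
                     class = "model_chain")
  validate_chain(chain)
  chain
}

validate_chain <- function(chain) {
  b <- chain$bindings
  for (proc in unique(b$process)) {
    sub <- b[b$process == proc, , drop = FALSE]
    sub <- sub[order(sub$e_lo_eV), , drop = FALSE]
    if (sub$e_lo_eV[1L] != 0 || !is.infinite(sub$e_hi_eV[nrow(sub)])) {
      stop(sprintf("chain '%s': process %s does not cover [0, Inf)",
                   chain$name, proc), call. = FALSE)
    }
    if (nrow(sub) > 1L &&
        any(sub$e_hi_eV[-nrow(sub)] != sub$e_lo_eV[-1L])) {
      stop(sprintf("chain '%s': process %s bindings overlap or leave gaps",
                   chain$name, proc), call. = FALSE)
    }
  }
  invisible(chain)
}

#' Model bound by a chain for a process at a given energy
#'
#' @param chain A `model_chain`.
#' @param process One of `"electron_ionisation"`, `"electron_excitation"`,
#'   `"proton_ionisation"`.
#' @param E_eV Particle kinetic energy (eV).
#' @return The model identifier (character scalar).
#' @export
chain_model_for <- function(chain, process, E_eV) {
  stopifnot(inherits(chain, "model_chain"))
  b <- chain$bindings
  sub <- b[b$process == process, , drop = FALSE]
  if (!nrow(sub)) {
    stop(sprintf("chain '%s' has no bindings for process '%s'",
                 chain$name, process), call. = FALSE)
  }
  hit <- sub$e_lo_eV <= E_eV & E_eV < sub$e_hi_eV
  if (!any(hit)) {
    stop(sprintf("no model bound for %s at %g eV", process, E_eV),
         call. = FALSE)
  }
  sub$model[which(hit)[1L]]
}

#' @export
print.model_chain <- function(x, ...) {
  cat(sprintf("Model chain '%s'\n", x$name))
  b <- x$bindings
  for (k in seq_len(nrow(b))) {
    cat(sprintf("  %-20s %-14s [%g, %g) eV\n", b$process[k], b$model[k],
                b$e_lo_eV[k], b$e_hi_eV[k]))
  }
  invisible(x)
}
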