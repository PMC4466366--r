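## Scan drivers, CSV/JSON writers, configuration hashing and synthetic
## fixture generation: the front end over the cross-section and transport
## machinery.

#' Describe a cross-section scan
#'
#' @param particle `"electron"` or `"proton"`.
#' @param process `"ionisation"` or `"excitation"` (electron only).
#' @param chain Chain name.
#' @param emin_eV,emax_eV Energy-grid limits (eV), `emin < emax`.
#' @param points Number of grid points (\eqn{\ge 2}).
#' @param log Logarithmic grid?
#' @return An object of class `scan_request`.
#' @export
scan_request <- function(particle, process, chain = "ritracks_like",
                         emin_eV = 1e3, emax_eV = 1e7, points = 50L,
                         log = TRUE) {
  if (!particle %in% c("electron", "proton")) {
    stop("particle must be 'electron' or 'proton'", call. = FALSE)
  }
  if (!process %in% c("ionisation", "excitation")) {
    stop("process must be 'ionisation' or 'excitation'", call. = FALSE)
  }
  if (particle == "proton" && process == "excitation") {
    stop("no proton excitation model is implemented", call. = FALSE)
  }
  if (!(emin_eV < emax_eV)) stop("emin must be < emax", call. = FALSE)
  if (points < 2L) stop("points must be >= 2", call. = FALSE)
  structure(list(particle = particle, process = process, chain = chain,
                 emin_eV = emin_eV, emax_eV = emax_eV,
                 points = as.integer(points), log = isTRUE(log)),
            class = "scan_request")
}

scan_grid <- function(request) {
  if (request$log) {
    10^seq(log10(request$emin_eV), log10(request$emax_eV),
           length.out = request$points)
  } else {
    seq(request$emin_eV, request$emax_eV, length.out = request$points)
  }
}

## Total cross-section for (particle, process) at one energy under a chain.
scan_sigma_at <- function(E, request, config, chain) {
  if (request$particle == "proton") {
    proton_tics(E, config, chain)
  } else if (request$process == "ionisation") {
    electron_tics(E, config, chain)
  } else {
    sum(vapply(seq_along(config$medium$excitation_levels), function(i) {
      ch <- electron_exc_channel_dcs(E, config, chain, i)
      total_cross_section(ch$dcs, ch$support)
    }, 0))
  }
}

scan_process_name <- function(request) {
  paste0(request$particle, "_", request$process)
}

#' Run a total-cross-section scan
#'
#' Evaluates the total cross-section of the requested process on the energy
#' grid, recording per energy the model the chain dispatched to.  Output is
#' deterministic for a fixed configuration; two runs write byte-identical
#' CSV.
#'
#' @param request A `scan_request`.
#' @param config A `trackmc_config`.
#' @param out Optional CSV path.
#' @return A data.frame (`energy_eV`, `sigma_m2`, `sigma_cm2`, `model`,
#'   `chain`, `particle`, `process`), invisibly written to `out` if given.
#' @export
cmd_scan <- function(request, config = load_config(), out = NULL) {
  chain <- model_chain(request$chain, config)
  grid <- scan_grid(request)
  proc <- scan_process_name(request)
  sigma <- vapply(grid, scan_sigma_at, 0, request = request,
                  config = config, chain = chain)
  model <- vapply(grid, function(E) chain_model_for(chain, proc, E), "")
  res <- data.frame(energy_eV = grid, sigma_m2 = sigma,
                    sigma_cm2 = sigma * 1e4, model = model,
                    chain = chain$name, particle = request$particle,
                    process = request$process, stringsAsFactors = FALSE)
  if (!is.null(out)) write_xs_csv(res, out)
  res
}

#' Compare two model chains on the same scan
#'
#' @param chainA,chainB Chain names.
#' @param request A `scan_request` (its `chain` field is ignored).
#' @param config A `trackmc_config`.
#' @param out Optional CSV path.
#' @return A data.frame with `sigma_A_m2`, `sigma_B_m2` and `ratio`
#'   (`NaN` wherever either total vanishes).
#' @export
cmd_compare <- function(chainA, chainB, request, config = load_config(),
                        out = NULL) {
  ra <- request; ra$chain <- chainA
  rb <- request; rb$chain <- chainB
  a <- cmd_scan(ra, config)
  b <- cmd_scan(rb, config)
  ratio <- ifelse(a$sigma_m2 > 0 & b$sigma_m2 > 0,
                  a$sigma_m2 / b$sigma_m2, NaN)
  res <- data.frame(energy_eV = a$energy_eV, sigma_A_m2 = a$sigma_m2,
                    sigma_B_m2 = b$sigma_m2, ratio = ratio,
                    model_A = a$model, model_B = b$model,
                    chain_A = chainA, chain_B = chainB,
                    stringsAsFactors = FALSE)
  if (!is.null(out)) write_xs_csv(res, out)
  res
}

#' Run the single-primary counting experiment at one energy
#'
#' Transports `sim$n_histories` primaries, writes (optionally) the
#' event-level CSV of every history and a JSON summary with the mean
#' ionisation count, its standard error, the seed, chain and configuration
#' hash.
#'
#' @param energy_eV Primary kinetic energy (eV).
#' @param config A `trackmc_config`.
#' @param sim A `sim_config`.
#' @param species Primary species.
#' @param tables Optional prebuilt `physics_tables` (rebuilt from the chain
#'   in `sim` otherwise).
#' @param out Optional output prefix; writes `<out>_events.csv` and
#'   `<out>_summary.json`.
#' @return List with `summary` (list) and `histories` (list of
#'   `mc_history`).
#' @export
cmd_track <- function(energy_eV, config = load_config(),
                      sim = sim_config(), species = "proton",
                      tables = NULL, out = NULL) {
  if (is.null(tables)) {
    tables <- build_physics_tables(config, model_chain(sim$chain, config),
                                   species = species)
  }
  hists <- lapply(seq_len(sim$n_histories), function(i) {
    run_history(energy_eV, tables, sim, species,
                seed = history_seed(sim$seed, i))
  })
  counts <- vapply(hists, `[[`, 0, "n_ionisation")
  summary <- list(
    energy_eV = energy_eV, species = species, chain = tables$chain_name,
    n_histories = sim$n_histories, seed = sim$seed,
    mean_ionisations = mean(counts),
    se = if (length(counts) > 1) {
      stats::sd(counts) / sqrt(length(counts))
    } else {
      0
    },
    config_hash = config_hash(config))
  if (!is.null(out)) {
    ev <- do.call(rbind, lapply(seq_along(hists), function(i) {
      e <- hists[[i]]$events
      if (is.null(e) || !nrow(e)) return(NULL)
      cbind(history = i, e)
    }))
    if (!is.null(ev)) write_xs_csv(ev, paste0(out, "_events.csv"))
    jsonlite::write_json(summary, paste0(out, "_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(summary = summary, histories = hists)
}

#' Run the ionisation yield-scan protocol
#'
#' @param energy_grid_eV Sorted primary-energy grid (eV).
#' @param config A `trackmc_config`.
#' @param sim A `sim_config`.
#' @param species Primary species.
#' @param tables Optional prebuilt `physics_tables`.
#' @param out Optional CSV path.
#' @return The [ionisation_yield_scan()] data.frame.
#' @export
cmd_yield_scan <- function(energy_grid_eV, config = load_config(),
                           sim = sim_config(), species = "proton",
                           tables = NULL, out = NULL) {
  if (is.null(tables)) {
    tables <- build_physics_tables(config, model_chain(sim$chain, config),
                                   species = species)
  }
  res <- ionisation_yield_scan(energy_grid_eV, tables, sim, species)
  if (!is.null(out)) write_xs_csv(res, out)
  res
}

#' Write a numeric table as CSV with lossless full precision
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xs_csv <- function(df, path) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]])) {
      fmt[[j]] <- sprintf("%.17g", fmt[[j]])
    }
  }
  utils::write.csv(fmt, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a CSV written by [write_xs_csv()]
#'
#' @param path CSV path.
#' @return A data.frame with numeric columns restored at full precision.
#' @export
read_xs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) {
      num <- suppressWarnings(as.numeric(df[[j]]))
      parse_failed <- is.na(num) & !(df[[j]] %in% c("NA", "NaN", "Inf",
                                                    "-Inf"))
      if (!any(parse_failed)) df[[j]] <- num
    }
  }
  df
}

#' Hash of the physics-relevant configuration
#'
#' Canonically serialises every section that affects a computed number
#' (constants, medium, fitted parameters, ELF, chain boundaries, transport
#' defaults) and returns its MD5; changing any such field changes the hash,
#' while bookkeeping fields (e.g. the source path) do not.
#'
#' @param config A `trackmc_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(unclass(x), strip)
    }
    x
  }
  keep <- c("constants", "medium", "orbitals", "excitation_levels",
            "rudd_electron", "rudd_proton", "born_elf", "photoeffect",
            "chains", "transport", "ions", "effective_charge")
  canon <- strip(config[intersect(keep, names(config))])
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(canon, tmp, precision = 17L)
  unname(tools::md5sum(tmp))
}

#' Deterministic synthetic fixtures for oracle tests
#'
#' Produces seed-reproducible toy cross-sections and parameter sets with
#' analytic closed forms attached, for use as independent oracles:
#'
#' * `toy_dcs` — power-law (`shape = "power_law"`, exponent `a`) or uniform
#'   DCS on `[w_lo, w_hi]` with analytic total, CDF and median.
#' * `random_rudd_params` — random positive electron- and proton-model
#'   parameter sets.
#' * `toy_elf` — constant and Drude-shaped ELF callables.
#' * `toy_pe` — zero and constant-above-threshold photoelectric providers.
#'
#' @param kind Fixture kind (see above).
#' @param seed Integer seed.
#' @param shape For `toy_dcs`: `"power_law"` or `"uniform"`.
#' @param a Power-law exponent (default 2).
#' @param w_lo,w_hi Support (eV).
#' @return A list of callables and analytic metadata; deterministic in
#'   `seed`.
#' @export
generate_fixtures <- function(kind, seed = 1L, shape = "power_law", a = 2,
                              w_lo = 1, w_hi = 100) {
  set.seed(seed)
  switch(
    kind,
    toy_dcs = {
      if (shape == "power_law") {
        stopifnot(a > 1)
        total <- (w_lo^(1 - a) - w_hi^(1 - a)) / (a - 1)
        cdf <- function(W) {
          pmin(pmax((w_lo^(1 - a) - W^(1 - a)) / (a - 1) / total, 0), 1)
        }
        quant <- function(u) {
          (w_lo^(1 - a) - u * total * (a - 1))^(1 / (1 - a))
        }
        list(kind = kind, shape = shape,
             dcs = function(W) ifelse(W >= w_lo & W <= w_hi, W^(-a), 0),
             support = c(w_lo, w_hi), total = total, cdf = cdf,
             quantile = quant, median = quant(0.5))
      } else if (shape == "uniform") {
        list(kind = kind, shape = shape,
             dcs = function(W) ifelse(W >= w_lo & W <= w_hi, 1, 0),
             support = c(w_lo, w_hi), total = w_hi - w_lo,
             cdf = function(W) {
               pmin(pmax((W - w_lo) / (w_hi - w_lo), 0), 1)
             },
             quantile = function(u) w_lo + u * (w_hi - w_lo),
             median = (w_lo + w_hi) / 2)
      } else {
        stop(sprintf("unknown toy_dcs shape '%s'", shape), call. = FALSE)
      }
    },
    random_rudd_params = {
      list(kind = kind,
           electron = list(A1 = stats::runif(1, 0.5, 2),
                           A2 = stats::runif(1, 0.5, 2),
                           B1 = stats::runif(1, 0, 5),
                           B2 = stats::runif(1, 0, 30)),
           proton = list(A1 = stats::runif(1, 0.5, 2),
                         B1 = stats::runif(1, 10, 100),
                         C1 = stats::runif(1, 0.1, 1),
                         D1 = stats::runif(1, -0.5, 0.5),
                         E1 = stats::runif(1, 0.1, 1),
                         A2 = stats::runif(1, 0.5, 2),
                         B2 = stats::runif(1, 5, 30),
                         C2 = stats::runif(1, 0.1, 1),
                         D2 = stats::runif(1, 0, 0.2),
                         alpha = stats::runif(1, 0.4, 0.9)))
    },
    toy_elf = {
      const <- stats::runif(1, 0.5, 2)
      list(kind = kind, constant_value = const,
           constant = function(E, q) ifelse(E > 0, const, 0),
           drude = function(E, q) {
             ifelse(E > 0, 400 * 13 * E / ((E^2 - 21.4^2)^2 + (13 * E)^2),
                    0)
           })
    },
    toy_pe = {
      s0 <- stats::runif(1, 1e-23, 1e-21)
      list(kind = kind, sigma0 = s0,
           zero = function(orbital, E) 0 * E,
           constant = function(orbital, E) {
             ifelse(E >= orbital$binding_eV, s0, 0)
           })
    },
    stop(sprintf("unknown fixture kind '%s'", kind), call. = FALSE))
}
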