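# Shared fixtures: configuration, synthetic orbitals/levels and memoised
# physics tables (building tables is the expensive step, so each chain's
# tables are built once per test run).

test_cfg <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- load_config()
    cfg
  }
})

test_tables <- local({
  cache <- list()
  function(chain_name, n_energy = 48L) {
    key <- paste0(chain_name, "_", n_energy)
    if (is.null(cache[[key]])) {
      cfg <- test_cfg()
      cache[[key]] <<- build_physics_tables(
        cfg, model_chain(chain_name, cfg), n_energy = n_energy)
    }
    cache[[key]]
  }
})

# a synthetic outer-shell orbital with convenient round numbers
syn_orbital <- function(n = 2, binding = 10, kinetic = 25) {
  molecular_orbital("syn", n_electrons = n, binding_eV = binding,
                    kinetic_eV = kinetic)
}

# a synthetic excitation level centred at `center` eV
syn_level <- function(amplitude = 1, center = 10, width = 2, w0 = 10) {
  excitation_level("syn", w0_eV = w0, center_eV = center, width_eV = width,
                   amplitude = amplitude)
}

# synthetic proton-model parameter set (positive, well-behaved)
syn_proton_params <- function(scale = 1) {
  list(A1 = 1.0 * scale, B1 = 50, C1 = 0.5 * scale, D1 = -0.2, E1 = 0.4,
       A2 = 1.0 * scale, B2 = 15 * scale, C2 = 0.8 * scale, D2 = 0.05,
       alpha = 0.66)
}
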