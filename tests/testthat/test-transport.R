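cfg <- test_cfg()

test_that("with all cross-sections zero the primary exits untouched", {
  tab <- toy_physics_tables(0, 1, "excitation")
  h <- run_history(1e6, tab, sim_config(), "proton", seed = 1)
  expect_identical(h$n_ionisation + h$n_excitation, 0)
  expect_equal(h$energy$exited_eV, 1e6)
  expect_equal(h$energy$deposited_eV, 0)
})

test_that("histories are bit-identical under a fixed seed", {
  tab <- test_tables("ritracks_like")
  sim <- sim_config(seed = 5)
  h1 <- run_history(2e5, tab, sim, "proton", seed = 77)
  h2 <- run_history(2e5, tab, sim, "proton", seed = 77)
  expect_identical(h1$events, h2$events)
  expect_identical(h1$energy, h2$energy)
  h3 <- run_history(2e5, tab, sim, "proton", seed = 78)
  expect_false(identical(h1$n_ionisation, h3$n_ionisation) &&
                 identical(h1$events, h3$events))
})

test_that("constant toy cross-section gives Poisson ionisation counts", {
  # lambda chosen so the 7 um box holds ~10 events per crossing;
  # secondaries are born below the electron cutoff and deposit locally
  N <- 3.3428e28
  L <- 7e-6
  sigma <- 10 / (N * L)
  tab <- toy_physics_tables(sigma, 1, "ionisation", binding_eV = 0,
                            number_density_m3 = N)
  sim <- sim_config(seed = 3)
  n <- 2000L
  counts <- vapply(seq_len(n), function(i) {
    run_history(1e8, tab, sim, "proton", seed = history_seed(3, i),
                record_events = FALSE)$n_ionisation
  }, 0)
  mu <- N * sigma * L
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / n))
  # counting statistics: variance consistent with Poisson
  expect_gt(stats::var(counts), 0.5 * mu)
  expect_lt(stats::var(counts), 1.5 * mu)
})

test_that("energy bookkeeping closes to 1e-9 on mixed-energy histories", {
  tab <- test_tables("ritracks_like")
  sim <- sim_config(seed = 9)
  set.seed(31)
  specs <- data.frame(
    species = sample(c("electron", "proton"), 60, replace = TRUE),
    energy = 10^stats::runif(60, 2, 5.5))
  for (k in seq_len(nrow(specs))) {
    h <- run_history(specs$energy[k], tab, sim, specs$species[k],
                     seed = history_seed(9, k), record_events = FALSE)
    expect_lt(abs(energy_residual(h)), 1e-9)
  }
})

test_that("event positions stay inside the box", {
  tab <- test_tables("ritracks_like")
  h <- run_history(5e5, tab, sim_config(seed = 2), "proton", seed = 13)
  L <- 7e-6
  ev <- h$events
  expect_true(all(ev$x_m >= 0 & ev$x_m <= L))
  expect_true(all(ev$y_m >= 0 & ev$y_m <= L))
  expect_true(all(ev$z_m >= 0 & ev$z_m <= L))
  expect_true(all(ev$W_eV > 0))
  # events record species, generation and model codes
  expect_true(all(ev$generation >= 0))
  expect_true(all(ev$process %in% c(1L, 2L)))
})

test_that("ionisation count grows with box length under a constant sigma", {
  N <- 3.3428e28
  sigma <- 5 / (N * 7e-6)     # ~5 events in the 7 um box
  tab <- toy_physics_tables(sigma, 1, "ionisation", number_density_m3 = N)
  n <- 1000L
  count_at <- function(box_um, seed0) {
    sim <- sim_config(box_um = box_um, seed = seed0)
    mean(vapply(seq_len(n), function(i) {
      run_history(1e8, tab, sim, "proton", seed = history_seed(seed0, i),
                  record_events = FALSE)$n_ionisation
    }, 0))
  }
  small <- count_at(7, 21)
  big <- count_at(14, 21)
  # means differ by ~5 with SE ~0.07: a 3 sigma ordering test
  se <- sqrt(5 / n + 10 / n)
  expect_gt(big - small, 5 - 3 * se)
})

test_that("run_history validates its inputs", {
  tab <- toy_physics_tables(1e-21, 1, "excitation")
  expect_error(run_history(1e6, tab, sim_config(), "carbon"),
               "no physics table")
  expect_error(run_history(1e6, tab, sim_config(), "proton",
                           direction = c(1, 1, 0)), "unit vector")
  expect_error(sim_config(box_um = -1), "> 0")
  expect_error(sim_config(n_histories = 0), ">= 1")
  expect_error(sim_config(cutoff_electron_eV = -5), ">= 0")
})

test_that("yield scan reports means, standard errors and provenance", {
  tab0 <- toy_physics_tables(0, 1, "ionisation")
  sim <- sim_config(n_histories = 5, seed = 1)
  # zero cross-section: mean 0, SE 0
  ys <- ionisation_yield_scan(1e6, tab0, sim)
  expect_identical(ys$mean_ionisations, 0)
  expect_identical(ys$se, 0)
  expect_equal(ys$chain, "toy")
  expect_error(ionisation_yield_scan(numeric(), tab0, sim), "empty")
  expect_error(ionisation_yield_scan(c(2, 1), tab0, sim), "sorted")
  # SE shrinks with more histories (same seed family)
  N <- 3.3428e28
  tabp <- toy_physics_tables(10 / (N * 7e-6), 1, "ionisation",
                             number_density_m3 = N)
  y1 <- ionisation_yield_scan(1e8, tabp, sim_config(n_histories = 50,
                                                    seed = 4))
  y2 <- ionisation_yield_scan(1e8, tabp, sim_config(n_histories = 400,
                                                    seed = 4))
  expect_lt(y2$se, y1$se)
})

test_that("secondary electrons are produced and transported", {
  tab <- test_tables("ritracks_like")
  h <- run_history(1e6, tab, sim_config(seed = 6), "proton", seed = 8)
  ev <- h$events
  expect_true(any(ev$species == "electron"))
  expect_true(any(ev$generation >= 1))
  # electron events never precede a generation-0 ionisation in energy terms:
  # every electron event descends from an ionisation, so counts are coupled
  expect_gte(h$n_ionisation, sum(ev$species == "electron" &
                                   ev$process == 1L))
})
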