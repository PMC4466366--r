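cfg <- test_cfg()
cst <- cfg$constants

test_that("Rudd electron DCS vanishes below threshold and outside its support", {
  orb <- cfg$medium$orbitals[[1]]   # 1b1, I = 11.5 eV
  par <- cfg$rudd_electron$liquid
  expect_equal(rudd_electron_dcs(10, c(0, 1, 5), orb, par), rep(0, 3))
  expect_equal(rudd_electron_dcs(11.5, 0, orb, par), 0)
  # support ends at (T - I)/2
  expect_gt(rudd_electron_dcs(100, 44, orb, par), 0)
  expect_equal(rudd_electron_dcs(100, 44.5, orb, par), 0)
  expect_error(rudd_electron_dcs(-5, 1, orb, par), "non-negative")
  expect_error(rudd_electron_dcs(100, -1, orb, par), "non-negative")
})

test_that("Rudd electron DCS matches an independent transcription", {
  orb <- cfg$medium$orbitals[[1]]
  par <- cfg$rudd_electron$liquid
  # second, independently written single-expression evaluation
  oracle <- function(T, W, I, N, A1, A2, B1, B2) {
    S <- 4 * pi * cst$a0^2 * N * (cst$rydberg / I)^2
    t <- T / I; w <- W / I
    (S / I) * ((A1 * log(t) / (t + B1)) *
                 (1 / (1 + w)^3 + 1 / (t - w)^3 -
                    1 / ((1 + w)^1.5 * (t - w)^1.5)) +
               (A2 * log(t) / (t + B2)) *
                 (1 / (1 + w)^2 + 1 / (t - w)^2 -
                    1 / ((1 + w) * (t - w))))
  }
  expect_equal(rudd_electron_dcs(100, 10, orb, par),
               oracle(100, 10, 11.5, 2, 0.94, 1.13, 2.30, 22.0),
               tolerance = 1e-12)
  # linearity: doubling A1 and A2 with B1 = B2 = 0 doubles the DCS
  p0 <- list(A1 = 0.9, A2 = 1.1, B1 = 0, B2 = 0)
  p2 <- list(A1 = 1.8, A2 = 2.2, B1 = 0, B2 = 0)
  W <- c(2, 10, 30)
  expect_equal(rudd_electron_dcs(200, W, orb, p2),
               2 * rudd_electron_dcs(200, W, orb, p0), tolerance = 1e-15)
})

test_that("Seltzer DCS separates close and distant collisions", {
  orb <- cfg$medium$orbitals[[1]]
  pe0 <- function(orbital, E) 0 * E
  # pe == 0 leaves the close term alone; a constant pe adds a distant term
  # proportional to the photoelectric cross-section
  close_only <- seltzer_dcs(1e5, 100, orb, pe0, cst)
  fx <- generate_fixtures("toy_pe", seed = 4)
  with_pe <- seltzer_dcs(1e5, 100, orb, fx$constant, cst)
  with_2pe <- seltzer_dcs(
    1e5, 100, orb, function(o, E) 2 * fx$constant(o, E), cst)
  expect_gt(with_pe, close_only)
  expect_equal(with_2pe - close_only, 2 * (with_pe - close_only),
               tolerance = 1e-12)
  # close term scales linearly in the orbital occupancy N_i
  o2 <- syn_orbital(n = 2, binding = 11.5, kinetic = 30)
  o4 <- syn_orbital(n = 4, binding = 11.5, kinetic = 30)
  expect_equal(seltzer_dcs(1e5, 100, o4, pe0, cst),
               2 * seltzer_dcs(1e5, 100, o2, pe0, cst), tolerance = 1e-14)
  # a provider returning negative values violates the contract
  expect_error(seltzer_dcs(1e5, 100, orb, function(o, E) -1e-25, cst),
               "negative")
})

test_that("Seltzer close term matches an independent transcription", {
  orb <- cfg$medium$orbitals[[1]]
  oracle <- function(T, W, B, U, N) {
    mc2 <- cst$mc2; tau <- T / mc2; b2 <- 1 - 1 / (1 + tau)^2
    E <- W + B; y <- W / U
    G <- (8 * U / (3 * pi)) * (1 / E^3 + 1 / (T - W)^3) *
      (atan(sqrt(y)) + sqrt(y) * (y - 1) / (y + 1)^2)
    2 * pi * cst$r_e^2 * mc2 * N * T / (b2 * (T + B + U)) *
      (1 / E^2 + 1 / (T - W)^2 + (1 / T^2) * (tau / (tau + 1))^2 -
         (2 * tau + 1) / (tau + 1)^2 / (E * (T - W)) + G)
  }
  pe0 <- function(orbital, E) 0 * E
  expect_equal(seltzer_dcs(1e5, 100, orb, pe0, cst),
               oracle(1e5, 100, 11.5, 30, 2), tolerance = 1e-10)
})

test_that("Q_min follows the free-collision kinematics", {
  expect_equal(q_min(100, 100), 100, tolerance = 1e-12)   # W = T
  expect_equal(q_min(100, 0), 0)
  # soft-collision limit: Q_min -> W^2 / (4T)
  T <- 500; W <- T * 1e-4
  expect_equal(q_min(T, W) / (W^2 / (4 * T)), 1, tolerance = 1e-3)
  expect_error(q_min(10, 11), "W <= T")
})

test_that("rho(W) is the Rutherford free-electron kernel", {
  T <- 200; W <- 15
  expect_equal(rho_free(T, W, cst),
               4 * pi * cst$a0^2 * cst$rydberg^2 / (T * W^2),
               tolerance = 1e-15)
  expect_error(rho_free(10, 20, cst), "W <= T")
})

test_that("Kutcher-Green excitation DCS is linear in the strength function", {
  lev0 <- syn_level(amplitude = 0)
  expect_equal(kutcher_green_dcs(1000, c(5, 10, 20), lev0, cst), rep(0, 3))
  lev1 <- syn_level(amplitude = 1)
  lev2 <- syn_level(amplitude = 2)
  W <- c(8, 10, 14)
  expect_equal(kutcher_green_dcs(1000, W, lev2, cst),
               2 * kutcher_green_dcs(1000, W, lev1, cst), tolerance = 1e-14)
  # independent transcription at one point
  T <- 1000; W1 <- 10
  qm <- 2 * T * (1 - W1 / (2 * T) - sqrt(1 - W1 / T))
  oracle <- (4 * pi * cst$a0^2 * cst$rydberg^2 / (T * W1^2)) / W1 *
    exp(-(W1 - 10)^2 / (2 * 2^2)) * log(4 * T / qm)
  expect_equal(kutcher_green_dcs(T, W1, lev1, cst), oracle,
               tolerance = 1e-12)
})

test_that("Kaplan excitation DCS uses the interpolating alpha factor", {
  lev <- syn_level(amplitude = 1, center = 10, width = 2, w0 = 10)
  # at W = W0 the factor is exactly alpha = 1
  T <- 80; W0 <- 10
  oracle_at_w0 <- (4 * pi * cst$a0^2 * cst$rydberg^2 / (T * W0^2)) / W0 *
    1 * log(1 * T / W0)
  expect_equal(kaplan_dcs(T, W0, lev, cst), oracle_at_w0, tolerance = 1e-12)
  # far above W0 the interpolating factor saturates at 4 (the linking
  # scale alpha_i ~ 42 eV makes this a limit, not an in-domain value)
  a_i <- 4 * 7.34 / log(2)
  expect_equal(4 - 3 * exp(-(1e4 - 10) / a_i), 4, tolerance = 1e-12)
  # in-domain consistency with the exact alpha at a moderate W
  lev_wide <- syn_level(amplitude = 1, center = 60, width = 5, w0 = 8)
  W <- 60
  alpha_w <- 4 - 3 * exp(-(W - 8) / a_i)
  ratio <- kaplan_dcs(90, W, lev_wide, cst) /
    ((4 * pi * cst$a0^2 * cst$rydberg^2 / (90 * W^2)) / W *
       level_strength(lev_wide, W) * log(alpha_w * 90 / W))
  expect_equal(ratio, 1, tolerance = 1e-12)
  # below the minimum excitation transfer the DCS is zero
  expect_equal(kaplan_dcs(50, 5, lev, cst), 0)
  # clamp: negative/small log argument gives zero, not NaN
  lev_low <- syn_level(amplitude = 1, center = 30, width = 5, w0 = 60)
  val <- kaplan_dcs(31, 30, lev_low, cst)
  expect_true(is.finite(val) && val >= 0)
})

test_that("excitation and ionisation DCS are non-negative on a random grid", {
  set.seed(17)
  orb <- cfg$medium$orbitals[[2]]
  lev <- cfg$medium$excitation_levels[[4]]
  par <- cfg$rudd_electron$liquid
  for (k in 1:50) {
    T <- 10^stats::runif(1, 1.1, 4.5)
    W <- stats::runif(1, 0, T)
    expect_gte(rudd_electron_dcs(T, W, orb, par), 0)
    expect_gte(kutcher_green_dcs(T, W, lev, cst), 0)
    expect_gte(kaplan_dcs(T, W, lev, cst), 0)
  }
})

test_that("chain dispatch switches models at the documented boundaries", {
  rit <- model_chain("ritracks_like", cfg)
  expect_equal(chain_model_for(rit, "electron_ionisation", 49e3), "rudd")
  expect_equal(chain_model_for(rit, "electron_ionisation", 51e3), "seltzer")
  expect_equal(chain_model_for(rit, "electron_excitation", 99), "kaplan")
  expect_equal(chain_model_for(rit, "electron_excitation", 101),
               "kutcher_green")
  g4 <- model_chain("geant4dna_like", cfg)
  expect_equal(chain_model_for(g4, "electron_ionisation", 1e3), "born")
  expect_error(model_chain("foo", cfg), "unknown model chain")
  # channel table records the dispatched model per channel
  ch <- electron_channel_dcs(49e3, 20, cfg, rit)
  expect_true(all(ch$model[ch$process == "ionisation"] == "rudd"))
  ch2 <- electron_channel_dcs(51e3, 20, cfg, rit)
  expect_true(all(ch2$model[ch2$process == "ionisation"] == "seltzer"))
  expect_true(all(ch$dcs_m2_eV >= 0))
})

test_that("total_cross_section integrates exactly and matches brute force", {
  # constant integrand
  expect_equal(total_cross_section(function(W) rep(3e-21, length(W)),
                                   c(0, 10)), 3e-20, tolerance = 1e-9)
  # empty support
  expect_equal(total_cross_section(function(W) W, c(5, 5)), 0)
  expect_equal(total_cross_section(function(W) W, c(7, 3)), 0)
  # brute-force midpoint Riemann oracle for the Rudd electron DCS
  orb <- cfg$medium$orbitals[[1]]
  par <- cfg$rudd_electron$liquid
  T <- 500
  hi <- (T - orb$binding_eV) / 2
  n <- 1e5
  mid <- (seq_len(n) - 0.5) * hi / n
  riemann <- sum(rudd_electron_dcs(T, mid, orb, par)) * hi / n
  adaptive <- total_cross_section(
    function(W) rudd_electron_dcs(T, W, orb, par), c(0, hi))
  expect_equal(adaptive, riemann, tolerance = 1e-3)
})

test_that("electron ionisation total vanishes below the minimum binding energy", {
  rit <- model_chain("ritracks_like", cfg)
  for (T in c(5, 8, 10, 11.49)) {
    expect_equal(electron_tics(T, cfg, rit), 0)
  }
  expect_gt(electron_tics(12, cfg, rit), 0)
})

test_that("Rudd electron total cross-section is unimodal in energy", {
  rit <- model_chain("ritracks_like", cfg)
  grid <- 10^seq(log10(15), log10(5e4), length.out = 200)
  sig <- vapply(grid, electron_tics, 0, config = cfg, chain = rit)
  peak <- which.max(sig)
  expect_gt(peak, 1)
  expect_lt(peak, length(grid))
  # single interior maximum: rises before the peak, falls after
  expect_true(all(diff(sig[1:peak]) >= 0))
  expect_true(all(diff(sig[peak:length(sig)]) <= 0))
})
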