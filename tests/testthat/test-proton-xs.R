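cfg <- test_cfg()
cst <- cfg$constants

test_that("scaled velocity obeys the classical and relativistic limits", {
  I <- 11.5
  # classical: T / I with T the electron-equivalent energy
  expect_equal(scaled_velocity_sq(1e5, I, "classical", cst),
               1e5 * cst$m_over_Mp / I, tolerance = 1e-15)
  # at T = mc^2 the relativistic form gives (3/8) mc^2 / I
  Ep_at_mc2 <- cst$mc2 / cst$m_over_Mp
  expect_equal(scaled_velocity_sq(Ep_at_mc2, I, "relativistic", cst),
               (3 / 8) * cst$mc2 / I, tolerance = 1e-12)
  # below 500 keV the two agree to 0.1%
  for (Ep in c(1e4, 1e5, 3e5, 5e5)) {
    cl <- scaled_velocity_sq(Ep, I, "classical", cst)
    rl <- scaled_velocity_sq(Ep, I, "relativistic", cst)
    expect_lt(abs(rl / cl - 1), 1e-3)
  }
  # monotone increasing in E_p and bounded by mc^2/(2I)
  grid <- 10^seq(4, 12, length.out = 60)
  v2 <- scaled_velocity_sq(grid, I, "relativistic", cst)
  expect_true(all(diff(v2) > 0))
  expect_true(all(v2 < cst$mc2 / (2 * I)))
  expect_error(scaled_velocity_sq(-1, I, "classical", cst), "positive")
})

test_that("proton Rudd DCS is linear in F1, F2 and vanishes when they do", {
  orb <- syn_orbital(n = 2, binding = 12, kinetic = 30)
  zero <- list(A1 = 0, B1 = 50, C1 = 0, D1 = -0.2, E1 = 0.4,
               A2 = 0, B2 = 0, C2 = 0, D2 = 0.05, alpha = 0.66)
  W <- c(0, 5, 50, 500)
  expect_equal(proton_rudd_dcs(5e5, W, orb, zero, "classical", cst),
               rep(0, 4))
  # doubling A1, C1 doubles F1; doubling A2, B2, C2 doubles F2
  p1 <- syn_proton_params(1)
  p2 <- syn_proton_params(2)
  expect_equal(proton_rudd_dcs(5e5, W, orb, p2, "classical", cst),
               2 * proton_rudd_dcs(5e5, W, orb, p1, "classical", cst),
               tolerance = 1e-13)
})

test_that("proton Rudd DCS matches an independent transcription", {
  orb <- cfg$medium$orbitals[[1]]
  p <- cfg$rudd_proton$outer
  oracle <- function(Ep, W, I, N) {
    T <- Ep * cst$m_over_Mp
    v <- sqrt(T / I)
    S <- 4 * pi * cst$a0^2 * N * (cst$rydberg / I)^2
    H1 <- p$A1 * log(1 + v^2) / (v^2 + p$B1 / v^2)
    L1 <- p$C1 * v^p$D1 / (1 + p$E1 * v^(p$D1 + 4))
    H2 <- p$A2 / v^2 + p$B2 / v^4
    L2 <- p$C2 * v^p$D2
    F1 <- H1 + L1
    F2 <- L2 * H2 / (L2 + H2)
    w <- W / I
    wc <- 4 * v^2 - 2 * v - cst$rydberg / (4 * I)
    (S / I) * (F1 + w * F2) /
      ((1 + w)^3 * (1 + exp(p$alpha * (w - wc) / v)))
  }
  expect_equal(proton_rudd_dcs(5e5, 20, orb, p, "classical", cst),
               oracle(5e5, 20, 11.5, 2), tolerance = 1e-12)
  # DCS decays to zero at large secondary energies
  T <- 5e5 * cst$m_over_Mp
  expect_equal(proton_rudd_dcs(5e5, 17 * T, orb, p, "classical", cst), 0)
})

test_that("Born momentum-transfer window satisfies its algebraic identities", {
  M <- cst$mc2 / cst$m_over_Mp
  tau <- 1e6
  # E = tau collapses the window to sqrt(2 M tau)
  qb <- born_q_bounds(tau, tau, M)
  expect_equal(qb$q_minus, sqrt(2 * M * tau), tolerance = 1e-12)
  expect_equal(qb$q_plus, sqrt(2 * M * tau), tolerance = 1e-12)
  # q+ q- = 2 M E exactly (difference of squares)
  E <- c(1, 21.4, 500, 1e4)
  qb <- born_q_bounds(tau, E, M)
  expect_equal(qb$q_plus * qb$q_minus, 2 * M * E, tolerance = 1e-10)
  expect_true(all(qb$q_minus <= qb$q_plus))
  # E = 0 gives q- = 0
  expect_equal(born_q_bounds(tau, 0, M)$q_minus, 0)
  expect_error(born_q_bounds(100, 101, M), "E <= tau")
})

test_that("Born DDCS respects the kinematic theta window", {
  M <- cst$mc2
  elf1 <- function(E, q) rep(1, max(length(E), length(q)))
  # energy transfer above tau is forbidden
  expect_equal(born_ddcs(100, 150, 10, M, elf1, cst), 0)
  # momentum transfer outside [q-, q+] is forbidden
  qb <- born_q_bounds(100, 20, M)
  expect_equal(born_ddcs(100, 20, qb$q_minus * 0.5, M, elf1, cst), 0)
  expect_equal(born_ddcs(100, 20, qb$q_plus * 2, M, elf1, cst), 0)
  inside <- born_ddcs(100, 20, sqrt(qb$q_minus * qb$q_plus), M, elf1, cst)
  expect_gt(inside, 0)
  expect_error(born_ddcs(100, 20, qb$q_minus * 1.5, M,
                         function(E, q) -1, cst), "negative")
})

test_that("q-integrated Born matches the constant-ELF closed form", {
  elf_const <- function(E, q) rep(1.37, max(length(E), length(q)))
  for (M in c(cst$mc2, cst$mc2 / cst$m_over_Mp)) {
    for (tau in c(1e3, 1e5, 1e7)) {
      E <- c(8, 21.4, 100)
      E <- E[E < tau]
      qb <- born_q_bounds(tau, E, M)
      T <- (cst$mc2 / M) * tau
      closed <- 1.37 * log(qb$q_plus / qb$q_minus) / (pi * cst$a0 * T)
      expect_equal(born_sdcs(tau, E, M, elf_const, cst), closed,
                   tolerance = 1e-9)
    }
  }
})

test_that("proton chain dispatch records the bound model", {
  g4 <- model_chain("geant4dna_like", cfg)
  rit <- model_chain("ritracks_like", cfg)
  below <- proton_ionisation_dcs(499e3, 20, cfg, g4)
  above <- proton_ionisation_dcs(501e3, 20, cfg, g4)
  expect_equal(attr(below, "model"), "rudd")
  expect_equal(attr(above, "model"), "born")
  expect_equal(attr(proton_ionisation_dcs(2e6, 20, cfg, rit), "model"),
               "rudd")
  # Born requested with no ELF configured is a config error
  cfg_noelf <- cfg
  cfg_noelf$born_elf <- NULL
  expect_error(proton_ionisation_dcs(2e6, 20, cfg_noelf, g4), "born_elf")
})

test_that("proton Rudd total cross-section is unimodal over 10 keV - 10 MeV", {
  rit <- model_chain("ritracks_like", cfg)
  grid <- 10^seq(4, 7, length.out = 200)
  sig <- vapply(grid, proton_tics, 0, config = cfg, chain = rit,
                rel_tol = 1e-5)
  peak <- which.max(sig)
  expect_gt(peak, 1)
  expect_lt(peak, length(grid))
  expect_true(all(diff(sig[1:peak]) >= 0))
  expect_true(all(diff(sig[peak:length(sig)]) <= 0))
})

test_that("the default ELF is non-negative, zero at E <= 0, and sum-rule normalised", {
  elf <- elf_provider(cfg)
  E <- seq(-5, 200, by = 0.5)
  v <- elf(E, 10)
  expect_true(all(v >= 0))
  expect_true(all(v[E <= 0] == 0))
  # f-sum: integral of E * Im(-1/eps) equals (pi/2) * Ep^2
  fs <- stats::integrate(function(E) E * elf(E, 0), 0, 1e5,
                         rel.tol = 1e-8)$value
  expect_equal(fs, pi / 2 * cfg$born_elf$plasmon_energy_eV^2,
               tolerance = 1e-3)
})
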