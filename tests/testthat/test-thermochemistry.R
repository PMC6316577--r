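test_that("single-mode values match the textbook closed forms", {
  nu <- 1000; T <- 298.15
  vt <- vibrational_thermo(nu, T)
  # independent evaluation of the HO formulas with x = hc nu / kT
  x <- phys_const$h * phys_const$c_cm * nu / (phys_const$kB * T)
  R <- phys_const$R / 1e3
  zpe <- phys_const$N_A * phys_const$h * phys_const$c_cm * nu / 2 / 1e3
  expect_equal(vt$ZPE, zpe, tolerance = 1e-12)
  expect_equal(vt$U_vib, zpe + R * T * x / (exp(x) - 1), tolerance = 1e-12)
  expect_equal(vt$S_vib, R * (x / (exp(x) - 1) - log(1 - exp(-x))),
               tolerance = 1e-12)
})

test_that("low- and high-temperature limits hold", {
  nu <- 1000
  # T -> 0+: U -> ZPE, S -> 0
  vt0 <- vibrational_thermo(nu, 1e-3)
  expect_equal(vt0$U_vib, vt0$ZPE, tolerance = 1e-12)
  expect_equal(vt0$S_vib, 0, tolerance = 1e-12)
  # classical equipartition: thermal U per mode -> kT within 1% at x <= 0.01
  T_hot <- phys_const$h * phys_const$c_cm * nu / (phys_const$kB * 0.01)
  vth <- vibrational_thermo(nu, T_hot)
  expect_equal((vth$U_vib - vth$ZPE) / (phys_const$R / 1e3 * T_hot), 1,
               tolerance = 0.01)
  # empty mode list
  expect_equal(vibrational_thermo(numeric(0), 300),
               list(ZPE = 0, U_vib = 0, S_vib = 0))
  expect_error(vibrational_thermo(-100, 300), "negative")
})

test_that("Sackur-Tetrode entropy and symmetry-number shift are exact", {
  st <- gas_rrho(39.948, T = 298.15, P = 1)
  # independent Sackur-Tetrode evaluation
  m <- 39.948 * phys_const$amu
  lam3 <- (2 * pi * m * phys_const$kB * 298.15 / phys_const$h^2)^1.5
  S_exp <- phys_const$R * (log(lam3 * phys_const$kB * 298.15 / 101325) + 2.5)
  expect_equal(st$S_trans * 1e3, S_exp, tolerance = 1e-10)
  expect_equal(st$S_vib, 0)
  # doubling sigma lowers S_rot by exactly R ln 2
  g1 <- gas_rrho(45, rot_constants = c(2.1, 0.4, 0.35), sigma = 1)
  g2 <- gas_rrho(45, rot_constants = c(2.1, 0.4, 0.35), sigma = 2)
  expect_equal((g1$S_rot - g2$S_rot) * 1e3, phys_const$R * log(2),
               tolerance = 1e-10)
})

test_that("G = H - T S holds for every thermo state", {
  states <- list(
    gas_rrho(45.04, frequencies = c(600, 1100, 1600, 1754, 2900, 3550),
             rot_constants = c(2.43, 0.38, 0.33), sigma = 1),
    gas_rrho(39.948),
    adsorbed_thermo(c(150, 420, 980, 1690)),
    gas_rrho(90, frequencies = c(80, 3200), rot_constants = 0.2,
             sigma = 2, T = 500, P = 0.5))
  for (st in states)
    expect_equal(st$G, st$H - st$T * st$S, tolerance = 1e-9)
})

test_that("counterpoise correction reproduces the arithmetic oracle", {
  # zero BSSE, relaxed fragments: plain interaction energy
  l0 <- cp_ledger(E_complex = -100, E_fragA_ghost = -45, E_fragB_ghost = -40,
                  E_fragA_own = -45, E_fragB_own = -40,
                  E_A_relaxed = -45, E_B_relaxed = -40)
  expect_equal(counterpoise(l0), -100 - (-45) - (-40))
  # 5 kJ/mol BSSE per fragment: corrected exactly 10 kJ/mol less binding
  l1 <- cp_ledger(E_complex = -100, E_fragA_ghost = -50, E_fragB_ghost = -45,
                  E_fragA_own = -45, E_fragB_own = -40,
                  E_A_relaxed = -45, E_B_relaxed = -40)
  expect_equal(counterpoise(l1), counterpoise(l0) + 10)
  # all-zero ledger
  lz <- cp_ledger(0, 0, 0, 0, 0, 0, 0)
  expect_equal(counterpoise(lz), 0)
  # deformation switch removes the relaxation terms
  l2 <- cp_ledger(E_complex = -100, E_fragA_ghost = -50, E_fragB_ghost = -45,
                  E_fragA_own = -48, E_fragB_own = -44,
                  E_A_relaxed = -49, E_B_relaxed = -46)
  expect_equal(counterpoise(l2, deformation = FALSE), -100 + 50 + 45)
  expect_equal(counterpoise(l2), -100 + 50 + 45 + 1 + 2)
  # variational bound: ghost below own is required
  expect_error(cp_ledger(-100, -40, -45, -45, -40, -45, -40),
               "variational")
})

test_that("reaction deltas are antisymmetric, componentwise bookkeeping", {
  prod <- c(E = -80.5, H = -74.2, G = -21.3)
  reac <- c(E = 0, H = 0, G = 0)
  d <- reaction_delta(prod, reac)
  expect_equal(c(d$dE, d$dH, d$dG), c(-80.5, -74.2, -21.3))
  dn <- reaction_delta(reac, prod)
  expect_equal(c(dn$dE, dn$dH, dn$dG), -c(d$dE, d$dH, d$dG))
  dz <- reaction_delta(prod, prod)
  expect_equal(c(dz$dE, dz$dH, dz$dG), c(0, 0, 0))
})

test_that("stepwise adsorption deltas compose path-independently", {
  # surface S, gas molecule M, adducts SM and SM2 as thermo states; the
  # two-step route S + M -> SM, SM + M -> SM2 must sum to the direct
  # S + 2M -> SM2 delta
  S  <- adsorbed_thermo(c(200, 450, 900))
  M  <- gas_rrho(45.04, frequencies = c(600, 1754),
                 rot_constants = c(2.43, 0.38, 0.33))
  SM <- adsorbed_thermo(c(180, 300, 520, 880, 1690))
  SM2 <- adsorbed_thermo(c(160, 250, 340, 500, 860, 1675, 1705))
  d1 <- reaction_delta(SM, list(S, M))
  d2 <- reaction_delta(SM2, list(SM, M))
  dd <- reaction_delta(SM2, list(S, M, M))
  expect_equal(d1$dG + d2$dG, dd$dG, tolerance = 1e-10)
  expect_equal(d1$dH + d2$dH, dd$dH, tolerance = 1e-10)
  expect_equal(d1$dE + d2$dE, dd$dE, tolerance = 1e-10)
})
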