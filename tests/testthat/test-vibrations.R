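test_that("diatomic stretch frequency matches the closed form", {
  # two unit masses on a line with force constant k: the only nonzero mode
  # of the pair is at (1/2 pi c) sqrt(2 k / m)
  k <- 500  # kJ mol^-1 A^-2
  H1 <- matrix(0, 6, 6)
  H1[1, 1] <- k; H1[4, 4] <- k; H1[1, 4] <- -k; H1[4, 1] <- -k
  fh <- fragment_hessian(H1, masses = c(1, 1))
  ms <- normal_modes(fh)
  lambda <- 2 * k / 1
  nu_expected <- sqrt(lambda * 1e3 / phys_const$N_A /
                        (phys_const$amu * 1e-20)) / (2 * pi * phys_const$c_cm)
  expect_equal(max(ms$frequencies), nu_expected, tolerance = 1e-10)
  # remaining five modes are numerically zero (free translations of the
  # uncoupled directions); eigen noise on a zero eigenvalue appears as
  # sqrt(eps)-scale wavenumbers
  expect_equal(sum(abs(ms$frequencies) < 1e-2), 5)
})

test_that("prescribed eigenstructure is recovered through the Cartesian route", {
  # build L diag(lambda) L^T in mass-weighted coordinates, un-mass-weight,
  # and require normal_modes to return exactly the prescription
  set.seed(11)
  nus <- c(500, 1000, 1500)
  masses <- 7.3
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  L <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  lam <- vapply(nus, function(nu)
    (2 * pi * phys_const$c_cm * nu)^2 * phys_const$N_A *
      phys_const$amu * 1e-20 / 1e3, numeric(1))
  Hmw <- L %*% diag(lam) %*% t(L)
  H <- Hmw * masses             # M^{1/2} Hmw M^{1/2} with a single mass
  ms <- normal_modes(fragment_hessian(H, masses))
  expect_equal(ms$frequencies, nus, tolerance = 1e-6)
  # orthonormality and reconstruction
  expect_equal(crossprod(ms$modes), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  recon <- ms$modes %*% diag(lam[order(nus)]) %*% t(ms$modes)
  expect_lt(max(abs(recon - Hmw)) / max(abs(Hmw)), 1e-8)
})

test_that("zero and indefinite Hessians are handled", {
  ms <- normal_modes(fragment_hessian(matrix(0, 3, 3), 1))
  expect_equal(ms$frequencies, rep(0, 3))
  # a negative eigenvalue surfaces as a negative wavenumber
  H <- diag(c(-100, 50, 200))
  ms2 <- normal_modes(fragment_hessian(H, 1))
  expect_lt(ms2$frequencies[1], 0)
  expect_error(fragment_hessian(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3), 1),
               "not symmetric")
})

test_that("reduce_hessian deletes environment rows/columns", {
  set.seed(4)
  A <- matrix(rnorm(36), 6, 6); full_H <- (A + t(A)) / 2
  masses <- c(1.008, 15.999)
  # fragment = all atoms: identity
  fh_all <- reduce_hessian(full_H, 1:2, masses)
  expect_equal(fh_all$H, (full_H + t(full_H)) / 2)
  # 1-atom fragment from a 2-atom system: the 3x3 block
  fh1 <- reduce_hessian(full_H, 2L, masses)
  expect_equal(dim(fh1$H), c(3L, 3L))
  expect_equal(fh1$H, (full_H[4:6, 4:6] + t(full_H[4:6, 4:6])) / 2)
  expect_equal(fh1$masses, 15.999)
  expect_error(reduce_hessian(full_H, integer(0), masses), "non-empty")
  expect_error(reduce_hessian(full_H, c(1, 1), masses), "unique")
})

test_that("an uncoupled fragment has identical frequencies reduced or full", {
  # block-diagonal Hessian: fragment block plus an unrelated environment
  set.seed(21)
  B <- matrix(rnorm(9), 3, 3); frag_block <- crossprod(B) + diag(3) * 50
  C <- matrix(rnorm(9), 3, 3); env_block <- crossprod(C) + diag(3) * 80
  full_H <- matrix(0, 6, 6)
  full_H[1:3, 1:3] <- frag_block; full_H[4:6, 4:6] <- env_block
  masses <- c(12.011, 15.999)
  nu_red <- normal_modes(reduce_hessian(full_H, 1L, masses))$frequencies
  nu_full <- normal_modes(fragment_hessian(full_H, masses))$frequencies
  # fragment frequencies are a subset of the full-system ones
  for (v in nu_red)
    expect_lt(min(abs(nu_full - v)), 1e-6)
})

test_that("frequencies are invariant under atom permutation", {
  spec <- synthetic_spec(seed = 9, n_atoms = 3,
                         frequencies = c(300, 450, 700, 900, 1200, 1400,
                                         1550, 1650, 1754),
                         intensities = rep(10, 9),
                         masses = c(1.008, 12.011, 15.999))
  fr <- make_fragment(spec)
  perm <- c(3L, 1L, 2L)
  idx <- as.vector(vapply(perm, function(a) (3 * (a - 1) + 1):(3 * a),
                          integer(3)))
  fh_p <- fragment_hessian(fr$fh$H[idx, idx], fr$fh$masses[perm],
                           dipole_derivatives = fr$fh$dipole_derivatives[idx, ])
  expect_equal(normal_modes(fh_p)$frequencies,
               normal_modes(fr$fh)$frequencies, tolerance = 1e-9)
  # intensities are invariant too
  ms0 <- ir_intensities(fr$fh, normal_modes(fr$fh))
  msp <- ir_intensities(fh_p, normal_modes(fh_p))
  expect_equal(msp$intensities, ms0$intensities, tolerance = 1e-8)
})

test_that("IR intensities follow the dipole-derivative quadratic law", {
  spec <- synthetic_spec(seed = 2)
  fr <- make_fragment(spec)
  ms <- normal_modes(fr$fh)
  ms <- ir_intensities(fr$fh, ms)
  expect_equal(ms$intensities, spec$intensities, tolerance = 1e-8)
  # doubling all dipole derivatives quadruples every intensity
  fh2 <- fragment_hessian(fr$fh$H, fr$fh$masses,
                          dipole_derivatives = 2 * fr$fh$dipole_derivatives)
  ms2 <- ir_intensities(fh2, normal_modes(fh2))
  expect_equal(ms2$intensities, 4 * ms$intensities, tolerance = 1e-8)
  # zero dipole derivatives: exactly zero intensity
  fh0 <- fragment_hessian(fr$fh$H, fr$fh$masses,
                          dipole_derivatives = 0 * fr$fh$dipole_derivatives)
  expect_equal(ir_intensities(fh0, normal_modes(fh0))$intensities,
               rep(0, 6))
  # missing dipole derivatives: directed to the intensity-free workflow
  fhn <- fragment_hessian(fr$fh$H, fr$fh$masses)
  expect_error(ir_intensities(fhn, normal_modes(fhn)), "intensity-free")
})

test_that("intensity conversion constant agrees with dimensional analysis", {
  # N_A pi / (3 c^2) in km mol^-1 per (D/A/sqrt(amu))^2, from SI constants:
  # 1 D = 1e-21/c_SI C m; intensity integral A = N_A pi d^2 / (3 c^2) with
  # d in (C m) kg^-1/2 m^-1 gives m mol^-1; divide by 1000 for km mol^-1
  debye <- 1e-21 / phys_const$c
  d2 <- (debye / (1e-10 * sqrt(phys_const$amu)))^2
  A <- phys_const$N_A * pi * d2 / (3 * phys_const$c^2) *
    (1 / (4 * pi * 8.8541878128e-12))
  expect_equal(A / 1e3, phys_const$ir_intensity_factor, tolerance = 1e-5)
})

test_that("mode-class scaling applies factors inside windows only", {
  ms <- mode_set(c(900, 1550, 1758.9))
  ms <- apply_scaling(ms, default_scale_rules())
  # 1758.9 * 0.9972 recovers the 1754 cm^-1 gas-phase carbonyl position
  expect_equal(ms$scaled_frequencies[3], 1754.0, tolerance = 0.05)
  expect_equal(ms$scaled_frequencies[2], 1550 * 1.0102)
  expect_equal(ms$scaled_frequencies[1], 900)   # outside both windows
  expect_equal(ms$scale_class, c(NA, "NH2_bend", "CO_stretch"))
  # factor 1 is the identity
  ms_id <- apply_scaling(mode_set(c(900, 1700)),
                         list(scale_rule("any", c(1600, 1800), 1.0)))
  expect_equal(ms_id$scaled_frequencies, c(900, 1700))
  # overlapping windows are ambiguous
  expect_error(apply_scaling(ms, list(scale_rule("a", c(1500, 1700), 1),
                                      scale_rule("b", c(1650, 1800), 1))),
               "overlap")
})
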