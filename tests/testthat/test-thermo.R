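# Partition functions, normal modes, the multiwell sum and the binding
# decomposition.

pc <- physical_constants()

test_that("vibrational partition matches its closed form and limits", {
  # single mode at hbar*omega/kT = 1: exp(-1/2)/(1 - exp(-1))
  w1 <- pc$kB_J * 310 / pc$hbar_J
  expect_equal(vibrational_partition(w1, 310), 0.959517375667,
               tolerance = 1e-10)
  # classical limit: Z per mode -> kT / (hbar*omega)
  w_soft <- 1e-4 * pc$kB_J * 310 / pc$hbar_J
  expect_equal(vibrational_partition(w_soft, 310) / 1e4, 1,
               tolerance = 1e-4)
  # the classical value is also an upper bound for stiffer modes
  for (x in c(0.1, 1, 5)) {
    w <- x * pc$kB_J * 310 / pc$hbar_J
    expect_lt(vibrational_partition(w, 310), 1 / x)
  }
  # empty product
  expect_equal(vibrational_partition(numeric(0), 310), 1)
  expect_error(vibrational_partition(c(1e13, -1), 310), "positive")
})

test_that("translational partition follows the standard-state formula", {
  sp <- species_thermo(100, NULL, temperature = 310)
  # frozen constant-substitution value of e (2 pi M k T)^{3/2} / (h^3 rho)
  expect_equal(translational_partition(sp), 4630057.72541,
               tolerance = 1e-9)
  sp8 <- species_thermo(800, NULL, temperature = 310)
  expect_equal(translational_partition(sp8) / translational_partition(sp),
               8^1.5, tolerance = 1e-12)
  half <- species_thermo(100, NULL, 310,
                         density = 2 * pc$rho_standard)
  expect_equal(translational_partition(half) / translational_partition(sp),
               0.5, tolerance = 1e-12)
  expect_error(species_thermo(-1, NULL, 310))
})

test_that("rotational partition uses the principal moments correctly", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  # hand-computed inertia of a unit-mass equilateral triangle, side 1
  expect_equal(inertia_moments(tri, c(1, 1, 1)), c(0.5, 0.5, 1.0),
               tolerance = 1e-12)
  z0 <- rotational_partition(tri, c(1, 1, 1), 310)
  # rotation invariance
  R <- dockminima:::rotation_matrix(c(1, 2, 3), 0.7)
  expect_equal(rotational_partition(tri %*% t(R), c(1, 1, 1), 310), z0,
               tolerance = 1e-9)
  # mass scaling: doubling all masses scales Zr by 2^{3/2}
  expect_equal(rotational_partition(tri, c(2, 2, 2), 310) / z0, 2^1.5,
               tolerance = 1e-12)
  # collinear geometry unsupported
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(rotational_partition(line, c(1, 1, 1), 310), "collinear")
})

test_that("diatomic Hessian frequency matches sqrt(k/mu) to 0.1%", {
  lig <- make_toy_ligand(toy_system_spec("none", 2))$ligand
  model <- toy_energy_model()   # bond term k/2 (r-r0)^2 with k = 300
  well <- normal_mode_frequencies(model, NULL, lig, lig$ref_conf,
                                  "free-ligand")
  expect_equal(length(well$frequencies), 1L)
  mu <- lig$atoms$mass[1] / 2
  w_exact <- sqrt(300 * pc$kcalmol_J / pc$angstrom_m^2 / (mu * pc$amu_kg))
  expect_equal(well$frequencies, w_exact, tolerance = 1e-3)
  # the five rigid modes were removed, not the vibration
  expect_equal(well$n_vibrating_atoms, 2L)
})

test_that("an isotropic external well gives three equal modes sqrt(k/m)", {
  lig <- probe_ligand()
  k <- 12
  model <- quadratic_model(cbind(0, 0, 0), k = k)
  rec <- rigid_receptor("C", cbind(0, 0, 9))  # field source; unused by model
  well <- normal_mode_frequencies(model, rec, lig, cbind(0, 0, 0),
                                  "complex")
  expect_equal(length(well$frequencies), 3L)
  w_exact <- sqrt(k * pc$kcalmol_J / pc$angstrom_m^2 /
                    (lig$atoms$mass[1] * pc$amu_kg))
  expect_equal(well$frequencies, rep(w_exact, 3), tolerance = 1e-6)
})

test_that("saddle points are rejected by the curvature check", {
  lig <- probe_ligand()
  saddle <- energy_model("saddle", function(receptor, ligand, conf) {
    x <- conf[1, 1]; y <- conf[1, 2]; z <- conf[1, 3]
    list(energy = 0.5 * (x^2 + y^2 - z^2),
         gradient = cbind(x, y, -z))
  })
  expect_error(
    normal_mode_frequencies(saddle, NULL, lig, cbind(0, 0, 0), "complex"),
    "saddle|negative curvature"
  )
})

test_that("the multiwell sum is degenerate-well and ordering consistent", {
  w <- pc$kB_J * 310 / pc$hbar_J
  well_a <- well_descriptor(-5, w, 2, "free-ligand")
  well_b <- well_descriptor(-4.2, w * 2, 2, "free-ligand")
  sp <- species_thermo(24, NULL, 310)
  g1 <- multiwell_free_energy(list(well_a), sp)
  # single well: G = E0 - kT ln(Zv Zt Zr)
  kT <- pc$kB_kcal * 310
  expect_equal(g1, -5 - kT * (log(vibrational_partition(w, 310)) +
                                log_translational_partition(sp)),
               tolerance = 1e-10)
  # two identical wells: exactly kT ln 2 lower
  g2 <- multiwell_free_energy(list(well_a, well_a), sp)
  expect_equal(g1 - g2, kT * log(2), tolerance = 1e-12)
  # adding any well lowers G; ordering is irrelevant
  gab <- multiwell_free_energy(list(well_a, well_b), sp)
  expect_lt(gab, g1)
  expect_equal(gab, multiwell_free_energy(list(well_b, well_a), sp),
               tolerance = 1e-12)
  expect_error(multiwell_free_energy(list(), sp), "at least one")
})

test_that("the binding decomposition identity holds and dG_all behaves", {
  w <- pc$kB_J * 310 / pc$hbar_J
  kT <- pc$kB_kcal * 310
  sp_c <- species_thermo(1000, c(100, 200, 300), 310)
  sp_l <- species_thermo(50, c(5, 6, 7), 310)
  sp_p <- species_thermo(950, c(95, 195, 295), 310)
  wc <- well_descriptor(-30, rep(w, 3), 1, "complex")
  wl <- well_descriptor(-4, w, 2, "free-ligand")
  # single-well complex and ligand: no multiple-minima correction
  b <- binding_breakdown(list(wc), list(wl), -12, sp_c, sp_l, sp_p)
  expect_equal(b$dG_all, 0)
  expect_equal(b$dE, -30 - (-12) - (-4))
  expect_equal(b$dG_bind, b$dE + b$dG_v + b$dG_t + b$dG_r + b$dG_all,
               tolerance = 1e-12)
  # a second complex well, identical to the first: dG_all = -kT ln 2
  b2 <- binding_breakdown(list(wc, wc), list(wl), -12, sp_c, sp_l, sp_p)
  expect_equal(b2$dG_all, -kT * log(2), tolerance = 1e-12)
  # two-term closed form: second well offset so its Boltzmann weight is
  # exactly half the first one's (equal frequencies)
  wc_half <- well_descriptor(-30 + kT * log(2), rep(w, 3), 1, "complex")
  b3 <- binding_breakdown(list(wc, wc_half), list(wl), -12,
                          sp_c, sp_l, sp_p)
  expect_equal(b3$dG_all, -kT * log(1.5), tolerance = 1e-12)
  # ligand-side multiplicity raises the free-ligand reference instead
  b4 <- binding_breakdown(list(wc), list(wl, wl), -12, sp_c, sp_l, sp_p)
  expect_equal(b4$dG_all, kT * log(2), tolerance = 1e-12)
  expect_error(
    binding_breakdown(list(wc), list(wl), -12, sp_c,
                      species_thermo(50, NULL, 300), sp_p),
    "temperatures"
  )
})

test_that("experimental binding energies follow kT ln Ki", {
  expect_equal(dG_from_Ki(1, 310), 0)
  expect_equal(dG_from_Ki(1e-9, 310), -12.7662222585, tolerance = 1e-10)
  ks <- 10^seq(-9, -3)
  expect_true(all(diff(dG_from_Ki(ks, 310)) > 0))
  expect_error(dG_from_Ki(0), "positive")
})
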