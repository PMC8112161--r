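test_that("stopping power matches an independent Bethe-Bloch evaluation", {
  # frozen spot values computed from the closed form with m_u = 938.272,
  # I = 78 eV (verified against the independent oracle below)
  expect_equal(stopping_power(200, "proton"), 0.4460, tolerance = 1e-3)
  expect_equal(stopping_power(87, "proton"), 0.8032, tolerance = 1e-3)
  for (E in c(10, 50, 100, 200, 500)) {
    expect_equal(stopping_power(E, "proton"), oracle_bethe(E),
                 tolerance = 5e-3)
  }
  # helium at matched velocity, against the oracle with its own mass
  expect_equal(stopping_power(150, "helium"),
               oracle_bethe(150, Z = 2, m_u = 931.8448), tolerance = 5e-3)
})

test_that("stopping power scales exactly as Z^2 at fixed velocity", {
  # species sharing the proton's m_u isolate the charge scaling exactly
  for (Z in c(2, 3, 6)) {
    heavy <- ion("test", Z = Z, A = Z, m_u = 938.272)
    expect_equal(stopping_power(120, heavy) / stopping_power(120, "proton"),
                 Z^2, tolerance = 1e-12)
  }
  # and is decreasing in energy over the therapeutic range
  E <- seq(50, 500, by = 50)
  expect_true(all(diff(stopping_power(E, "carbon")) < 0))
})

test_that("stopping power rejects energies outside the validity range", {
  expect_error(stopping_power(0.5, "proton"), "validity floor")
  expect_error(stopping_power(1500, "proton"), "validity range")
})

test_that("pv follows relativistic kinematics", {
  expect_equal(pv(0, "proton"), 0)
  # frozen: E (E + 2 m) / (E + m) with m = 938.272
  expect_equal(pv(200, "proton"), 364.859, tolerance = 1e-4)
  # A-scaling at equal energy per nucleon (near-equal beta; the per-nucleon
  # rest energies of 4He and 1H differ by 0.7%)
  expect_equal(pv(137, "helium") / pv(137, "proton"), 4, tolerance = 1e-3)
  expect_error(pv(-1, "proton"), "negative")
})

test_that("CSDA range reproduces the published range-energy points", {
  expect_equal(csda_range(200, "proton"), 260, tolerance = 0.01)   # 26 cm
  expect_equal(csda_range(350, "proton"), 662, tolerance = 0.015)  # 66.2 cm
  expect_equal(csda_range(386.9, "carbon"), 260, tolerance = 0.02)
  # strictly increasing in energy; lighter ions outrange heavier at equal E/u
  E <- c(100, 200, 300)
  expect_true(all(diff(csda_range(E, "proton")) > 0))
  expect_gt(csda_range(200, "proton"), csda_range(200, "carbon"))
})

test_that("energy_for_range inverts csda_range", {
  for (nm in c("proton", "helium", "carbon")) {
    E <- energy_for_range(260, nm)
    expect_equal(csda_range(E, nm), 260, tolerance = 1e-6)
  }
  # round trip at an arbitrary energy, to < 0.1 MeV/u
  E0 <- 173.4
  expect_equal(energy_for_range(csda_range(E0, "helium"), "helium"), E0,
               tolerance = 0.1 / E0)
  expect_error(energy_for_range(-5), "positive")
})

test_that("depth-energy transport is consistent with the range integral", {
  expect_equal(energy_at_depth(200, 0, "proton"), 200)
  expect_equal(energy_at_depth(200, 200, "proton"), 87.0, tolerance = 0.02)
  expect_equal(energy_at_depth(386.9, 200, "carbon"), 161.5, tolerance = 0.03)
  # CSDA additivity: range(E(x)) = range(E0) - x to < 0.1 mm
  for (x in c(50, 120, 200)) {
    Ex <- energy_at_depth(200, x, "proton")
    expect_equal(csda_range(Ex, "proton"), csda_range(200, "proton") - x,
                 tolerance = 0.1 / 200)
  }
  expect_error(energy_at_depth(200, 280, "proton"), "stops")
})

test_that("depth_energy_profile tabulates a decreasing energy curve", {
  prof <- depth_energy_profile(200, "proton", 200, step = 2)
  expect_s3_class(prof, "depth_energy_profile")
  expect_true(all(diff(prof$E_MeV_u) < 0))
  expect_true(all(prof$pv_MeV > 0))
  expect_equal(prof$E_MeV_u[1], 200)
  expect_equal(tail(prof$E_MeV_u, 1), energy_at_depth(200, 200, "proton"),
               tolerance = 1e-4)
  expect_equal(prof$beta, sqrt(ion_beta2(prof$E_MeV_u, "proton")))
})

test_that("the five imaging ions are constructible from the registry", {
  reg <- ion_registry()
  expect_identical(unname(mapply(function(z, a) c(z, a), reg$Z, reg$A)),
                   matrix(c(1, 1, 2, 4, 3, 6, 5, 10, 6, 12), nrow = 2))
  for (nm in registry_ions) {
    sp <- ion(nm)
    expect_s3_class(sp, "ion_species")
    expect_true(sp$Z >= 1 && sp$A >= sp$Z && sp$m_u > 0)
  }
  expect_error(ion("iron"), "unknown ion")
  expect_error(ion("bad", Z = 3, A = 2, m_u = 931), "invalid species")
})
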