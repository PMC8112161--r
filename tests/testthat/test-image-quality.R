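test_that("SNR obeys its scaling laws exactly", {
  base <- imaging_scenario(n_particles = 100)
  s0 <- snr(base, 87, sigma_E = 2, "proton")
  # sqrt(N_D): quadrupling the particle count doubles SNR
  expect_equal(snr(imaging_scenario(n_particles = 400), 87, 2, "proton"),
               2 * s0)
  # pixel size enters linearly
  expect_equal(snr(imaging_scenario(pixel_mm = 2), 87, 2, "proton"), 2 * s0)
  # inverse in sigma_E
  expect_equal(snr(base, 87, 4, "proton"), s0 / 2)
  expect_error(snr(base, 87, 0, "proton"), "degenerate")
})

test_that("dose scales as SNR^2 and a^-4 and requires nuclear factors", {
  nuc <- nuclear_factors(1.12, 1.08, 1.13)
  sc <- imaging_scenario()
  d1 <- dose_for_snr(5, sc, 2.52, nuc)
  d2 <- dose_for_snr(10, sc, 2.52, nuc)
  expect_equal(d2$dose_MeV_mm3 / d1$dose_MeV_mm3, 4)
  d_half <- dose_for_snr(5, imaging_scenario(pixel_mm = 0.5), 2.52, nuc)
  expect_equal(d_half$dose_MeV_mm3 / d1$dose_MeV_mm3, 16)
  expect_error(dose_for_snr(5, sc, 2.52, nuclear = list(g_ph = 1)),
               "nuclear_factors")
  expect_error(nuclear_factors(g_ph = 1.1, g_dt = 1.1), "S_MC")
  # unit conversion wired through
  expect_equal(d1$dose_mGy / d1$dose_MeV_mm3, 1.602e-4)
})

test_that("published per-ion parameters give the known excess-dose ladder", {
  tab <- dose_ratio_table(ion_table("fixed_range"))
  expect_equal(tab$excess_dose_pct[tab$ion == "proton"], 0)
  expected <- c(helium = 36, lithium = 75, boron = 46, carbon = 40)
  for (nm in names(expected)) {
    expect_lt(abs(tab$excess_dose_pct[tab$ion == nm] - expected[[nm]]), 2,
              label = paste("excess dose", nm, "error [pct points]"))
  }
})

test_that("MTF is normalised, monotone (scattering-only) and capped at Nyquist", {
  f <- seq(0, 4, by = 0.05)
  m <- mtf(f, sigma_mm = 0.6)
  expect_equal(m$mtf[1], 1)
  expect_true(all(diff(m$mtf) <= 0))
  expect_error(mtf(-0.1, 0.6), "negative")
  # closed-form 10% crossing
  sig <- 0.6
  expect_equal(as.numeric(mtf10_from_sigma(sig)),
               sqrt(log(10) / (2 * pi^2)) / sig * 10)
  # complete mode: 10% frequency never exceeds 1/(2a), across widths
  for (sig in c(0.05, 0.127, 0.3, 0.6)) {
    v <- mtf10_from_sigma(sig, pixel_mm = 0.25, mode = "complete")
    expect_lte(as.numeric(v), 10 / (2 * 0.25) + 1e-9)
  }
  # a very sharp beam is sampling-limited: capped exactly at Nyquist
  v <- mtf10_from_sigma(0.05, pixel_mm = 0.25, mode = "complete")
  expect_true(attr(v, "at_nyquist"))
  expect_equal(as.numeric(v), 20)
})

test_that("spatial resolution is monotone in energy and thickness", {
  E <- c(200, 260, 320)
  m_E <- vapply(E, function(e) as.numeric(mtf10(e, "proton", 200)), numeric(1))
  expect_true(all(diff(m_E) > 0))
  th <- c(120, 160, 200)
  m_t <- vapply(th, function(t) as.numeric(mtf10(200, "proton", t)), numeric(1))
  expect_true(all(diff(m_t) < 0))
})

test_that("energy selection honours both policies and the exit-energy floor", {
  sel <- select_energy("proton", "fixed_range", range_mm = 260)
  expect_equal(sel$E_MeV_u, 200, tolerance = 0.005)
  # helium: the 70 MeV/u exit floor binds before the 10 lp/cm target
  sel_he <- select_energy("helium", "fixed_mtf", target_lp_cm = 10)
  expect_identical(sel_he$condition, "exit_energy_floor")
  expect_equal(sel_he$E_MeV_u, 191.1, tolerance = 0.01)
  expect_gt(sel_he$mtf10_lp_cm, 10)
  # proton: the target is attainable above the floor
  sel_p <- select_energy("proton", "fixed_mtf", target_lp_cm = 10)
  expect_identical(sel_p$condition, "target")
  expect_equal(sel_p$mtf10_lp_cm, 10, tolerance = 0.01)
})

test_that("dose uncertainty propagates in quadrature through the product form", {
  nuc0 <- nuclear_factors(1.12, 1.08, 1.13)
  expect_equal(propagate_dose_uncertainty(100, 2.52, 0, nuc0), 0)
  # single relative error passes straight through (log-derivative of a product)
  nuc1 <- nuclear_factors(1.12, 1.08, 1.13, sigma_g_ph = 0.112)
  expect_equal(propagate_dose_uncertainty(100, 2.52, 0, nuc1), 10)
  # full fixture row: hand quadrature of the printed relative errors
  tab <- ion_table("fixed_range")
  p <- tab[tab$ion == "proton", ]
  nucp <- fixture_nuclear(tab, "proton")
  rel <- sqrt((2 * p$sigma_wet_err / p$sigma_wet_mm)^2 +
                (p$g_ph_err / p$g_ph)^2 + (p$g_dt_err / p$g_dt)^2 +
                (p$S_MC_err / p$S_MC_MeV_mm3)^2)
  expect_equal(propagate_dose_uncertainty(1, p$sigma_wet_mm, p$sigma_wet_err,
                                          nucp), rel)
  expect_equal(binomial_sigma(c(0, 0.5, 1)), c(0, 0.5, 0))
})
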