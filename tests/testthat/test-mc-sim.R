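# Monte Carlo tests run at reduced history counts; the tighter 10%
# cross-validation against the analytic moments runs in the acceptance suite
# at 1e5 histories.

test_that("the simulator is deterministic given a seed", {
  a <- simulate_beam(500, 200, "proton", mc_world(), seed = 42)
  b <- simulate_beam(500, 200, "proton", mc_world(), seed = 42)
  expect_identical(a$E_out_MeV_u, b$E_out_MeV_u)
  expect_identical(a$y_rear_mm, b$y_rear_mm)
  c <- simulate_beam(500, 200, "proton", mc_world(), seed = 43)
  expect_false(identical(a$E_out_MeV_u, c$E_out_MeV_u))
})

test_that("the deterministic limit reproduces the transport solution", {
  tr <- simulate_beam(20, 200, "proton", mc_world(phantom = "slab"),
                      seed = 1, straggling = FALSE, scattering = FALSE)
  expect_equal(unique(tr$y_rear_mm), 0)
  expect_equal(unique(tr$theta_rear), 0)
  expect_equal(unique(tr$E_out_MeV_u), energy_at_depth(200, 200, "proton"),
               tolerance = 1e-5)
  expect_equal(unique(tr$wet_mm), 200, tolerance = 1e-3)
  expect_equal(conditional_spread(tr, min_count = 10), 0,
               ignore_attr = TRUE)
})

test_that("exit energies centre on the transport solution with straggling on", {
  tr <- simulate_beam(2e4, 200, "proton", mc_world(phantom = "slab"),
                      seed = 7, scattering = FALSE)
  expect_equal(mean(tr$E_out_MeV_u), energy_at_depth(200, 200, "proton"),
               tolerance = 5e-4)
  an <- sqrt(straggling_variance(200, energy_at_depth(200, 200, "proton"),
                                 "proton"))
  expect_equal(sd(tr$E_out_MeV_u), an, tolerance = 0.05)
})

test_that("helium halves the per-nucleon exit-energy spread of protons", {
  trp <- simulate_beam(1e4, 200, "proton", mc_world(phantom = "slab"),
                       seed = 5, scattering = FALSE)
  trh <- simulate_beam(1e4, 200, "helium", mc_world(phantom = "slab"),
                       seed = 6, scattering = FALSE)
  expect_equal(sd(trh$E_out_MeV_u) / sd(trp$E_out_MeV_u), 0.5,
               tolerance = 0.05)
})

test_that("transverse spread matches the position-variance moment", {
  tr <- simulate_beam(2e4, 200, "proton", mc_world(phantom = "slab"),
                      seed = 9, straggling = FALSE)
  fe <- fermi_eyges_moments(200, "proton", x_mm = 200)
  expect_equal(sd(tr$y_rear_mm), sqrt(fe$A2), tolerance = 0.05)
  expect_equal(sd(tr$theta_rear), sqrt(fe$A0), tolerance = 0.05)
})

test_that("energy is conserved within the straggling-sampling tolerance", {
  tr <- simulate_beam(5e3, 200, "proton", mc_world(phantom = "slab"), seed = 3)
  dep <- 200 - tr$E_out_MeV_u # per-nucleon deposit across 200 mm
  expect_true(all(dep > 0))
  # each history's recorded WET is consistent with its own energy loss
  idx <- c(1, 1000, 2500, 5000)
  wet_check <- vapply(idx, function(i) {
    wet_from_energies(200, tr$E_out_MeV_u[i], "proton")
  }, numeric(1))
  expect_equal(tr$wet_mm[idx], wet_check, tolerance = 1e-4)
})

test_that("stopped particles are flagged and excluded from exit statistics", {
  # 150 MeV/u protons have a 158 mm range: all stop inside the 200 mm slab
  tr <- simulate_beam(50, 150, "proton", mc_world(phantom = "slab"), seed = 2)
  expect_true(all(tr$stopped))
  expect_true(all(is.na(tr$wet_mm)))
})

test_that("noise profiles flag under-populated pixels and see the chord structure", {
  tr <- simulate_beam(2e4, 200, "proton", mc_world(), seed = 21)
  np <- noise_profile(tr, "rear", min_count = 50)
  expect_s3_class(np, "noise_profile")
  expect_true(any(np$unstable)) # scattering tails populate pixels sparsely
  ok <- !np$unstable
  expect_true(all(np$sigma_wet_mm[ok] > 0))
  # zero-noise slab run: identically zero profile (every chord equal)
  tr0 <- simulate_beam(2e3, 200, "proton", mc_world(phantom = "slab"),
                       seed = 22, beam_width_mm = 200,
                       straggling = FALSE, scattering = FALSE)
  np0 <- noise_profile(tr0, "front", min_count = 5)
  expect_true(all(np0$sigma_wet_mm[!np0$unstable] < 1e-6))
})

test_that("conditional spread recovers the constrained envelope (reduced n)", {
  tr <- simulate_beam(3e4, 200, "proton", mc_world(phantom = "slab"),
                      seed = 31, straggling = FALSE)
  cs <- suppressWarnings(conditional_spread(tr))
  env_mid <- attr(constrained_envelope(200, "proton", 200), "sigma_mid_mm")
  expect_equal(as.numeric(cs), env_mid, tolerance = 0.1)
  # binning on the exit direction as well reproduces the narrower envelope
  cs_t <- suppressWarnings(conditional_spread(tr, bin_mm = 0.5,
                                              bin_theta = TRUE,
                                              min_count = 10))
  env_vec <- attr(constrained_envelope(200, "proton", 200,
                                       conditioning = "exit_vector"),
                  "sigma_mid_mm")
  expect_equal(as.numeric(cs_t), env_vec, tolerance = 0.15)
})
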