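# Kinematics, stopping power, range and depth-energy transport.
#
# Convention: user-facing kinetic energies are per nucleon (MeV/u) throughout;
# totals (pv, stopping power, straggling variances) refer to the whole ion.
# Validity floor: 1 MeV/u (no shell or density-effect corrections below that
# the model is not meaningful).

.E_FLOOR <- 1 # MeV/u

.check_energy <- function(E_u, what = "E_u", floor = .E_FLOOR) {
  if (any(!is.finite(E_u))) abort(paste0(what, " must be finite."))
  if (any(E_u < floor)) {
    abort(sprintf("%s = %.3g MeV/u is below the %.3g MeV/u validity floor.",
                  what, min(E_u), floor))
  }
  if (any(E_u > 1000)) {
    abort(paste0(what, " above 1000 MeV/u is outside the model's validity range."))
  }
  invisible(E_u)
}

#' Relativistic kinematics of an ion beam
#'
#' `ion_beta2()` returns the squared velocity ratio beta^2 and `pv()` the
#' product of momentum and velocity for the whole ion,
#' `pv = A * E(E + 2 m_u) / (E + m_u)` with `E` the kinetic energy per
#' nucleon and `m_u` the rest energy per nucleon.
#'
#' @param E_u Kinetic energy per nucleon (MeV/u); vectorised.
#' @param ion Ion species (name or [ion()] object).
#' @return `ion_beta2()`: dimensionless beta^2; `pv()`: MeV (whole ion).
#' @examples
#' pv(200, "proton") # ~ 364.9 MeV
#' pv(200, "helium") / pv(200, "proton") # = 4, A scaling at equal velocity
#' @export
pv <- function(E_u, ion = "proton") {
  spec <- ion(ion)
  if (any(E_u < 0)) abort("negative kinetic energy.")
  spec$A * E_u * (E_u + 2 * spec$m_u) / (E_u + spec$m_u)
}

#' @rdname pv
#' @export
ion_beta2 <- function(E_u, ion = "proton") {
  spec <- ion(ion)
  g <- 1 + E_u / spec$m_u
  1 - 1 / g^2
}

#' Electromagnetic stopping power in a medium
#'
#' Bethe-Bloch stopping power (no shell or density-effect corrections):
#' `S = Z^2 K eta_e / beta^2 * (log(2 m_e c^2 / I * beta^2 / (1 - beta^2)) - beta^2)`
#' with `K = 0.170 MeV/cm` for water. This is the `k1` coefficient that also
#' drives the straggling model.
#'
#' @inheritParams pv
#' @param medium Stopping medium, default [water()].
#' @return Stopping power of the whole ion, MeV/mm; vectorised over `E_u`.
#' @examples
#' stopping_power(200, "proton") # ~ 0.446 MeV/mm
#' stopping_power(200, "helium") / stopping_power(200, "proton") # = 4 (Z^2)
#' @export
stopping_power <- function(E_u, ion = "proton", medium = water()) {
  spec <- ion(ion)
  .check_energy(E_u)
  b2 <- ion_beta2(E_u, spec)
  I_MeV <- medium$I_eV * 1e-6
  spec$Z^2 * .const$K_water * medium$eta_e / b2 *
    (log(2 * .const$me_c2 / I_MeV * b2 / (1 - b2)) - b2)
}

# Internal: CSDA range integral from the validity floor to E_u, in mm.
# R = int A dE_u / S(E_u). Adaptive quadrature; the residual range below the
# 1 MeV/u floor (~0.02 mm in water) is neglected.
.range_integral <- function(E_u, spec, medium) {
  f <- function(e) spec$A / stopping_power(e, spec, medium)
  out <- tryCatch(
    integrate(f, .E_FLOOR, E_u, rel.tol = 1e-9, subdivisions = 400L),
    error = function(e) abort(paste0("range integral failed: ", conditionMessage(e)))
  )
  out$value
}

#' CSDA range of an ion in a medium
#'
#' Continuous-slowing-down range `R = int dE' / S(E')` from the 1 MeV/u
#' validity floor up to the initial energy.
#'
#' @inheritParams stopping_power
#' @return Range in mm; vectorised over `E_u`.
#' @examples
#' csda_range(200, "proton") / 10 # ~ 26 cm
#' @export
csda_range <- function(E_u, ion = "proton", medium = water()) {
  spec <- ion(ion)
  .check_energy(E_u)
  vapply(E_u, .range_integral, numeric(1), spec = spec, medium = medium)
}

#' Beam energy producing a given range
#'
#' Numerical inverse of [csda_range()]: the energy per nucleon whose CSDA
#' range equals `R_mm`.
#'
#' @param R_mm Target range in mm (> 0).
#' @inheritParams stopping_power
#' @return Energy per nucleon (MeV/u); vectorised over `R_mm`.
#' @examples
#' energy_for_range(260, "proton") # ~ 200 MeV/u
#' @export
energy_for_range <- function(R_mm, ion = "proton", medium = water()) {
  spec <- ion(ion)
  if (any(R_mm <= 0)) abort("R_mm must be positive.")
  upper <- 1000
  r_max <- csda_range(upper, spec, medium)
  if (any(R_mm >= r_max)) {
    abort(sprintf("requested range %.1f mm exceeds the integrable domain (%.0f mm).",
                  max(R_mm), r_max))
  }
  vapply(R_mm, function(r) {
    uniroot(function(e) .range_integral(e, spec, medium) - r,
            interval = c(.E_FLOOR + 1e-6, upper), tol = 1e-7)$root
  }, numeric(1))
}

# Internal RK4 march of dE/dx = -S(E)/A (per-nucleon loss), fixed step.
.transport <- function(E0_u, x_mm, spec, medium, step = 0.1) {
  dE <- function(e) -stopping_power(e, spec, medium) / spec$A
  n_full <- floor(x_mm / step + 1e-12)
  hs <- c(rep(step, n_full), x_mm - n_full * step)
  hs <- hs[hs > 1e-12]
  E <- E0_u
  for (h in hs) {
    k1 <- dE(E)
    k2 <- dE(E + h / 2 * k1)
    k3 <- dE(E + h / 2 * k2)
    k4 <- dE(E + h * k3)
    E <- E + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (E < .E_FLOOR) abort("particle stopped inside the medium (energy fell below the validity floor).")
  }
  E
}

#' Residual energy after a water depth
#'
#' Solves `dE/dx = -S(E)` with a fixed-step 4th-order Runge-Kutta march
#' (default 0.1 mm step).
#'
#' @param E0_u Initial energy per nucleon (MeV/u).
#' @param x_mm Depth travelled in the medium (mm); must be less than the
#'   CSDA range.
#' @inheritParams stopping_power
#' @param step RK4 step (mm).
#' @return Residual energy per nucleon (MeV/u); vectorised over `x_mm`.
#' @examples
#' energy_at_depth(200, 200, "proton") # ~ 87 MeV/u
#' @export
energy_at_depth <- function(E0_u, x_mm, ion = "proton", medium = water(),
                            step = 0.1) {
  spec <- ion(ion)
  .check_energy(E0_u, "E0_u")
  if (any(x_mm < 0)) abort("depth must be non-negative.")
  rng <- csda_range(E0_u, spec, medium)
  if (any(x_mm >= rng)) {
    abort(sprintf("depth %.1f mm is beyond the CSDA range (%.1f mm): particle stops.",
                  max(x_mm), rng))
  }
  vapply(x_mm, function(x) {
    if (x == 0) return(E0_u)
    .transport(E0_u, x, spec, medium, step)
  }, numeric(1))
}

#' Depth-energy profile of a beam in a medium
#'
#' Tabulates energy per nucleon, whole-ion `pv` and `beta` on a regular depth
#' grid; the profile feeds the scattering and straggling integrals.
#'
#' @inheritParams energy_at_depth
#' @param depth_mm Total depth to tabulate (mm); must be below the CSDA range.
#' @param step Grid spacing (mm).
#' @return A tibble of class `depth_energy_profile` with columns `depth_mm`,
#'   `E_MeV_u`, `pv_MeV`, `beta`; the ion and medium ride along as attributes.
#' @examples
#' prof <- depth_energy_profile(200, "proton", depth_mm = 200)
#' tail(prof, 3)
#' @export
depth_energy_profile <- function(E0_u, ion = "proton", depth_mm,
                                 medium = water(), step = 0.5) {
  spec <- ion(ion)
  .check_energy(E0_u, "E0_u")
  if (depth_mm <= 0) abort("depth_mm must be positive.")
  if (depth_mm >= csda_range(E0_u, spec, medium)) {
    abort("depth_mm is beyond the CSDA range: particle stops inside.")
  }
  xs <- seq(0, depth_mm, by = step)
  if (tail(xs, 1) < depth_mm) xs <- c(xs, depth_mm)
  Es <- numeric(length(xs))
  Es[1] <- E0_u
  for (i in seq_along(xs)[-1]) {
    Es[i] <- .transport(Es[i - 1], xs[i] - xs[i - 1], spec, medium, step = min(step, 0.1))
  }
  out <- tibble::tibble(
    depth_mm = xs,
    E_MeV_u  = Es,
    pv_MeV   = pv(Es, spec),
    beta     = sqrt(ion_beta2(Es, spec))
  )
  structure(out,
            class = c("depth_energy_profile", class(out)),
            ion = spec, medium = medium, E0_u = E0_u)
}

# trapezoidal weights/integral on an irregular grid
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# cumulative trapezoid, same length as x, starting at 0
.cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}
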