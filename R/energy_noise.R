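# Energy-domain noise: Tschalar straggling, path-ensemble scattering variance,
# and propagation to water-equivalent-thickness (WET) noise.

# Straggling kernel k2 (MeV^2/mm, whole ion): Bohr coefficient K * m_e c^2
# times the relativistic correction. Non-relativistic unit-charge limit:
# 0.0170 * 0.511 = 0.0087 MeV^2/mm = 0.0871 MeV^2/cm (Bohr value for water).
.k2 <- function(E_u, spec, medium) {
  b2 <- ion_beta2(E_u, spec)
  spec$Z^2 * .const$K_water * .const$me_c2 * medium$eta_e *
    (1 - b2 / 2) / (1 - b2)
}

#' Energy-loss straggling variance (Tschalar)
#'
#' Variance of the whole-ion energy at the exit of a slab, accumulated from
#' collision statistics:
#' `sigma2(E_out) = k1(E_out)^2 * int_{E_out}^{E0} k2(E) / k1(E)^3 dE`
#' with `k1` the stopping power and `k2` the Bohr straggling power per unit
#' length (with relativistic correction). The integral runs over whole-ion
#' energy; the Gaussian straggling regime is assumed.
#'
#' @param E0_u,Eout_u Entry and exit energies per nucleon (MeV/u),
#'   `Eout_u <= E0_u`.
#' @inheritParams stopping_power
#' @return Variance of the whole-ion exit energy (MeV^2).
#' @examples
#' straggling_variance(200, 87, "proton") # ~ 4.5 MeV^2
#' @export
straggling_variance <- function(E0_u, Eout_u, ion = "proton", medium = water()) {
  spec <- ion(ion)
  .check_energy(E0_u, "E0_u")
  .check_energy(Eout_u, "Eout_u")
  if (Eout_u > E0_u) abort("Eout_u must not exceed E0_u.")
  if (Eout_u == E0_u) return(0)
  k1 <- function(Et) stopping_power(Et / spec$A, spec, medium)
  integrand <- function(Et) .k2(Et / spec$A, spec, medium) / k1(Et)^3
  val <- integrate(integrand, spec$A * Eout_u, spec$A * E0_u,
                   rel.tol = 1e-9, subdivisions = 400L)$value
  k1(spec$A * Eout_u)^2 * val
}

#' Water-equivalent thickness between two energies
#'
#' `WET = int_{Eout}^{E0} dE / S_w(E)` for the given ion; in pure water this
#' equals the geometric path length. Additive over intermediate energies.
#'
#' @inheritParams straggling_variance
#' @return WET in mm.
#' @examples
#' wet_from_energies(200, 87, "proton") # ~ 200 mm
#' @export
wet_from_energies <- function(E0_u, Eout_u, ion = "proton", medium = water()) {
  spec <- ion(ion)
  .check_energy(E0_u, "E0_u")
  .check_energy(Eout_u, "Eout_u")
  if (Eout_u > E0_u) abort("Eout_u must not exceed E0_u.")
  .range_integral(E0_u, spec, medium) - .range_integral(Eout_u, spec, medium)
}

# Shared evaluator for the path ensemble: per-path energy loss through a slab
# whose straight-through thickness is the envelope's, with each path's
# effective thickness equal to its arc length.
.path_losses <- function(paths, E0_u = NULL, ion = NULL, medium = NULL) {
  if (!inherits(paths, "path_set")) abort("`paths` must come from sample_paths().")
  spec <- ion %||% attr(paths, "ion")
  spec <- ion(spec)
  med <- medium %||% attr(paths, "medium")
  E0 <- E0_u %||% attr(paths, "E0_u")
  pl <- path_lengths(paths)
  lens <- pl$length_mm
  if (any(lens >= csda_range(E0, spec, med))) {
    abort("a sampled path is longer than the particle range: particle stops.")
  }
  # residual energy after each arc length, from the inverted range-energy
  # relation (exact under continuous slowing down)
  grid <- exp(seq(log(.E_FLOOR), log(E0 + 1), length.out = 300))
  Rg <- vapply(grid, .range_integral, numeric(1), spec = spec, medium = med)
  Rinv <- splinefun(Rg, grid, method = "monoH.FC")
  R0 <- .range_integral(E0, spec, med)
  Eout <- Rinv(R0 - lens)
  tibble::tibble(
    path = pl$path, weight = pl$weight, length_mm = lens,
    dE_u = E0 - Eout
  )
}

#' Expected energy loss over the path ensemble
#'
#' Probability-weighted mean of the per-path energy losses, each obtained by
#' integrating the stopping power along the path's arc length through the
#' phantom. Curved paths are longer than the chord, so the expectation exceeds
#' the straight-path loss.
#'
#' @param paths A [sample_paths()] result.
#' @param E0_u,ion,medium Override the attributes carried by `paths`.
#' @return Expected energy loss per nucleon (MeV/u).
#' @export
expected_energy_loss <- function(paths, E0_u = NULL, ion = NULL, medium = NULL) {
  pl <- .path_losses(paths, E0_u, ion, medium)
  sum(pl$weight * pl$dE_u) / sum(pl$weight)
}

#' Scattering-induced energy-loss variance
#'
#' Variance of the whole-ion energy loss across the path ensemble,
#' `E[dE^2] - E[dE]^2` under the path probability weights. Vanishes with the
#' envelope.
#'
#' @inheritParams expected_energy_loss
#' @return Variance of the whole-ion energy loss (MeV^2).
#' @export
scattering_energy_variance <- function(paths, E0_u = NULL, ion = NULL,
                                       medium = NULL) {
  pl <- .path_losses(paths, E0_u, ion, medium)
  spec <- ion(ion %||% attr(paths, "ion"))
  dE <- pl$dE_u * spec$A
  w <- pl$weight / sum(pl$weight)
  m <- sum(w * dE)
  max(0, sum(w * dE^2) - m^2)
}

#' WET noise from exit-energy noise
#'
#' Propagates the exit-energy standard deviation through the energy-WET
#' relation: `sigma_WET = sigma_E / S_w(E_out)`.
#'
#' @param sigma2_E Variance of the whole-ion exit energy (MeV^2).
#' @param Eout_u Exit energy per nucleon (MeV/u).
#' @inheritParams stopping_power
#' @return WET standard deviation (mm).
#' @export
sigma_wet <- function(sigma2_E, Eout_u, ion = "proton", medium = water()) {
  if (any(sigma2_E < 0)) abort("sigma2_E must be non-negative.")
  .check_energy(Eout_u, "Eout_u")
  sqrt(sigma2_E) / stopping_power(Eout_u, ion, medium)
}

#' Full electromagnetic noise budget for a slab crossing
#'
#' Chains the pieces: depth-energy transport for the exit energy, the Tschalar
#' straggling variance, the path-ensemble scattering variance from the
#' constrained envelope, their quadrature sum, and the WET noise at the exit.
#'
#' @param E0_u Entry energy per nucleon (MeV/u).
#' @param ion Ion species.
#' @param thickness_mm Water thickness crossed (mm).
#' @param medium Stopping medium.
#' @param quantiles Number of envelope quantile paths for the scattering term.
#' @param conditioning Envelope conditioning mode, see
#'   [constrained_envelope()].
#' @return One-row tibble of class `noise_budget`: `ion`, `E0_MeV_u`,
#'   `Eout_MeV_u`, `wet_mm`, `sigma2_strag_MeV2`, `sigma2_mcs_MeV2`,
#'   `sigma2_E_MeV2`, `sigma_E_MeV`, `sigma_wet_mm`.
#' @examples
#' \donttest{
#' noise_budget(200, "proton", 200)
#' }
#' @export
noise_budget <- function(E0_u, ion = "proton", thickness_mm, medium = water(),
                         quantiles = 65,
                         conditioning = c("exit_position", "exit_vector")) {
  conditioning <- match.arg(conditioning)
  spec <- ion(ion)
  Eout <- energy_at_depth(E0_u, thickness_mm, spec, medium)
  v_strag <- straggling_variance(E0_u, Eout, spec, medium)
  env <- constrained_envelope(E0_u, spec, thickness_mm, medium,
                              conditioning = conditioning)
  v_mcs <- scattering_energy_variance(sample_paths(env, quantiles))
  v_tot <- v_strag + v_mcs
  out <- tibble::tibble(
    ion = spec$ion,
    E0_MeV_u = E0_u,
    Eout_MeV_u = Eout,
    wet_mm = wet_from_energies(E0_u, Eout, spec, medium),
    sigma2_strag_MeV2 = v_strag,
    sigma2_mcs_MeV2 = v_mcs,
    sigma2_E_MeV2 = v_tot,
    sigma_E_MeV = sqrt(v_tot),
    sigma_wet_mm = sigma_wet(v_tot, Eout, spec, medium)
  )
  structure(out, class = c("noise_budget", class(out)),
            ion_spec = spec, medium = medium)
}

#' @export
glance.noise_budget <- function(x, ...) {
  tibble::tibble(
    ion = x$ion, E0_MeV_u = x$E0_MeV_u, Eout_MeV_u = x$Eout_MeV_u,
    sigma_wet_mm = x$sigma_wet_mm,
    straggling_fraction = x$sigma2_strag_MeV2 / x$sigma2_E_MeV2
  )
}

#' @export
tidy.noise_budget <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x)[, -1], dplyr::everything(),
                      names_to = "quantity", values_to = "value")
}
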