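# Tomographic figures of merit: SNR, dose for a target SNR, MTF with pixel
# sampling, MTF10% extraction, beam-energy selection, uncertainty propagation.

#' Imaging scenario description
#'
#' @param diameter_mm Phantom diameter (mm).
#' @param pixel_mm Reconstructed pixel size `a` (mm). 1 mm is used for
#'   SNR/dose figures, 0.25 mm for spatial-resolution figures.
#' @param projections Number of projections `M`.
#' @param n_particles Particles measured at the exit detector, `N_D`.
#' @param rsp Reconstructed relative stopping power (1 for water).
#' @param rho Object density (g/cm^3).
#' @return A list of class `imaging_scenario`.
#' @examples
#' imaging_scenario(n_particles = 100)
#' @export
imaging_scenario <- function(diameter_mm = 200, pixel_mm = 1,
                             projections = 360, n_particles = 100,
                             rsp = 1, rho = 1) {
  stopifnot(diameter_mm > 0, pixel_mm > 0, projections >= 1,
            n_particles >= 1, rsp > 0, rho > 0)
  structure(list(diameter_mm = diameter_mm, pixel_mm = pixel_mm,
                 projections = projections, n_particles = n_particles,
                 rsp = rsp, rho = rho),
            class = "imaging_scenario")
}

#' Nuclear correction factors
#'
#' Fluence and dose factors that the electromagnetic model consumes as
#' external inputs (they come from full Monte Carlo simulation, shipped here
#' as fixtures): `g_ph` and `g_dt` are the primary attenuation factors (>= 1)
#' in the phantom and in the energy detector, `S_MC` is the primary dose per
#' particle in the central voxel (MeV/mm^3).
#'
#' @param g_ph,g_dt Attenuation factors (>= 1).
#' @param S_MC Central-voxel dose per primary (MeV/mm^3).
#' @param sigma_g_ph,sigma_g_dt,sigma_S_MC One-sigma uncertainties.
#' @return A list of class `nuclear_factors`.
#' @export
nuclear_factors <- function(g_ph, g_dt, S_MC,
                            sigma_g_ph = 0, sigma_g_dt = 0, sigma_S_MC = 0) {
  if (missing(g_ph) || missing(g_dt) || missing(S_MC)) {
    abort("nuclear factors g_ph, g_dt and S_MC must all be supplied (they are never defaulted to 1).")
  }
  stopifnot(g_ph >= 1, g_dt >= 1, S_MC > 0,
            sigma_g_ph >= 0, sigma_g_dt >= 0, sigma_S_MC >= 0)
  structure(list(g_ph = g_ph, g_dt = g_dt, S_MC = S_MC,
                 sigma_g_ph = sigma_g_ph, sigma_g_dt = sigma_g_dt,
                 sigma_S_MC = sigma_S_MC),
            class = "nuclear_factors")
}

#' Signal-to-noise ratio in the central voxel
#'
#' `SNR = sqrt(3 M a^2 / pi^2) * S_w(E_out) sqrt(N_D) RSP / sigma_E`,
#' for the centre of a uniform cylindrical water phantom.
#'
#' @param scenario An [imaging_scenario()].
#' @param Eout_u Exit energy per nucleon (MeV/u).
#' @param sigma_E Standard deviation of the whole-ion exit energy (MeV).
#' @param ion Ion species (sets the stopping power scale).
#' @param medium Stopping medium.
#' @return Dimensionless SNR.
#' @export
snr <- function(scenario, Eout_u, sigma_E, ion = "proton", medium = water()) {
  stopifnot(inherits(scenario, "imaging_scenario"))
  if (any(sigma_E <= 0)) abort("sigma_E must be positive (degenerate noise).")
  Sw <- stopping_power(Eout_u, ion, medium)
  sqrt(3 * scenario$projections * scenario$pixel_mm^2 / pi^2) *
    Sw * sqrt(scenario$n_particles) * scenario$rsp / sigma_E
}

#' Central-voxel dose required for a target SNR
#'
#' `D_c = pi^2 SNR^2 sigma_WET^2 g_ph g_dt S_MC / (3 a^4 rho RSP^2)`,
#' reported both in the model's native unit (MeV/mm^3 per unit density) and
#' in mGy, via 1 MeV mm^-3 (g/cm^3)^-1 = 1.602e-4 mGy.
#'
#' @param target_snr Desired SNR.
#' @param scenario An [imaging_scenario()].
#' @param sigma_wet_mm WET noise at the detector (mm).
#' @param nuclear A [nuclear_factors()] object; required.
#' @return One-row tibble: `snr`, `dose_MeV_mm3`, `dose_mGy`.
#' @export
dose_for_snr <- function(target_snr, scenario, sigma_wet_mm, nuclear) {
  stopifnot(inherits(scenario, "imaging_scenario"))
  if (!inherits(nuclear, "nuclear_factors")) {
    abort("`nuclear` must be a nuclear_factors() object; factors are never silently 1.")
  }
  stopifnot(target_snr > 0, sigma_wet_mm >= 0)
  d <- pi^2 * target_snr^2 * sigma_wet_mm^2 * nuclear$g_ph * nuclear$g_dt *
    nuclear$S_MC / (3 * scenario$pixel_mm^4 * scenario$rho * scenario$rsp^2)
  tibble::tibble(snr = target_snr, dose_MeV_mm3 = d,
                 dose_mGy = d * .const$mev_per_mm3_to_mgy)
}

#' Modulation transfer function with pixel sampling
#'
#' Scattering blurs the reconstruction with a Gaussian of width `sigma_scatt`,
#' the pixel aperture multiplies by `sinc(eps a)` and the sampling comb folds
#' spectral replicas at multiples of `1/a`:
#' `MTF(eps) = |sinc(eps a) exp(-2 pi^2 sigma^2 eps^2)| (x) III_{1/a}`.
#' Mode `"scattering_only"` returns the Gaussian factor alone; `"complete"`
#' multiplies by the sinc and sums aliased replicas (truncated at +/- 3, whose
#' neglected tail is < 1e-6 for the relevant widths), capping recoverable
#' frequencies at Nyquist `1/(2a)`.
#'
#' @param freq_lp_mm Spatial frequencies (lp/mm), non-negative.
#' @param sigma_mm Scattering width at the reconstruction point (mm).
#' @param pixel_mm Pixel size `a` (mm); needed for `"complete"`.
#' @param mode `"scattering_only"` or `"complete"`.
#' @return A tibble of class `mtf_curve`: `freq_lp_mm`, `mtf`.
#' @examples
#' mtf(c(0, 0.3, 0.6), sigma_mm = 0.6)
#' @export
mtf <- function(freq_lp_mm, sigma_mm, pixel_mm = 0.25,
                mode = c("scattering_only", "complete")) {
  mode <- match.arg(mode)
  if (any(freq_lp_mm < 0)) abort("negative spatial frequency.")
  if (sigma_mm < 0) abort("sigma_mm must be non-negative.")
  gauss <- function(f) exp(-2 * pi^2 * sigma_mm^2 * f^2)
  if (mode == "scattering_only") {
    val <- gauss(freq_lp_mm)
  } else {
    stopifnot(pixel_mm > 0)
    base <- function(f) {
      s <- ifelse(f == 0, 1, sin(pi * f * pixel_mm) / (pi * f * pixel_mm))
      s * gauss(f)
    }
    val <- abs(Reduce(`+`, lapply(-3:3, function(k) {
      base(freq_lp_mm - k / pixel_mm)
    })))
    val[freq_lp_mm > 1 / (2 * pixel_mm)] <- 0
    val <- val / abs(sum(vapply(-3:3, function(k) base(-k / pixel_mm), 1)))
  }
  out <- tibble::tibble(freq_lp_mm = freq_lp_mm, mtf = val)
  structure(out, class = c("mtf_curve", class(out)),
            sigma_mm = sigma_mm, pixel_mm = pixel_mm, mode = mode)
}

#' Spatial frequency at 10% modulation
#'
#' For `"scattering_only"` the closed form
#' `eps_10 = sqrt(log(10) / (2 pi^2)) / sigma` applies; for `"complete"` the
#' crossing is found by a bracketed root solve and is capped at Nyquist
#' `1/(2a)` (flagged via the `at_nyquist` attribute).
#'
#' @inheritParams mtf
#' @return Frequency in lp/cm (attribute `at_nyquist` flags a capped result).
#' @examples
#' mtf10_from_sigma(0.6) # ~ 5.7 lp/cm
#' @export
mtf10_from_sigma <- function(sigma_mm, pixel_mm = 0.25,
                             mode = c("scattering_only", "complete")) {
  mode <- match.arg(mode)
  if (sigma_mm < 0) abort("sigma_mm must be non-negative.")
  if (mode == "scattering_only") {
    if (sigma_mm == 0) return(structure(Inf, at_nyquist = FALSE))
    return(structure(sqrt(log(10) / (2 * pi^2)) / sigma_mm * 10,
                     at_nyquist = FALSE))
  }
  nyq <- 1 / (2 * pixel_mm)
  m <- function(f) mtf(f, sigma_mm, pixel_mm, mode = "complete")$mtf - 0.1
  if (m(nyq) > 0) return(structure(nyq * 10, at_nyquist = TRUE))
  root <- uniroot(m, c(1e-9, nyq), tol = 1e-8)$root
  structure(root * 10, at_nyquist = FALSE)
}

#' Spatial resolution of an ion beam crossing a water slab
#'
#' Full chain: depth-energy profile, tracker-constrained envelope, scattering
#' width at the reconstruction point (mid-depth), MTF10% extraction.
#'
#' @inheritParams constrained_envelope
#' @param pixel_mm Pixel size for `"complete"` mode (mm).
#' @param mode MTF mode, see [mtf()].
#' @return MTF10% in lp/cm (attribute `at_nyquist` as in
#'   [mtf10_from_sigma()]).
#' @examples
#' \donttest{
#' mtf10(200, "proton", thickness_mm = 200) # ~ 5.6 lp/cm
#' }
#' @export
mtf10 <- function(E0_u, ion = "proton", thickness_mm = 200, pixel_mm = 0.25,
                  mode = c("scattering_only", "complete"),
                  medium = water(),
                  conditioning = c("exit_position", "exit_vector")) {
  mode <- match.arg(mode)
  conditioning <- match.arg(conditioning)
  env <- constrained_envelope(E0_u, ion, thickness_mm, medium,
                              conditioning = conditioning)
  mtf10_from_sigma(attr(env, "sigma_mid_mm"), pixel_mm, mode)
}

#' Select a beam energy for an imaging task
#'
#' Two policies: `"fixed_range"` returns the energy whose CSDA range equals
#' `range_mm`; `"fixed_mtf"` searches for the energy whose scattering-only
#' MTF10% matches `target_lp_cm`, subject to the hard floor that the beam
#' must cross the phantom with an exit energy above `min_exit_MeV_u`
#' (energy-independent stopping-power reconstruction). When the floor already
#' yields a sharper MTF than the target, the floor energy is returned and the
#' result is flagged (`condition = "exit_energy_floor"`).
#'
#' @param ion Ion species.
#' @param policy `"fixed_range"` or `"fixed_mtf"`.
#' @param range_mm Target range for `"fixed_range"` (mm).
#' @param target_lp_cm Target MTF10% for `"fixed_mtf"` (lp/cm).
#' @param thickness_mm Phantom thickness crossed (mm).
#' @param min_exit_MeV_u Exit-energy floor (MeV/u).
#' @param medium Stopping medium.
#' @param tol_lp_cm Bisection tolerance on the MTF target.
#' @return One-row tibble: `ion`, `policy`, `E_MeV_u`, `mtf10_lp_cm`,
#'   `condition` (`"target"`, `"exit_energy_floor"`, or `"range"`).
#' @examples
#' \donttest{
#' select_energy("proton", "fixed_range", range_mm = 260)
#' }
#' @export
select_energy <- function(ion, policy = c("fixed_range", "fixed_mtf"),
                          range_mm = 260, target_lp_cm = 10,
                          thickness_mm = 200, min_exit_MeV_u = 70,
                          medium = water(), tol_lp_cm = 0.05) {
  policy <- match.arg(policy)
  spec <- ionct::ion(ion)
  if (policy == "fixed_range") {
    E <- energy_for_range(range_mm, spec, medium)
    return(tibble::tibble(ion = spec$ion, policy = policy, E_MeV_u = E,
                          mtf10_lp_cm = as.numeric(mtf10(E, spec, thickness_mm,
                                                         medium = medium)),
                          condition = "range"))
  }
  # floor: range(E_min) = thickness + range(min_exit)
  r_floor <- thickness_mm + csda_range(min_exit_MeV_u, spec, medium)
  E_min <- energy_for_range(r_floor, spec, medium)
  m_min <- as.numeric(mtf10(E_min, spec, thickness_mm, medium = medium))
  if (m_min >= target_lp_cm) {
    return(tibble::tibble(ion = spec$ion, policy = policy, E_MeV_u = E_min,
                          mtf10_lp_cm = m_min, condition = "exit_energy_floor"))
  }
  # mtf10 is monotone increasing in energy: bisection
  lo <- E_min; hi <- 900
  m_hi <- as.numeric(mtf10(hi, spec, thickness_mm, medium = medium))
  if (m_hi < target_lp_cm) {
    abort(sprintf("infeasible: even %d MeV/u yields MTF10 = %.1f < %.1f lp/cm.",
                  hi, m_hi, target_lp_cm))
  }
  while (TRUE) {
    mid <- (lo + hi) / 2
    m_mid <- as.numeric(mtf10(mid, spec, thickness_mm, medium = medium))
    if (abs(m_mid - target_lp_cm) < tol_lp_cm) break
    if (m_mid < target_lp_cm) lo <- mid else hi <- mid
    if (hi - lo < 1e-3) break
  }
  tibble::tibble(ion = spec$ion, policy = policy, E_MeV_u = mid,
                 mtf10_lp_cm = m_mid, condition = "target")
}

#' Binomial standard deviation of an attenuation fraction
#'
#' Helper for the uncertainty of fluence factors estimated from particle
#' counting: `sigma = sqrt(p (1 - p))` (per trial).
#'
#' @param p_eff Fractional attenuation, in `[0, 1]`.
#' @return Standard deviation.
#' @export
binomial_sigma <- function(p_eff) {
  stopifnot(all(p_eff >= 0 & p_eff <= 1))
  sqrt(p_eff * (1 - p_eff))
}

#' First-order uncertainty of the central-voxel dose
#'
#' Uncorrelated propagation through the dose relation, which is a product of
#' powers: `sigma(D)/D = sqrt((2 sigma_wet/sigma_wet)^2 + (sigma_gph/gph)^2 +
#' (sigma_gdt/gdt)^2 + (sigma_SMC/SMC)^2)` -- the WET term enters squared in
#' the dose, hence the factor 2 on its relative error.
#'
#' @param dose Central dose value(s), any unit.
#' @param sigma_wet_mm WET noise (mm) and `sigma_sigma_wet_mm` its
#'   uncertainty.
#' @param sigma_sigma_wet_mm Uncertainty on `sigma_wet_mm`.
#' @param nuclear A [nuclear_factors()] object carrying its uncertainties.
#' @return `sigma(D)` in the unit of `dose`.
#' @export
propagate_dose_uncertainty <- function(dose, sigma_wet_mm, sigma_sigma_wet_mm,
                                       nuclear) {
  stopifnot(inherits(nuclear, "nuclear_factors"),
            sigma_wet_mm > 0, sigma_sigma_wet_mm >= 0)
  rel2 <- (2 * sigma_sigma_wet_mm / sigma_wet_mm)^2 +
    (nuclear$sigma_g_ph / nuclear$g_ph)^2 +
    (nuclear$sigma_g_dt / nuclear$g_dt)^2 +
    (nuclear$sigma_S_MC / nuclear$S_MC)^2
  dose * sqrt(rel2)
}

#' Dose needed by each ion relative to proton at equal SNR
#'
#' At fixed SNR, pixel size and density, the dose relation reduces to
#' `D propto sigma_WET^2 g_ph g_dt S_MC`; everything else cancels in the
#' ratio. Input is a fixture table as returned by [ion_table()].
#'
#' @param table A tibble with columns `ion`, `sigma_wet_mm`, `g_ph`, `g_dt`,
#'   `S_MC_MeV_mm3` (and optional uncertainty columns used for error bars).
#' @param reference Reference ion (default `"proton"`).
#' @return The table augmented with `dose_rel` (reference = 1) and
#'   `excess_dose_pct`.
#' @examples
#' dose_ratio_table(ion_table("fixed_range"))
#' @export
dose_ratio_table <- function(table, reference = "proton") {
  need <- c("ion", "sigma_wet_mm", "g_ph", "g_dt", "S_MC_MeV_mm3")
  if (!all(need %in% names(table))) {
    abort(paste0("table must have columns: ", paste(need, collapse = ", ")))
  }
  d <- table$sigma_wet_mm^2 * table$g_ph * table$g_dt * table$S_MC_MeV_mm3
  ref <- d[match(reference, table$ion)]
  if (is.na(ref)) abort(paste0("reference ion '", reference, "' not in table."))
  dplyr::mutate(table,
                dose_rel = d / ref,
                excess_dose_pct = 100 * (d / ref - 1))
}
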