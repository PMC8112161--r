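# ggplot2 views of the package's result objects.

#' @export
autoplot.scatter_envelope <- function(object, ...) {
  spec <- attr(object, "ion")
  ggplot2::ggplot(object, ggplot2::aes(.data$depth_mm, .data$sigma_mm)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "depth [mm]", y = expression(sigma[scatt] ~ "[mm]"),
      title = sprintf("Constrained scattering envelope: %s, %.1f MeV/u",
                      spec$ion, attr(object, "E0_u"))
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mtf_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$freq_lp_mm * 10, .data$mtf)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.1, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "spatial frequency [lp/cm]", y = "MTF",
                  title = paste0("MTF (", attr(object, "mode"), ")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.noise_profile <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !.data$unstable),
                  ggplot2::aes(.data$y_mm, .data$sigma_wet_mm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lateral position [mm]",
                  y = expression(sigma[WET] ~ "[mm]"),
                  title = paste0("WET noise profile (", attr(object, "plane"),
                                 " tracker)")) +
    ggplot2::theme_minimal()
}

#' SNR-dose curves for a fixture table
#'
#' One curve per ion: the central-voxel dose required to reach each SNR
#' level, from the published per-ion parameters.
#'
#' @param table An [ion_table()] tibble.
#' @param snr_range SNR levels to span.
#' @param scenario Imaging scenario (pixel size, projections, density).
#' @return A ggplot.
#' @export
plot_snr_dose <- function(table, snr_range = seq(1, 20, by = 0.5),
                          scenario = imaging_scenario()) {
  curves <- snr_dose_curves(table, snr_range, scenario)
  ggplot2::ggplot(curves, ggplot2::aes(.data$dose_mGy, .data$snr,
                                       colour = .data$ion)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "central-voxel dose [mGy]", y = "SNR", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_snr_dose
#' @export
snr_dose_curves <- function(table, snr_range = seq(1, 20, by = 0.5),
                            scenario = imaging_scenario()) {
  purrr::map_dfr(table$ion, function(nm) {
    nuc <- fixture_nuclear(table, nm)
    sw <- table$sigma_wet_mm[table$ion == nm]
    purrr::map_dfr(snr_range, function(s) {
      d <- dose_for_snr(s, scenario, sw, nuc)
      tibble::tibble(ion = nm, snr = s, dose_MeV_mm3 = d$dose_MeV_mm3,
                     dose_mGy = d$dose_mGy)
    })
  })
}

#' @export
tidy.scatter_envelope <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.scatter_envelope <- function(x, ...) {
  spec <- attr(x, "ion")
  tibble::tibble(
    ion = spec$ion, E0_MeV_u = attr(x, "E0_u"),
    thickness_mm = attr(x, "thickness_mm"),
    conditioning = attr(x, "conditioning"),
    sigma_mid_mm = attr(x, "sigma_mid_mm"),
    sigma_max_mm = attr(x, "sigma_max_mm"),
    mtf10_lp_cm = as.numeric(mtf10_from_sigma(attr(x, "sigma_mid_mm")))
  )
}

#' @export
glance.mc_tracks <- function(x, ...) {
  spec <- attr(x, "ion_spec")
  ok <- !x$stopped
  tibble::tibble(
    ion = spec$ion, E0_MeV_u = attr(x, "E0_u"),
    n = nrow(x), n_stopped = sum(x$stopped),
    E_out_mean_MeV_u = mean(x$E_out_MeV_u[ok]),
    E_out_sd_MeV_u = stats::sd(x$E_out_MeV_u[ok]),
    sigma_wet_mm = stats::sd(x$wet_mm[ok]),
    y_rear_sd_mm = stats::sd(x$y_rear_mm[ok])
  )
}
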