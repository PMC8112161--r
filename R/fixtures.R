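# Shipped parameter fixtures: published Monte Carlo ion-by-ion parameters for
# the two beam-selection scenarios, stored verbatim (two-significant-figure
# uncertainties included, no re-rounding).

#' Published per-ion imaging parameters
#'
#' Loads the packaged parameter table for one of the two beam-selection
#' scenarios: `"fixed_range"` (every ion's energy chosen for a 26 cm range in
#' water) or `"fixed_mtf"` (energy chosen for a 10 lp/cm spatial-resolution
#' target, subject to a 70 MeV/u exit-energy floor). Columns carry the beam
#' energy, the measured WET noise, the nuclear attenuation factors `g_ph` and
#' `g_dt`, the central-voxel dose per primary `S_MC`, exit energy, range and
#' (for the fixed-MTF scenario) the achieved MTF10%; `*_err` columns are the
#' published one-sigma uncertainties.
#'
#' @param scenario `"fixed_range"` or `"fixed_mtf"`.
#' @param file Optional path to a compatible CSV (for round-tripping edited
#'   tables); overrides `scenario`.
#' @return A tibble with one row per ion.
#' @examples
#' ion_table("fixed_range")
#' @export
ion_table <- function(scenario = c("fixed_range", "fixed_mtf"), file = NULL) {
  if (is.null(file)) {
    scenario <- match.arg(scenario)
    file <- system.file("extdata",
                        paste0("ion_table_", scenario, ".csv"),
                        package = "ionct", mustWork = TRUE)
  }
  out <- readr::read_csv(file, show_col_types = FALSE,
                         col_types = readr::cols(
                           ion = readr::col_character(),
                           symbol = readr::col_character(),
                           .default = readr::col_double()
                         ))
  need <- c("ion", "E_init_MeV_u", "sigma_wet_mm", "g_ph", "g_dt",
            "S_MC_MeV_mm3", "E_out_MeV_u")
  if (!all(need %in% names(out)) || nrow(out) == 0) {
    abort("corrupted fixture: required columns missing.")
  }
  if (any(out$g_ph < 1, na.rm = TRUE) || any(out$g_dt < 1, na.rm = TRUE) ||
      any(out$S_MC_MeV_mm3 <= 0, na.rm = TRUE)) {
    abort("corrupted fixture: attenuation factors must be >= 1 and S_MC > 0.")
  }
  out
}

#' @rdname ion_table
#' @param table A tibble as returned by `ion_table()`.
#' @param path Destination CSV path.
#' @export
write_ion_table <- function(table, path) {
  readr::write_csv(table, path, na = "NA")
  invisible(path)
}

#' Nuclear factors for one ion row
#'
#' Convenience accessor turning one row of [ion_table()] into the
#' [nuclear_factors()] object that [dose_for_snr()] consumes.
#'
#' @param table An [ion_table()] tibble.
#' @param which_ion Ion name.
#' @return A [nuclear_factors()] object.
#' @examples
#' fixture_nuclear(ion_table("fixed_range"), "helium")
#' @export
fixture_nuclear <- function(table, which_ion) {
  row <- table[table$ion == which_ion, ]
  if (nrow(row) != 1) abort(paste0("ion '", which_ion, "' not found in table."))
  err <- function(nm) if (nm %in% names(row)) row[[nm]] else 0
  nuclear_factors(row$g_ph, row$g_dt, row$S_MC_MeV_mm3,
                  err("g_ph_err"), err("g_dt_err"), err("S_MC_err"))
}
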