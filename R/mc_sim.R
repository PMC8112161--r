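# Desk-scale condensed-history electromagnetic Monte Carlo: deterministic
# mean energy loss, Gaussian (Bohr/Tschalar) straggling and correlated
# Fermi-Eyges (theta, y) kicks, in one transverse plane, through either a
# uniform slab or the water cylinder sitting in an air (vacuum-equivalent)
# world. Nuclear interactions are out of scope by design; their net effect
# enters the dose model through fixture factors.

#' World geometry for the Monte Carlo
#'
#' @param diameter_mm Phantom diameter / slab thickness (mm).
#' @param world_mm Lateral world extent (mm); the beam can be spread over it.
#' @param phantom `"cylinder"` (beam crosses chords of length
#'   `2 sqrt(R^2 - y^2)`) or `"slab"` (uniform thickness for every history).
#' @return A list of class `mc_world`. Tracker planes sit at the phantom
#'   entry face (front), mid-plane, and exit face (rear).
#' @export
mc_world <- function(diameter_mm = 200, world_mm = 300,
                     phantom = c("cylinder", "slab")) {
  phantom <- match.arg(phantom)
  stopifnot(diameter_mm > 0, world_mm >= diameter_mm)
  structure(list(diameter_mm = diameter_mm, world_mm = world_mm,
                 phantom = phantom),
            class = "mc_world")
}

#' Simulate an ion beam through the world
#'
#' Condensed-history transport with a fixed step limiter (default 1 mm).
#' Per step in water: 4th-order deterministic mean energy loss, a Gaussian
#' straggling draw with the Bohr/Tschalar per-step variance, and a correlated
#' bivariate (direction, position) multiple-scattering kick with the step's
#' Fermi-Eyges moments (the Highland logarithmic factor is evaluated once per
#' history for its full water chord). Air is treated as vacuum. Scattering is
#' confined to one transverse plane. Histories whose energy falls below the
#' validity floor are recorded as stopped and excluded from exit statistics.
#'
#' @param n Number of histories.
#' @param E0_u Beam energy per nucleon (MeV/u).
#' @param ion Ion species.
#' @param world An [mc_world()].
#' @param seed Integer seed; identical seeds give identical track streams.
#' @param step Step limiter (mm).
#' @param beam_width_mm Lateral extent of the (uniform) beam; `0` gives a
#'   pencil beam on the central axis. Default: the phantom diameter for a
#'   cylinder world, `0` for a slab.
#' @param straggling,scattering Logical switches; disabling both yields the
#'   deterministic limit.
#' @param medium Phantom medium.
#' @return A tibble of class `mc_tracks`, one row per history: `history`,
#'   `y_front_mm`, `y_mid_mm`, `theta_mid`, `y_rear_mm`, `theta_rear`,
#'   `E_mid_MeV_u`, `E_out_MeV_u`, `wet_mm`, `chord_mm`, `stopped`.
#' @examples
#' tr <- simulate_beam(200, 200, "proton", mc_world(phantom = "slab"),
#'                     seed = 1)
#' mean(tr$E_out_MeV_u) # ~ 87 MeV/u
#' @export
simulate_beam <- function(n, E0_u, ion = "proton", world = mc_world(),
                          seed = NULL, step = 1, beam_width_mm = NULL,
                          straggling = TRUE, scattering = TRUE,
                          medium = water()) {
  spec <- ion(ion)
  stopifnot(n >= 1)
  .check_energy(E0_u, "E0_u")
  if (!is.null(seed)) set.seed(seed)
  d <- world$diameter_mm
  R <- d / 2
  if (is.null(beam_width_mm)) {
    beam_width_mm <- if (world$phantom == "cylinder") d else 0
  }
  y0 <- if (beam_width_mm > 0) {
    stats::runif(n, -beam_width_mm / 2, beam_width_mm / 2)
  } else {
    rep(0, n)
  }
  chord <- if (world$phantom == "cylinder") {
    ifelse(abs(y0) < R, 2 * sqrt(pmax(0, R^2 - y0^2)), 0)
  } else {
    rep(d, n)
  }
  fL <- .log_factor(chord, medium$X0_mm)^2 # per-history Highland factor
  y <- y0
  th <- rep(0, n)
  E <- rep(E0_u, n)
  alive <- rep(TRUE, n)
  y_mid <- rep(NA_real_, n); th_mid <- rep(NA_real_, n); E_mid <- rep(NA_real_, n)
  xs <- seq(0, d - step, by = step)
  # raw Bethe-Bloch, clamped at the validity floor instead of erroring:
  # histories that dip below the floor are flagged stopped after the step
  sp_raw <- function(e) {
    e <- pmax(e, .E_FLOOR)
    b2 <- ion_beta2(e, spec)
    I_MeV <- medium$I_eV * 1e-6
    spec$Z^2 * .const$K_water * medium$eta_e / b2 *
      (log(2 * .const$me_c2 / I_MeV * b2 / (1 - b2)) - b2)
  }
  dEdx <- function(e) -sp_raw(e) / spec$A
  for (x in xs) {
    if (abs(x - d / 2) < step / 2) { # mid-plane record (pre-step state)
      y_mid <- y; th_mid <- th; E_mid <- E
    }
    # water membership at the step midpoint
    in_w <- if (world$phantom == "cylinder") {
      (x + step / 2 - R)^2 + y^2 <= R^2
    } else {
      rep(TRUE, n)
    }
    act <- alive & in_w
    if (any(act)) {
      e <- E[act]
      # deterministic mean loss (RK4 across the step)
      k1 <- dEdx(e); k2 <- dEdx(e + step / 2 * k1)
      k3 <- dEdx(e + step / 2 * k2); k4 <- dEdx(e + step * k3)
      e_new <- e + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (straggling) {
        s2 <- .k2(e, spec, medium) * step # whole-ion MeV^2 per step
        e_new <- e_new + rnorm(sum(act), 0, sqrt(s2)) / spec$A
      }
      dead <- e_new < .E_FLOOR
      if (scattering) {
        Tstep <- fL[act] * spec$Z^2 * .const$E0_highland^2 /
          (pv(pmax(e, .E_FLOOR), spec)^2 * medium$X0_mm)
        v_th <- Tstep * step
        v_y <- Tstep * step^3 / 3
        cov_ <- Tstep * step^2 / 2
        z1 <- rnorm(sum(act)); z2 <- rnorm(sum(act))
        d_th <- sqrt(v_th) * z1
        # conditional draw of the position kick given the angular kick
        rho2 <- ifelse(v_th * v_y > 0, cov_^2 / (v_th * v_y), 0)
        d_y <- cov_ / pmax(v_th, 1e-300) * d_th +
          sqrt(pmax(v_y * (1 - rho2), 0)) * z2
      } else {
        d_th <- 0; d_y <- 0
      }
      y[act] <- y[act] + th[act] * step + d_y
      th[act] <- th[act] + d_th
      E[act] <- e_new
      if (any(dead)) {
        idx <- which(act)[dead]
        alive[idx] <- FALSE
        E[idx] <- NA_real_
      }
    }
    drift <- alive & !in_w
    y[drift] <- y[drift] + th[drift] * step
  }
  wet <- rep(NA_real_, n)
  ok <- alive
  if (any(ok)) wet[ok] <- .wet_vec(E0_u, E[ok], spec, medium)
  out <- tibble::tibble(
    history = seq_len(n),
    y_front_mm = y0, y_mid_mm = y_mid, theta_mid = th_mid,
    y_rear_mm = y, theta_rear = th,
    E_mid_MeV_u = E_mid, E_out_MeV_u = E,
    wet_mm = wet, chord_mm = chord, stopped = !alive
  )
  structure(out, class = c("mc_tracks", class(out)),
            ion_spec = spec, medium = medium, E0_u = E0_u, world = world,
            step = step, seed = seed)
}

# Vectorised WET via a range-energy spline (exact to spline tolerance):
# wet = R(E0) - R(Eout).
.wet_vec <- function(E0_u, Eout_u, spec, medium) {
  grid <- exp(seq(log(.E_FLOOR), log(E0_u + 1), length.out = 200))
  Rg <- vapply(grid, .range_integral, numeric(1), spec = spec, medium = medium)
  Rfun <- splinefun(grid, Rg, method = "monoH.FC")
  Rfun(E0_u) - Rfun(pmax(Eout_u, .E_FLOOR))
}

#' Lateral WET-noise profile of a radiograph
#'
#' Bins histories into lateral pixels at the chosen tracker plane and reports
#' the per-pixel standard deviation of the water-equivalent thickness.
#' Under-populated pixels are flagged, not zero-filled.
#'
#' @param tracks A [simulate_beam()] result.
#' @param plane `"front"` (bin by entry position) or `"rear"` (exit position).
#' @param pixel_mm Pixel size (mm).
#' @param min_count Pixels with fewer histories are flagged `unstable`.
#' @return A tibble of class `noise_profile`: `y_mm` (pixel centre), `n`,
#'   `sigma_wet_mm`, `unstable`.
#' @export
noise_profile <- function(tracks, plane = c("front", "rear"), pixel_mm = 1,
                          min_count = 100) {
  plane <- match.arg(plane)
  stopifnot(inherits(tracks, "mc_tracks"))
  yy <- if (plane == "front") tracks$y_front_mm else tracks$y_rear_mm
  keep <- !tracks$stopped & !is.na(tracks$wet_mm)
  dat <- tibble::tibble(y = yy[keep], wet = tracks$wet_mm[keep])
  dat$bin <- floor(dat$y / pixel_mm)
  out <- dat |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     sigma_wet_mm = stats::sd(.data$wet),
                     .groups = "drop") |>
    dplyr::mutate(y_mm = (.data$bin + 0.5) * pixel_mm,
                  unstable = .data$n < min_count) |>
    dplyr::select("y_mm", "n", "sigma_wet_mm", "unstable") |>
    dplyr::arrange(.data$y_mm)
  structure(out, class = c("noise_profile", class(out)),
            plane = plane, pixel_mm = pixel_mm)
}

#' Mid-plane lateral spread conditional on boundary measurements
#'
#' The Monte Carlo counterpart of [constrained_envelope()]: histories are
#' grouped by their measured exit position (pencil beam: the entry vector is
#' shared by construction), and the pooled within-bin standard deviation of
#' the mid-plane lateral position is returned. Binning on the exit direction
#' as well (`bin_theta = TRUE`) reproduces the narrower `"exit_vector"`
#' envelope. Under-populated bins are dropped with a warning.
#'
#' @param tracks A [simulate_beam()] result (pencil beam recommended).
#' @param bin_mm Exit-position bin width (mm); small against the
#'   unconditional spread.
#' @param bin_theta Also bin on exit direction (bin width `bin_mm / 100`
#'   rad).
#' @param min_count Minimum histories per bin.
#' @return Pooled conditional standard deviation of `y_mid` (mm), with the
#'   number of bins and histories used as attributes.
#' @export
conditional_spread <- function(tracks, bin_mm = 0.2, bin_theta = FALSE,
                               min_count = 30) {
  stopifnot(inherits(tracks, "mc_tracks"))
  keep <- !tracks$stopped
  dat <- tibble::tibble(
    y_mid = tracks$y_mid_mm[keep],
    b_y = floor(tracks$y_rear_mm[keep] / bin_mm)
  )
  if (bin_theta) dat$b_t <- floor(tracks$theta_rear[keep] / (bin_mm / 100))
  grp <- if (bin_theta) c("b_y", "b_t") else "b_y"
  agg <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n = dplyr::n(), v = stats::var(.data$y_mid),
                     .groups = "drop")
  used <- dplyr::filter(agg, .data$n >= min_count)
  if (nrow(used) < nrow(agg)) {
    warn(sprintf("%d under-populated exit bins dropped (< %d histories).",
                 nrow(agg) - nrow(used), min_count))
  }
  if (nrow(used) == 0) abort("no exit bin has enough histories.")
  pooled <- sqrt(sum((used$n - 1) * used$v) / sum(used$n - 1))
  structure(pooled, n_bins = nrow(used), n_histories = sum(used$n))
}

#' Interior-bump statistic of a front-tracker noise profile
#'
#' Quantifies the off-centre noise bumps that scattering produces in proton
#' radiographs: the profile is folded about the beam axis, averaged in 5 mm
#' bands, and the ratio of the interior maximum (bands between `interior_mm`)
#' to the mean near-edge level is returned. A ratio above 1 means the profile
#' has a local maximum strictly between centre and edge (bump present, the
#' proton signature); a ratio at or below 1 means the profile keeps rising
#' toward the cylinder edge (heavier ions).
#'
#' @param profile A front-plane [noise_profile()].
#' @param interior_mm Folded-position window searched for the bump (mm).
#' @param edge_mm Folded-position window defining the near-edge level (mm).
#' @return The bump ratio, with the bump location (mm) as an attribute.
#' @export
bump_statistic <- function(profile, interior_mm = c(30, 80),
                           edge_mm = c(84, 92)) {
  stopifnot(inherits(profile, "noise_profile"))
  ok <- !profile$unstable & is.finite(profile$sigma_wet_mm)
  dat <- tibble::tibble(fold = abs(profile$y_mm[ok]),
                        s = profile$sigma_wet_mm[ok])
  dat$band <- floor(dat$fold / 5) * 5
  agg <- dat |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(s = mean(.data$s), .groups = "drop")
  inner <- agg[agg$band >= interior_mm[1] & agg$band <= interior_mm[2], ]
  edge <- agg[agg$band >= edge_mm[1] & agg$band <= edge_mm[2], ]
  if (nrow(inner) == 0 || nrow(edge) == 0) abort("profile too sparse for the bump statistic.")
  ratio <- max(inner$s) / mean(edge$s)
  structure(ratio, bump_mm = inner$band[which.max(inner$s)])
}
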