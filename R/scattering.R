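# Multiple-Coulomb-scattering moments and the tracker-constrained envelope.
#
# Scattering power (Highland form): T(u) = f^2 Z^2 E0^2 / (pv(u)^2 X0), with
# f = 1 + c * log(l / X0) the logarithmic thickness correction (c = 1/9 by
# default) clamped at zero for very short paths (l < X0 exp(-9/ (9 c))).
# Moments use the kernel (x - u)^n: distance from the evaluation depth.

.log_factor <- function(len_mm, X0, coef = 1 / 9) {
  ifelse(len_mm <= 0, 0, pmax(0, 1 + coef * log(len_mm / X0)))
}

# Scattering power along a profile, without the log factor (applied by callers
# with the appropriate path length).
.scatt_power <- function(profile) {
  spec <- attr(profile, "ion")
  med <- attr(profile, "medium")
  spec$Z^2 * .const$E0_highland^2 / (profile$pv_MeV^2 * med$X0_mm)
}

#' Fermi-Eyges scattering moments
#'
#' Moments of the bivariate (position, direction) Gaussian accumulated by a
#' beam between the entry plane and depth `x`:
#' `sigma2_n(x) = Z^2 E0^2 f(x - x0)^2 * int (x - u)^n du / (pv(u)^2 X0)`,
#' where `n = 0` is the direction variance (rad^2), `n = 1` the
#' position-direction covariance (mm rad) and `n = 2` the position variance
#' (mm^2), and `f` is the logarithmic thickness correction.
#'
#' @param E0_u Initial energy per nucleon (MeV/u).
#' @param ion Ion species.
#' @param x_mm Evaluation depth(s) in the medium (mm), measured from the entry
#'   plane `x0`.
#' @param x0_mm Entry plane (mm), default 0.
#' @param medium Stopping medium.
#' @param log_coefficient Coefficient of the logarithmic correction; `1/9`
#'   (default) or the Highland value `0.038`.
#' @param step Depth grid spacing for the moment integrals (mm).
#' @return A tibble with columns `depth_mm`, `A0`, `A1`, `A2`.
#' @examples
#' fermi_eyges_moments(200, "proton", x_mm = c(100, 200))
#' @export
fermi_eyges_moments <- function(E0_u, ion = "proton", x_mm, x0_mm = 0,
                                medium = water(), log_coefficient = 1 / 9,
                                step = 0.5) {
  spec <- ion(ion)
  if (any(x_mm < x0_mm)) abort("x_mm must be >= x0_mm.")
  L <- max(x_mm) - x0_mm
  if (L == 0) {
    return(tibble::tibble(depth_mm = x_mm, A0 = 0, A1 = 0, A2 = 0))
  }
  prof <- depth_energy_profile(E0_u, spec, depth_mm = L, medium = medium,
                               step = step)
  Tu <- .scatt_power(prof)
  u <- prof$depth_mm
  C0 <- .cumtrapz(u, Tu)
  C1 <- .cumtrapz(u, u * Tu)
  C2 <- .cumtrapz(u, u^2 * Tu)
  interp <- function(C) splinefun(u, C, method = "monoH.FC")
  f0 <- interp(C0); f1 <- interp(C1); f2 <- interp(C2)
  x_rel <- x_mm - x0_mm
  fac <- .log_factor(x_rel, medium$X0_mm, log_coefficient)^2
  tibble::tibble(
    depth_mm = x_mm,
    A0 = fac * f0(x_rel),
    A1 = fac * (x_rel * f0(x_rel) - f1(x_rel)),
    A2 = fac * (x_rel^2 * f0(x_rel) - 2 * x_rel * f1(x_rel) + f2(x_rel))
  )
}

#' Tracker-constrained scattering envelope
#'
#' Lateral path uncertainty at each depth for a particle whose entry vector
#' (position and direction) and exit measurement are known exactly. The
#' envelope is the posterior standard deviation of the lateral position under
#' Gaussian conditioning of the Fermi-Eyges process on both boundary
#' measurements; it vanishes at both trackers and peaks near mid-depth.
#'
#' Two conditioning modes are available. `"exit_position"` (default) uses the
#' measured exit position only, matching a reconstruction that bins particles
#' by their measured entry and exit points; `"exit_vector"` additionally
#' conditions on the measured exit direction (maximum-likelihood-path style)
#' and gives a narrower envelope. The logarithmic thickness correction is
#' evaluated once for the full traversed thickness.
#'
#' @inheritParams fermi_eyges_moments
#' @param thickness_mm Water thickness between entry and exit trackers (mm).
#' @param conditioning `"exit_position"` or `"exit_vector"`.
#' @return A tibble of class `scatter_envelope` with columns `depth_mm`,
#'   `sigma_mm`; attributes carry the ion, energy and `sigma` at mid-depth.
#' @examples
#' env <- constrained_envelope(200, "proton", thickness_mm = 200)
#' attr(env, "sigma_mid_mm") # ~ 0.61 mm
#' @export
constrained_envelope <- function(E0_u, ion = "proton", thickness_mm,
                                 medium = water(),
                                 conditioning = c("exit_position", "exit_vector"),
                                 log_coefficient = 1 / 9, step = 0.5) {
  conditioning <- match.arg(conditioning)
  spec <- ion(ion)
  prof <- depth_energy_profile(E0_u, spec, depth_mm = thickness_mm,
                               medium = medium, step = step)
  L <- thickness_mm
  fL2 <- .log_factor(L, medium$X0_mm, log_coefficient)^2
  Tu <- fL2 * .scatt_power(prof)
  u <- prof$depth_mm
  C0 <- .cumtrapz(u, Tu)
  C1 <- .cumtrapz(u, u * Tu)
  C2 <- .cumtrapz(u, u^2 * Tu)
  x <- u
  # forward moments from the entry vector, kernel (x - u)^n
  A0f <- C0
  A1f <- x * C0 - C1
  A2f <- x^2 * C0 - 2 * x * C1 + C2
  n <- length(x)
  V0 <- C0[n]; V1 <- C1[n]; V2tot <- L^2 * V0 - 2 * L * V1 + C2[n]
  if (conditioning == "exit_position") {
    # var(y_x) - cov(y_x, y_exit)^2 / var(y_exit), with
    # cov(y_x, y_exit) = A2f + (L - x) A1f
    cov_xe <- A2f + (L - x) * A1f
    s2 <- if (V2tot > 0) A2f - cov_xe^2 / V2tot else rep(0, n)
  } else {
    # full 2x2 conditioning on the exit (y, theta) vector: posterior precision
    # P = S1^{-1} + H' Ss^{-1} H, H = [[1, d], [0, 1]], d = L - x, with Ss the
    # backward scattering moments over [x, L] evaluated at the exit plane.
    d <- L - x
    B0 <- V0 - C0
    B1 <- L * (V0 - C0) - (V1 - C1)
    B2 <- L^2 * (V0 - C0) - 2 * L * (V1 - C1) + (C2[n] - C2)
    s2 <- numeric(n)
    for (i in seq_len(n)) {
      det1 <- A2f[i] * A0f[i] - A1f[i]^2
      det2 <- B2[i] * B0[i] - B1[i]^2
      if (det1 <= 0 || det2 <= 0) { s2[i] <- 0; next }
      S1inv <- matrix(c(A0f[i], -A1f[i], -A1f[i], A2f[i]), 2) / det1
      Ssinv <- matrix(c(B0[i], -B1[i], -B1[i], B2[i]), 2) / det2
      H <- matrix(c(1, 0, d[i], 1), 2)
      P <- S1inv + t(H) %*% Ssinv %*% H
      s2[i] <- solve(P)[1, 1]
    }
  }
  s2 <- pmax(s2, 0)
  s2[c(1, n)] <- 0
  out <- tibble::tibble(depth_mm = x, sigma_mm = sqrt(s2))
  mid <- sqrt(max(0, stats::approx(x, s2, xout = L / 2)$y))
  structure(out,
            class = c("scatter_envelope", class(out)),
            ion = spec, medium = medium, E0_u = E0_u,
            thickness_mm = L, conditioning = conditioning,
            sigma_mid_mm = mid, sigma_max_mm = sqrt(max(s2)))
}

#' Quantile paths of the scattering envelope
#'
#' Representative lateral paths through the phantom at equally spaced
#' probability levels of the Gaussian envelope: path `p` follows
#' `y(x) = z_p * sigma(x)` with `z_p` the Gaussian quantile. Each path carries
#' probability weight `1/quantiles`; weights sum to one and the median path is
#' included when `quantiles` is odd.
#'
#' @param envelope A [constrained_envelope()] result.
#' @param quantiles Odd number of paths (>= 1).
#' @return A tibble of class `path_set` with columns `path`, `z`, `weight`,
#'   nested depth grid shared via attributes: long format
#'   (`path`, `z`, `weight`, `depth_mm`, `y_mm`).
#' @examples
#' env <- constrained_envelope(200, "proton", thickness_mm = 200)
#' paths <- sample_paths(env, quantiles = 5)
#' @export
sample_paths <- function(envelope, quantiles = 65) {
  if (!inherits(envelope, "scatter_envelope")) {
    abort("`envelope` must come from constrained_envelope().")
  }
  if (quantiles < 1 || quantiles %% 2 == 0) {
    abort("`quantiles` must be a positive odd count (so the median path is included).")
  }
  p <- (seq_len(quantiles) - 0.5) / quantiles
  z <- qnorm(p)
  grid <- tidyr::expand_grid(
    tibble::tibble(path = seq_len(quantiles), z = z, weight = 1 / quantiles),
    tibble::tibble(depth_mm = envelope$depth_mm)
  )
  grid$y_mm <- grid$z * envelope$sigma_mm[match(grid$depth_mm, envelope$depth_mm)]
  structure(grid,
            class = c("path_set", class(grid)),
            ion = attr(envelope, "ion"), medium = attr(envelope, "medium"),
            E0_u = attr(envelope, "E0_u"),
            thickness_mm = attr(envelope, "thickness_mm"))
}

#' @export
#' @rdname sample_paths
#' @param x A `path_set`.
#' @param ... Unused.
path_lengths <- function(x, ...) {
  if (!inherits(x, "path_set")) abort("`x` must be a path_set.")
  x |>
    dplyr::group_by(.data$path, .data$z, .data$weight) |>
    dplyr::summarise(
      length_mm = {
        dx <- diff(.data$depth_mm)
        dy <- diff(.data$y_mm)
        sum(sqrt(dx^2 + dy^2))
      },
      .groups = "drop"
    )
}
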