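# Localization of X-ray radiolysis.
#
# X-ray absorption ejects a photoelectron or Auger electron that deposits its
# energy over a range R (nm) = 0.01 E^1.3 (E in eV, organic material). The
# depth distribution of that deposition follows the Everhart-Hoff universal
# depth-dose polynomial
#   lambda(y) = 0.60 + 6.21 y - 12.40 y^2 + 5.69 y^3,  y = z/R in [0, 1]
# (Everhart & Hoff, J. Appl. Phys. 42, 5837 (1971)), renormalized so the
# cumulative deposition reaches exactly 1 at y = 1. A time scale follows from
# integrating the inverse electron speed along the path, taking the residual
# kinetic energy at each depth as the initial energy minus the cumulative
# deposition.

#' Photoelectron / Auger-electron range
#'
#' `R (nm) = 0.01 E^1.3` with `E` in eV, for organic material.
#'
#' @param E_eV Initial electron energy, eV (> 0). Vectorized.
#' @return Range in nm.
#' @examples
#' photoelectron_range(500)   # ~32 nm
#' photoelectron_range(8000)  # ~1.2 um
#' @export
photoelectron_range <- function(E_eV) {
  if (any(E_eV <= 0)) stop("`E_eV` must be positive", call. = FALSE)
  0.01 * E_eV^1.3
}

# Everhart-Hoff depth-dose polynomial, unnormalized
.eh_lambda <- function(y) 0.60 + 6.21 * y - 12.40 * y^2 + 5.69 * y^3
# its antiderivative from 0
.eh_cum_raw <- function(y) 0.60 * y + 3.105 * y^2 - 12.40 / 3 * y^3 + 5.69 / 4 * y^4
.eh_norm <- .eh_cum_raw(1)

# relativistic speed in nm/fs for kinetic energy E (eV)
.electron_speed <- function(E_eV) {
  gamma <- 1 + E_eV / (.const$me_c2_keV * 1e3)
  .const$c_nm_fs * sqrt(1 - 1 / gamma^2)
}

#' Depth-dose deposition profile of an ejected electron
#'
#' Cumulative energy deposition versus depth for an electron of initial
#' energy `E_eV`, using the Everhart-Hoff universal depth-dose curve scaled
#' to the range [photoelectron_range()], together with a cumulative time
#' scale from the speed-distance relation (residual energy = initial energy
#' minus energy already deposited; a small residual floor keeps the end-of-
#' range speed finite).
#'
#' @param E_eV Initial electron energy, eV. The parameterization is intended
#'   for ~0.5-30 keV; outside that a warning is raised and the profile
#'   computed anyway.
#' @param n Number of depth steps (default 400).
#' @return A tibble of class `deposition_profile` with columns `y`
#'   (fractional depth), `depth_nm`, `cum_fraction` (0 to 1) and
#'   `cum_time_fs`.
#' @examples
#' prof <- deposition_profile(500)
#' half_energy_depth(prof)  # depth by which half the energy is deposited
#' @export
deposition_profile <- function(E_eV, n = 400) {
  stopifnot(length(E_eV) == 1, E_eV > 0, n >= 10)
  if (E_eV < 500 || E_eV > 30000)
    warning("Everhart-Hoff parameterization applied outside ~0.5-30 keV",
            call. = FALSE)
  R <- photoelectron_range(E_eV)
  y <- seq(0, 1, length.out = n + 1)
  cum <- .eh_cum_raw(y) / .eh_norm
  # cumulative time: trapezoid of 1/v over depth, v from residual energy
  resid <- pmax(E_eV * (1 - cum), E_eV * 1e-4)
  inv_v <- 1 / .electron_speed(resid)
  dz <- R / n
  cum_t <- c(0, cumsum((inv_v[-1] + inv_v[-(n + 1)]) / 2 * dz))
  out <- tibble::tibble(y = y, depth_nm = y * R,
                        cum_fraction = cum, cum_time_fs = cum_t)
  structure(out, class = c("deposition_profile", class(out)),
            E_eV = E_eV, range_nm = R)
}

#' Cumulative deposition time versus depth
#'
#' Convenience wrapper returning the time-scale columns of
#' [deposition_profile()].
#'
#' @inheritParams deposition_profile
#' @return A tibble with `depth_nm`, `cum_fraction` and `cum_time_fs`.
#' @export
deposition_timescale <- function(E_eV, n = 400) {
  deposition_profile(E_eV, n)[, c("depth_nm", "cum_fraction", "cum_time_fs")]
}

#' Depth by which half the energy is deposited
#'
#' @param profile A [deposition_profile()].
#' @return Depth in nm (linear interpolation of the cumulative curve).
#' @export
half_energy_depth <- function(profile) {
  stats::approx(profile$cum_fraction, profile$depth_nm, xout = 0.5,
                ties = "ordered")$y
}

#' Time by which half the energy is deposited
#'
#' @param profile A [deposition_profile()].
#' @return Time in fs.
#' @export
half_energy_time <- function(profile) {
  stats::approx(profile$cum_fraction, profile$cum_time_fs, xout = 0.5,
                ties = "ordered")$y
}
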