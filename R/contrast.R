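# Per-modality contrast and collection efficiency.
#
# Each mode maps (feature, matrix, beam, thickness t, feature size delta,
# geometry) to the initial Weber contrast C and the collection efficiency F.
# Column geometry: the feature spans the thickness (contrast ~ t).
# Voxel geometry: an equiaxed feature of height delta <= t (contrast ~ delta).

#' Imaging-mode configuration
#'
#' @param mode One of `"xray_absorption"`, `"xray_phase"`, `"tem_phase"`,
#'   `"tem_brightfield"`, `"stem_darkfield"`.
#' @param DQE Detective quantum efficiency in (0, 1]; default 0.5.
#' @param beta_mrad Aperture semi-angle (bright field) or annular-detector
#'   inner angle (dark field), mrad; default 5.
#' @param snr_threshold Rose detection threshold; default 3.
#' @param phase_plate `"ideal_zernike"` or `"none"` (phase modes).
#' @param zero_loss Apply zero-loss energy filtering to the scattering-contrast
#'   efficiency (multiplies F by `exp(-t/lambda_i)`); off by default since no
#'   matching filtered-contrast model is provided.
#' @param t_max_nm Beer's-law validity bound for the scattering-contrast
#'   modes; thicker specimens trigger a warning flag (default 500 nm,
#'   appropriate for light-element specimens at 300 keV).
#' @return A `dlr_mode` object.
#' @export
mode_config <- function(mode = c("xray_absorption", "xray_phase", "tem_phase",
                                 "tem_brightfield", "stem_darkfield"),
                        DQE = 0.5, beta_mrad = 5, snr_threshold = 3,
                        phase_plate = c("ideal_zernike", "none"),
                        zero_loss = FALSE, t_max_nm = 500) {
  mode <- match.arg(mode)
  phase_plate <- match.arg(phase_plate)
  stopifnot(DQE > 0, DQE <= 1, snr_threshold > 0)
  if (mode %in% c("tem_brightfield", "stem_darkfield") && beta_mrad <= 0)
    stop("scattering-contrast modes need a positive `beta_mrad`",
         call. = FALSE)
  structure(list(mode = mode, DQE = DQE, beta_mrad = beta_mrad,
                 snr_threshold = snr_threshold, phase_plate = phase_plate,
                 zero_loss = zero_loss, t_max_nm = t_max_nm),
            class = "dlr_mode")
}

#' @export
print.dlr_mode <- function(x, ...) {
  cat("<dlr_mode> ", x$mode, ", DQE = ", x$DQE,
      ", SNR threshold = ", x$snr_threshold,
      if (x$mode %in% c("tem_brightfield", "stem_darkfield"))
        paste0(", beta = ", x$beta_mrad, " mrad"),
      "\n", sep = "")
  invisible(x)
}

.check_geometry <- function(geometry, t_nm, delta_nm) {
  if (geometry == "voxel" && delta_nm > t_nm * (1 + 1e-12))
    stop("voxel feature size delta (", delta_nm,
         " nm) exceeds the specimen thickness (", t_nm, " nm)", call. = FALSE)
}

#' X-ray absorption contrast and efficiency
#'
#' Thin-specimen absorption contrast. Column: `C = (mu_f - mu_m) t`,
#' `F = exp(-mu_f t)` (the feature column attenuates its own signal).
#' Voxel: `C = (mu_f - mu_m) delta`, with the signal attenuated along the
#' full path, `F = exp(-mu_m (t - delta) - mu_f delta)` (reduces to
#' `exp(-mu_m t)` when the coefficients are close or delta << t).
#'
#' @param t_nm Specimen thickness, nm.
#' @param delta_nm Feature size, nm (voxel geometry; must not exceed `t_nm`).
#' @param mu_f,mu_m Linear absorption coefficients of feature and matrix,
#'   nm^-1 (>= 0).
#' @param geometry `"column"` or `"voxel"`.
#' @return List with Weber contrast `C` (signed) and efficiency `F`.
#' @export
cf_xray_absorption <- function(t_nm, delta_nm, mu_f, mu_m,
                               geometry = c("column", "voxel")) {
  geometry <- match.arg(geometry)
  stopifnot(mu_f >= 0, mu_m >= 0, t_nm > 0)
  .check_geometry(geometry, t_nm, delta_nm)
  if (geometry == "column") {
    list(C = (mu_f - mu_m) * t_nm, F = exp(-mu_f * t_nm))
  } else {
    list(C = (mu_f - mu_m) * delta_nm,
         F = exp(-mu_m * (t_nm - delta_nm) - mu_f * delta_nm))
  }
}

#' X-ray (Zernike) phase contrast and efficiency
#'
#' Weak-phase contrast from an ideal phase plate: the phase advance over a
#' path `z` through the refractive-index difference is
#' `dphi = (2 pi / lambda) d_eps1 z`, and the ideal-Zernike Weber contrast is
#' twice the phase shift, `C = 2 (2 pi / lambda) d_eps1 z` with `z = t`
#' (column) or `delta` (voxel). The efficiency is the absorption expression
#' of the column geometry, `F = exp(-mu_f t)`.
#'
#' @inheritParams cf_xray_absorption
#' @param lambda_nm Photon wavelength, nm.
#' @param d_eps1 Difference in the real refractive-index decrement
#'   (`1 + eps1`) between feature and matrix.
#' @param mu_f Feature absorption coefficient (for the efficiency), nm^-1.
#' @return List with `C` and `F`.
#' @export
cf_xray_phase <- function(t_nm, delta_nm, lambda_nm, d_eps1, mu_f,
                          geometry = c("column", "voxel")) {
  geometry <- match.arg(geometry)
  stopifnot(lambda_nm > 0, t_nm > 0, mu_f >= 0)
  .check_geometry(geometry, t_nm, delta_nm)
  z <- if (geometry == "column") t_nm else delta_nm
  list(C = 2 * (2 * pi / lambda_nm) * d_eps1 * z,
       F = exp(-mu_f * t_nm))
}

#' TEM phase contrast and efficiency
#'
#' The electron phase shift per unit path in a material of mean inner
#' potential `Phi` is `dphi/dz = pi RF Phi / (lambda E0)` (`E0` in volts,
#' `lambda` the electron wavelength, RF the relativistic factor). The feature
#' contrast uses the difference in mean inner potential over `t` (column) or
#' `delta` (voxel); for a weak phase object `|C0| = 2 dphi`. The efficiency
#' removes electrons lost to plural elastic and to inelastic scattering:
#' `F = exp(-t/lambda_e - t/lambda_i)` with mean free paths of the matrix.
#' A warning is raised if the phase shift leaves the weak-phase regime
#' (`dphi > 0.5`).
#'
#' @param feature,matrix `dlr_material` objects with mean inner potentials.
#' @param beam An electron [beam()].
#' @param t_nm,delta_nm,geometry As in [cf_xray_absorption()].
#' @return List with `C` and `F`.
#' @export
cf_tem_phase <- function(feature, matrix, beam, t_nm, delta_nm,
                         geometry = c("column", "voxel")) {
  geometry <- match.arg(geometry)
  stopifnot(beam$kind == "electron", t_nm > 0)
  .check_geometry(geometry, t_nm, delta_nm)
  if (is.null(feature$mip) || is.null(matrix$mip))
    stop("TEM phase contrast needs mean inner potentials for both materials",
         call. = FALSE)
  dphi_dz <- pi * beam$rf * (feature$mip - matrix$mip) /
    (beam$wavelength_nm * beam$energy_eV)
  z <- if (geometry == "column") t_nm else delta_nm
  dphi <- dphi_dz * z
  if (abs(dphi) > 0.5)
    warning(sprintf("weak-phase assumption questionable: |dphi| = %.2f > 0.5",
                    abs(dphi)), call. = FALSE)
  mfp <- lenz_mean_free_paths(matrix, beam$energy_eV / 1e3)
  list(C = 2 * dphi,
       F = exp(-t_nm / mfp$lambda_e_nm - t_nm / mfp$lambda_i_nm))
}

# Beer's-law scattering lengths + contrast per unit depth for BF/DF
.bf_df_parts <- function(feature, matrix, beam, beta_mrad) {
  Lf <- lenz_mean_free_paths(feature, beam$energy_eV / 1e3, beta_mrad)$L_beta_nm
  Lm <- lenz_mean_free_paths(matrix, beam$energy_eV / 1e3, beta_mrad)$L_beta_nm
  list(Lf = Lf, Lm = Lm, delta_k = 1 / Lf - 1 / Lm)
}

#' Bright-field scattering contrast and efficiency
#'
#' Beer's-law bright-field model with an objective aperture of semi-angle
#' `beta`: the fraction of electrons reaching the detector is
#' `F = exp(-t / L_m(beta))` where `L(beta)` is the Lenz-model scattering
#' length for elastic scattering beyond `beta`. The contrast per unit depth is
#' `delta_k = 1/L_f - 1/L_m`; columnar contrast `(delta_k) t`, voxel contrast
#' `(delta_k) delta`. Beyond the Beer's-law validity thickness the result is
#' flagged (`beyond_validity`), not rejected.
#'
#' @inheritParams cf_tem_phase
#' @param beta_mrad Aperture semi-angle, mrad.
#' @param zero_loss Apply zero-loss filtering (`F` multiplied by
#'   `exp(-t/lambda_i)` of the matrix).
#' @param t_max_nm Validity bound for the warning flag, nm.
#' @return List with `C`, `F`, `delta_k` and `beyond_validity`.
#' @export
cf_tem_brightfield <- function(feature, matrix, beam, t_nm, delta_nm,
                               geometry = c("column", "voxel"),
                               beta_mrad = 5, zero_loss = FALSE,
                               t_max_nm = 500) {
  geometry <- match.arg(geometry)
  stopifnot(beam$kind == "electron", beta_mrad > 0, t_nm > 0)
  .check_geometry(geometry, t_nm, delta_nm)
  p <- .bf_df_parts(feature, matrix, beam, beta_mrad)
  F <- exp(-t_nm / p$Lm)
  if (zero_loss) {
    li <- lenz_mean_free_paths(matrix, beam$energy_eV / 1e3)$lambda_i_nm
    F <- F * exp(-t_nm / li)
  }
  z <- if (geometry == "column") t_nm else delta_nm
  list(C = p$delta_k * z, F = F, delta_k = p$delta_k,
       beyond_validity = t_nm > t_max_nm)
}

#' Dark-field (annular STEM) scattering contrast and efficiency
#'
#' Complementary to the bright-field Beer's-law model: an annular detector
#' collects the electrons elastically scattered beyond the inner angle `beta`,
#' `F = 1 - exp(-t / L_m(beta))` (so `F_BF + F_DF = 1`: together they account
#' for every electron under the shared single-scattering Beer's-law model).
#' Contrast per unit depth as for bright field.
#'
#' @inheritParams cf_tem_brightfield
#' @return List with `C`, `F`, `delta_k` and `beyond_validity`.
#' @export
cf_stem_darkfield <- function(feature, matrix, beam, t_nm, delta_nm,
                              geometry = c("column", "voxel"),
                              beta_mrad = 5, zero_loss = FALSE,
                              t_max_nm = 500) {
  geometry <- match.arg(geometry)
  stopifnot(beam$kind == "electron", beta_mrad > 0, t_nm > 0)
  .check_geometry(geometry, t_nm, delta_nm)
  p <- .bf_df_parts(feature, matrix, beam, beta_mrad)
  F <- 1 - exp(-t_nm / p$Lm)
  if (zero_loss) {
    li <- lenz_mean_free_paths(matrix, beam$energy_eV / 1e3)$lambda_i_nm
    F <- F * exp(-t_nm / li)
  }
  z <- if (geometry == "column") t_nm else delta_nm
  list(C = p$delta_k * z, F = F, delta_k = p$delta_k,
       beyond_validity = t_nm > t_max_nm)
}

#' Contrast and efficiency for a configured mode
#'
#' Uniform dispatcher used by [dlr_curve()]: evaluates the configured mode's
#' contrast `C` and collection efficiency `F` for a feature/matrix pair.
#'
#' @param mode A [mode_config()].
#' @param feature,matrix `dlr_material` objects.
#' @param beam A [beam()].
#' @param t_nm,delta_nm,geometry As in [cf_xray_absorption()].
#' @return List with at least `C` and `F`.
#' @export
contrast_efficiency <- function(mode, feature, matrix, beam, t_nm, delta_nm,
                                geometry = c("column", "voxel")) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(mode, "dlr_mode"))
  switch(mode$mode,
    xray_absorption = {
      mu_f <- xray_optical_constants(feature, beam$energy_eV)$mu_nm
      mu_m <- xray_optical_constants(matrix, beam$energy_eV)$mu_nm
      cf_xray_absorption(t_nm, delta_nm, mu_f, mu_m, geometry)
    },
    xray_phase = {
      of <- xray_optical_constants(feature, beam$energy_eV)
      om <- xray_optical_constants(matrix, beam$energy_eV)
      cf_xray_phase(t_nm, delta_nm, beam$wavelength_nm,
                    of$one_plus_eps1 - om$one_plus_eps1, of$mu_nm, geometry)
    },
    tem_phase = suppressWarnings(
      cf_tem_phase(feature, matrix, beam, t_nm, delta_nm, geometry)),
    tem_brightfield =
      cf_tem_brightfield(feature, matrix, beam, t_nm, delta_nm, geometry,
                         mode$beta_mrad, mode$zero_loss, mode$t_max_nm),
    stem_darkfield =
      cf_stem_darkfield(feature, matrix, beam, t_nm, delta_nm, geometry,
                        mode$beta_mrad, mode$zero_loss, mode$t_max_nm))
}

# Precompute the per-mode constants once and return a fast (t, delta,
# geometry) evaluator; used by the solvers where contrast/efficiency are
# called thousands of times inside bisection loops. Semantics identical to
# contrast_efficiency().
.cf_factory <- function(mode, feature, matrix, beam) {
  switch(mode$mode,
    xray_absorption = {
      mu_f <- xray_optical_constants(feature, beam$energy_eV)$mu_nm
      mu_m <- xray_optical_constants(matrix, beam$energy_eV)$mu_nm
      function(t, delta, geometry) {
        if (geometry == "column")
          list(C = (mu_f - mu_m) * t, F = exp(-mu_f * t))
        else
          list(C = (mu_f - mu_m) * delta,
               F = exp(-mu_m * (t - delta) - mu_f * delta))
      }
    },
    xray_phase = {
      of <- xray_optical_constants(feature, beam$energy_eV)
      om <- xray_optical_constants(matrix, beam$energy_eV)
      ck <- 2 * (2 * pi / beam$wavelength_nm) *
        (of$one_plus_eps1 - om$one_plus_eps1)
      mu_f <- of$mu_nm
      function(t, delta, geometry) {
        z <- if (geometry == "column") t else delta
        list(C = ck * z, F = exp(-mu_f * t))
      }
    },
    tem_phase = {
      if (is.null(feature$mip) || is.null(matrix$mip))
        stop("TEM phase contrast needs mean inner potentials for both ",
             "materials", call. = FALSE)
      dphi_dz <- pi * beam$rf * (feature$mip - matrix$mip) /
        (beam$wavelength_nm * beam$energy_eV)
      mfp <- lenz_mean_free_paths(matrix, beam$energy_eV / 1e3)
      decay <- 1 / mfp$lambda_e_nm + 1 / mfp$lambda_i_nm
      function(t, delta, geometry) {
        z <- if (geometry == "column") t else delta
        list(C = 2 * dphi_dz * z, F = exp(-t * decay))
      }
    },
    {
      dark <- mode$mode == "stem_darkfield"
      p <- .bf_df_parts(feature, matrix, beam, mode$beta_mrad)
      zl <- if (mode$zero_loss)
        1 / lenz_mean_free_paths(matrix, beam$energy_eV / 1e3)$lambda_i_nm
      else 0
      function(t, delta, geometry) {
        z <- if (geometry == "column") t else delta
        F <- if (dark) 1 - exp(-t / p$Lm) else exp(-t / p$Lm)
        list(C = p$delta_k * z, F = F * exp(-t * zl))
      }
    })
}

# ---- figures of merit -------------------------------------------------------

#' Information coefficient for phase-contrast imaging
#'
#' Thickness-dependent information coefficient built on the unscattered
#' fraction `T = exp(-n t (sigma_e + sigma_i))`: both elastic and inelastic
#' scattering remove electrons from the coherent image (chromatic aberration
#' disperses the rest), so the usable information decays with `T`. The
#' coefficient reported is `zeta = sigma_e / (sigma_e + sigma_i) * T` (the
#' elastic share of the interacting flux, damped by transmission); `T` itself
#' is also returned.
#'
#' @param sigma_e,sigma_i Elastic and inelastic cross sections per scatterer,
#'   nm^2 (>= 0).
#' @param t_nm Specimen thickness, nm.
#' @param n_density Scatterer number density, nm^-3.
#' @return A tibble with `T` and `zeta` (`zeta` is `NA` when both cross
#'   sections vanish).
#' @export
information_coefficient <- function(sigma_e, sigma_i, t_nm, n_density) {
  stopifnot(sigma_e >= 0, sigma_i >= 0, t_nm >= 0, n_density > 0)
  tot <- sigma_e + sigma_i
  T <- exp(-n_density * t_nm * tot)
  tibble::tibble(T = T,
                 zeta = if (tot > 0) sigma_e / tot * T else NA_real_)
}

#' Damage-limited figure of merit
#'
#' From the fixed-contrast DLR closed form, the resolution at a fixed damage
#' model improves monotonically with `|C0| sqrt(DQE F N_1/e)`; with the
#' damage model and DQE held fixed the material/mode-dependent part is
#' `zeta0 = |C0| sqrt(F / k)` where `k` is the fluence-to-dose conversion
#' factor (MGy per particle/nm^2) on the chosen dose basis. Larger `zeta0`
#' means a smaller damage-limited resolution.
#'
#' @param C0 Initial Weber contrast (sign ignored; 0 allowed).
#' @param F Collection efficiency in (0, 1].
#' @param material,beam,conv_basis Passed to [dose_per_fluence()].
#' @return `zeta0` (units: particles^(1/2) nm^-1 MGy^(-1/2)).
#' @export
figure_of_merit <- function(C0, F, material, beam, conv_basis = "computed") {
  stopifnot(F > 0, F <= 1)
  k <- dose_per_fluence(material, beam, conv_basis, quiet = TRUE)
  abs(C0) * sqrt(F / k)
}
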