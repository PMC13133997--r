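# Damage-limited resolution under exponential contrast fading.
#
# A feature of size delta observed with collection efficiency F and fading
# contrast C = C0 exp(-N/N_1/e) yields
#   SNR(N) = |C0| exp(-N/N_1/e) delta sqrt(DQE F N),
# which is maximal at the optimum exposure N = N_1/e / 2, where
#   SNR_max = |C0| e^{-1/2} delta sqrt(DQE F N_1/e / 2).
# Setting SNR_max equal to a detection threshold (Rose criterion, default 3)
# and inverting for delta gives the damage-limited resolution. With a
# resolution-dependent characteristic fluence N_1/e(delta) the inversion is
# self-consistent: closed-form for alpha = 1 fixed contrast, bisection in
# general.

#' Signal-to-noise ratio at a given fluence
#'
#' @param N Particle fluence, particles/nm^2 (>= 0). Vectorized.
#' @param C0 Initial Weber contrast (sign ignored; may be negative).
#' @param N_1e Characteristic fluence at which contrast falls to 1/e.
#' @param delta Feature size, nm.
#' @param F Collection efficiency in (0, 1].
#' @param DQE Detective quantum efficiency in (0, 1].
#' @return SNR (dimensionless).
#' @examples
#' snr_vs_fluence(5e3, C0 = 0.1, N_1e = 1e4, delta = 3.13, F = 0.1, DQE = 0.5)
#' @export
snr_vs_fluence <- function(N, C0, N_1e, delta, F = 1, DQE = 1) {
  if (any(N < 0)) stop("`N` must be non-negative", call. = FALSE)
  stopifnot(N_1e > 0, delta > 0, F > 0, DQE > 0)
  abs(C0) * exp(-N / N_1e) * delta * sqrt(DQE * F * N)
}

#' Optimum exposure
#'
#' The fluence maximizing the SNR under exponential contrast fading:
#' `N_opt = N_1/e / 2`.
#'
#' @param N_1e Characteristic fluence (> 0). Vectorized.
#' @return Optimum fluence, same units.
#' @export
optimum_exposure <- function(N_1e) {
  if (any(N_1e <= 0)) stop("`N_1e` must be positive", call. = FALSE)
  N_1e / 2
}

# SNR at the optimum exposure
.snr_max <- function(C0, N_1e, delta, F, DQE) {
  abs(C0) * exp(-0.5) * delta * sqrt(DQE * F * N_1e / 2)
}

#' Damage-limited resolution at fixed contrast
#'
#' Closed-form inversion of the optimum-exposure SNR for the feature size at
#' which the maximal SNR equals the detection threshold, for a contrast that
#' does not itself depend on `delta`:
#' `delta = snr * e^{1/2} / (|C0| * sqrt(DQE * F * N_1e / 2))`.
#'
#' @param C0 Initial Weber contrast (sign ignored).
#' @param N_1e Characteristic fluence, particles/nm^2.
#' @param F Collection efficiency in (0, 1].
#' @param DQE Detective quantum efficiency in (0, 1].
#' @param snr Detection threshold (Rose criterion); default 3, sometimes 5.
#' @return Feature size `delta` in nm.
#' @examples
#' dlr_fixed_contrast(0.1, 1e4, F = 0.1, DQE = 0.5)  # 3.13 nm
#' @export
dlr_fixed_contrast <- function(C0, N_1e, F = 1, DQE = 1, snr = 3) {
  stopifnot(abs(C0) > 0, N_1e > 0, F > 0, DQE > 0, snr > 0)
  snr * exp(0.5) / (abs(C0) * sqrt(DQE * F * N_1e / 2))
}

# ---- self-consistent solver -------------------------------------------------

# Solve SNR_max(delta) = snr for delta by bisection on log(delta).
# C_fun(delta) -> contrast, F_fun(delta) -> efficiency, N1e_fun(delta) ->
# characteristic fluence. All must be positive on the bracket.
.solve_dlr <- function(C_fun, F_fun, N1e_fun, DQE, snr,
                       lower = 1e-3, upper = 1e5,
                       tol = 1e-6, max_iter = 200L) {
  g <- function(delta)
    .snr_max(C_fun(delta), N1e_fun(delta), delta, F_fun(delta), DQE) - snr
  glo <- g(lower); ghi <- g(upper)
  if (is.na(glo) || is.na(ghi) || glo * ghi > 0)
    stop(sprintf(
      "DLR root not bracketed in [%g, %g] nm (SNR-threshold residuals %.3g, %.3g)",
      lower, upper, glo, ghi), call. = FALSE)
  lo <- log(lower); hi <- log(upper)
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    gm <- g(exp(mid))
    if (gm * glo <= 0) hi <- mid else { lo <- mid; glo <- gm }
    if ((hi - lo) < tol || it >= max_iter) break
  }
  if (it >= max_iter && (hi - lo) >= tol)
    stop("DLR solver did not converge after ", max_iter, " iterations",
         call. = FALSE)
  delta <- exp((lo + hi) / 2)
  list(delta = delta, iterations = it, converged = (hi - lo) < tol)
}

# package a solution with its at-optimum diagnostics
.dlr_solution <- function(sol, geometry, t_nm, C_fun, F_fun, N1e_fun,
                          DQE, snr, k_dose) {
  delta <- sol$delta
  N1e <- N1e_fun(delta)
  F <- F_fun(delta)
  C0 <- C_fun(delta)
  out <- list(
    delta_nm = delta,
    geometry = geometry,
    thickness_nm = t_nm,
    contrast_C0 = C0,
    efficiency_F = F,
    N_1e = N1e,
    optimum_fluence = N1e / 2,
    optimum_dose_MGy = if (is.null(k_dose)) NA_real_ else N1e / 2 * k_dose,
    characteristic_dose_MGy = if (is.null(k_dose)) NA_real_ else N1e * k_dose,
    DQE = DQE,
    snr_threshold = snr,
    snr_at_solution = .snr_max(C0, N1e, delta, F, DQE),
    converged = sol$converged,
    iterations = sol$iterations,
    voxel_exceeds_thickness = geometry == "voxel" && delta > t_nm
  )
  if (out$voxel_exceeds_thickness)
    warning(sprintf(
      "voxel DLR (%.3g nm) exceeds the specimen thickness (%.3g nm); reported as-is",
      delta, t_nm), call. = FALSE)
  if (abs(C0) > 0.3)
    warning(sprintf(
      "weak-contrast linearization questionable: |C0| = %.2f > 0.3", abs(C0)),
      call. = FALSE)
  structure(out, class = "dlr_solution")
}

#' @export
print.dlr_solution <- function(x, ...) {
  cat(sprintf(
    "<dlr_solution> %s DLR = %.4g nm at t = %.4g nm\n", x$geometry,
    x$delta_nm, x$thickness_nm))
  cat(sprintf("  C0 = %.3g, F = %.3g, N_1/e = %.4g /nm^2, N_opt = %.4g /nm^2\n",
              x$contrast_C0, x$efficiency_F, x$N_1e, x$optimum_fluence))
  if (!is.na(x$optimum_dose_MGy))
    cat(sprintf("  optimum dose = %.4g MGy (D_1/e = %.4g MGy)\n",
                x$optimum_dose_MGy, x$characteristic_dose_MGy))
  invisible(x)
}

#' Tidy a DLR solution
#'
#' @param x A `dlr_solution`.
#' @param ... Unused.
#' @return One-row tibble with the solution and its at-optimum quantities.
#' @export
tidy.dlr_solution <- function(x, ...) {
  tibble::tibble(
    geometry = x$geometry,
    thickness_nm = x$thickness_nm,
    delta_nm = x$delta_nm,
    contrast_C0 = x$contrast_C0,
    efficiency_F = x$efficiency_F,
    N_1e_per_nm2 = x$N_1e,
    optimum_fluence_per_nm2 = x$optimum_fluence,
    optimum_dose_MGy = x$optimum_dose_MGy)
}

#' Solver diagnostics for a DLR solution
#'
#' @param x A `dlr_solution`.
#' @param ... Unused.
#' @return One-row tibble with convergence information.
#' @export
glance.dlr_solution <- function(x, ...) {
  tibble::tibble(
    converged = x$converged,
    iterations = x$iterations,
    snr_at_solution = x$snr_at_solution,
    snr_threshold = x$snr_threshold,
    voxel_exceeds_thickness = x$voxel_exceeds_thickness)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# resolve the N_1/e(delta) function and MGy-per-fluence factor
.n1e_fun <- function(damage, material, beam, dose_basis, conv_basis) {
  stopifnot(inherits(damage, "damage_model"))
  dose_mat <- if (identical(dose_basis, "matrix")) attr(material, "matrix_alt")
              else material
  k <- dose_per_fluence(dose_mat %||% material, beam, conv_basis, quiet = TRUE)
  list(fun = function(delta) characteristic_dose(damage, delta) / k, k = k)
}

#' Column damage-limited resolution
#'
#' Solves for the smallest detectable columnar feature (a feature spanning the
#' full specimen thickness, contrast `|C0| = t * delta_k`) self-consistently
#' with the resolution-dependent characteristic fluence of the damage model.
#' With the linear damage law the solution obeys `delta_c ~ t^(-2/3)` at
#' fixed efficiency.
#'
#' @param delta_k Contrast per unit depth, nm^-1 (nonzero; sign ignored).
#' @param t_nm Specimen thickness, nm.
#' @param damage A [damage_model()].
#' @param material Material absorbing the dose (the *feature* by default; pass
#'   the matrix material to use a solvent dose basis).
#' @param beam A [beam()].
#' @param F Collection efficiency: a number or a function of `delta` (nm).
#' @param DQE Detective quantum efficiency; default 0.5.
#' @param snr Detection threshold; default 3.
#' @param conv_basis Fluence-dose conversion basis, see [dose_per_fluence()].
#' @return A `dlr_solution`.
#' @export
solve_dlr_column <- function(delta_k, t_nm, damage = damage_model(),
                             material, beam, F = 1, DQE = 0.5, snr = 3,
                             conv_basis = "computed") {
  if (delta_k == 0) stop("`delta_k` must be nonzero", call. = FALSE)
  stopifnot(t_nm > 0)
  n1e <- .n1e_fun(damage, material, beam, "feature", conv_basis)
  F_fun <- if (is.function(F)) F else function(delta) F
  C_fun <- function(delta) abs(delta_k) * t_nm
  sol <- .solve_dlr(C_fun, F_fun, n1e$fun, DQE, snr)
  .dlr_solution(sol, "column", t_nm, C_fun, F_fun, n1e$fun, DQE, snr, n1e$k)
}

#' Voxel damage-limited resolution
#'
#' Solves for the smallest detectable equiaxed feature (contrast
#' `|C0| = delta * delta_k`) self-consistently: both the contrast and the
#' characteristic fluence grow with `delta`. With the linear damage law the
#' solution scales as the inverse fifth root of the reference dose and as
#' `|delta_k|^(-2/5)`; at fixed fluence (`alpha = 0`) it follows the
#' quarter-power law. If the solution exceeds the specimen thickness a warning
#' is raised and the value reported as-is.
#'
#' @inheritParams solve_dlr_column
#' @param F Collection efficiency: a number or a function of `delta` (nm),
#'   re-evaluated inside the solve when the efficiency depends on the feature
#'   size.
#' @return A `dlr_solution`.
#' @export
solve_dlr_voxel <- function(delta_k, t_nm, damage = damage_model(),
                            material, beam, F = 1, DQE = 0.5, snr = 3,
                            conv_basis = "computed") {
  if (delta_k == 0) stop("`delta_k` must be nonzero", call. = FALSE)
  stopifnot(t_nm > 0)
  n1e <- .n1e_fun(damage, material, beam, "feature", conv_basis)
  F_fun <- if (is.function(F)) F else function(delta) F
  C_fun <- function(delta) abs(delta_k) * delta
  sol <- .solve_dlr(C_fun, F_fun, n1e$fun, DQE, snr)
  .dlr_solution(sol, "voxel", t_nm, C_fun, F_fun, n1e$fun, DQE, snr, n1e$k)
}

#' DLR versus thickness for an imaging mode
#'
#' Evaluates the column and voxel damage-limited resolution over a thickness
#' grid for a configured imaging mode and feature/matrix material pair, with
#' per-mode contrast and collection efficiency supplied by
#' [contrast_efficiency()].
#'
#' @param mode A [mode_config()].
#' @param feature,matrix `dlr_material` objects for the feature and its
#'   surroundings.
#' @param beam A [beam()].
#' @param thicknesses Positive, sorted thickness grid, nm.
#' @param damage A [damage_model()].
#' @param dose_basis `"feature"` (default) or `"matrix"`: which material is
#'   assumed to absorb the characteristic dose.
#' @param conv_basis See [dose_per_fluence()].
#' @return A tibble of class `dlr_curve` with one row per thickness:
#'   `t_nm`, `delta_c_nm`, `delta_v_nm`, `F_column`, `F_voxel`,
#'   `dose_column_MGy`, `dose_voxel_MGy` (optimum doses), plus fluences.
#' @examples
#' \donttest{
#' dlr_curve(mode_config("xray_absorption"), dlr_materials("protein"),
#'           dlr_materials("ice"), beam("xray", 500),
#'           thicknesses = 10^seq(1, 3, length.out = 9))
#' }
#' @export
dlr_curve <- function(mode, feature, matrix, beam,
                      thicknesses, damage = damage_model(),
                      dose_basis = c("feature", "matrix"),
                      conv_basis = "computed") {
  dose_basis <- match.arg(dose_basis)
  stopifnot(inherits(mode, "dlr_mode"))
  if (length(thicknesses) == 0) {
    out <- tibble::tibble(t_nm = numeric(0), delta_c_nm = numeric(0),
                          delta_v_nm = numeric(0), F_column = numeric(0),
                          F_voxel = numeric(0),
                          fluence_column_per_nm2 = numeric(0),
                          fluence_voxel_per_nm2 = numeric(0),
                          dose_column_MGy = numeric(0),
                          dose_voxel_MGy = numeric(0))
    return(structure(out, class = c("dlr_curve", class(out))))
  }
  if (any(thicknesses <= 0) || is.unsorted(thicknesses))
    stop("`thicknesses` must be positive and sorted", call. = FALSE)
  dose_mat <- if (dose_basis == "feature") feature else matrix
  n1e <- .n1e_fun(damage, dose_mat, beam, "feature", conv_basis)
  cf <- .cf_factory(mode, feature, matrix, beam)
  rows <- purrr::map_dfr(thicknesses, function(t_nm) {
    col_cf <- function(delta) cf(t_nm, delta, "column")
    vox_cf <- function(delta) cf(t_nm, min(delta, t_nm), "voxel")
    solve_one <- function(cf, geometry) {
      C_fun <- function(delta) abs(cf(delta)$C)
      F_fun <- function(delta) cf(delta)$F
      sol <- .solve_dlr(C_fun, F_fun, n1e$fun, mode$DQE, mode$snr_threshold)
      suppressWarnings(
        .dlr_solution(sol, geometry, t_nm, C_fun, F_fun, n1e$fun,
                      mode$DQE, mode$snr_threshold, n1e$k))
    }
    sc <- solve_one(col_cf, "column")
    sv <- solve_one(vox_cf, "voxel")
    tibble::tibble(
      t_nm = t_nm,
      delta_c_nm = sc$delta_nm, delta_v_nm = sv$delta_nm,
      F_column = sc$efficiency_F, F_voxel = sv$efficiency_F,
      fluence_column_per_nm2 = sc$optimum_fluence,
      fluence_voxel_per_nm2 = sv$optimum_fluence,
      dose_column_MGy = sc$optimum_dose_MGy,
      dose_voxel_MGy = sv$optimum_dose_MGy)
  })
  structure(rows, class = c("dlr_curve", class(rows)),
            mode = mode$mode, beam_energy_eV = beam$energy_eV,
            feature = feature$name, matrix = matrix$name)
}
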