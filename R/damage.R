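# Resolution-dependent radiation-damage model.
#
# Diffraction-fading measurements show the critical exposure grows with the
# length scale d of the recorded information: outer (high-resolution) spots
# fade first. The characteristic dose is modelled as a power law
#   D_1/e(d) = D_ref * (d / d0)^alpha
# anchored at a reference resolution d0. The default (d0 = 1 nm,
# D_ref = 100 MGy, alpha = 1) is the linear cryo calibration D = 100 d MGy.
# A piecewise-alpha variant supports the steeper sub-0.5 nm regime
# (alpha ~ 1.7-2) while staying continuous across segment boundaries.

#' Resolution-dependent characteristic-dose model
#'
#' Defines `D_1/e(d) = D_ref * (d/d0)^alpha` in MGy for a resolution `d` in
#' nm. `alpha` may be a single exponent or a vector of per-segment exponents
#' accompanied by `breaks` (interior segment boundaries, nm, increasing);
#' piecewise models are continuous by construction, anchored at
#' `D_1/e(d0) = D_ref`.
#'
#' @param d0_nm Reference resolution, nm (> 0).
#' @param D_ref_MGy Characteristic dose at `d0_nm`, MGy (> 0).
#' @param alpha Exponent(s), each in `[0, 2]`. `alpha = 0` describes
#'   resolution-independent damage.
#' @param breaks Interior segment boundaries (length `length(alpha) - 1`).
#' @return A `damage_model` object.
#' @examples
#' damage_model()                   # D = 100 d MGy
#' damage_model(alpha = c(1.86, 1), breaks = 0.5)  # steep below 0.5 nm
#' @export
damage_model <- function(d0_nm = 1, D_ref_MGy = 100, alpha = 1, breaks = NULL) {
  stopifnot(d0_nm > 0, D_ref_MGy > 0)
  if (any(alpha < 0 | alpha > 2))
    stop("`alpha` must lie in [0, 2]", call. = FALSE)
  if (length(alpha) > 1) {
    if (is.null(breaks) || length(breaks) != length(alpha) - 1)
      stop("piecewise models need `breaks` of length length(alpha) - 1",
           call. = FALSE)
    if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0))
      stop("`breaks` must be positive and strictly increasing", call. = FALSE)
  } else breaks <- numeric(0)
  structure(list(d0_nm = d0_nm, D_ref_MGy = D_ref_MGy,
                 alpha = alpha, breaks = breaks),
            class = "damage_model")
}

#' @export
print.damage_model <- function(x, ...) {
  if (length(x$alpha) == 1) {
    cat(sprintf("<damage_model> D_1/e(d) = %g MGy * (d / %g nm)^%g\n",
                x$D_ref_MGy, x$d0_nm, x$alpha))
  } else {
    cat("<damage_model> piecewise, anchored at D_1/e(", x$d0_nm, " nm) = ",
        x$D_ref_MGy, " MGy\n", sep = "")
    lo <- c(0, x$breaks); hi <- c(x$breaks, Inf)
    for (i in seq_along(x$alpha))
      cat(sprintf("  d in (%g, %g] nm: alpha = %g\n", lo[i], hi[i], x$alpha[i]))
  }
  invisible(x)
}

#' Characteristic (critical) dose at a resolution
#'
#' @param model A [damage_model()].
#' @param d_nm Resolution / feature size, nm (> 0). Vectorized.
#' @return `D_1/e` in MGy.
#' @examples
#' characteristic_dose(damage_model(), 0.2)  # 20 MGy
#' @export
characteristic_dose <- function(model, d_nm) {
  stopifnot(inherits(model, "damage_model"))
  if (any(d_nm <= 0)) stop("`d_nm` must be positive", call. = FALSE)
  if (length(model$alpha) == 1)
    return(model$D_ref_MGy * (d_nm / model$d0_nm)^model$alpha)
  # piecewise: integrate the log-log slope from d0 to d, segment by segment
  edges <- c(0, model$breaks, Inf)
  seg_of <- function(d) findInterval(d, edges, left.open = TRUE)
  vapply(d_nm, function(d) {
    lo <- min(d, model$d0_nm); hi <- max(d, model$d0_nm)
    # boundaries crossed between lo and hi
    cuts <- c(lo, model$breaks[model$breaks > lo & model$breaks < hi], hi)
    logstep <- 0
    for (i in seq_len(length(cuts) - 1)) {
      a <- model$alpha[seg_of(sqrt(cuts[i] * cuts[i + 1]))]
      logstep <- logstep + a * (log(cuts[i + 1]) - log(cuts[i]))
    }
    if (d < model$d0_nm) logstep <- -logstep
    model$D_ref_MGy * exp(logstep)
  }, numeric(1))
}

#' Characteristic (critical) fluence at a resolution
#'
#' Converts [characteristic_dose()] to a particle fluence for a given
#' material/beam on the chosen dose basis.
#'
#' @inheritParams characteristic_dose
#' @param material,beam,basis Passed to [dose_per_fluence()].
#' @return `N_1/e` in particles/nm^2.
#' @export
characteristic_fluence <- function(model, d_nm, material, beam,
                                   basis = c("computed", "table")) {
  k <- dose_per_fluence(material, beam, basis, quiet = TRUE)
  characteristic_dose(model, d_nm) / k
}

#' Convert a half-fading fluence to a 1/e fluence
#'
#' Under exponential contrast fading, the fluence at which contrast halves is
#' `ln 2` times the 1/e fluence: `N_1/e = N_1/2 / ln 2` (a factor 1.44).
#'
#' @param n_half `N_1/2`, particles/nm^2 (> 0). Vectorized.
#' @return `N_1/e`.
#' @export
ne_from_nhalf <- function(n_half) {
  if (any(n_half <= 0)) stop("`n_half` must be positive", call. = FALSE)
  n_half / log(2)
}
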