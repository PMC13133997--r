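#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a DLR curve
#'
#' Log-log plot of column (dashed) and voxel (solid) damage-limited
#' resolution versus specimen thickness.
#'
#' @param object A [dlr_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dlr_curve <- function(object, ...) {
  df <- tibble::tibble(
    t_nm = rep(object$t_nm, 2),
    delta_nm = c(object$delta_c_nm, object$delta_v_nm),
    geometry = rep(c("column", "voxel"), each = nrow(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_nm, y = .data$delta_nm,
                                   linetype = .data$geometry)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_linetype_manual(values = c(column = "dashed",
                                              voxel = "solid")) +
    ggplot2::labs(
      x = "specimen thickness t (nm)",
      y = "damage-limited resolution (nm)",
      linetype = NULL,
      title = paste0(attr(object, "mode") %||% "DLR", ", ",
                     attr(object, "feature") %||% "feature", " in ",
                     attr(object, "matrix") %||% "matrix")) +
    ggplot2::theme_minimal()
}

#' Plot a deposition profile
#'
#' Cumulative energy fraction and cumulative time versus depth for an
#' ejected photoelectron or Auger electron.
#'
#' @param object A [deposition_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.deposition_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_nm,
                                       y = .data$cum_fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (nm)", y = "cumulative energy fraction",
                  title = paste0("energy deposition, E = ",
                                 attr(object, "E_eV"), " eV")) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
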