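# ggplot2 presentation helpers.

#' Map of annual sensitivities
#'
#' @param object A [run_adjoint()] sensitivity field.
#' @param species Species subset to facet (default all).
#' @param ... Unused.
#' @return A ggplot: per-species maps of the annual mean per-ton sensitivity.
#' @export
autoplot.sensitivity_field <- function(object, species = NULL, ...) {
  df <- sens_annual(object)
  if (!is.null(species)) df <- df[df$species %in% species, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$ix, .data$iy, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~species) +
    ggplot2::scale_fill_viridis_c(name = object$units) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x cell", y = "y cell",
                  title = "Annual emission sensitivities")
}

#' Map of period-mean PM2.5
#'
#' @param object A [run_forward()] trajectory.
#' @param ... Unused.
#' @return A ggplot raster of the exposure field.
#' @export
autoplot.trajectory <- function(object, ...) {
  g <- object$grid
  df <- tibble::tibble(iy = rep(seq_len(g$ny), g$nx),
                       ix = rep(seq_len(g$nx), each = g$ny),
                       pm = as.numeric(object$pm_mean))
  ggplot2::ggplot(df, ggplot2::aes(.data$ix, .data$iy, fill = .data$pm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "ug/m3") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x cell", y = "y cell", title = "Period-mean PM2.5")
}

#' Sectoral burden bars
#'
#' @param object A [reduction_burden()] report.
#' @param ... Unused.
#' @return A ggplot of per-sector avoided deaths stacked by species.
#' @export
autoplot.burden_report <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$sector, .data$deaths, fill = .data$species)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(y = sprintf("avoided deaths (f = %g)", object$f), x = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Adjoint-vs-FDM scatter
#'
#' @param object An [adjoint_vs_fdm_report()] result.
#' @param ... Unused.
#' @return A ggplot scatter of adjoint vs central-difference sensitivities
#'   with the 1:1 line.
#' @export
autoplot.adjoint_fdm_report <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(.data$fdm, .data$adjoint)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$species), alpha = 0.8) +
    ggplot2::labs(x = "brute-force (central difference)", y = "adjoint",
                  title = sprintf("slope %.4f, R2 %.5f", object$slope, object$r_squared))
}
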