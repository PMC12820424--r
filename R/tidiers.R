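# broom-style tidiers for the package's result objects.

#' Tidy a burden report
#'
#' @param x A [reduction_burden()] report.
#' @param ... Unused.
#' @return The tidy table (region, sector, species, level, deaths, usd).
#' @export
tidy.burden_report <- function(x, ...) x$table

#' One-row summary of a burden report
#'
#' @param x A [reduction_burden()] report.
#' @param ... Unused.
#' @return Tibble with `f`, `total_deaths`, `total_usd`, top sector/region.
#' @export
glance.burden_report <- function(x, ...) {
  by_sector <- x$table |> dplyr::group_by(.data$sector) |>
    dplyr::summarise(deaths = sum(.data$deaths))
  by_region <- x$table |> dplyr::group_by(.data$region) |>
    dplyr::summarise(deaths = sum(.data$deaths))
  tibble::tibble(
    f = x$f, total_deaths = x$total_deaths, total_usd = x$total_usd,
    top_sector = by_sector$sector[which.max(by_sector$deaths)],
    top_region = by_region$region[which.max(by_region$deaths)]
  )
}

#' Tidy an adjoint-vs-FDM report
#'
#' @param x An [adjoint_vs_fdm_report()] result.
#' @param ... Unused.
#' @return The per-probe table (species, iy, ix, hour, delta, adjoint, fdm,
#'   rel_err).
#' @export
tidy.adjoint_fdm_report <- function(x, ...) x$table

#' One-row summary of an adjoint-vs-FDM report
#'
#' @param x An [adjoint_vs_fdm_report()] result.
#' @param ... Unused.
#' @return Tibble with slope, intercept, r_squared, error stats, mode.
#' @export
glance.adjoint_fdm_report <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, max_rel_err = x$max_rel_err,
                 median_rel_err = x$median_rel_err,
                 n_probes = x$n_probes, mode = x$mode)
}

#' Tidy a mortality cost object
#'
#' @param x A [gemm_mortality()] result.
#' @param ... Unused.
#' @return Per-cell tibble (iy, ix, pm, z, attributable_fraction, deaths, and
#'   usd/vsl when monetized).
#' @export
tidy.gemm_mortality <- function(x, ...) x$cells

#' One-row summary of a mortality cost object
#'
#' @param x A [gemm_mortality()] result.
#' @param ... Unused.
#' @return Tibble with total deaths, USD (if monetized), active cell count.
#' @export
glance.gemm_mortality <- function(x, ...) {
  tibble::tibble(total_deaths = x$total,
                 total_usd = if (!is.null(x$total_usd)) x$total_usd else NA_real_,
                 n_cells_above_cf = sum(x$cells$z > 0))
}

#' Tidy a sensitivity field (annual aggregate)
#'
#' @param x A [run_adjoint()] sensitivity field.
#' @param ... Passed to [sens_annual()].
#' @return Tibble (iy, ix, species, value) in the field's units.
#' @export
tidy.sensitivity_field <- function(x, ...) sens_annual(x, ...)
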