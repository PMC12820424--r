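# VSL unit-value transfer and monetization of mortality-valued quantities.

econ_cols <- c("region", "gdp_pc", "gdp_pc_ref", "cpi_change", "income_growth",
               "elasticity", "vsl_base")

#' Regional economics panel for VSL transfer
#'
#' @param panel Data frame with exactly the columns `region`, `gdp_pc`
#'   (GDP per capita of the region, base-year currency), `gdp_pc_ref`
#'   (reference-economy GDP per capita), `cpi_change` (cumulative
#'   consumer-price-index change, fraction), `income_growth` (cumulative
#'   income growth, fraction), `elasticity` (income elasticity `b`, default
#'   0.8) and `vsl_base` (base VSL in USD; required, no default).
#' @return A tibble of class `econ_panel`.
#' @export
econ_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  unknown <- setdiff(names(panel), econ_cols)
  if (length(unknown)) {
    abort(paste("unknown econ panel column(s):", paste(unknown, collapse = ", ")),
          class = "adjointpm_input_error")
  }
  miss <- setdiff(econ_cols, names(panel))
  if (length(miss)) abort(paste("econ panel missing columns:", paste(miss, collapse = ", ")),
                          class = "adjointpm_input_error")
  if (any(panel$gdp_pc <= 0 | panel$gdp_pc_ref <= 0)) {
    abort("GDP per capita must be positive", class = "adjointpm_input_error")
  }
  if (any(panel$elasticity <= 0 | panel$elasticity > 2)) {
    abort("income elasticity must lie in (0, 2]", class = "adjointpm_input_error")
  }
  if (any(panel$vsl_base <= 0)) abort("vsl_base must be positive", class = "adjointpm_input_error")
  class(panel) <- c("econ_panel", class(panel))
  panel
}

#' VSL unit-value transfer
#'
#' Transfers a base value of statistical life to each region via the
#' income-elasticity power law
#' `VSL_c = VSL_base * (Y_c / Y_ref)^b * (1 + dCPI + dY)^b`,
#' with the price and income adjustments additive inside the bracket.
#'
#' @param econ An [econ_panel()] (or data frame coercible to one).
#' @return The panel with a `vsl` column (USD per statistical life).
#' @export
vsl_transfer <- function(econ) {
  if (!inherits(econ, "econ_panel")) econ <- econ_panel(econ)
  dplyr::mutate(
    econ,
    vsl = .data$vsl_base * (.data$gdp_pc / .data$gdp_pc_ref)^.data$elasticity *
      (1 + .data$cpi_change + .data$income_growth)^.data$elasticity
  )
}

#' Map regional VSLs onto grid cells
#'
#' @param mask A [region_mask()].
#' @param econ Output of [vsl_transfer()] (must have `region` and `vsl`).
#' @return Numeric vector of length `n_cells` (USD/death), receptor-side.
#' @export
vsl_map <- function(mask, econ) {
  if (!"vsl" %in% names(econ)) econ <- vsl_transfer(econ)
  idx <- match(mask$region_of_cell, econ$region)
  if (anyNA(idx)) {
    abort(paste("cells mapped to region(s) missing from the econ panel:",
                paste(unique(mask$region_of_cell[is.na(idx)]), collapse = ", ")),
          class = "adjointpm_config_error")
  }
  econ$vsl[idx]
}

#' Monetize a mortality-valued object
#'
#' Multiplies each cell's death-valued quantity by its receptor-side VSL.
#' Works on a [gemm_mortality()] cost or a [gemm_forcing()] object. A
#' sensitivity field cannot be monetized after the fact: the VSL weighting
#' belongs in the forcing before the adjoint run (receptor-side weighting does
#' not commute with backward transport), so monetized sensitivities come from
#' a second adjoint run with USD-valued forcing.
#'
#' @param x Object to monetize.
#' @param vsl Per-cell VSL vector from [vsl_map()].
#' @return The USD-valued twin of `x`.
#' @export
monetize <- function(x, vsl) UseMethod("monetize")

#' @export
monetize.gemm_mortality <- function(x, vsl) {
  if (length(vsl) != nrow(x$cells)) abort("vsl must map every cell", class = "adjointpm_config_error")
  x$cells$vsl <- vsl
  x$cells$usd <- x$cells$deaths * vsl
  x$total_usd <- sum(x$cells$usd)
  x
}

#' @export
monetize.adjoint_forcing <- function(x, vsl) {
  if (x$units == "usd") abort("forcing is already monetized", class = "adjointpm_input_error")
  if (length(vsl) != length(x$phi_cell)) abort("vsl must map every cell", class = "adjointpm_config_error")
  x$phi_cell <- x$phi_cell * vsl
  x$per_hour <- x$per_hour * vsl
  x$units <- "usd"
  x
}

#' @export
monetize.sensitivity_field <- function(x, vsl) {
  abort(paste("sensitivities cannot be monetized after the adjoint run:",
              "apply the VSL in the forcing (gemm_forcing(..., vsl = )) and rerun the adjoint"),
        class = "adjointpm_input_error")
}

#' Reporting-unit views of a sensitivity field
#'
#' Internal sensitivities are deaths/ton (or USD/ton). Reporting uses
#' deaths/kton for mortality sensitivities; USD/ton is unchanged.
#'
#' @param sens A [run_adjoint()] sensitivity field.
#' @return The field with values and units converted (deaths_per_kton).
#' @export
to_reporting_units <- function(sens) {
  if (sens$units == "deaths_per_ton") {
    sens$sens <- sens$sens * 1000
    sens$units <- "deaths_per_kton"
  } else if (sens$units == "deaths_per_kton") {
    sens$sens <- sens$sens / 1000
    sens$units <- "deaths_per_ton"
  }
  sens
}
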