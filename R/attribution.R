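# Reporting layer: turn sensitivity fields plus emission inventories into
# regional fractional-reduction burdens, sectoral contributions and shares,
# seasonal summaries, and the negative-sensitivity census.

# sum_h sens[cell, sp, h] * E[sector, sp, cell, h] per sector, via the
# factored inventory profiles
burden_by_sector <- function(sens, inv, hours) {
  nc <- dim(sens$sens)[1]; nsp <- dim(sens$sens)[2]
  sens_flat <- matrix(sens$sens[, , hours, drop = FALSE], nc * nsp, length(hours))
  out <- array(0, c(nc, nsp, length(inv$sectors)),
               dimnames = list(NULL, colnames(sens$sens), inv$sectors))
  for (s in inv$sectors) {
    W <- as.numeric(sens_flat %*% inv$prof[s, hours])   # sum_h sens * profile
    out[, , s] <- matrix(W * inv$base_flat[, match(s, inv$sectors)], nc, nsp)
  }
  out
}

#' Burden of a fractional emission reduction
#'
#' First-order estimate of the avoided burden when every source's emissions
#' are reduced by fraction `f`:
#' `burden[region, sector, species, level] = f * sum_{cells, hours} sens * E`,
#' attributed to the *source* cell's region (where the reduction happens).
#' Deaths and USD variants come from the respective sensitivity fields (the
#' USD field from a monetized-forcing adjoint run).
#'
#' @param sens Deaths-valued [run_adjoint()] sensitivity field.
#' @param inv The [emission_inventory()] the sensitivities multiply.
#' @param mask A [region_mask()].
#' @param f Reduction fraction in (0, 1]; defaults to 0.10.
#' @param sens_usd Optional USD-valued sensitivity field for the monetized
#'   column.
#' @param include_spinup Include spin-up-flagged hours in the integral
#'   (default `TRUE`: emissions during spin-up still influence the exposure
#'   window, so they are bona fide parts of the gradient).
#' @return A `burden_report`: tidy tibble (region, sector, species, level,
#'   deaths, usd) with the fraction and totals attached.
#' @export
reduction_burden <- function(sens, inv, mask, f = 0.1, sens_usd = NULL,
                             include_spinup = TRUE) {
  if (f < 0 || f > 1) abort("f must lie in [0, 1]", class = "adjointpm_input_error")
  if (dim(sens$sens)[1] != inv$n_cells || dim(sens$sens)[3] != inv$n_hours) {
    abort("sensitivity field and inventory are misaligned", class = "adjointpm_input_error")
  }
  hours <- if (include_spinup) seq_len(dim(sens$sens)[3]) else effective_hours(sens)
  bd <- f * burden_by_sector(sens, inv, hours)
  bu <- if (!is.null(sens_usd)) f * burden_by_sector(sens_usd, inv, hours)
  reg <- mask$region_of_cell
  rows <- purrr::map_dfr(inv$sectors, function(s) {
    purrr::map_dfr(colnames(bd), function(sp) {
      d <- tapply(bd[, sp, s], reg, sum)
      r <- tibble::tibble(region = names(d), sector = s, species = sp,
                          level = unname(inv$level[s]), deaths = as.numeric(d))
      if (!is.null(bu)) r$usd <- as.numeric(tapply(bu[, sp, s], reg, sum))
      r
    })
  })
  structure(list(table = rows, f = f,
                 total_deaths = sum(rows$deaths),
                 total_usd = if (!is.null(bu)) sum(rows$usd) else NA_real_),
            class = "burden_report")
}

#' @exportS3Method base::print
print.burden_report <- function(x, ...) {
  cat(sprintf("<burden_report> f = %g: %.4g avoided deaths%s across %d regions, %d sectors\n",
              x$f, x$total_deaths,
              if (!is.na(x$total_usd)) sprintf(", %.4g USD", x$total_usd) else "",
              length(unique(x$table$region)), length(unique(x$table$sector))))
  invisible(x)
}

#' Sectoral contributions and fractional shares
#'
#' Sector burdens are additive (sensitivities are marginal), so shares over
#' all sectors — the anthropogenic categories plus the natural residual — sum
#' to one.
#'
#' @param report A [reduction_burden()] report.
#' @return Tibble (sector, level, deaths, usd, share) sorted by share.
#' @export
sector_contribution <- function(report) {
  tb <- report$table
  if (!nrow(tb)) abort("empty burden report", class = "adjointpm_input_error")
  out <- tb |>
    dplyr::group_by(.data$sector, .data$level) |>
    dplyr::summarise(deaths = sum(.data$deaths),
                     usd = if ("usd" %in% names(tb)) sum(.data$usd) else NA_real_,
                     .groups = "drop") |>
    dplyr::mutate(share = .data$deaths / sum(.data$deaths)) |>
    dplyr::arrange(dplyr::desc(.data$share))
  out
}

#' Regional roll-up in a species-by-region layout
#'
#' @param report A [reduction_burden()] report.
#' @return Tibble: one row per region x level, one column per species (deaths),
#'   plus a total column.
#' @export
region_summary <- function(report) {
  report$table |>
    dplyr::group_by(.data$region, .data$level, .data$species) |>
    dplyr::summarise(deaths = sum(.data$deaths), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "species", values_from = "deaths",
                       values_fill = 0) |>
    dplyr::mutate(total = rowSums(dplyr::across(dplyr::where(is.numeric))))
}

#' Seasonal summaries of a sensitivity field
#'
#' Partitions the non-spin-up hours into meteorological seasons and reports
#' the per-season mean-per-ton sensitivity aggregated over cells (max and
#' mean), in reporting units (deaths/kton for mortality fields).
#'
#' @param sens A [run_adjoint()] sensitivity field.
#' @param species Species subset (default all).
#' @return Tibble (season, species, n_hours, max, mean, units).
#' @export
seasonal_summary <- function(sens, species = colnames(sens$sens)) {
  N <- dim(sens$sens)[3]
  seas <- season_of_hour(N)
  hours_ok <- effective_hours(sens)
  scale <- if (sens$units == "deaths_per_ton") 1000 else 1
  units <- if (sens$units == "deaths_per_ton") "deaths_per_kton" else sens$units
  purrr::map_dfr(c("DJF", "MAM", "JJA", "SON"), function(se) {
    hs <- intersect(which(seas == se), hours_ok)
    if (!length(hs)) return(NULL)
    purrr::map_dfr(species, function(sp) {
      v <- apply(sens$sens[, sp, hs, drop = FALSE], 1, mean) * scale
      tibble::tibble(season = se, species = sp, n_hours = length(hs),
                     max = max(v), mean = mean(v), units = units)
    })
  })
}

#' Census of negative annual sensitivities
#'
#' Identifies cells whose aggregate (non-spin-up) sensitivity is negative for
#' each species — expected empty in linear chemistry, possibly non-empty for
#' NOx under the titration regime.
#'
#' @param sens A [run_adjoint()] sensitivity field.
#' @return Tibble (species, n_negative, min_value) with a `cells` attribute
#'   listing the negative cells (iy, ix, species, value).
#' @export
negative_sensitivity_census <- function(sens) {
  hours <- effective_hours(sens)
  agg <- apply(sens$sens[, , hours, drop = FALSE], c(1, 2), sum)
  grid <- sens$grid
  neg <- which(agg < 0, arr.ind = TRUE)
  cells <- tibble::tibble(
    iy = ((neg[, 1] - 1) %% grid$ny) + 1,
    ix = ((neg[, 1] - 1) %/% grid$ny) + 1,
    species = colnames(agg)[neg[, 2]],
    value = agg[neg]
  )
  out <- purrr::map_dfr(colnames(agg), function(sp) {
    tibble::tibble(species = sp,
                   n_negative = sum(agg[, sp] < 0),
                   min_value = min(agg[, sp]))
  })
  attr(out, "cells") <- cells
  out
}

#' Linear (exposure-weighted) cost function
#'
#' `J_lin = sum_i w_i * PM_mean_i`: the linearized cost used for exactness
#' checks of the adjoint and the first-order burden identity.
#'
#' @param trajectory A [run_forward()] trajectory.
#' @param weights Per-cell weights (cost per ug/m3).
#' @return Scalar cost.
#' @export
linear_cost <- function(trajectory, weights) {
  sum(as.numeric(trajectory$pm_mean) * weights)
}

#' Forcing of the linear cost
#'
#' @param weights Per-cell weights (cost per ug/m3 of period-mean PM2.5).
#' @param trajectory Trajectory defining the exposure window.
#' @return An `adjoint_forcing` driving [run_adjoint()].
#' @export
linear_forcing <- function(weights, trajectory) {
  structure(list(
    phi_cell = weights,
    per_hour = weights / trajectory$n_eff,
    hours = (trajectory$spinup_hours + 1):(trajectory$spinup_hours + trajectory$n_eff),
    n_eff = trajectory$n_eff,
    units = "deaths"
  ), class = "adjoint_forcing")
}
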