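# GEMM concentration-response: hazard transform, mortality cost function, and
# its analytic derivative with respect to concentrations (the adjoint forcing).

#' GEMM concentration-response parameters
#'
#' The GEMM hazard for chronic PM2.5 exposure is
#' `HR(z) = exp(theta * T(z))` with `T(z) = log(1 + z/alpha) * omega(z)`,
#' `omega(z) = 1 / (1 + exp(-(z - mu)/nu))`, and
#' `z = max(0, PM2.5 - cf)`. Defaults are the published NCD+LRI coefficients
#' for adults 25+.
#'
#' @param theta Log-hazard slope.
#' @param alpha Curvature parameter (ug/m3).
#' @param mu Logistic-weight centre (ug/m3).
#' @param nu Logistic-weight width (ug/m3).
#' @param cf Counterfactual concentration (ug/m3) below which no excess
#'   mortality is attributed.
#' @return A `gemm_params` object.
#' @export
gemm_params <- function(theta = 0.1231, alpha = 1.5, mu = 10.4, nu = 25.9, cf = 2.4) {
  if (alpha <= 0 || nu <= 0) abort("alpha and nu must be > 0", class = "adjointpm_config_error")
  if (cf < 0) abort("cf must be >= 0", class = "adjointpm_config_error")
  structure(list(theta = theta, alpha = alpha, mu = mu, nu = nu, cf = cf),
            class = "gemm_params")
}

#' Logistic weight omega(z)
#'
#' @param z Exposure above the counterfactual (ug/m3), `z >= 0`.
#' @param params A [gemm_params()].
#' @return Weights in (0, 1).
#' @export
gemm_omega <- function(z, params = gemm_params()) {
  1 / (1 + exp(-(z - params$mu) / params$nu))
}

#' GEMM hazard transform T(z)
#'
#' `T(z) = log(1 + z/alpha) * omega(z)`; the hazard ratio is
#' `exp(theta * T(z))`.
#'
#' @inheritParams gemm_omega
#' @return Unitless transform values, `T(0) = 0`.
#' @export
gemm_hazard <- function(z, params = gemm_params()) {
  log1p(z / params$alpha) * gemm_omega(z, params)
}

# dT/dz, used by the analytic forcing
gemm_hazard_deriv <- function(z, params = gemm_params()) {
  w <- gemm_omega(z, params)
  w / (params$alpha + z) + log1p(z / params$alpha) * w * (1 - w) / params$nu
}

#' Exposure panel (population and baseline mortality)
#'
#' @param panel Data frame with columns `iy`, `ix`, `population` (adults 25+,
#'   persons) and `bmr` (baseline mortality rate from the modelled endpoints,
#'   deaths/person/year).
#' @param grid A [grid_spec()]; every grid cell must appear exactly once.
#' @return A tibble of class `exposure_panel`.
#' @export
exposure_panel <- function(panel, grid) {
  panel <- tibble::as_tibble(panel)
  req <- c("iy", "ix", "population", "bmr")
  miss <- setdiff(req, names(panel))
  if (length(miss)) abort(paste("exposure panel missing columns:", paste(miss, collapse = ", ")),
                          class = "adjointpm_input_error")
  if (any(panel$population < 0)) abort("population must be >= 0", class = "adjointpm_input_error")
  if (any(panel$bmr < 0 | panel$bmr > 1)) abort("bmr must lie in [0, 1]", class = "adjointpm_input_error")
  if (nrow(panel) != grid$n_cells ||
      anyDuplicated(cell_index(panel$iy, panel$ix, grid))) {
    abort("exposure panel must cover every grid cell exactly once",
          class = "adjointpm_input_error")
  }
  panel <- panel[order(cell_index(panel$iy, panel$ix, grid)), ]
  class(panel) <- c("exposure_panel", class(panel))
  panel
}

#' GEMM mortality cost function
#'
#' `J = sum_i M0_i * P_i * (1 - exp(-theta * T(z_i)))` with
#' `z_i = max(0, PM_i - cf)`: the annual excess deaths attributable to PM2.5
#' above the counterfactual, given each cell's population and baseline
#' mortality rate.
#'
#' @param pm `ny x nx` matrix of period-mean PM2.5 (ug/m3), or a
#'   [run_forward()] trajectory (its `pm_mean` is used).
#' @param panel An [exposure_panel()].
#' @param params A [gemm_params()].
#' @return A `gemm_mortality` object: `total` deaths plus a per-cell tibble.
#' @export
gemm_mortality <- function(pm, panel, params = gemm_params()) {
  if (inherits(pm, "trajectory")) pm <- pm$pm_mean
  pm_vec <- as.numeric(pm)
  if (length(pm_vec) != nrow(panel)) abort("pm and panel shapes differ", class = "adjointpm_input_error")
  z <- pmax(0, pm_vec - params$cf)
  af <- 1 - exp(-params$theta * gemm_hazard(z, params))  # attributable fraction
  deaths <- panel$bmr * panel$population * af
  structure(list(
    total = sum(deaths),
    cells = tibble::tibble(iy = panel$iy, ix = panel$ix, pm = pm_vec, z = z,
                           attributable_fraction = af, deaths = deaths),
    params = params
  ), class = "gemm_mortality")
}

#' @exportS3Method base::print
print.gemm_mortality <- function(x, ...) {
  cat(sprintf("<gemm_mortality> J = %.4g excess deaths over %d cells (%d above counterfactual)\n",
              x$total, nrow(x$cells), sum(x$cells$z > 0)))
  invisible(x)
}

#' Adjoint forcing: derivative of the mortality cost w.r.t. concentrations
#'
#' The analytic gradient of [gemm_mortality()] with respect to the period-mean
#' PM2.5 in each cell:
#' `dJ/dPM_i = M0_i * P_i * theta * exp(-theta*T(z_i)) * T'(z_i)` for
#' `PM_i > cf`, zero otherwise, with
#' `T'(z) = omega/(alpha+z) + log(1+z/alpha) * omega * (1-omega) / nu`.
#' Because the exposure metric is a uniform mean over `n_eff` non-spin-up
#' hours, the per-hour forcing is `dJ/dPM_i / n_eff`, applied identically to
#' every particulate species (a microgram of PM2.5 is a microgram regardless
#' of composition).
#'
#' @inheritParams gemm_mortality
#' @param n_eff Number of non-spin-up hours in the exposure mean; taken from
#'   the trajectory when `pm` is one.
#' @param hours Integer vector of forced hours; defaults to the non-spin-up
#'   hours of the trajectory (or `1:n_eff`).
#' @param vsl Optional per-cell VSL vector (USD/death); when given the forcing
#'   is monetized receptor-side, so a subsequent adjoint run yields USD-valued
#'   sensitivities.
#' @return An `adjoint_forcing` object.
#' @export
gemm_forcing <- function(pm, panel, params = gemm_params(), n_eff = NULL,
                         hours = NULL, vsl = NULL) {
  if (inherits(pm, "trajectory")) {
    if (is.null(n_eff)) n_eff <- pm$n_eff
    if (is.null(hours)) hours <- (pm$spinup_hours + 1):(pm$spinup_hours + pm$n_eff)
    pm <- pm$pm_mean
  }
  if (is.null(n_eff) || n_eff <= 0) abort("n_eff must be a positive hour count",
                                          class = "adjointpm_input_error")
  if (is.null(hours)) hours <- seq_len(n_eff)
  pm_vec <- as.numeric(pm)
  z <- pmax(0, pm_vec - params$cf)
  dJdPM <- ifelse(z > 0,
                  panel$bmr * panel$population * params$theta *
                    exp(-params$theta * gemm_hazard(z, params)) *
                    gemm_hazard_deriv(z, params),
                  0)
  units <- "deaths"
  if (!is.null(vsl)) {
    if (length(vsl) != length(dJdPM)) abort("vsl must map every cell", class = "adjointpm_config_error")
    dJdPM <- dJdPM * vsl
    units <- "usd"
  }
  structure(list(
    phi_cell = dJdPM,             # d(cost)/d(period-mean PM) per cell
    per_hour = dJdPM / n_eff,     # forcing injected at each forced hour
    hours = as.integer(hours),
    n_eff = as.integer(n_eff),
    units = units
  ), class = "adjoint_forcing")
}

#' @exportS3Method base::print
print.adjoint_forcing <- function(x, ...) {
  cat(sprintf("<adjoint_forcing> %s-valued, %d forced hours, %d active cells, total dJ/dPM = %.4g\n",
              x$units, length(x$hours), sum(x$phi_cell > 0), sum(x$phi_cell)))
  invisible(x)
}
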