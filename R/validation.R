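# Brute-force finite-difference verification of the adjoint gradients.

#' Brute-force (finite-difference) sensitivity
#'
#' Central-difference sensitivity of the true (non-linearized) cost to an
#' emission perturbation at one (species, cell, hour):
#' `(J(E + d) - J(E - d)) / (2 * d_tons)` from two full forward runs.
#'
#' @param model A [ctm_model()].
#' @param emissions Emission container for the baseline.
#' @param panel An [exposure_panel()] (GEMM cost) — or `NULL` with `weights`
#'   for the linear cost.
#' @param probe `list(species=, iy=, ix=, hour=, delta=)`, `delta` in tons/hr
#'   over one hour (so `delta` tons).
#' @param params [gemm_params()] for the GEMM cost.
#' @param spinup_hours Spin-up excluded from the exposure mean.
#' @param weights Per-cell weights selecting the linear cost instead of GEMM.
#' @param vsl Optional per-cell VSL: monetizes the GEMM cost (USD/ton result).
#' @return Scalar sensitivity (deaths/ton or USD/ton).
#' @export
fdm_sensitivity <- function(model, emissions, panel, probe,
                            params = gemm_params(), spinup_hours = 0,
                            weights = NULL, vsl = NULL) {
  if (probe$delta <= 0) abort("probe delta must be > 0", class = "adjointpm_input_error")
  grid <- model$grid
  if (probe$iy < 1 || probe$iy > grid$ny || probe$ix < 1 || probe$ix > grid$nx ||
      probe$hour < 1 || probe$hour > grid$n_hours) {
    abort("probe outside grid/time bounds", class = "adjointpm_input_error")
  }
  evalJ <- function(sign) {
    p <- probe; p$dtons <- sign * probe$delta
    traj <- run_forward(model, emissions, spinup_hours = spinup_hours,
                        perturb = p, store = FALSE)
    if (!is.null(weights)) {
      linear_cost(traj, weights)
    } else {
      J <- gemm_mortality(traj, panel, params)
      if (!is.null(vsl)) sum(J$cells$deaths * vsl) else J$total
    }
  }
  # run minus first so a +delta NaN and a -delta negative-emission clip both surface
  Jm <- evalJ(-1); Jp <- evalJ(1)
  diffJ <- Jp - Jm
  if (abs(diffJ) < 64 * .Machine$double.eps * max(abs(Jp), abs(Jm))) {
    warn(sprintf("FDM difference %.3g is at round-off level (J ~ %.3g); increase delta",
                 diffJ, Jp))
  }
  diffJ / (2 * probe$delta)
}

#' Adjoint-versus-brute-force verification report
#'
#' Samples probes over (cell, hour, emitted species), weighted toward
#' locations of non-negligible adjoint sensitivity, computes paired adjoint
#' and central-difference values, and summarises agreement with an OLS fit
#' (adjoint ~ FDM) and relative-error statistics. In titration mode the
#' perturbation is chosen adaptively from a decreasing ladder, keeping the
#' smallest delta whose estimate has converged.
#'
#' @param world A [make_world()] world.
#' @param n_probes Number of probes (>= 2).
#' @param seed Seed for probe sampling.
#' @param delta_rel Perturbation as a fraction of the local emission rate.
#' @param delta_floor Absolute floor (tons/hr) when the local emission is zero.
#' @param delta_ladder Relative delta ladder used in titration mode.
#' @return An `adjoint_fdm_report` with the probe table, OLS `slope`,
#'   `intercept`, `r_squared`, and error summaries.
#' @export
adjoint_vs_fdm_report <- function(world, n_probes = 50, seed = 1,
                                  delta_rel = 0.01, delta_floor = 0.5,
                                  delta_ladder = c(1e-1, 1e-2, 1e-3)) {
  if (n_probes < 2) abort("n_probes must be >= 2", class = "adjointpm_input_error")
  model <- world_model(world)
  spin <- world$config$spinup_hours
  traj <- run_forward(model, world$emissions, spinup_hours = spin,
                      store = model$chem$mode == "titration")
  forcing <- gemm_forcing(traj, world$panel)
  sens <- run_adjoint(model, forcing, traj)
  emitted <- c(model$species$primary, model$species$gases)
  sub <- sens$sens[, emitted, , drop = FALSE]
  if (all(sub == 0)) abort("all sensitivities are zero: degenerate verification (no forcing?)",
                           class = "adjointpm_input_error")
  w <- abs(as.numeric(sub))
  w <- w + 1e-6 * max(w)
  set.seed(seed)
  picks <- sample.int(length(w), n_probes, prob = w)
  dims <- dim(sub)
  grid <- model$grid
  rows <- purrr::map_dfr(picks, function(p) {
    idx <- arrayInd(p, dims)
    cell <- idx[1]; spn <- emitted[idx[2]]; hour <- idx[3]
    iy <- ((cell - 1) %% grid$ny) + 1
    ix <- ((cell - 1) %/% grid$ny) + 1
    e_loc <- emis_hour_total(world$emissions, hour, model)[cell, spn]
    scale <- if (e_loc > 0) e_loc else delta_floor
    adj <- sens$sens[cell, spn, hour]
    if (model$chem$mode == "titration") {
      vals <- vapply(delta_ladder * scale, function(d) {
        fdm_sensitivity(model, world$emissions, world$panel,
                        list(species = spn, iy = iy, ix = ix, hour = hour, delta = d),
                        spinup_hours = spin)
      }, numeric(1))
      # keep the smallest delta whose estimate changed least from the previous rung
      gaps <- abs(diff(vals))
      pick <- which.min(gaps) + 1L
      fdm <- vals[pick]; delta <- delta_ladder[pick] * scale
    } else {
      delta <- if (e_loc > 0) delta_rel * e_loc else delta_floor
      fdm <- fdm_sensitivity(model, world$emissions, world$panel,
                             list(species = spn, iy = iy, ix = ix, hour = hour, delta = delta),
                             spinup_hours = spin)
    }
    tibble::tibble(species = spn, iy = iy, ix = ix, hour = hour, delta = delta,
                   adjoint = adj, fdm = fdm,
                   rel_err = abs(adj - fdm) / max(abs(fdm), 1e-300))
  })
  fit <- lm(adjoint ~ fdm, data = rows)
  structure(list(
    table = rows,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    max_rel_err = max(rows$rel_err),
    median_rel_err = median(rows$rel_err),
    n_probes = n_probes,
    mode = model$chem$mode
  ), class = "adjoint_fdm_report")
}

#' @exportS3Method base::print
print.adjoint_fdm_report <- function(x, ...) {
  cat(sprintf("<adjoint_fdm_report> %s chemistry, %d probes: slope %.6f, R^2 %.6f, median rel err %.2e\n",
              x$mode, x$n_probes, x$slope, x$r_squared, x$median_rel_err))
  invisible(x)
}
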