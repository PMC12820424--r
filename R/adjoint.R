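# Exact discrete adjoint of the forward model: backward-in-time propagation of
# the cost gradient, accumulating per-species, per-cell, per-hour emission
# sensitivities in a single sweep.

#' One backward (adjoint) step
#'
#' Applies the transposes of the forward sub-operators in exactly reversed
#' order (diffuse, advect, deposit, chemistry), then adds the hour's forcing.
#' For the linear model this is the exact transpose action of the forward
#' step; in titration mode the chemistry transpose is the Jacobian of the
#' forward step evaluated at the stored (checkpointed) state.
#'
#' @param lambda `n_cells x n_species` adjoint state, the gradient of the cost
#'   w.r.t. the state at the end of `hour`.
#' @param model A [ctm_model()].
#' @param hour Forward hour being reversed (1-based).
#' @param forcing_hour Optional `n_cells x n_species` matrix added after the
#'   transposes (the derivative of the cost w.r.t. the state at the start of
#'   the hour).
#' @param checkpoint Pre-chemistry state of this hour (`n_cells x n_species`);
#'   required in titration mode.
#' @return The propagated adjoint state (gradient w.r.t. the post-injection
#'   state of `hour`, plus any forcing).
#' @export
adjoint_step <- function(lambda, model, hour, forcing_hour = NULL, checkpoint = NULL) {
  sp <- model$species
  for (s in seq_len(model$grid$substeps)) {
    lambda <- as.matrix(Matrix::crossprod(model$adv[[hour]],
                                          Matrix::crossprod(model$diff, lambda)))
  }
  lambda <- sweep(lambda, 2, exp(-sp$dep_rate), `*`)
  if (model$chem$mode == "titration" && is.null(checkpoint)) {
    abort(sprintf("missing checkpoint for hour %d (titration adjoint needs the stored state)", hour),
          class = "adjointpm_state_error")
  }
  lambda <- chemistry_adjoint(lambda, checkpoint, sp, model$chem,
                              model$met$temp_index[hour], as.numeric(model$met$o3bg))
  if (!is.null(forcing_hour)) lambda <- lambda + forcing_hour
  lambda
}

#' Run the adjoint model
#'
#' Iterates [adjoint_step()] from the final hour back to hour 1. The
#' sensitivity to an emission at (species, cell, hour) is the adjoint state
#' immediately before that hour's injection, times the tons-to-concentration
#' unit bridge, giving cost units per ton (deaths/ton, or USD/ton for
#' monetized forcing).
#'
#' @param model A [ctm_model()].
#' @param forcing A [gemm_forcing()] object (or compatible list with
#'   `per_hour`, `hours`, `units`).
#' @param trajectory The forward [run_forward()] trajectory the adjoint
#'   linearizes about; its stored states are required in titration mode.
#' @return A `sensitivity_field`: array `n_cells x n_species x n_hours` with a
#'   units attribute, hours inside the spin-up window flagged.
#' @export
run_adjoint <- function(model, forcing, trajectory = NULL) {
  grid <- model$grid; sp <- model$species
  N <- grid$n_hours
  if (any(forcing$hours < 1 | forcing$hours > N)) {
    abort("forcing hours outside the trajectory", class = "adjointpm_input_error")
  }
  need_ckpt <- model$chem$mode == "titration"
  if (need_ckpt && (is.null(trajectory) || is.null(trajectory$states))) {
    abort("titration-mode adjoint requires a stored forward trajectory",
          class = "adjointpm_state_error")
  }
  pm_idx <- match(sp$pm, sp$names)
  forced <- logical(N); forced[forcing$hours] <- TRUE
  lambda <- matrix(0, grid$n_cells, sp$n, dimnames = list(NULL, sp$names))
  sens <- array(0, c(grid$n_cells, sp$n, N), dimnames = list(NULL, sp$names, NULL))
  for (h in N:1) {
    # forcing acts on the stored state at the end of hour h
    if (forced[h]) lambda[, pm_idx] <- lambda[, pm_idx] + forcing$per_hour
    ckpt <- NULL
    if (need_ckpt) {
      E <- emis_hour_total(trajectory$emissions, h, model)
      if (!is.null(trajectory$perturb) && trajectory$perturb$hour == h) {
        p <- trajectory$perturb
        E[cell_index(p$iy, p$ix, grid), p$species] <- E[cell_index(p$iy, p$ix, grid), p$species] + p$dtons
      }
      ckpt <- trajectory$states[, , h] + E * model$uconv
    }
    lambda <- adjoint_step(lambda, model, h, checkpoint = ckpt)
    sens[, , h] <- lambda * model$uconv
  }
  spinup <- if (!is.null(trajectory)) trajectory$spinup_hours else 0L
  structure(list(
    sens = sens, grid = grid, species = sp,
    units = paste0(forcing$units, "_per_ton"),
    spinup_hours = as.integer(spinup),
    lambda0 = lambda   # gradient w.r.t. the initial condition (per ug/m3)
  ), class = "sensitivity_field")
}

#' @exportS3Method base::print
print.sensitivity_field <- function(x, ...) {
  cat(sprintf("<sensitivity_field> %s, %d species x %d cells x %d hours (%d spin-up flagged)\n",
              x$units, dim(x$sens)[2], dim(x$sens)[1], dim(x$sens)[3], x$spinup_hours))
  invisible(x)
}

# hours used for annual aggregates (spin-up excluded)
effective_hours <- function(sens) {
  setdiff(seq_len(dim(sens$sens)[3]), seq_len(sens$spinup_hours))
}

#' Annual (non-spin-up) aggregate of a sensitivity field
#'
#' @param sens A [run_adjoint()] sensitivity field.
#' @param stat `"mean"` (per-ton sensitivity of a source sustained over the
#'   period) or `"sum"`.
#' @return Tidy tibble (iy, ix, species, value) in the field's units.
#' @export
sens_annual <- function(sens, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  hours <- effective_hours(sens)
  agg <- apply(sens$sens[, , hours, drop = FALSE], c(1, 2), sum)
  if (stat == "mean") agg <- agg / length(hours)
  grid <- sens$grid
  tibble::tibble(
    iy = rep(rep(seq_len(grid$ny), grid$nx), ncol(agg)),
    ix = rep(rep(seq_len(grid$nx), each = grid$ny), ncol(agg)),
    species = rep(colnames(agg), each = grid$n_cells),
    value = as.numeric(agg)
  )
}

#' Emission-weighted primary-PM2.5 aggregation
#'
#' Collapses the per-species sensitivities of the primary PM2.5 components
#' into one "primary PM2.5" channel, weighting each species by its share of
#' primary-PM emission mass at that cell-hour. Cell-hours with zero primary
#' emissions receive the unweighted mean.
#'
#' @param sens A [run_adjoint()] sensitivity field.
#' @param emissions Emission container aligned with `sens` (tons/hr).
#' @param model The [ctm_model()] used to produce `sens`.
#' @return A `sensitivity_field` with a single `PM25_primary` species.
#' @export
emission_weighted_primary_pm <- function(sens, emissions, model) {
  prim <- model$species$primary
  N <- dim(sens$sens)[3]
  out <- array(0, c(model$grid$n_cells, 1, N),
               dimnames = list(NULL, "PM25_primary", NULL))
  for (h in seq_len(N)) {
    E <- emis_hour_total(emissions, h, model)[, prim, drop = FALSE]
    tot <- rowSums(E)
    S <- sens$sens[, prim, h, drop = TRUE]
    if (is.null(dim(S))) S <- matrix(S, ncol = length(prim))
    w_mean <- rowSums(S) / length(prim)
    w_emis <- rowSums(S * E) / ifelse(tot > 0, tot, 1)
    out[, 1, h] <- ifelse(tot > 0, w_emis, w_mean)
  }
  structure(list(sens = out, grid = sens$grid, species = model$species,
                 units = sens$units, spinup_hours = sens$spinup_hours),
            class = "sensitivity_field")
}
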