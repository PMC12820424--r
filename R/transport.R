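# Forward reduced chemical-transport model.
#
# State layout: a field is an ny x nx matrix; vectorized column-major so cell
# k = iy + (ix-1)*ny. Multi-species state is an (n_cells x n_species) matrix.
# Transport sub-operators are assembled as sparse matrices, which makes the
# discrete adjoint an exact transpose (crossprod) of the coded forward update.

cell_index <- function(iy, ix, grid) iy + (ix - 1L) * grid$ny

# donor-cell (first-order upwind) advection operator for one timestep dt_s
advection_matrix <- function(u, v, grid, dt_s = grid$dt_s) {
  ny <- grid$ny; nx <- grid$nx
  cfl <- max(abs(u) + abs(v)) * dt_s / grid$dx_m
  if (cfl > 1 + 1e-12) {
    abort(sprintf(
      "CFL violation: max(|u|+|v|) = %.3g m/s, dt = %g s, dx = %g m gives CFL = %.3g > 1",
      max(abs(u) + abs(v)), dt_s, grid$dx_m, cfl), class = "adjointpm_config_error")
  }
  cc <- dt_s / grid$dx_m
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    keep <- x != 0
    ii <<- c(ii, i[keep]); jj <<- c(jj, j[keep]); xx <<- c(xx, x[keep])
  }
  # x-direction interfaces between (iy, ix) and (iy, ix+1)
  iy_all <- seq_len(ny)
  x_pairs <- if (grid$boundary == "periodic") cbind(seq_len(nx), c(seq_len(nx - 1) + 1L, 1L)[seq_len(nx)]) else
    if (nx > 1) cbind(seq_len(nx - 1), seq_len(nx - 1) + 1L) else matrix(integer(0), 0, 2)
  if (grid$boundary == "periodic" && nx == 1) x_pairs <- matrix(integer(0), 0, 2)
  if (nrow(x_pairs)) {
    for (p in seq_len(nrow(x_pairs))) {
      ixL <- x_pairs[p, 1]; ixR <- x_pairs[p, 2]
      ui <- 0.5 * (u[, ixL] + u[, ixR])
      up <- pmax(ui, 0); um <- pmin(ui, 0)
      L <- cell_index(iy_all, ixL, grid); R <- cell_index(iy_all, ixR, grid)
      add(L, L, -cc * up); add(L, R, -cc * um)
      add(R, L,  cc * up); add(R, R,  cc * um)
    }
  }
  # y-direction interfaces between (iy, ix) and (iy+1, ix)
  ix_all <- seq_len(nx)
  y_pairs <- if (grid$boundary == "periodic") cbind(seq_len(ny), c(seq_len(ny - 1) + 1L, 1L)[seq_len(ny)]) else
    if (ny > 1) cbind(seq_len(ny - 1), seq_len(ny - 1) + 1L) else matrix(integer(0), 0, 2)
  if (grid$boundary == "periodic" && ny == 1) y_pairs <- matrix(integer(0), 0, 2)
  if (nrow(y_pairs)) {
    for (p in seq_len(nrow(y_pairs))) {
      iyL <- y_pairs[p, 1]; iyR <- y_pairs[p, 2]
      vi <- 0.5 * (v[iyL, ] + v[iyR, ])
      vp <- pmax(vi, 0); vm <- pmin(vi, 0)
      L <- cell_index(rep(iyL, nx), ix_all, grid); R <- cell_index(rep(iyR, nx), ix_all, grid)
      add(L, L, -cc * vp); add(L, R, -cc * vm)
      add(R, L,  cc * vp); add(R, R,  cc * vm)
    }
  }
  # zero_inflow domain edges: outflow only (inflow concentration is zero)
  if (grid$boundary == "zero_inflow") {
    west <- cell_index(iy_all, rep(1L, ny), grid)
    add(west, west, cc * pmin(u[, 1], 0))          # u<0 at west edge exports mass
    east <- cell_index(iy_all, rep(nx, ny), grid)
    add(east, east, -cc * pmax(u[, nx], 0))
    south <- cell_index(rep(1L, nx), ix_all, grid)
    add(south, south, cc * pmin(v[1, ], 0))
    north <- cell_index(rep(ny, nx), ix_all, grid)
    add(north, north, -cc * pmax(v[ny, ], 0))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(grid$n_cells, grid$n_cells))
  A + Matrix::Diagonal(grid$n_cells)
}

# explicit 5-point diffusion operator; Neumann no-flux walls for zero_inflow
diffusion_matrix <- function(K, grid, dt_s = grid$dt_s) {
  d <- K * dt_s / grid$dx_m^2
  if (d > 0.25 + 1e-12) {
    abort(sprintf("diffusion stability violation: K*dt/dx^2 = %.3g > 1/4 (K = %g, dt = %g, dx = %g)",
                  d, K, dt_s, grid$dx_m), class = "adjointpm_config_error")
  }
  ny <- grid$ny; nx <- grid$nx
  if (d == 0) return(Matrix::Diagonal(grid$n_cells))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) { ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, rep_len(x, length(i))) }
  link <- function(L, R) { add(L, R, d); add(R, L, d); add(L, L, -d); add(R, R, -d) }
  iy_all <- seq_len(ny); ix_all <- seq_len(nx)
  if (nx > 1) for (ix in seq_len(nx - 1)) {
    link(cell_index(iy_all, rep(ix, ny), grid), cell_index(iy_all, rep(ix + 1L, ny), grid))
  }
  if (ny > 1) for (iy in seq_len(ny - 1)) {
    link(cell_index(rep(iy, nx), ix_all, grid), cell_index(rep(iy + 1L, nx), ix_all, grid))
  }
  if (grid$boundary == "periodic") {
    if (nx > 2) link(cell_index(iy_all, rep(nx, ny), grid), cell_index(iy_all, rep(1L, ny), grid))
    if (ny > 2) link(cell_index(rep(ny, nx), ix_all, grid), cell_index(rep(1L, nx), ix_all, grid))
  }
  if (!length(ii)) return(Matrix::Diagonal(grid$n_cells))
  D <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(grid$n_cells, grid$n_cells))
  D + Matrix::Diagonal(grid$n_cells)
}

#' Advect a field one timestep (first-order upwind)
#'
#' @param field `ny x nx` concentration matrix (ug/m3).
#' @param u,v `ny x nx` wind components (m/s) at cell centres.
#' @param grid A [grid_spec()].
#' @param dt_s Timestep (defaults to the grid timestep).
#' @return The advected `ny x nx` field.
#' @export
advect <- function(field, u, v, grid, dt_s = grid$dt_s) {
  stopifnot(all(is.finite(field)))
  A <- advection_matrix(u, v, grid, dt_s)
  matrix(as.numeric(A %*% as.numeric(field)), grid$ny, grid$nx)
}

#' Diffuse a field one timestep (explicit 5-point Laplacian)
#'
#' @inheritParams advect
#' @param K Horizontal eddy diffusivity (m2/s); stability requires
#'   `K*dt/dx^2 <= 1/4`.
#' @return The diffused field.
#' @export
diffuse <- function(field, K, grid, dt_s = grid$dt_s) {
  D <- diffusion_matrix(K, grid, dt_s)
  matrix(as.numeric(D %*% as.numeric(field)), grid$ny, grid$nx)
}

#' Exponential first-order deposition
#'
#' Exact exponential removal `conc * exp(-rate * dt_h)`, chosen over forward
#' Euler for unconditional stability and a self-adjoint update.
#'
#' @param conc `n_cells x n_species` matrix (or any numeric array) of
#'   concentrations.
#' @param rates Per-species deposition rates (1/h), recycled over columns.
#' @param dt_h Duration in hours.
#' @return Deposited concentrations, same shape.
#' @export
deposit <- function(conc, rates, dt_h = 1) {
  if (any(rates < 0)) abort("deposition rates must be >= 0", class = "adjointpm_input_error")
  if (is.matrix(conc)) {
    sweep(conc, 2, exp(-rates * dt_h), `*`)
  } else {
    conc * exp(-rates * dt_h)
  }
}

#' Inject emissions into the mixed layer
#'
#' Emission mass is diluted over the cell volume: a source of `E` tons/hr
#' running for `dt_h` hours raises the cell concentration by
#' `E * 1e12 * dt_h / (cell_area_m2 * mixing_height_m)` ug/m3.
#'
#' @param conc Concentration matrix/array (ug/m3).
#' @param E Emission rates, same shape as `conc` (tons/hr).
#' @param grid A [grid_spec()].
#' @param dt_h Duration in hours.
#' @return Updated concentrations.
#' @export
inject_emissions <- function(conc, E, grid, dt_h = 1) {
  if (!identical(dim(conc), dim(E)) && length(conc) != length(E)) {
    abort("conc and E shapes differ", class = "adjointpm_input_error")
  }
  if (any(E < 0)) abort("emissions must be >= 0", class = "adjointpm_input_error")
  conc + E * emission_unit_conversion(grid) * dt_h
}

# ug/m3 gained per (ton/hr sustained for 1 h) in one cell
emission_unit_conversion <- function(grid) {
  1e12 / (grid$cell_area_m2 * grid$mixing_height_m)
}

#' Chemistry configuration
#'
#' First-order gas-to-particle conversion, optionally with a stylized
#' NOx-titration regime. In `linear` mode each gas converts at
#' `k[gas] * temp_index` per hour. In `titration` mode the NOx rate becomes
#' `k_titr * temp_index * max(0, o3bg - gamma * [NOx])` — added NOx consumes
#' the oxidant proxy, so nitrate production can *decrease* with NOx
#' (NOx-inhibited regime), the mechanism behind negative NOx sensitivities.
#'
#' @param mode `"linear"` or `"titration"`.
#' @param k Named per-gas linear rates (1/h) at `temp_index = 1`.
#' @param k_titr Titration rate constant (1/h per ug/m3 of oxidant).
#' @param gamma Oxidant consumed per unit NOx (unitless proxy).
#' @return A `chem_config` list.
#' @export
chem_config <- function(mode = c("linear", "titration"),
                        k = c(SO2 = 0.02, NOX = 0.04, NH3 = 0.08),
                        k_titr = 8e-4, gamma = 2) {
  mode <- match.arg(mode)
  if (any(k < 0) || k_titr < 0 || gamma < 0) {
    abort("chemistry rates must be >= 0", class = "adjointpm_config_error")
  }
  structure(list(mode = mode, k = k, k_titr = k_titr, gamma = gamma),
            class = "chem_config")
}

#' One chemistry step (gas-to-particle conversion)
#'
#' @param conc `n_cells x n_species` matrix with species names as column
#'   names; all values must be non-negative.
#' @param species A [species_set()].
#' @param chem A [chem_config()].
#' @param temp_index Hourly rate modulator (unitless).
#' @param o3bg Background oxidant proxy, vector of length `n_cells`
#'   (titration mode only).
#' @param dt_h Duration in hours.
#' @param check Reject negative input concentrations (disabled internally for
#'   signed finite-difference probe runs, where a negative emission
#'   perturbation is a legitimate linearization device).
#' @return List with `conc` (updated matrix) and `jacobian_record` (per-gas
#'   local linearization slope `d(reacted)/d(gas)`, plus the NOx regime
#'   indicator in titration mode) — everything the adjoint needs to linearize
#'   this step about the current state.
#' @export
chemistry_step <- function(conc, species, chem, temp_index = 1, o3bg = NULL, dt_h = 1,
                           check = TRUE) {
  if (check && any(conc < 0)) abort("negative concentrations passed to chemistry",
                                    class = "adjointpm_domain_error")
  jac <- list()
  for (g in species$gases) {
    p <- species$product_of[[g]]
    yield <- species$yield_of[[g]]
    cg <- conc[, g]
    if (chem$mode == "titration" && g == "NOX") {
      if (is.null(o3bg)) abort("titration mode requires o3bg", class = "adjointpm_config_error")
      avail <- o3bg - chem$gamma * cg
      active <- avail > 0
      rate <- chem$k_titr * temp_index * pmax(0, avail)      # 1/h
      reacted <- rate * cg * dt_h
      # d(reacted)/d(cg); subgradient 0 at the max(0, .) kink
      slope <- ifelse(active, chem$k_titr * temp_index * dt_h * (o3bg - 2 * chem$gamma * cg), 0)
      jac[[g]] <- list(slope = slope, active = active)
    } else {
      r <- unname(chem$k[g]) * temp_index * dt_h
      if (is.na(r)) r <- 0
      if (r > 1) abort(sprintf("chemistry rate k*temp_index*dt = %.3g > 1 for %s", r, g),
                       class = "adjointpm_config_error")
      reacted <- r * cg
      jac[[g]] <- list(slope = rep(r, length(cg)), active = rep(TRUE, length(cg)))
    }
    conc[, g] <- cg - reacted
    conc[, p] <- conc[, p] + yield * reacted
  }
  list(conc = conc, jacobian_record = jac)
}

# adjoint of chemistry_step linearized at the stored pre-chemistry state
chemistry_adjoint <- function(lambda, conc_in, species, chem, temp_index = 1,
                              o3bg = NULL, dt_h = 1) {
  for (g in species$gases) {
    p <- species$product_of[[g]]
    yield <- species$yield_of[[g]]
    if (chem$mode == "titration" && g == "NOX") {
      cg <- conc_in[, g]
      avail <- o3bg - chem$gamma * cg
      slope <- ifelse(avail > 0,
                      chem$k_titr * temp_index * dt_h * (o3bg - 2 * chem$gamma * cg), 0)
    } else {
      r <- unname(chem$k[g]) * temp_index * dt_h
      if (is.na(r)) r <- 0
      slope <- rep(r, nrow(lambda))
    }
    lambda[, g] <- (1 - slope) * lambda[, g] + yield * slope * lambda[, p]
  }
  lambda
}

#' Assemble a transport model
#'
#' Validates stability (CFL, explicit diffusion, chemistry rate bounds) and
#' precomputes the per-hour sparse transport operators shared by the forward
#' model, the adjoint, and brute-force runs.
#'
#' @param grid A [grid_spec()].
#' @param species A [species_set()].
#' @param met A [met_fields()].
#' @param chem A [chem_config()].
#' @param K Horizontal diffusivity (m2/s).
#' @return A `ctm_model` object.
#' @export
ctm_model <- function(grid, species, met, chem = chem_config(), K = 2000) {
  tmax <- max(met$temp_index)
  if (chem$mode == "titration") {
    bound <- chem$k_titr * tmax * max(met$o3bg)
    if (bound > 1) abort(sprintf("titration rate bound k_titr*temp*o3bg = %.3g > 1", bound),
                         class = "adjointpm_config_error")
  }
  if (length(chem$k) && max(chem$k) * tmax > 1) {
    abort("linear chemistry rate k*temp_index exceeds 1/h", class = "adjointpm_config_error")
  }
  adv <- lapply(seq_len(grid$n_hours), function(h) {
    advection_matrix(matrix(met$u[h, , ], grid$ny, grid$nx),
                     matrix(met$v[h, , ], grid$ny, grid$nx), grid)
  })
  structure(list(
    grid = grid, species = species, met = met, chem = chem, K = K,
    adv = adv, diff = diffusion_matrix(K, grid),
    uconv = emission_unit_conversion(grid)
  ), class = "ctm_model")
}

# total emission matrix (n_cells x n_species) for hour h; generic over
# emission containers
emis_hour_total <- function(emissions, h, model) UseMethod("emis_hour_total")

#' @export
emis_hour_total.matrix <- function(emissions, h, model) emissions

#' @export
emis_hour_total.array <- function(emissions, h, model) emissions[, , h]

#' @export
emis_hour_total.NULL <- function(emissions, h, model) {
  matrix(0, model$grid$n_cells, model$species$n,
         dimnames = list(NULL, model$species$names))
}

#' Run the forward model
#'
#' Applies the fixed operator-split sequence — inject, chemistry, deposit,
#' advect, diffuse — each hour, storing hourly states. The exposure metric is
#' the mean total PM2.5 (primary + secondary mass) over non-spin-up hours.
#'
#' @param model A [ctm_model()].
#' @param emissions An emission container: `NULL`, a constant
#'   `n_cells x n_species` matrix (tons/hr), an `n_cells x n_species x n_hours`
#'   array, or an `emission_inventory`.
#' @param spinup_hours Leading hours excluded from the exposure mean.
#' @param init Initial state (`n_cells x n_species`), default zero.
#' @param perturb Optional point perturbation
#'   `list(species=, iy=, ix=, hour=, dtons=)` in tons/hr applied at one
#'   cell-hour (used by brute-force sensitivity runs).
#' @param store Keep the full hourly trajectory (needed by the adjoint).
#' @return A `trajectory` object with `states` (if stored), `pm_mean`
#'   (`ny x nx`), and bookkeeping fields.
#' @export
run_forward <- function(model, emissions = NULL, spinup_hours = 0, init = NULL,
                        perturb = NULL, store = TRUE) {
  grid <- model$grid; sp <- model$species
  N <- grid$n_hours
  if (spinup_hours >= N) abort("spinup_hours must be < n_hours", class = "adjointpm_config_error")
  C <- if (is.null(init)) matrix(0, grid$n_cells, sp$n, dimnames = list(NULL, sp$names)) else init
  states <- if (store) array(NA_real_, c(grid$n_cells, sp$n, N + 1),
                             dimnames = list(NULL, sp$names, NULL)) else NULL
  if (store) states[, , 1] <- C
  pm_idx <- match(sp$pm, sp$names)
  pm_sum <- numeric(grid$n_cells)
  n_eff <- N - spinup_hours
  o3 <- as.numeric(model$met$o3bg)
  dep_fac <- exp(-sp$dep_rate)
  for (h in seq_len(N)) {
    E <- emis_hour_total(emissions, h, model)
    if (!is.null(perturb) && perturb$hour == h) {
      k <- cell_index(perturb$iy, perturb$ix, grid)
      E[k, perturb$species] <- E[k, perturb$species] + perturb$dtons
    }
    C <- C + E * model$uconv
    C <- chemistry_step(C, sp, model$chem, model$met$temp_index[h], o3,
                        check = is.null(perturb))$conc
    C <- sweep(C, 2, dep_fac, `*`)
    for (s in seq_len(grid$substeps)) {
      C <- as.matrix(model$diff %*% (model$adv[[h]] %*% C))
    }
    if (anyNA(C) || any(!is.finite(C))) {
      abort(sprintf("non-finite state detected at hour %d", h), class = "adjointpm_state_error")
    }
    if (store) states[, , h + 1] <- C
    if (h > spinup_hours) pm_sum <- pm_sum + rowSums(C[, pm_idx, drop = FALSE])
  }
  structure(list(
    states = states,
    pm_mean = matrix(pm_sum / n_eff, grid$ny, grid$nx),
    grid = grid, species = sp,
    spinup_hours = as.integer(spinup_hours),
    n_eff = as.integer(n_eff),
    emissions = emissions, perturb = perturb,
    units = "ug/m3"
  ), class = "trajectory")
}

#' @exportS3Method base::print
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d h on %dx%d grid (%d spin-up); domain-mean PM2.5 = %.3g ug/m3\n",
              x$grid$n_hours, x$grid$nx, x$grid$ny, x$spinup_hours, mean(x$pm_mean)))
  invisible(x)
}
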