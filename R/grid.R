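#' Define the model grid
#'
#' A single-layer rectangular grid for the reduced Eulerian transport model.
#' Horizontal resolution is uniform; the vertical dimension is collapsed into
#' one well-mixed layer of depth `mixing_height_m`, so emissions injected into
#' a cell are diluted over `cell_area_m2 * mixing_height_m`.
#'
#' @param nx,ny Number of cells in the x (east) and y (north) directions.
#' @param dx_km Cell edge length in kilometres.
#' @param dt_s Timestep in seconds. The model steps hourly; `dt_s` below 3600
#'   sub-steps transport within the hour.
#' @param n_hours Simulation length in hours.
#' @param boundary `"zero_inflow"` (limited-area domain: outflow is lost,
#'   inflow is zero) or `"periodic"` (used for mass-conservation checks).
#' @param mixing_height_m Effective mixed-layer depth in metres.
#'
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(nx, ny, dx_km, dt_s = 3600, n_hours = 24,
                      boundary = c("zero_inflow", "periodic"),
                      mixing_height_m = 1000) {
  boundary <- match.arg(boundary)
  if (nx < 1 || ny < 1) abort("nx and ny must be >= 1", class = "adjointpm_config_error")
  if (dx_km <= 0 || dt_s <= 0 || mixing_height_m <= 0) {
    abort("dx_km, dt_s and mixing_height_m must be positive",
          class = "adjointpm_config_error")
  }
  if (n_hours < 1) abort("n_hours must be >= 1", class = "adjointpm_config_error")
  if (3600 %% dt_s != 0) {
    abort("dt_s must divide 3600 s so states can be stored on the hour",
          class = "adjointpm_config_error")
  }
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny),
    dx_km = dx_km, dx_m = dx_km * 1000,
    dt_s = dt_s, substeps = as.integer(3600 / dt_s),
    n_hours = as.integer(n_hours),
    boundary = boundary,
    mixing_height_m = mixing_height_m,
    cell_area_m2 = (dx_km * 1000)^2,
    n_cells = as.integer(nx * ny)
  ), class = "grid_spec")
}

#' @exportS3Method base::print
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, dx = %g km, dt = %g s, %d h, %s boundary\n",
              x$nx, x$ny, x$dx_km, x$dt_s, x$n_hours, x$boundary))
  invisible(x)
}

#' Define the chemical species set
#'
#' Species are partitioned into three roles: `primary` particulate species
#' emitted directly as PM2.5 mass (elemental carbon, organic carbon, fine
#' crustal), precursor gases (`gas`: SO2, NOx, NH3), and `secondary`
#' particulate products (pSO4, pNO3, pNH4) formed from the gases. Each gas
#' converts to exactly one product with a first-order rate (1/h) and a
#' transferred-mass yield in [0, 1]. Every species has a first-order
#' deposition rate (1/h).
#'
#' @param species A data frame with columns `name`, `role`
#'   (`primary`/`gas`/`secondary`), `dep_rate` (1/h), and for gases `product`
#'   (name of the secondary species) and `yield` (mass fraction transferred,
#'   in \[0, 1\]). Defaults to the standard 9-species set.
#'
#' @return A `species_set` object.
#' @export
species_set <- function(species = default_species_table()) {
  species <- tibble::as_tibble(species)
  req <- c("name", "role", "dep_rate", "product", "yield")
  missing_cols <- setdiff(req, names(species))
  if (length(missing_cols)) {
    abort(paste("species table missing columns:", paste(missing_cols, collapse = ", ")),
          class = "adjointpm_config_error")
  }
  if (anyDuplicated(species$name)) abort("duplicate species names", class = "adjointpm_config_error")
  if (!all(species$role %in% c("primary", "gas", "secondary"))) {
    abort("species roles must be primary/gas/secondary", class = "adjointpm_config_error")
  }
  if (any(species$dep_rate < 0)) abort("deposition rates must be >= 0", class = "adjointpm_config_error")
  gas <- species[species$role == "gas", ]
  if (any(is.na(gas$product)) || !all(gas$product %in% species$name[species$role == "secondary"])) {
    abort("every gas must name a secondary-species product", class = "adjointpm_config_error")
  }
  if (any(gas$yield < 0 | gas$yield > 1)) {
    abort("gas->particle yields must lie in [0, 1]", class = "adjointpm_config_error")
  }
  structure(list(
    table = species,
    names = species$name,
    n = nrow(species),
    primary = species$name[species$role == "primary"],
    gases = gas$name,
    secondary = species$name[species$role == "secondary"],
    pm = species$name[species$role %in% c("primary", "secondary")],
    product_of = setNames(gas$product, gas$name),
    yield_of = setNames(gas$yield, gas$name),
    dep_rate = setNames(species$dep_rate, species$name)
  ), class = "species_set")
}

#' Standard 9-species table
#'
#' Primary PM2.5 mass (EC, OC, CRUST), precursor gases (SO2, NOX, NH3) and
#' their secondary inorganic products (pSO4, pNO3, pNH4). Deposition rates are
#' effective first-order removal rates typical of a well-mixed boundary layer;
#' yields default to 1 (all reacted gas mass appears as particle mass).
#'
#' @return A tibble suitable for [species_set()].
#' @export
default_species_table <- function() {
  tibble::tribble(
    ~name,   ~role,       ~dep_rate, ~product, ~yield,
    "EC",    "primary",   0.02,      NA,       NA,
    "OC",    "primary",   0.02,      NA,       NA,
    "CRUST", "primary",   0.03,      NA,       NA,
    "SO2",   "gas",       0.05,      "pSO4",   1,
    "NOX",   "gas",       0.03,      "pNO3",   1,
    "NH3",   "gas",       0.10,      "pNH4",   1,
    "pSO4",  "secondary", 0.02,      NA,       NA,
    "pNO3",  "secondary", 0.02,      NA,       NA,
    "pNH4",  "secondary", 0.02,      NA,       NA
  )
}

#' @exportS3Method base::print
print.species_set <- function(x, ...) {
  cat(sprintf("<species_set> %d species: %s primary, %s gas, %s secondary\n",
              x$n, length(x$primary), length(x$gases), length(x$secondary)))
  invisible(x)
}

#' Assemble meteorological fields
#'
#' @param u,v Wind components, `n_hours x ny x nx` arrays (m/s), defined at
#'   cell centres.
#' @param temp_index Length-`n_hours` unitless seasonal modulator of the
#'   gas-to-particle conversion rates (1 = nominal). Captures the temperature
#'   dependence of secondary-inorganic formation and partitioning.
#' @param o3bg Background oxidant proxy (scalar or `ny x nx`, ug/m3),
#'   consumed only by the titration chemistry mode.
#' @param grid A [grid_spec()].
#'
#' @return A `met_fields` object.
#' @export
met_fields <- function(u, v, temp_index = NULL, o3bg = 60, grid) {
  dims <- c(grid$n_hours, grid$ny, grid$nx)
  for (nm in c("u", "v")) {
    f <- get(nm)
    if (!identical(dim(f), as.integer(dims))) {
      abort(sprintf("%s must have dim (n_hours, ny, nx) = (%s)", nm,
                    paste(dims, collapse = ", ")),
            class = "adjointpm_config_error")
    }
    if (!all(is.finite(f))) abort(sprintf("%s contains non-finite values", nm),
                                  class = "adjointpm_config_error")
  }
  if (is.null(temp_index)) temp_index <- rep(1, grid$n_hours)
  if (length(temp_index) != grid$n_hours || !all(is.finite(temp_index)) || any(temp_index < 0)) {
    abort("temp_index must be n_hours finite non-negative values",
          class = "adjointpm_config_error")
  }
  if (length(o3bg) == 1) o3bg <- matrix(o3bg, grid$ny, grid$nx)
  if (!identical(dim(o3bg), c(grid$ny, grid$nx)) || any(o3bg < 0)) {
    abort("o3bg must be a non-negative scalar or ny x nx matrix",
          class = "adjointpm_config_error")
  }
  structure(list(u = u, v = v, temp_index = temp_index, o3bg = o3bg),
            class = "met_fields")
}

#' Hour-to-season calendar
#'
#' Hours are mapped proportionally onto the four meteorological seasons:
#' the first quarter of the run is DJF, then MAM, JJA, SON. Runs shorter than
#' a year are treated as a compressed year.
#'
#' @param n_hours Run length in hours.
#' @return Character vector of length `n_hours` with levels DJF/MAM/JJA/SON.
#' @export
season_of_hour <- function(n_hours) {
  p <- (seq_len(n_hours) - 1) / n_hours
  c("DJF", "MAM", "JJA", "SON")[pmin(4L, 1L + as.integer(p * 4))]
}
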