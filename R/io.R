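# Text-format artifact I/O. Gridded fields are serialized as long-format CSV
# (one row per element, dimension indices first, column-major) with a JSON
# metadata sidecar carrying dimension sizes, dimnames and a mandatory units
# attribute. Floats are written as %.17g so read(write(x)) round-trips
# exactly. Unit bookkeeping is the main failure mode of this kind of
# artifact, so a missing units attribute is a hard error on read.

meta_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a gridded array
#'
#' @param x Numeric array (any number of dimensions).
#' @param path CSV output path; a `.json` metadata sidecar is written next to
#'   it.
#' @param dim_names Names of the dimensions, e.g. `c("hour", "y", "x")`.
#' @param units Units string (mandatory).
#' @param extra Named list of extra metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_gridded <- function(x, path, dim_names, units, extra = list()) {
  d <- dim(x); if (is.null(d)) d <- length(x)
  if (length(d) != length(dim_names)) {
    abort("dim_names must name every dimension", class = "adjointpm_input_error")
  }
  idx <- do.call(expand.grid, lapply(d, seq_len))  # column-major, matches as.numeric(x)
  names(idx) <- dim_names
  idx$value <- sprintf("%.17g", as.numeric(x))
  write.csv(idx, path, row.names = FALSE, quote = FALSE)
  meta <- list(dims = setNames(as.list(as.integer(d)), dim_names),
               dimnames = dimnames(x), units = units)
  jsonlite::write_json(c(meta, extra), meta_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a gridded array
#'
#' @param path CSV path written by [write_gridded()].
#' @param require_dims Dimension names that must be present (e.g. `"hour"`).
#' @return The array with `units` and any extra metadata as attributes.
#' @export
read_gridded <- function(path, require_dims = NULL) {
  mp <- meta_path(path)
  if (!file.exists(mp)) abort(paste("missing metadata sidecar:", mp),
                              class = "adjointpm_input_error")
  meta <- jsonlite::fromJSON(mp, simplifyVector = TRUE)
  if (is.null(meta$units) || !nzchar(meta$units)) {
    abort(paste("gridded file lacks a units attribute:", path),
          class = "adjointpm_input_error")
  }
  missing_dims <- setdiff(require_dims, names(meta$dims))
  if (length(missing_dims)) {
    abort(paste("gridded file lacks required dimension(s):",
                paste(missing_dims, collapse = ", ")),
          class = "adjointpm_input_error")
  }
  df <- read.csv(path, colClasses = c(value = "character"))
  d <- unlist(meta$dims)
  if (nrow(df) != prod(d)) abort("gridded file size does not match metadata dims",
                                 class = "adjointpm_input_error")
  x <- array(as.numeric(df$value), dim = unname(d))
  if (!is.null(meta$dimnames)) {
    dn <- vector("list", length(d))
    for (i in seq_along(d)) {
      nm <- meta$dimnames[[i]]
      if (!is.null(nm) && length(nm) == d[i]) dn[[i]] <- nm
    }
    dimnames(x) <- dn
  }
  attr(x, "units") <- meta$units
  for (nm in setdiff(names(meta), c("dims", "dimnames", "units"))) {
    attr(x, nm) <- meta[[nm]]
  }
  x
}

write_table_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write / read an exposure panel
#'
#' @param panel An [exposure_panel()].
#' @param path CSV path.
#' @param grid A [grid_spec()] used to validate on read.
#' @return The path / the panel.
#' @export
write_exposure_panel <- function(panel, path) write_table_csv(panel, path)

#' @rdname write_exposure_panel
#' @export
read_exposure_panel <- function(path, grid) {
  df <- read.csv(path)
  exposure_panel(df, grid)
}

#' Write / read an economics panel
#'
#' Columns are validated strictly: an unknown column is an error naming it.
#'
#' @param econ An [econ_panel()].
#' @param path CSV path.
#' @return The path / the panel.
#' @export
write_econ_panel <- function(econ, path) write_table_csv(as.data.frame(econ), path)

#' @rdname write_econ_panel
#' @export
read_econ_panel <- function(path) econ_panel(read.csv(path))

#' Write / read a forward trajectory
#'
#' States are stored with dimensions (y, x, species, hour) where hour runs
#' 0..n_hours; grid parameters, the species table and the spin-up window ride
#' along in the metadata so the trajectory is self-describing.
#'
#' @param traj A [run_forward()] trajectory (with stored states).
#' @param path CSV path.
#' @return The path / the reconstructed trajectory.
#' @export
write_trajectory <- function(traj, path) {
  if (is.null(traj$states)) abort("trajectory has no stored states", class = "adjointpm_input_error")
  g <- traj$grid
  x <- array(traj$states, c(g$ny, g$nx, traj$species$n, g$n_hours + 1))
  dimnames(x) <- list(NULL, NULL, traj$species$names, NULL)
  write_gridded(x, path, c("y", "x", "species", "hour"), units = "ug/m3",
                extra = list(grid = g[c("nx", "ny", "dx_km", "dt_s", "n_hours",
                                        "boundary", "mixing_height_m")],
                             spinup_hours = traj$spinup_hours,
                             species_table = traj$species$table))
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  x <- read_gridded(path, require_dims = c("hour", "y", "x"))
  gp <- attr(x, "grid")
  grid <- grid_spec(gp$nx, gp$ny, gp$dx_km, gp$dt_s, gp$n_hours, gp$boundary,
                    gp$mixing_height_m)
  sp <- species_set(tibble::as_tibble(attr(x, "species_table")))
  spin <- attr(x, "spinup_hours")
  states <- array(x, c(grid$n_cells, sp$n, grid$n_hours + 1))
  dimnames(states) <- list(NULL, sp$names, NULL)
  pm_idx <- match(sp$pm, sp$names)
  eff <- (spin + 2):(grid$n_hours + 1)
  pm_sum <- rowSums(apply(states[, pm_idx, eff, drop = FALSE], c(1, 3), sum))
  structure(list(states = states,
                 pm_mean = matrix(pm_sum / length(eff), grid$ny, grid$nx),
                 grid = grid, species = sp,
                 spinup_hours = as.integer(spin),
                 n_eff = as.integer(grid$n_hours - spin),
                 emissions = NULL, perturb = NULL, units = "ug/m3"),
            class = "trajectory")
}

#' Write / read a sensitivity field
#'
#' @param sens A [run_adjoint()] sensitivity field.
#' @param path CSV path.
#' @param grid Grid used on read.
#' @param species Species set used on read.
#' @return The path / the field.
#' @export
write_sensitivity <- function(sens, path) {
  g <- sens$grid
  x <- array(sens$sens, c(g$ny, g$nx, dim(sens$sens)[2], dim(sens$sens)[3]))
  dimnames(x) <- list(NULL, NULL, colnames(sens$sens), NULL)
  write_gridded(x, path, c("y", "x", "species", "hour"), units = sens$units,
                extra = list(spinup_hours = sens$spinup_hours,
                             grid = g[c("nx", "ny", "dx_km", "dt_s", "n_hours",
                                        "boundary", "mixing_height_m")]))
}

#' @rdname write_sensitivity
#' @export
read_sensitivity <- function(path, species = species_set()) {
  x <- read_gridded(path, require_dims = c("hour", "y", "x", "species"))
  gp <- attr(x, "grid")
  grid <- grid_spec(gp$nx, gp$ny, gp$dx_km, gp$dt_s, gp$n_hours, gp$boundary,
                    gp$mixing_height_m)
  nsp <- dim(x)[3]; N <- dim(x)[4]
  sens <- array(x, c(grid$n_cells, nsp, N))
  dimnames(sens) <- list(NULL, dimnames(x)[[3]], NULL)
  structure(list(sens = sens, grid = grid, species = species,
                 units = attr(x, "units"),
                 spinup_hours = as.integer(attr(x, "spinup_hours"))),
            class = "sensitivity_field")
}
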