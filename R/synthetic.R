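# Seeded synthetic-world generators: gridded population with urban clustering,
# region masks with regional baseline mortality, sector- and species-resolved
# hourly emission inventories with diurnal/seasonal profiles, wind regimes,
# and a regional economics table for VSL transfer.

#' Region mask
#'
#' @param region_of_cell Character vector, length `n_cells` (column-major cell
#'   order), assigning every cell to exactly one region.
#' @param grid A [grid_spec()].
#' @return A `region_mask` object.
#' @export
region_mask <- function(region_of_cell, grid) {
  if (length(region_of_cell) != grid$n_cells || anyNA(region_of_cell)) {
    abort("region mask must assign every cell exactly once", class = "adjointpm_input_error")
  }
  structure(list(region_of_cell = as.character(region_of_cell),
                 regions = sort(unique(as.character(region_of_cell))),
                 grid = grid),
            class = "region_mask")
}

#' Sector-resolved emission inventory
#'
#' Stored in factored form: a spatial/species base pattern per sector times a
#' 24-hour diurnal profile and a 4-season profile. `E[sector, species, cell,
#' hour] = base[cell, species, sector] * diurnal[sector, hour-of-day] *
#' seasonal[sector, season(hour)]`, rescaled per sector so the run-total tons
#' match `totals` exactly.
#'
#' @param base `n_cells x n_species x n_sectors` non-negative array with
#'   species/sector dimnames.
#' @param diurnal `n_sectors x 24` profile matrix.
#' @param seasonal `n_sectors x 4` profile matrix (DJF, MAM, JJA, SON).
#' @param level Named character vector per sector: `"surface"` or
#'   `"elevated"` (carried as an attribution label; single-layer transport).
#' @param n_hours Run length the hourly profiles are laid over.
#' @param totals Optional named per-sector run totals (tons) to normalize to.
#' @return An `emission_inventory` object.
#' @export
emission_inventory <- function(base, diurnal, seasonal, level, n_hours, totals = NULL) {
  if (any(base < 0) || any(diurnal < 0) || any(seasonal < 0)) {
    abort("emission inventory values must be >= 0", class = "adjointpm_input_error")
  }
  sectors <- dimnames(base)[[3]]
  if (is.null(sectors)) abort("base needs sector dimnames", class = "adjointpm_input_error")
  if (!all(sectors %in% names(level)) || !all(level[sectors] %in% c("surface", "elevated"))) {
    abort("every sector needs a surface/elevated level tag", class = "adjointpm_input_error")
  }
  season_idx <- match(season_of_hour(n_hours), c("DJF", "MAM", "JJA", "SON"))
  hod <- ((seq_len(n_hours) - 1L) %% 24L) + 1L
  prof <- diurnal[, hod, drop = FALSE] * seasonal[, season_idx, drop = FALSE]
  rownames(prof) <- sectors
  if (!is.null(totals)) {
    for (s in sectors) {
      cur <- sum(base[, , s]) * sum(prof[s, ])
      if (cur > 0) base[, , s] <- base[, , s] * totals[[s]] / cur
    }
  }
  n_cells <- dim(base)[1]; n_species <- dim(base)[2]
  structure(list(
    base = base,
    base_flat = matrix(base, n_cells * n_species, length(sectors)),
    prof = prof, sectors = sectors, level = level[sectors],
    species = dimnames(base)[[2]], n_hours = as.integer(n_hours),
    n_cells = n_cells
  ), class = "emission_inventory")
}

#' @export
emis_hour_total.emission_inventory <- function(emissions, h, model) {
  E <- matrix(emissions$base_flat %*% emissions$prof[, h],
              emissions$n_cells, length(emissions$species))
  colnames(E) <- emissions$species
  E
}

# per-sector hourly field (n_cells x n_species)
emis_hour_sector <- function(inv, h, sector) {
  E <- inv$base[, , sector] * inv$prof[sector, h]
  colnames(E) <- inv$species
  E
}

#' Run-total tons by sector and species
#'
#' @param inv An [emission_inventory()].
#' @return Tibble (sector, species, level, tons).
#' @export
emission_totals <- function(inv) {
  hrs <- rowSums(inv$prof)
  purrr::map_dfr(inv$sectors, function(s) {
    tons <- colSums(inv$base[, , s]) * hrs[s]
    tibble::tibble(sector = s, species = inv$species, level = unname(inv$level[s]),
                   tons = unname(tons))
  })
}

#' @exportS3Method base::print
print.emission_inventory <- function(x, ...) {
  tot <- emission_totals(x)
  cat(sprintf("<emission_inventory> %d sectors x %d species x %d cells x %d h; %.4g tons total\n",
              length(x$sectors), length(x$species), x$n_cells, x$n_hours, sum(tot$tons)))
  invisible(x)
}

#' Synthetic-world configuration
#'
#' One integer seed fixes every stochastic draw through named substreams, so
#' adding a generator never perturbs earlier draws. Defaults describe the
#' standard verification world: a 30 x 30 continental-scale grid run for 240
#' hours with clustered urban population, four regions, eight emission sectors
#' (seven anthropogenic plus natural), and seasonally shifting winds.
#'
#' @param seed Integer seed.
#' @param nx,ny,dx_km,dt_s,n_hours,boundary,mixing_height_m Grid parameters,
#'   see [grid_spec()].
#' @param spinup_hours Forward spin-up excluded from the exposure mean (and
#'   flagged in sensitivity aggregates).
#' @param n_regions,n_clusters Region count and urban cluster count.
#' @param total_population Domain adult (25+) population.
#' @param bmr_range Regional baseline mortality rate range (deaths/person/yr).
#' @param wind_regime `"uniform"`, `"rotational"` or `"seasonal-shift"`.
#' @param wind_speed Characteristic speed (m/s).
#' @param K Horizontal diffusivity (m2/s).
#' @param temp_amp Seasonal amplitude of the chemistry temperature index
#'   (peaks in winter, emulating cold-season secondary-inorganic formation).
#' @param o3bg Background oxidant proxy (ug/m3).
#' @param chem_mode,k_titr,gamma Chemistry options, see [chem_config()].
#' @param sector_totals Named run-total tons per sector.
#' @param vsl_base Base VSL (USD); required input for monetization.
#' @param gdp_pc_ref Reference GDP per capita (currency units).
#' @param elasticity Income elasticity for VSL transfer.
#' @param preset Internal scenario tag set by [make_scenario()].
#' @return A `world_config` list.
#' @export
world_config <- function(seed = 1L,
                         nx = 30, ny = 30, dx_km = 100, dt_s = 3600,
                         n_hours = 240, spinup_hours = 24,
                         boundary = "zero_inflow", mixing_height_m = 1000,
                         n_regions = 4, n_clusters = 5,
                         total_population = 5e7,
                         bmr_range = c(0.005, 0.015),
                         wind_regime = c("seasonal-shift", "uniform", "rotational"),
                         wind_speed = 6, K = 2000,
                         temp_amp = 0.3, o3bg = 60,
                         chem_mode = "linear", k_titr = 8e-4, gamma = 2,
                         sector_totals = c(agriculture = 120000, residential = 80000,
                                           energy = 100000, industry = 80000,
                                           transport = 70000, shipping = 20000,
                                           aviation = 5000, natural = 40000),
                         vsl_base = 3e6, gdp_pc_ref = 35000, elasticity = 0.8,
                         preset = NULL) {
  wind_regime <- match.arg(wind_regime)
  if (any(sector_totals < 0) || total_population < 0) {
    abort("totals must be >= 0", class = "adjointpm_config_error")
  }
  structure(as.list(environment()), class = "world_config")
}

# named substream seeds derived once from the master seed (order is frozen)
substreams <- function(seed) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, 8),
           c("population", "regions", "bmr", "emissions", "met", "econ",
             "reserved1", "reserved2"))
}

smooth_field <- function(ny, nx, passes = 6, sdlog = 1) {
  if (ny * nx == 1) return(matrix(1, ny, nx))
  f <- matrix(rnorm(ny * nx), ny, nx)
  for (i in seq_len(passes)) {
    up <- f[c(1, seq_len(ny - 1)), , drop = FALSE]
    dn <- f[c(seq_len(ny - 1) + 1, ny), , drop = FALSE]
    lf <- f[, c(1, seq_len(nx - 1)), drop = FALSE]
    rt <- f[, c(seq_len(nx - 1) + 1, nx), drop = FALSE]
    f <- (f + up + dn + lf + rt) / 5
  }
  exp(sdlog * f / max(stats::sd(f), 1e-12))
}

cluster_field <- function(ny, nx, centers, sigmas, weights) {
  f <- matrix(0, ny, nx)
  iy <- matrix(seq_len(ny), ny, nx)
  ix <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (j in seq_along(weights)) {
    d2 <- (iy - centers[j, 1])^2 + (ix - centers[j, 2])^2
    f <- f + weights[j] * exp(-d2 / (2 * sigmas[j]^2))
  }
  f
}

#' Generate a synthetic world
#'
#' Builds every input the pipeline needs from a [world_config()]: grid,
#' species, meteorology, a factored emission inventory, an exposure panel
#' (clustered log-normal urban population, region-constant baseline mortality),
#' a region mask, and a regional economics panel. Identical seeds yield
#' bit-identical worlds.
#'
#' @param config A [world_config()] (or a scenario from [make_scenario()]).
#' @return A `world` list: `config`, `grid`, `species`, `met`, `emissions`,
#'   `panel`, `mask`, `econ`, `population` (matrix).
#' @export
make_world <- function(config) {
  if (!inherits(config, "world_config")) abort("config must be a world_config",
                                               class = "adjointpm_config_error")
  if (!is.null(config$preset)) return(build_preset_world(config))
  ss <- substreams(config$seed)
  grid <- grid_spec(config$nx, config$ny, config$dx_km, config$dt_s,
                    config$n_hours, config$boundary, config$mixing_height_m)
  sp <- species_set()
  ny <- grid$ny; nx <- grid$nx

  # population: sum of log-normal-weighted Gaussian urban clusters
  set.seed(ss[["population"]])
  centers <- cbind(runif(config$n_clusters, 1, ny), runif(config$n_clusters, 1, nx))
  sigmas <- runif(config$n_clusters, 1.2, 2.8)
  weights <- rlnorm(config$n_clusters, 0, 1)
  pop <- cluster_field(ny, nx, centers, sigmas, weights)
  pop <- pop * config$total_population / sum(pop)

  # regions: nearest-centre partition
  set.seed(ss[["regions"]])
  rc <- cbind(runif(config$n_regions, 1, ny), runif(config$n_regions, 1, nx))
  iy <- rep(seq_len(ny), nx); ix <- rep(seq_len(nx), each = ny)
  d2 <- outer(seq_len(config$n_regions), seq_len(grid$n_cells),
              function(r, k) (iy[k] - rc[r, 1])^2 + (ix[k] - rc[r, 2])^2)
  mask <- region_mask(paste0("R", apply(d2, 2, which.min)), grid)

  set.seed(ss[["bmr"]])
  bmr_region <- setNames(runif(config$n_regions, config$bmr_range[1], config$bmr_range[2]),
                         paste0("R", seq_len(config$n_regions)))
  panel <- exposure_panel(tibble::tibble(
    iy = iy, ix = ix, population = as.numeric(pop),
    bmr = unname(bmr_region[mask$region_of_cell])
  ), grid)

  # emissions: sector-specific geography
  set.seed(ss[["emissions"]])
  sectors <- names(config$sector_totals)
  base <- array(0, c(grid$n_cells, sp$n, length(sectors)),
                dimnames = list(NULL, sp$names, sectors))
  pop_n <- as.numeric(pop) / mean(pop)
  put <- function(sector, w, split) {
    if (!sector %in% sectors) return(invisible())
    for (s in names(split)) base[, s, sector] <<- w * split[[s]]
  }
  rural <- as.numeric(smooth_field(ny, nx)) / (1 + pop_n)
  put("agriculture", rural, c(NH3 = .8, CRUST = .1, OC = .05, NOX = .05))
  put("residential", as.numeric(pop), c(OC = .35, EC = .3, SO2 = .15, NOX = .1, NH3 = .1))
  pts <- sample.int(grid$n_cells, 4)
  wp <- numeric(grid$n_cells); wp[pts] <- runif(4, 0.5, 1)
  put("energy", wp, c(SO2 = .7, NOX = .2, EC = .05, CRUST = .05))
  ind <- sample.int(grid$n_cells, 6, prob = as.numeric(pop)^0.5 + 1e-9)
  wi <- numeric(grid$n_cells); wi[ind] <- runif(6, 0.5, 1)
  put("industry", wi, c(SO2 = .4, NOX = .25, EC = .15, OC = .1, CRUST = .1))
  put("transport", as.numeric(pop)^0.7, c(NOX = .6, EC = .2, OC = .1, SO2 = .05, NH3 = .05))
  shipping <- numeric(grid$n_cells); shipping[iy <= 2] <- 1
  put("shipping", shipping, c(NOX = .5, SO2 = .4, EC = .1))
  avi <- numeric(grid$n_cells)
  avi[order(as.numeric(pop), decreasing = TRUE)[1:3]] <- 1
  put("aviation", avi, c(NOX = .8, EC = .1, OC = .1))
  put("natural", as.numeric(smooth_field(ny, nx)), c(CRUST = .6, OC = .3, NH3 = .1))

  diurnal <- default_diurnal_profiles()[sectors, , drop = FALSE]
  seasonal <- default_seasonal_profiles()[sectors, , drop = FALSE]
  level <- c(agriculture = "surface", residential = "surface", energy = "elevated",
             industry = "elevated", transport = "surface", shipping = "surface",
             aviation = "elevated", natural = "surface")[sectors]
  inv <- emission_inventory(base, diurnal, seasonal, level, grid$n_hours,
                            totals = config$sector_totals)

  set.seed(ss[["met"]])
  met <- make_met(grid, config)

  set.seed(ss[["econ"]])
  regions <- paste0("R", seq_len(config$n_regions))
  ratio <- pmin(pmax(rlnorm(config$n_regions, log(0.4), 0.9), 0.02), 3)
  econ <- econ_panel(tibble::tibble(
    region = regions,
    gdp_pc = ratio * config$gdp_pc_ref,
    gdp_pc_ref = config$gdp_pc_ref,
    cpi_change = runif(config$n_regions, 0.10, 0.35),
    income_growth = runif(config$n_regions, 0.05, 0.60),
    elasticity = config$elasticity,
    vsl_base = config$vsl_base
  ))

  structure(list(config = config, grid = grid, species = sp, met = met,
                 emissions = inv, panel = panel, mask = mask, econ = econ,
                 population = pop),
            class = "world")
}

default_diurnal_profiles <- function() {
  h <- 1:24
  peak <- function(center, width) exp(-((h - center)^2) / (2 * width^2))
  m <- rbind(
    agriculture = 0.3 + peak(13, 4),
    residential = 0.5 + peak(7, 1.5) + peak(20, 2.5),
    energy      = rep(1, 24),
    industry    = 0.6 + peak(13, 5),
    transport   = 0.3 + peak(8, 1.5) + peak(18, 2),
    shipping    = rep(1, 24),
    aviation    = 0.5 + peak(14, 5),
    natural     = 0.6 + peak(14, 5)
  )
  sweep(m, 1, rowMeans(m), `/`)
}

default_seasonal_profiles <- function() {
  m <- rbind(
    agriculture = c(0.7, 1.2, 1.3, 0.8),
    residential = c(1.6, 0.9, 0.6, 0.9),
    energy      = c(1.2, 0.9, 1.0, 0.9),
    industry    = c(1, 1, 1, 1),
    transport   = c(1, 1, 1, 1),
    shipping    = c(1, 1, 1, 1),
    aviation    = c(0.9, 1, 1.2, 0.9),
    natural     = c(0.7, 1.0, 1.4, 0.9)
  )
  colnames(m) <- c("DJF", "MAM", "JJA", "SON")
  m
}

make_met <- function(grid, config) {
  N <- grid$n_hours; ny <- grid$ny; nx <- grid$nx
  u <- array(0, c(N, ny, nx)); v <- array(0, c(N, ny, nx))
  theta0 <- runif(1, 0, 2 * pi)
  spat <- 1 + 0.15 * (smooth_field(ny, nx, sdlog = 0.3) - 1)  # mild spatial modulation
  spat <- pmin(pmax(spat, 0.7), 1.3)
  season_idx <- match(season_of_hour(N), c("DJF", "MAM", "JJA", "SON"))
  for (h in seq_len(N)) {
    if (config$wind_regime == "rotational") {
      yc <- (ny + 1) / 2; xc <- (nx + 1) / 2
      ry <- matrix(seq_len(ny), ny, nx) - yc
      rx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - xc
      rmax <- max(sqrt(ry^2 + rx^2), 1e-9)
      omega <- config$wind_speed / rmax
      u[h, , ] <- -omega * ry
      v[h, , ] <- omega * rx
    } else {
      th <- theta0 + 0.15 * sin(2 * pi * h / 24)
      if (config$wind_regime == "seasonal-shift") th <- th + (season_idx[h] - 1) * pi / 2
      u[h, , ] <- config$wind_speed * cos(th) * spat
      v[h, , ] <- config$wind_speed * sin(th) * spat
    }
  }
  p <- (seq_len(N) - 1) / N
  temp_index <- 1 + config$temp_amp * cos(2 * pi * (p - 0.125))
  met_fields(u, v, temp_index, config$o3bg, grid)
}

#' Build the transport model for a world
#'
#' @param world A [make_world()] result.
#' @return A [ctm_model()].
#' @export
world_model <- function(world) {
  cfg <- world$config
  ctm_model(world$grid, world$species, world$met,
            chem_config(cfg$chem_mode, k_titr = cfg$k_titr, gamma = cfg$gamma),
            K = cfg$K)
}

#' Named fixture scenarios
#'
#' Documented worlds used by the tests and the vignette:
#' * `box` — 1 x 1 grid, zero wind/diffusion: the analytic box model whose
#'   adjoint has a geometric-series closed form.
#' * `plume` — one emitting cell strictly upwind of one populated cell.
#' * `two_region` — two regions with different GDP (hence VSL) but comparable
#'   emissions, for monetization checks.
#' * `titration_demo` — NOx-saturated city under the titration chemistry, so
#'   annual NOx sensitivities go negative near the receptor.
#' * `seasonal_demo` — winter-boosted gas-to-particle conversion, so winter
#'   NH3 sensitivities exceed summer ones.
#'
#' @param name Scenario name.
#' @param seed Seed for any remaining stochastic draws.
#' @return A [world_config()] with the scenario preset attached.
#' @export
make_scenario <- function(name = c("box", "plume", "two_region",
                                   "titration_demo", "seasonal_demo"),
                          seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    box = world_config(seed, nx = 1, ny = 1, n_hours = 48, spinup_hours = 0,
                       wind_regime = "uniform", wind_speed = 0, K = 0,
                       n_regions = 1, n_clusters = 1, total_population = 1e6,
                       sector_totals = c(residential = 200)),
    plume = world_config(seed, nx = 12, ny = 5, n_hours = 96, spinup_hours = 12,
                         wind_regime = "uniform", wind_speed = 8, K = 500,
                         n_regions = 1, total_population = 2e6,
                         sector_totals = c(residential = 30000)),
    two_region = world_config(seed, nx = 10, ny = 10, n_hours = 120, spinup_hours = 12,
                              wind_regime = "uniform", wind_speed = 5,
                              n_regions = 2, total_population = 1e7,
                              sector_totals = c(residential = 30000, agriculture = 20000)),
    titration_demo = world_config(seed, nx = 10, ny = 10, n_hours = 120, spinup_hours = 12,
                                  wind_regime = "uniform", wind_speed = 4, K = 1000,
                                  chem_mode = "titration", o3bg = 40, gamma = 2,
                                  k_titr = 8e-4,
                                  n_regions = 1, total_population = 8e6,
                                  sector_totals = c(transport = 60000, residential = 8000)),
    seasonal_demo = world_config(seed, nx = 15, ny = 15, n_hours = 240, spinup_hours = 24,
                                 temp_amp = 0.8, wind_regime = "seasonal-shift",
                                 n_regions = 2, total_population = 2e7,
                                 sector_totals = c(agriculture = 80000, residential = 20000))
  )
  cfg$preset <- name
  cfg
}

# deterministic fixture worlds; share the inventory/panel machinery
build_preset_world <- function(config) {
  ss <- substreams(config$seed)
  grid <- grid_spec(config$nx, config$ny, config$dx_km, config$dt_s,
                    config$n_hours, config$boundary, config$mixing_height_m)
  sp <- species_set()
  ny <- grid$ny; nx <- grid$nx
  iy <- rep(seq_len(ny), nx); ix <- rep(seq_len(nx), each = ny)
  pop <- matrix(0, ny, nx)
  base <- NULL; level <- NULL; region <- rep("R1", grid$n_cells)
  sectors <- names(config$sector_totals)
  mk_base <- function() array(0, c(grid$n_cells, sp$n, length(sectors)),
                              dimnames = list(NULL, sp$names, sectors))

  if (config$preset == "box") {
    pop[1, 1] <- config$total_population
    base <- mk_base()
    base[1, "EC", "residential"] <- 1
    level <- c(residential = "surface")
  } else if (config$preset == "plume") {
    src <- cell_index(3L, 3L, grid); city <- cell_index(3L, 9L, grid)
    pop[3, 9] <- config$total_population
    base <- mk_base()
    base[src, "EC", "residential"] <- 1
    level <- c(residential = "surface")
  } else if (config$preset == "two_region") {
    region <- ifelse(ix <= nx / 2, "R1", "R2")
    pop[5, 3] <- config$total_population * 0.5
    pop[5, 8] <- config$total_population * 0.5
    base <- mk_base()
    base[cell_index(5L, 3L, grid), c("EC", "OC"), "residential"] <- c(.5, .5)
    base[cell_index(5L, 8L, grid), c("EC", "OC"), "residential"] <- c(.5, .5)
    base[cell_index(3L, 3L, grid), "NH3", "agriculture"] <- 1
    base[cell_index(3L, 8L, grid), "NH3", "agriculture"] <- 1
    level <- c(residential = "surface", agriculture = "surface")
  } else if (config$preset == "titration_demo") {
    cy <- 5L; cx <- 5L
    pop[cy, cx] <- config$total_population * 0.8
    pop[cy, cx + 1L] <- config$total_population * 0.2
    base <- mk_base()
    k_city <- cell_index(cy, cx, grid)
    base[k_city, "NOX", "transport"] <- 0.9
    base[k_city, "EC", "transport"] <- 0.1
    base[k_city, c("EC", "OC"), "residential"] <- c(.5, .5)
    level <- c(transport = "surface", residential = "surface")
  } else if (config$preset == "seasonal_demo") {
    set.seed(ss[["population"]])
    centers <- cbind(runif(3, 3, ny - 2), runif(3, 3, nx - 2))
    pop <- cluster_field(ny, nx, centers, rep(1.8, 3), rlnorm(3, 0, 0.5))
    pop <- pop * config$total_population / sum(pop)
    region <- ifelse(ix <= nx / 2, "R1", "R2")
    set.seed(ss[["emissions"]])
    base <- mk_base()
    rural <- as.numeric(smooth_field(ny, nx)) / (1 + as.numeric(pop) / mean(pop))
    base[, "NH3", "agriculture"] <- rural * 0.9
    base[, "CRUST", "agriculture"] <- rural * 0.1
    base[, "OC", "residential"] <- as.numeric(pop) * 0.5
    base[, "EC", "residential"] <- as.numeric(pop) * 0.5
    level <- c(agriculture = "surface", residential = "surface")
  }

  dn <- default_diurnal_profiles(); sn <- default_seasonal_profiles()
  extra <- setdiff(sectors, rownames(dn))
  if (length(extra)) {
    dn <- rbind(dn, matrix(1, length(extra), 24, dimnames = list(extra)))
    sn <- rbind(sn, matrix(1, length(extra), 4, dimnames = list(extra)))
  }
  flat <- config$preset %in% c("box", "plume", "two_region")
  diurnal <- if (flat) matrix(1, length(sectors), 24, dimnames = list(sectors)) else dn[sectors, , drop = FALSE]
  seasonal <- if (flat) matrix(1, length(sectors), 4, dimnames = list(sectors)) else sn[sectors, , drop = FALSE]
  inv <- emission_inventory(base, diurnal, seasonal, level, grid$n_hours,
                            totals = config$sector_totals)

  mask <- region_mask(region, grid)
  set.seed(ss[["bmr"]])
  regions <- mask$regions
  bmr_region <- setNames(rep(0.01, length(regions)), regions)
  panel <- exposure_panel(tibble::tibble(
    iy = iy, ix = ix, population = as.numeric(pop),
    bmr = unname(bmr_region[mask$region_of_cell])
  ), grid)

  set.seed(ss[["met"]])
  met <- make_met(grid, config)
  if (config$preset == "plume") {
    # steady eastward flow so the populated cell sits strictly downwind
    met$u[] <- config$wind_speed
    met$v[] <- 0
  }

  gdp_ratio <- if (config$preset == "two_region") c(R1 = 1, R2 = 0.25) else
    setNames(rep(1, length(regions)), regions)
  econ <- econ_panel(tibble::tibble(
    region = regions,
    gdp_pc = unname(gdp_ratio[regions]) * config$gdp_pc_ref,
    gdp_pc_ref = config$gdp_pc_ref,
    cpi_change = 0, income_growth = 0,
    elasticity = config$elasticity, vsl_base = config$vsl_base
  ))

  structure(list(config = config, grid = grid, species = sp, met = met,
                 emissions = inv, panel = panel, mask = mask, econ = econ,
                 population = pop),
            class = "world")
}

#' @exportS3Method base::print
print.world <- function(x, ...) {
  cat(sprintf("<world> seed %d%s: %dx%d grid, %d h, %d regions, %d sectors, pop %.3g\n",
              x$config$seed,
              if (!is.null(x$config$preset)) paste0(" (", x$config$preset, ")") else "",
              x$grid$nx, x$grid$ny, x$grid$n_hours, length(x$mask$regions),
              length(x$emissions$sectors), sum(x$population)))
  invisible(x)
}
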