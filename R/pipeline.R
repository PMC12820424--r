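# Stage-based pipeline: synth -> forward -> forcing -> adjoint (deaths and
# USD) -> attribute -> validate, with a run manifest, config hashing and
# skip-if-up-to-date semantics.

#' Write / read a synthetic world to a directory
#'
#' Serializes every pipeline input in the package's text formats: config JSON,
#' met fields and factored emission inventory as gridded CSV, and the
#' exposure/region/economics tables as CSV.
#'
#' @param world A [make_world()] world.
#' @param dir Output directory (created if needed).
#' @return `dir` / the reconstructed world.
#' @export
world_write <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- world$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  g <- world$grid
  write_gridded(world$met$u, file.path(dir, "met_u.csv"), c("hour", "y", "x"), "m/s")
  write_gridded(world$met$v, file.path(dir, "met_v.csv"), c("hour", "y", "x"), "m/s")
  write_gridded(world$met$o3bg, file.path(dir, "met_o3bg.csv"), c("y", "x"), "ug/m3")
  jsonlite::write_json(list(temp_index = world$met$temp_index),
                       file.path(dir, "met_scalars.json"), digits = NA)
  inv <- world$emissions
  base <- array(inv$base, c(g$ny, g$nx, length(inv$species), length(inv$sectors)))
  dimnames(base) <- list(NULL, NULL, inv$species, inv$sectors)
  write_gridded(base, file.path(dir, "emissions_base.csv"),
                c("y", "x", "species", "sector"), "tons/hr",
                extra = list(level = as.list(inv$level)))
  jsonlite::write_json(list(prof = as.data.frame(t(inv$prof))),
                       file.path(dir, "emissions_prof.json"), digits = NA)
  write_exposure_panel(world$panel, file.path(dir, "panel.csv"))
  write_table_csv(tibble::tibble(cell = seq_len(g$n_cells),
                                 region = world$mask$region_of_cell),
                  file.path(dir, "mask.csv"))
  write_econ_panel(world$econ, file.path(dir, "econ.csv"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname world_write
#' @export
world_read <- function(dir) {
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  cfg$preset <- cfg$preset %||% NULL
  args <- cfg[intersect(names(cfg), names(formals(world_config)))]
  args$sector_totals <- unlist(cfg$sector_totals)
  args$bmr_range <- unlist(cfg$bmr_range)
  config <- do.call(world_config, args[setdiff(names(args), "preset")])
  config$preset <- cfg$preset
  grid <- grid_spec(config$nx, config$ny, config$dx_km, config$dt_s,
                    config$n_hours, config$boundary, config$mixing_height_m)
  sp <- species_set()
  u <- read_gridded(file.path(dir, "met_u.csv"), require_dims = c("hour", "y", "x"))
  v <- read_gridded(file.path(dir, "met_v.csv"), require_dims = c("hour", "y", "x"))
  o3 <- read_gridded(file.path(dir, "met_o3bg.csv"))
  ti <- jsonlite::fromJSON(file.path(dir, "met_scalars.json"))$temp_index
  met <- met_fields(array(u, dim(u)), array(v, dim(v)), ti,
                    matrix(o3, grid$ny, grid$nx), grid)
  baseg <- read_gridded(file.path(dir, "emissions_base.csv"),
                        require_dims = c("species", "sector"))
  sectors <- dimnames(baseg)[[4]]
  base <- array(baseg, c(grid$n_cells, dim(baseg)[3], length(sectors)))
  dimnames(base) <- list(NULL, dimnames(baseg)[[3]], sectors)
  prof <- t(as.matrix(jsonlite::fromJSON(file.path(dir, "emissions_prof.json"))$prof))
  rownames(prof) <- sectors
  level <- unlist(attr(baseg, "level"))
  inv <- structure(list(
    base = base, base_flat = matrix(base, prod(dim(base)[1:2]), length(sectors)),
    prof = prof, sectors = sectors, level = level[sectors],
    species = dimnames(base)[[2]], n_hours = grid$n_hours,
    n_cells = grid$n_cells
  ), class = "emission_inventory")
  panel <- read_exposure_panel(file.path(dir, "panel.csv"), grid)
  mask_df <- read.csv(file.path(dir, "mask.csv"))
  mask <- region_mask(mask_df$region[order(mask_df$cell)], grid)
  econ <- read_econ_panel(file.path(dir, "econ.csv"))
  pop <- matrix(panel$population, grid$ny, grid$nx)
  structure(list(config = config, grid = grid, species = sp, met = met,
                 emissions = inv, panel = panel, mask = mask, econ = econ,
                 population = pop),
            class = "world")
}

#' Read and validate a pipeline configuration file
#'
#' A JSON file with a `world` section (fields of [world_config()]) and an
#' optional `pipeline` section (`f`, `n_probes`, `scenario`). Unknown fields
#' are field-level errors.
#'
#' @param path JSON config path.
#' @return List with `world` (a [world_config()]) and `pipeline` options.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  unknown <- setdiff(names(cfg), c("world", "pipeline"))
  if (length(unknown)) abort(paste("unknown config section(s):", paste(unknown, collapse = ", ")),
                             class = "adjointpm_config_error")
  wc <- cfg$world %||% list()
  if (!is.null(wc$scenario)) {
    world <- make_scenario(wc$scenario, seed = wc$seed %||% 1L)
  } else {
    bad <- setdiff(names(wc), names(formals(world_config)))
    if (length(bad)) abort(paste("unknown world config field(s):", paste(bad, collapse = ", ")),
                           class = "adjointpm_config_error")
    if (!is.null(wc$sector_totals)) wc$sector_totals <- unlist(wc$sector_totals)
    if (!is.null(wc$bmr_range)) wc$bmr_range <- unlist(wc$bmr_range)
    world <- do.call(world_config, wc)
  }
  pl <- cfg$pipeline %||% list()
  bad <- setdiff(names(pl), c("f", "n_probes", "monetize", "delta_rel"))
  if (length(bad)) abort(paste("unknown pipeline config field(s):", paste(bad, collapse = ", ")),
                         class = "adjointpm_config_error")
  list(world = world, pipeline = modifyList(list(f = 0.1, n_probes = 12,
                                                 monetize = TRUE, delta_rel = 0.01), pl))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

stage_log <- function(manifest, stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
  invisible(manifest)
}

#' Run the attribution pipeline
#'
#' Executes the requested stages in dependency order — `synth` (generate and
#' serialize the world), `forward` (transport run), `forcing` (GEMM gradient),
#' `adjoint` (mortality sensitivities, plus monetized twin), `attribute`
#' (burden roll-ups), `validate` (adjoint-vs-FDM report) — skipping stages
#' whose outputs already exist under the same config hash. Per-stage JSON
#' summaries are logged and collected in the run manifest.
#'
#' @param config A [world_config()], a scenario name, or a path to a JSON
#'   pipeline config (see [read_pipeline_config()]).
#' @param outdir Output directory.
#' @param stages Subset of stages to run (dependencies must already exist).
#' @param f Reduction fraction for the attribution stage.
#' @param n_probes Probes for the validation stage.
#' @return The run manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("synth", "forward", "forcing", "adjoint",
                                    "attribute", "validate"),
                         f = 0.1, n_probes = 12) {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    pc <- read_pipeline_config(config)
    config <- pc$world
    f <- pc$pipeline$f; n_probes <- pc$pipeline$n_probes
  } else if (is.character(config)) {
    config <- make_scenario(config)
  }
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(config))
  man_path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(man_path)) jsonlite::fromJSON(man_path, simplifyVector = FALSE)
              else list(config_hash = hash, seed = config$seed, stages = list())
  if (!identical(manifest$config_hash, hash)) {
    manifest <- list(config_hash = hash, seed = config$seed, stages = list())
  }
  paths <- list(
    synth = file.path(outdir, "world"),
    forward = file.path(outdir, "trajectory.csv"),
    forcing = file.path(outdir, "forcing.csv"),
    adjoint = file.path(outdir, "sensitivity_deaths.csv"),
    adjoint_usd = file.path(outdir, "sensitivity_usd.csv"),
    attribute = file.path(outdir, "burden.csv"),
    validate = file.path(outdir, "fdm_report.csv")
  )
  done <- function(stage) {
    p <- paths[[stage]]
    (dir.exists(p) || file.exists(p)) && !is.null(manifest$stages[[stage]])
  }
  run_stage <- function(stage, fn) {
    if (done(stage)) {
      stage_log(manifest, stage, "up to date, skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    summary <- fn()
    manifest$stages[[stage]] <<- list(
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = paths[[stage]], summary = summary)
    stage_log(manifest, stage, jsonlite::toJSON(summary, auto_unbox = TRUE, digits = 6))
  }

  env <- new.env()
  get_world <- function() {
    if (is.null(env$world)) {
      env$world <- if (dir.exists(paths$synth) && done("synth")) world_read(paths$synth)
                   else make_world(config)
    }
    env$world
  }
  get_model <- function() {
    if (is.null(env$model)) env$model <- world_model(get_world())
    env$model
  }
  get_traj <- function() {
    if (is.null(env$traj)) {
      w <- get_world()
      env$traj <- run_forward(get_model(), w$emissions,
                              spinup_hours = w$config$spinup_hours)
    }
    env$traj
  }
  get_sens <- function() {
    if (is.null(env$sens)) {
      if (file.exists(paths$adjoint) && done("adjoint")) {
        env$sens <- read_sensitivity(paths$adjoint)
        env$sens_usd <- read_sensitivity(paths$adjoint_usd)
      } else {
        w <- get_world(); traj <- get_traj()
        forcing <- gemm_forcing(traj, w$panel)
        env$sens <- run_adjoint(get_model(), forcing, traj)
        vsl <- vsl_map(w$mask, vsl_transfer(w$econ))
        forcing_usd <- gemm_forcing(traj, w$panel, vsl = vsl)
        env$sens_usd <- run_adjoint(get_model(), forcing_usd, traj)
      }
    }
    list(deaths = env$sens, usd = env$sens_usd)
  }

  if ("synth" %in% stages) run_stage("synth", function() {
    w <- get_world()
    world_write(w, paths$synth)
    list(n_cells = w$grid$n_cells, population = sum(w$population),
         total_tons = sum(emission_totals(w$emissions)$tons))
  })
  if ("forward" %in% stages) run_stage("forward", function() {
    traj <- get_traj()
    write_trajectory(traj, paths$forward)
    list(mean_pm = mean(traj$pm_mean), max_pm = max(traj$pm_mean))
  })
  if ("forcing" %in% stages) run_stage("forcing", function() {
    w <- get_world()
    fo <- gemm_forcing(get_traj(), w$panel)
    J <- gemm_mortality(get_traj(), w$panel)
    write_gridded(matrix(fo$phi_cell, w$grid$ny, w$grid$nx), paths$forcing,
                  c("y", "x"), "deaths per ug/m3",
                  extra = list(n_eff = fo$n_eff, hours = fo$hours))
    list(total_J_deaths = J$total, active_cells = sum(fo$phi_cell > 0))
  })
  if ("adjoint" %in% stages) run_stage("adjoint", function() {
    s <- get_sens()
    write_sensitivity(s$deaths, paths$adjoint)
    write_sensitivity(s$usd, paths$adjoint_usd)
    list(max_deaths_per_kton = max(s$deaths$sens) * 1000,
         max_usd_per_ton = max(s$usd$sens))
  })
  if ("attribute" %in% stages) run_stage("attribute", function() {
    w <- get_world(); s <- get_sens()
    rep <- reduction_burden(s$deaths, w$emissions, w$mask, f = f, sens_usd = s$usd)
    write_table_csv(rep$table, paths$attribute)
    write_table_csv(sector_contribution(rep), file.path(outdir, "sectors.csv"))
    write_table_csv(seasonal_summary(s$deaths), file.path(outdir, "seasonal.csv"))
    census <- negative_sensitivity_census(s$deaths)
    list(f = f, total_deaths = rep$total_deaths, total_usd = rep$total_usd,
         negative_cells = sum(census$n_negative))
  })
  if ("validate" %in% stages) run_stage("validate", function() {
    w <- get_world()
    repo <- adjoint_vs_fdm_report(w, n_probes = n_probes, seed = config$seed)
    write_table_csv(repo$table, paths$validate)
    glance(repo) |> as.list()
  })
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(manifest)
}
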