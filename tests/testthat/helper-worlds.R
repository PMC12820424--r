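# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

box_world <- function() fixture("box", function() make_world(make_scenario("box")))
plume_world <- function() fixture("plume", function() make_world(make_scenario("plume")))
two_region_world <- function() fixture("two_region", function() make_world(make_scenario("two_region")))

# small random world for property tests (fast: 8x7 cells, 24 h)
small_world <- function() fixture("small", function() {
  make_world(world_config(seed = 11, nx = 8, ny = 7, n_hours = 24, spinup_hours = 4,
                          total_population = 2e6,
                          sector_totals = c(agriculture = 3000, residential = 2000,
                                            energy = 2500, transport = 1500,
                                            natural = 1000)))
})

small_model <- function() fixture("small_model", function() world_model(small_world()))

# species set with zero deposition and zero chemistry, for conservation tests
inert_species <- function() {
  tb <- default_species_table()
  tb$dep_rate <- 0
  species_set(tb)
}

zero_chem <- function() chem_config(k = c(SO2 = 0, NOX = 0, NH3 = 0))

# uniform-wind met fields
uniform_met <- function(grid, u = 0, v = 0, temp_index = NULL, o3bg = 60) {
  met_fields(array(u, c(grid$n_hours, grid$ny, grid$nx)),
             array(v, c(grid$n_hours, grid$ny, grid$nx)),
             temp_index, o3bg, grid)
}

# total mass in the domain (ug/m3 summed over cells; volumes are uniform)
domain_mass <- function(field) sum(field)

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.xmin)
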