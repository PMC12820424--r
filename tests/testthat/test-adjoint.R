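test_that("one-step duality: <forward(x), y> = <x, adjoint(y)> to machine precision", {
  m <- small_model()
  sp <- m$species
  forward_step <- function(C, h) {
    C <- chemistry_step(C, sp, m$chem, m$met$temp_index[h], as.numeric(m$met$o3bg))$conc
    C <- deposit(C, sp$dep_rate)
    as.matrix(m$diff %*% (m$adv[[h]] %*% C))
  }
  set.seed(21)
  for (h in c(1, 7, 20)) {
    x <- matrix(abs(rnorm(m$grid$n_cells * sp$n)), m$grid$n_cells, sp$n,
                dimnames = list(NULL, sp$names))
    y <- matrix(rnorm(m$grid$n_cells * sp$n), m$grid$n_cells, sp$n,
                dimnames = list(NULL, sp$names))
    lhs <- sum(forward_step(x, h) * y)
    rhs <- sum(x * adjoint_step(y, m, h))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-12)
  }
})

test_that("zero forcing propagates to identically zero sensitivities", {
  m <- small_model()
  w <- small_world()
  tr <- run_forward(m, w$emissions, spinup_hours = 0)
  fo <- linear_forcing(rep(0, m$grid$n_cells), tr)
  s <- run_adjoint(m, fo, tr)
  expect_true(all(s$sens == 0))
})

test_that("sensitivities scale linearly with forcing magnitude", {
  m <- small_model()
  w <- small_world()
  tr <- run_forward(m, w$emissions, spinup_hours = 4)
  set.seed(3)
  wts <- runif(m$grid$n_cells)
  s1 <- run_adjoint(m, linear_forcing(wts, tr), tr)
  s3 <- run_adjoint(m, linear_forcing(3 * wts, tr), tr)
  expect_equal(s3$sens, 3 * s1$sens, tolerance = 1e-12)
})

test_that("adjoint of eastward advection carries receptor influence upwind (westward)", {
  w <- plume_world()
  # pure advection model (K = 0) so downwind cells are exactly causally isolated
  m <- ctm_model(w$grid, w$species, w$met, chem_config(), K = 0)
  tr <- run_forward(m, w$emissions, spinup_hours = w$config$spinup_hours)
  fo <- gemm_forcing(tr, w$panel)
  s <- run_adjoint(m, fo, tr)
  ann <- apply(s$sens[, "EC", ], 1, sum)
  grid <- m$grid
  receptor_x <- 9
  east <- which(rep(seq_len(grid$nx), each = grid$ny) > receptor_x)
  west <- 3 + (seq(3, receptor_x - 1) - 1) * grid$ny  # row-3 cells in the upwind corridor
  expect_true(all(ann[east] == 0))   # strictly downwind of the receptor: no influence
  expect_true(all(ann[west] > 0))    # upwind corridor: positive influence
})

test_that("1x1 adjoint equals the geometric-series closed form", {
  w <- box_world()
  m <- world_model(w)
  tr <- run_forward(m, w$emissions, spinup_hours = 0)
  fo <- gemm_forcing(tr, w$panel)
  s <- run_adjoint(m, fo, tr)
  k <- m$species$dep_rate[["EC"]]
  N <- m$grid$n_hours
  phi <- fo$per_hour[1]
  for (n in c(1, 10, 25, N)) {
    # emission pulse at hour n survives its own-hour deposition (factor e^-k),
    # then decays geometrically through the forced stored states n..N
    closed <- m$uconv * phi * exp(-k) * (1 - exp(-k * (N - n + 1))) / (1 - exp(-k))
    expect_lt(abs(s$sens[1, "EC", n] - closed) / closed, 1e-10)
  }
  # gradient w.r.t. a unit pulse in the initial state: pure decay series
  closed0 <- phi * exp(-k) * (1 - exp(-k * N)) / (1 - exp(-k))
  expect_lt(abs(s$lambda0[1, "EC"] - closed0) / closed0, 1e-10)
})

test_that("precursor sensitivity flows only through its secondary-product channel", {
  g <- grid_spec(1, 1, 100, n_hours = 24)
  sp <- species_set()
  met <- uniform_met(g)
  # with SO2 -> pSO4 conversion off, SO2 emissions cannot reach the PM cost
  m_off <- ctm_model(g, sp, met, chem_config(k = c(SO2 = 0, NOX = 0.04, NH3 = 0.08)), K = 0)
  m_on <- ctm_model(g, sp, met, chem_config(), K = 0)
  E <- matrix(0, 1, sp$n, dimnames = list(NULL, sp$names)); E[1, "SO2"] <- 5
  fo <- structure(list(phi_cell = 1, per_hour = 1 / 24, hours = 1:24, n_eff = 24L,
                       units = "deaths"), class = "adjoint_forcing")
  tr_off <- run_forward(m_off, E, spinup_hours = 0)
  tr_on <- run_forward(m_on, E, spinup_hours = 0)
  s_off <- run_adjoint(m_off, fo, tr_off)
  s_on <- run_adjoint(m_on, fo, tr_on)
  expect_true(all(s_off$sens[, "SO2", ] == 0))
  expect_true(all(s_on$sens[, "SO2", 1:23] > 0))
})

test_that("global duality: adjoint gradient reproduces the forward response exactly (linear cost)", {
  m <- small_model()
  w <- small_world()
  g <- m$grid; sp <- m$species
  tr <- run_forward(m, w$emissions, spinup_hours = 4)
  set.seed(31)
  wts <- runif(g$n_cells)
  s <- run_adjoint(m, linear_forcing(wts, tr), tr)
  Earr <- array(0, c(g$n_cells, sp$n, g$n_hours))
  for (h in seq_len(g$n_hours)) Earr[, , h] <- emis_hour_total(w$emissions, h, m)
  dE <- array(abs(rnorm(length(Earr), sd = 0.2)), dim(Earr))
  J0 <- linear_cost(tr, wts)
  J1 <- linear_cost(run_forward(m, Earr + dE, spinup_hours = 4), wts)
  pred <- sum(s$sens * dE)
  expect_lt(abs((J1 - J0) - pred) / abs(pred), 1e-8)
})

test_that("emission-weighted primary-PM aggregation is a proper weighted mean", {
  g <- grid_spec(1, 1, 100, n_hours = 2)
  sp <- species_set()
  m <- ctm_model(g, sp, uniform_met(g), chem_config(), K = 0)
  sens <- structure(list(
    sens = array(0, c(1, sp$n, 2), dimnames = list(NULL, sp$names, NULL)),
    grid = g, species = sp, units = "deaths_per_ton", spinup_hours = 0L
  ), class = "sensitivity_field")
  # deaths/kton (10, 20) with emissions (3, 1) tons -> 12.5 deaths/kton
  sens$sens[1, c("EC", "OC", "CRUST"), ] <- c(0.010, 0.020, 0.7)
  E <- matrix(0, 1, sp$n, dimnames = list(NULL, sp$names))
  E[1, c("EC", "OC")] <- c(3, 1)  # CRUST emission zero: its sens carries no weight
  agg <- emission_weighted_primary_pm(sens, E, m)
  expect_equal(unname(agg$sens[1, 1, 1]) * 1000, 12.5)
  # rescaling all emissions leaves the weights invariant
  agg2 <- emission_weighted_primary_pm(sens, 7 * E, m)
  expect_equal(agg$sens, agg2$sens)
  # equal species sensitivities pass through regardless of weights
  sens$sens[1, c("EC", "OC", "CRUST"), ] <- 0.004
  agg3 <- emission_weighted_primary_pm(sens, E, m)
  expect_equal(as.numeric(agg3$sens), rep(0.004, 2))
  # zero-emission cell-hours fall back to the unweighted mean
  agg4 <- emission_weighted_primary_pm(sens, 0 * E, m)
  expect_equal(as.numeric(agg4$sens), rep(0.004, 2))
})

test_that("titration adjoint requires the stored checkpoint and names the missing hour", {
  w <- make_world(make_scenario("titration_demo"))
  m <- world_model(w)
  tr <- run_forward(m, w$emissions, spinup_hours = 12, store = FALSE)
  fo <- gemm_forcing(tr, w$panel)
  expect_error(run_adjoint(m, fo, tr), class = "adjointpm_state_error")
  expect_error(adjoint_step(matrix(0, m$grid$n_cells, m$species$n), m, 5),
               regexp = "hour 5", class = "adjointpm_state_error")
})
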