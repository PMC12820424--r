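test_that("grid_spec validates geometry and timestep", {
  g <- grid_spec(4, 3, 100)
  expect_equal(g$cell_area_m2, 1e10)
  expect_equal(g$n_cells, 12L)
  expect_error(grid_spec(0, 3, 100), class = "adjointpm_config_error")
  expect_error(grid_spec(4, 3, -1), class = "adjointpm_config_error")
  expect_error(grid_spec(4, 3, 100, dt_s = 1000), class = "adjointpm_config_error")
})

test_that("advection: uniform field unchanged, CFL=1 pulse shifts one cell, mass conserved", {
  g <- grid_spec(6, 5, 100, boundary = "periodic")
  u <- matrix(7, g$ny, g$nx); v <- matrix(-3, g$ny, g$nx)
  # gradient-free field is invariant under any admissible wind
  f <- matrix(2.5, g$ny, g$nx)
  expect_equal(advect(f, u, v, g), f)
  # CFL = 1 eastward: pure shift by one cell
  uu <- matrix(g$dx_m / g$dt_s, g$ny, g$nx); vv <- matrix(0, g$ny, g$nx)
  pulse <- matrix(0, g$ny, g$nx); pulse[3, 2] <- 1
  shifted <- advect(pulse, uu, vv, g)
  expected <- matrix(0, g$ny, g$nx); expected[3, 3] <- 1
  expect_equal(shifted, expected)
  # periodic boundary conserves mass to machine precision
  set.seed(1)
  r <- matrix(runif(g$n_cells), g$ny, g$nx)
  r2 <- advect(r, u, v, g)
  expect_lt(abs(sum(r2) - sum(r)) / sum(r), 1e-12)
  # zero-inflow boundary: mass is non-increasing
  gz <- grid_spec(6, 5, 100, boundary = "zero_inflow")
  r3 <- advect(r, u, v, gz)
  expect_lte(sum(r3), sum(r) + 1e-12)
  expect_lt(sum(r3), sum(r))  # outflow actually happens with this wind
})

test_that("advection refuses CFL violations with a named diagnostic", {
  g <- grid_spec(4, 4, 50, dt_s = 3600)
  u <- matrix(30, 4, 4); v <- matrix(0, 4, 4)  # 30 m/s * 3600 s / 50 km > 1
  err <- expect_error(advect(matrix(1, 4, 4), u, v, g), class = "adjointpm_config_error")
  expect_match(conditionMessage(err), "CFL")
  expect_match(conditionMessage(err), "dx")
})

test_that("diffusion: identity at K=0, exact hand stencil, conservation, spread reduction", {
  g <- grid_spec(5, 5, 100, boundary = "periodic")
  set.seed(2)
  f <- matrix(runif(25), 5, 5)
  expect_equal(diffuse(f, 0, g), f)
  expect_equal(diffuse(matrix(3, 5, 5), 1500, g), matrix(3, 5, 5))
  # single pulse: centre loses 4*d*pulse, each neighbour gains d*pulse
  K <- 2000; d <- K * g$dt_s / g$dx_m^2
  pulse <- matrix(0, 5, 5); pulse[3, 3] <- 1
  out <- diffuse(pulse, K, g)
  expect_equal(out[3, 3], 1 - 4 * d)
  expect_equal(out[2, 3], d); expect_equal(out[4, 3], d)
  expect_equal(out[3, 2], d); expect_equal(out[3, 4], d)
  # conservation and contraction
  out2 <- diffuse(f, K, g)
  expect_lt(abs(sum(out2) - sum(f)) / sum(f), 1e-12)
  expect_lte(max(out2) - min(out2), max(f) - min(f))
  expect_error(diffuse(f, 1e6, g), class = "adjointpm_config_error")
})

test_that("chemistry: identity at zero rates, first-order decay, conservation of converted mass", {
  sp <- species_set()
  conc <- matrix(1, 4, sp$n, dimnames = list(NULL, sp$names))
  conc[, "SO2"] <- c(2, 4, 0, 1)
  out0 <- chemistry_step(conc, sp, zero_chem())
  expect_equal(out0$conc, conc)
  ch <- chem_config(k = c(SO2 = 0.1, NOX = 0, NH3 = 0))
  out <- chemistry_step(conc, sp, ch)
  expect_equal(out$conc[, "SO2"], conc[, "SO2"] * (1 - 0.1))
  expect_equal(out$conc[, "pSO4"], conc[, "pSO4"] + 1 * 0.1 * conc[, "SO2"])
  # reacted gas mass equals yield x particle gain (yield = 1 here)
  expect_equal(sum(conc) - sum(out$conc), 0)
  expect_error(chemistry_step(conc - 5, sp, ch), class = "adjointpm_domain_error")
})

test_that("titration chemistry: saturated regime makes zero production and non-positive slope", {
  sp <- species_set()
  ch <- chem_config("titration", k = c(SO2 = 0, NOX = 0, NH3 = 0),
                    k_titr = 1e-3, gamma = 2)
  o3 <- rep(40, 3)
  conc <- matrix(0, 3, sp$n, dimnames = list(NULL, sp$names))
  conc[, "NOX"] <- c(5, 15, 30)   # active/positive, active/negative-slope, saturated
  out <- chemistry_step(conc, sp, ch, o3bg = o3)
  # saturated cell: gamma*NOx = 60 > o3bg = 40, no production at all
  expect_equal(unname(out$conc[3, "pNO3"]), 0)
  # finite difference of pNO3 production w.r.t. NOx at each state
  dprod <- vapply(1:3, function(i) {
    cp <- conc; cm <- conc
    cp[i, "NOX"] <- cp[i, "NOX"] + 1e-6
    cm[i, "NOX"] <- cm[i, "NOX"] - 1e-6
    (chemistry_step(cp, sp, ch, o3bg = o3, check = FALSE)$conc[i, "pNO3"] -
       chemistry_step(cm, sp, ch, o3bg = o3, check = FALSE)$conc[i, "pNO3"]) / 2e-6
  }, numeric(1))
  expect_gt(dprod[1], 0)          # NOx-limited: more NOx, more nitrate
  expect_lt(dprod[2], 0)          # NOx-inhibited: more NOx, less nitrate
  expect_equal(dprod[3], 0)       # saturated: flat
  # stored jacobian matches the finite differences (production slope = yield * d(reacted)/dc)
  jac <- chemistry_step(conc, sp, ch, o3bg = o3)$jacobian_record$NOX
  expect_equal(jac$slope, dprod, tolerance = 1e-6)
})

test_that("deposition: identity at zero rate, exact exponential, semigroup property", {
  conc <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(deposit(conc, c(0, 0)), conc)
  out <- deposit(conc, c(0.1, 0.3))
  expect_equal(out[, 1], conc[, 1] * exp(-0.1))
  expect_equal(out[, 2], conc[, 2] * exp(-0.3))
  # two successive steps equal one step of doubled duration
  expect_equal(deposit(deposit(conc, c(0.1, 0.3)), c(0.1, 0.3)),
               deposit(conc, c(0.1, 0.3), dt_h = 2))
  expect_error(deposit(conc, c(-0.1, 0)), class = "adjointpm_input_error")
})

test_that("emission injection: exact unit bridge and linearity", {
  g <- grid_spec(1, 1, 100, mixing_height_m = 1000)
  conc <- matrix(0, 1, 1)
  E <- matrix(1, 1, 1)  # 1 ton/hr for 1 h into a 100 km cell, 1000 m deep
  expect_equal(inject_emissions(conc, E, g)[1, 1], 0.1)
  expect_equal(inject_emissions(conc, 0 * E, g), conc)
  expect_equal(inject_emissions(conc, 2 * E, g)[1, 1],
               2 * inject_emissions(conc, E, g)[1, 1])
  expect_error(inject_emissions(conc, -E, g), class = "adjointpm_input_error")
})

test_that("forward model: zero emissions give a zero trajectory; NaN hour is named", {
  m <- small_model()
  tr <- run_forward(m, NULL, spinup_hours = 0)
  expect_true(all(tr$states == 0))
  expect_true(all(tr$pm_mean == 0))
})

test_that("box model matches the closed-form solution and its continuous limit", {
  w <- box_world()
  m <- world_model(w)
  tr <- run_forward(m, w$emissions, spinup_hours = 0)
  k <- m$species$dep_rate[["EC"]]
  E_hr <- emis_hour_total(w$emissions, 1, m)[1, "EC"]
  r <- E_hr * m$uconv                       # ug/m3 injected per hour
  n <- 1:m$grid$n_hours
  exact <- r * exp(-k) * (1 - exp(-k * n)) / (1 - exp(-k))
  expect_equal(tr$states[1, "EC", n + 1], unname(exact), tolerance = 1e-12)
  # continuous-limit box solution r*(1-e^{-kn})/k agrees to O(k)
  cont <- r * (1 - exp(-k * n)) / k
  expect_lt(max(abs(exact - cont) / cont), k)
})

test_that("mass conservation: periodic boundary, no deposition/chemistry", {
  g <- grid_spec(6, 6, 100, n_hours = 20, boundary = "periodic")
  sp <- inert_species()
  met <- met_fields(array(5, c(20, 6, 6)), array(-4, c(20, 6, 6)), grid = g)
  m <- ctm_model(g, sp, met, zero_chem(), K = 1500)
  E <- matrix(0.5, g$n_cells, sp$n, dimnames = list(NULL, sp$names))
  tr <- run_forward(m, E, spinup_hours = 0)
  injected <- sum(E) * m$uconv * g$n_hours
  expect_lt(abs(sum(tr$states[, , g$n_hours + 1]) - injected) / injected, 1e-10)
})

test_that("trajectory is linear in emissions and non-negative (linear chemistry)", {
  m <- small_model()
  w <- small_world()
  g <- m$grid; sp <- m$species
  set.seed(4)
  E1 <- matrix(abs(rnorm(g$n_cells * sp$n)), g$n_cells, sp$n, dimnames = list(NULL, sp$names))
  E2 <- matrix(abs(rnorm(g$n_cells * sp$n)), g$n_cells, sp$n, dimnames = list(NULL, sp$names))
  t1 <- run_forward(m, E1, spinup_hours = 0)
  t2 <- run_forward(m, E2, spinup_hours = 0)
  t12 <- run_forward(m, 2 * E1 + 0.5 * E2, spinup_hours = 0)
  expect_equal(t12$states, 2 * t1$states + 0.5 * t2$states, tolerance = 1e-10)
  expect_true(all(t1$states >= 0))
  tw <- run_forward(m, w$emissions, spinup_hours = 0)
  expect_true(all(tw$states >= 0))
})

test_that("box-model discretization error shrinks when the timestep halves", {
  # fixed physical problem: emission R = 1 ton/hr, loss k = 0.04/h, T = 100 h;
  # resolve with per-step rate k*dt and per-step injection R*dt. Continuous
  # solution: (R_conc/k) * (1 - e^{-kT}); discrete error is O(dt).
  k_phys <- 0.04; T_h <- 100
  run_box <- function(steps_per_h) {
    dt_h <- 1 / steps_per_h
    g <- grid_spec(1, 1, 100, dt_s = 3600, n_hours = T_h * steps_per_h)
    tb <- default_species_table(); tb$dep_rate <- k_phys * dt_h
    sp <- species_set(tb)
    m <- ctm_model(g, sp, uniform_met(g), zero_chem(), K = 0)
    E <- matrix(0, 1, sp$n, dimnames = list(NULL, sp$names))
    E[1, "EC"] <- dt_h   # R*dt tons per step
    tr <- run_forward(m, E, spinup_hours = 0)
    tr$states[1, "EC", g$n_hours + 1]
  }
  r_conc <- 1e12 / (1e10 * 1000)  # ug/m3 per (ton/hr * 1 h)
  cont <- (r_conc / k_phys) * (1 - exp(-k_phys * T_h))
  e1 <- abs(run_box(1) - cont)
  e2 <- abs(run_box(2) - cont)
  expect_lt(e2, e1 * 0.6)  # observed convergence order >= 1
})
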