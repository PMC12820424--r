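# shared fixture: two-region world with linear cost, gradient, and burden
attr_fixture <- function() fixture("attr", function() {
  w <- two_region_world()
  m <- world_model(w)
  tr <- run_forward(m, w$emissions, spinup_hours = w$config$spinup_hours)
  set.seed(17)
  wts <- runif(m$grid$n_cells)
  s <- run_adjoint(m, linear_forcing(wts, tr), tr)
  list(w = w, m = m, tr = tr, wts = wts, s = s)
})

test_that("reduction burden: zero fraction, uniform-sensitivity factorization", {
  fx <- attr_fixture()
  rep0 <- reduction_burden(fx$s, fx$w$emissions, fx$w$mask, f = 0)
  expect_equal(rep0$total_deaths, 0)
  # uniform sensitivity sigma: burden = f * sigma * total tons
  sigma <- 0.002
  s_unif <- fx$s
  s_unif$sens[] <- sigma
  repu <- reduction_burden(s_unif, fx$w$emissions, fx$w$mask, f = 0.1)
  M <- sum(emission_totals(fx$w$emissions)$tons)
  expect_equal(repu$total_deaths, 0.1 * sigma * M, tolerance = 1e-12)
  expect_error(reduction_burden(fx$s, fx$w$emissions, fx$w$mask, f = 2),
               class = "adjointpm_input_error")
})

test_that("linear-model identity: burden(f = 0.1) equals J(E) - J(0.9 E) exactly", {
  fx <- attr_fixture()
  rep <- reduction_burden(fx$s, fx$w$emissions, fx$w$mask, f = 0.1)
  scaled <- fx$w$emissions
  scaled$base_flat <- scaled$base_flat * 0.9
  tr9 <- run_forward(fx$m, scaled, spinup_hours = fx$w$config$spinup_hours)
  gap <- linear_cost(fx$tr, fx$wts) - linear_cost(tr9, fx$wts)
  expect_lt(abs(rep$total_deaths - gap) / gap, 1e-10)
})

test_that("sector contributions are additive and shares sum to one", {
  fx <- attr_fixture()
  rep <- reduction_burden(fx$s, fx$w$emissions, fx$w$mask, f = 0.1)
  sec <- sector_contribution(rep)
  expect_equal(sum(sec$share), 1, tolerance = 1e-12)
  # sum of per-sector burdens equals the whole-inventory burden
  per_sector <- sum(sec$deaths)
  expect_lt(abs(per_sector - rep$total_deaths) / rep$total_deaths, 1e-10)
  # proportionality: doubling one sector's emissions doubles its burden (linear sens)
  dbl <- fx$w$emissions
  i_agr <- match("agriculture", dbl$sectors)
  dbl$base_flat[, i_agr] <- 2 * dbl$base_flat[, i_agr]
  dbl$base <- array(dbl$base_flat, dim(dbl$base), dimnames = dimnames(dbl$base))
  rep2 <- reduction_burden(fx$s, dbl, fx$w$mask, f = 0.1)
  sec2 <- sector_contribution(rep2)
  expect_equal(sec2$deaths[sec2$sector == "agriculture"],
               2 * sec$deaths[sec$sector == "agriculture"], tolerance = 1e-12)
  # shares invariant under global rescaling of all emissions
  all5 <- fx$w$emissions
  all5$base_flat <- 5 * all5$base_flat
  sec5 <- sector_contribution(reduction_burden(fx$s, all5, fx$w$mask, f = 0.1))
  expect_equal(sec5$share, sec$share, tolerance = 1e-12)
})

test_that("two sectors in identical cells with 2:1 emissions split shares 2/3 : 1/3", {
  g <- grid_spec(2, 2, 100, n_hours = 6)
  sp <- species_set()
  base <- array(0, c(4, sp$n, 2), dimnames = list(NULL, sp$names, c("a", "b")))
  base[1, "EC", "a"] <- 1
  base[1, "EC", "b"] <- 2
  inv <- emission_inventory(base, matrix(1, 2, 24, dimnames = list(c("a", "b"))),
                            matrix(1, 2, 4, dimnames = list(c("a", "b"))),
                            c(a = "surface", b = "surface"), 6)
  sens <- structure(list(sens = array(1, c(4, sp$n, 6), dimnames = list(NULL, sp$names, NULL)),
                         grid = g, species = sp, units = "deaths_per_ton",
                         spinup_hours = 0L), class = "sensitivity_field")
  mask <- region_mask(rep("R1", 4), g)
  sec <- sector_contribution(reduction_burden(sens, inv, mask, f = 0.1))
  expect_equal(sec$share[sec$sector == "b"], 2 / 3, tolerance = 1e-12)
  expect_equal(sec$share[sec$sector == "a"], 1 / 3, tolerance = 1e-12)
})

test_that("burdens are attributed to the source region", {
  w <- plume_world()
  m <- world_model(w)
  tr <- run_forward(m, w$emissions, spinup_hours = w$config$spinup_hours)
  s <- run_adjoint(m, gemm_forcing(tr, w$panel), tr)
  # split the single region into source / receptor halves
  halves <- ifelse(rep(seq_len(m$grid$nx), each = m$grid$ny) <= 6, "W", "E")
  mask <- region_mask(halves, m$grid)
  rep <- reduction_burden(s, w$emissions, mask, f = 0.1)
  by_region <- tapply(rep$table$deaths, rep$table$region, sum)
  # the only emitting cell is at x = 3 (west); receptor at x = 9 gets nothing
  expect_gt(by_region[["W"]], 0)
  expect_equal(by_region[["E"]], 0)
})

test_that("seasonal summary: time-constant sensitivity yields identical seasonal values", {
  fx <- attr_fixture()
  s_const <- fx$s
  s_const$sens[] <- 0.004
  ss <- seasonal_summary(s_const, species = "NH3")
  expect_equal(unique(ss$max), 4)        # deaths/kton
  expect_equal(unique(ss$mean), 4)
  expect_equal(sum(ss$n_hours) + fx$s$spinup_hours, fx$m$grid$n_hours)
})

test_that("winter-boosted conversion raises winter NH3 sensitivity above summer", {
  w <- fixture("seasonal", function() make_world(make_scenario("seasonal_demo")))
  m <- world_model(w)
  tr <- run_forward(m, w$emissions, spinup_hours = w$config$spinup_hours)
  s <- run_adjoint(m, gemm_forcing(tr, w$panel), tr)
  ss <- seasonal_summary(s, species = "NH3")
  expect_gt(ss$max[ss$season == "DJF"], ss$max[ss$season == "JJA"])
  expect_gt(ss$mean[ss$season == "DJF"], ss$mean[ss$season == "JJA"])
})

test_that("negative census: empty in linear mode, NOx cells under titration, unit-invariant", {
  fx <- attr_fixture()
  # linear chemistry with non-negative forcing cannot produce negatives
  w2 <- two_region_world(); m2 <- fx$m
  tr2 <- fx$tr
  s_gemm <- run_adjoint(m2, gemm_forcing(tr2, w2$panel), tr2)
  cen <- negative_sensitivity_census(s_gemm)
  expect_equal(sum(cen$n_negative), 0)
  # engineered titration world: negative NOx cells appear, and only for NOx
  wt <- fixture("titration", function() make_world(make_scenario("titration_demo")))
  mt <- world_model(wt)
  trt <- run_forward(mt, wt$emissions, spinup_hours = wt$config$spinup_hours)
  st <- run_adjoint(mt, gemm_forcing(trt, wt$panel), trt)
  cent <- negative_sensitivity_census(st)
  expect_gt(cent$n_negative[cent$species == "NOX"], 0)
  expect_equal(sum(cent$n_negative[cent$species != "NOX"]), 0)
  # census invariant under deaths/ton <-> deaths/kton
  cent_k <- negative_sensitivity_census(to_reporting_units(st))
  expect_equal(cent_k$n_negative, cent$n_negative)
})

test_that("per-ton burden grows as the baseline shrinks (concave CRF direction)", {
  w <- plume_world()
  m <- world_model(w)
  scales <- c(1, 0.9, 0.8)
  per_ton <- vapply(scales, function(sc) {
    inv <- w$emissions
    inv$base_flat <- inv$base_flat * sc
    inv$base <- array(inv$base_flat, dim(inv$base), dimnames = dimnames(inv$base))
    tr <- run_forward(m, inv, spinup_hours = w$config$spinup_hours)
    s <- run_adjoint(m, gemm_forcing(tr, w$panel), tr)
    rep <- reduction_burden(s, inv, w$mask, f = 0.1)
    rep$total_deaths / (0.1 * sum(emission_totals(inv)$tons))
  }, numeric(1))
  expect_true(all(diff(per_ton) > 0))
})
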