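test_that("a single step closes its budget and normalises root inputs", {
  cfg <- toy_config(n_layers = 5)
  st <- column_state(cfg$grid)
  row <- cfg$forcing[cfg$forcing$year == 1901, ]
  out <- step_column(st, row, cfg$params, dt = 1 / 12)
  fl <- out$fluxes
  expect_equal(
    total_column_carbon(out$state),
    fl$inputs[["c_total"]] - fl$respiration[["c_total"]] -
      fl$doc_export[["c_total"]],
    tolerance = 1e-10
  )
  expect_equal(
    total_column_carbon(out$state, "c13"),
    fl$inputs[["c13"]] - fl$respiration[["c13"]] - fl$doc_export[["c13"]],
    tolerance = 1e-10
  )
  # zero inputs + zero rates: identity
  p0 <- iso_params(k = 0 * fast_k, d0 = 0, advection = 0, kd_doc = 0)
  cfg0 <- toy_config(n_layers = 5, params = p0, flux_above = 0,
                     flux_below = 0)
  st5 <- equilibrate_sorption(random_state(cfg0$grid, 9), 0)
  out0 <- step_column(st5, cfg0$forcing[1, ], p0, dt = 1 / 12)
  expect_equal(out0$state$C, st5$C, tolerance = 1e-12)
  expect_equal(out0$state$surface, st5$surface)
})

test_that("a single fully-respired pool reaches the I/k steady state", {
  k <- 0 * fast_k
  k["metabolic_bg_litter"] <- 0.02
  tr <- default_transfers(0.6)
  tr$metabolic_bg_litter <- list(to = numeric(0), resp = 1)
  p <- iso_params(k = k, transfers = tr, clay = 0, d0 = 0, advection = 0,
                  kd_doc = 0, enrich = 0, epsilon_resp = 0,
                  metabolic_frac = 1)
  cfg <- iso_config(grid = build_layer_grid(1, 2, 1), params = p,
                    scenario = scenario_spec(-27, 1901, suess_on = FALSE,
                                             co2_effect_on = FALSE),
                    flux_above = 0, flux_below = 100)
  sp <- spin_up(cfg, tol = 1e-6, window = 5, max_years = 3000)
  expect_true(sp$report$converged)
  expect_equal(unname(sp$state$C[1, "metabolic_bg_litter"]), 100 / 0.02,
               tolerance = 2e-3)
  # with no fractionation anywhere the pool sits at the input delta
  d <- delta_of_stock_pair(sp$state$C[1, "metabolic_bg_litter"],
                           sp$state$C13[1, "metabolic_bg_litter"])
  expect_equal(d, -27, tolerance = 1e-6)
})

test_that("respiration discrimination enriches a fully-respired pool by ~epsilon", {
  k <- 0 * fast_k
  k["metabolic_bg_litter"] <- 0.1
  tr <- default_transfers(0.6)
  tr$metabolic_bg_litter <- list(to = numeric(0), resp = 1)
  p <- iso_params(k = k, transfers = tr, clay = 0, d0 = 0, advection = 0,
                  kd_doc = 0, enrich = 0, epsilon_resp = 0.1,
                  metabolic_frac = 1)
  cfg <- iso_config(grid = build_layer_grid(1, 2, 1), params = p,
                    scenario = scenario_spec(-27, 1901, suess_on = FALSE,
                                             co2_effect_on = FALSE),
                    flux_above = 0, flux_below = 100)
  sp <- spin_up(cfg, tol = 1e-8, window = 5, max_years = 2000)
  d <- delta_of_stock_pair(sp$state$C[1, "metabolic_bg_litter"],
                           sp$state$C13[1, "metabolic_bg_litter"])
  # exact balance: R_pool = R_in / alpha, i.e. ~input + epsilon to first order
  expect_equal(d, (1000 - 27) / (1 - 0.1 / 1000) - 1000, tolerance = 1e-4)
  expect_lt(abs(d - (-27 + 0.1)), 0.01)
})

test_that("steady delta equals input delta when nothing fractionates", {
  p <- iso_params(k = fast_k, enrich = 0, epsilon_resp = 0)
  cfg <- toy_config(n_layers = 4, params = p)
  st <- solve_steady_state(cfg)
  prof <- delta_profile(st, list(total = LAYERED_POOLS))
  expect_true(all(abs(prof$delta13c - (-27)) < 1e-6))
  d_surf <- delta_of_stock_pair(sum(st$surface), sum(st$surface13))
  expect_lt(abs(d_surf - (-27)), 1e-6)
})

test_that("direct steady-state solve matches iterative spin-up", {
  cfg <- toy_config(n_layers = 3)
  direct <- solve_steady_state(cfg)
  iter <- spin_up(cfg, tol = 1e-7, window = 5, max_years = 2000)
  expect_true(iter$report$converged)
  rel <- abs(iter$state$C - direct$C) / pmax(direct$C, 1e-9)
  expect_lt(max(rel), 1e-3)
  rel13 <- abs(iter$state$C13 - direct$C13) / pmax(direct$C13, 1e-9)
  expect_lt(max(rel13), 1e-3)
  rels <- abs(iter$state$surface - direct$surface) / direct$surface
  expect_lt(max(rels), 1e-3)
})

test_that("the steady state is linear in the inputs", {
  cfg1 <- toy_config(n_layers = 3, flux_above = 120, flux_below = 180)
  cfg2 <- toy_config(n_layers = 3, flux_above = 240, flux_below = 360)
  s1 <- solve_steady_state(cfg1)
  s2 <- solve_steady_state(cfg2)
  expect_equal(s2$C, 2 * s1$C, tolerance = 1e-8)
  expect_equal(s2$C13, 2 * s1$C13, tolerance = 1e-8)
})

test_that("a pool with no loss pathway is reported by name", {
  k <- fast_k
  k["passive_soc"] <- 0
  cfg <- toy_config(n_layers = 3, params = iso_params(k = k, d0 = 0))
  expect_error(solve_steady_state(cfg), "passive_soc")
})

test_that("historical run continues an equilibrium under constant forcing", {
  cfg <- toy_config(n_layers = 3, start_year = 1951, end_year = 1970)
  st <- solve_steady_state(cfg)
  res <- run_historical(cfg, st)
  drift <- abs(res$annual$total_c[20] - res$annual$total_c[1]) /
    res$annual$total_c[1]
  expect_lt(drift, 1e-6)
})

test_that("Suess-declining forcing depletes topsoil faster than deep soil", {
  cfg <- toy_config(n_layers = 6, constant_delta = FALSE,
                    params = iso_params(k = fast_k),
                    start_year = 1901, end_year = 2011, output_every = 110)
  st <- solve_steady_state(cfg)
  res <- run_historical(cfg, st)
  first <- delta_profile(res$snapshots[["1901"]],
                         list(total = LAYERED_POOLS))$delta13c
  last <- delta_profile(res$snapshots[["2011"]],
                        list(total = LAYERED_POOLS))$delta13c
  expect_lt(last[1], first[1])          # topsoil depleted over the century
  change <- abs(last - first)
  expect_lt(change[6], change[1])       # deep layer responds more slowly
})

test_that("run_historical refuses forcing that does not span the run", {
  cfg <- toy_config(n_layers = 3)
  expect_error(
    iso_config(grid = cfg$grid, params = cfg$params, forcing = cfg$forcing,
               start_year = 1700, end_year = 1800),
    "cover")
})

test_that("total carbon is blind to the 13C tracer", {
  cfg <- toy_config(n_layers = 3, start_year = 1951, end_year = 1960)
  st <- solve_steady_state(cfg)
  st_no13 <- st
  st_no13$C13[] <- 0
  st_no13$surface13[] <- 0
  r1 <- run_historical(cfg, st)
  r2 <- run_historical(cfg, st_no13)
  expect_identical(r1$annual$total_c, r2$annual$total_c)
  expect_identical(r1$annual$respiration, r2$annual$respiration)
})

test_that("paired C3/C4 experiment isolates the vegetation-switch signal", {
  mk <- function(switch_year = NULL) {
    iso_config(grid = build_layer_grid(6, 2, 1.5),
               params = iso_params(k = fast_k),
               scenario = scenario_spec(-27, 2005,
                                        switch_year = switch_year),
               start_year = 1971, end_year = 2011, output_every = 10)
  }
  ctrl <- mk(); c4 <- mk(1993)
  # identical scenarios: difference identically zero
  same <- run_paired_experiment(ctrl, mk())
  expect_true(all(same$difference$delta_diff == 0))
  ex <- run_paired_experiment(ctrl, c4, diff_years = c(2001, 2011))
  d <- ex$difference
  expect_true(all(d$delta_diff >= -1e-9))
  # strongest enrichment near the surface one-two decades post-switch
  for (y in c(2001, 2011)) {
    dy <- d[d$year == y, ]
    expect_lte(which.max(dy$delta_diff), 2)
    expect_gt(max(dy$delta_diff), 1)    # a clear C4 imprint in topsoil
  }
  # tracer neutrality: the pair shares its total-C trajectory exactly
  expect_identical(ex$control$annual$total_c, ex$c4$annual$total_c)
  # guard: configs may differ only in the forcing scenario
  bad <- mk(1993)
  bad$params <- iso_params(k = fast_k, clay = 0.5)
  expect_error(run_paired_experiment(ctrl, bad), "identical")
})
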