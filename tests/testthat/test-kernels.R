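test_that("clay modifier follows 1 - 0.75*clay on the unit interval", {
  expect_equal(clay_rate_modifier(0), 1)
  expect_equal(clay_rate_modifier(0.2), 0.85)
  expect_equal(clay_rate_modifier(1), 0.25)
  cl <- seq(0, 1, 0.05)
  expect_true(all(diff(clay_rate_modifier(cl)) <= 0))
  expect_error(clay_rate_modifier(1.2), "\\[0, 1\\]")
})

test_that("decomposition matches closed-form exponential decay", {
  g <- build_layer_grid(3, 1, 1.5)
  C <- matrix(0, 3, length(LAYERED_POOLS),
              dimnames = list(NULL, LAYERED_POOLS))
  C[, "slow_soc"] <- 100
  st <- column_state(g, C = C, C13 = c13_stock_from_total(C, -25))
  k <- rep(0, length(fast_k)); names(k) <- names(fast_k)
  k["slow_soc"] <- 0.01
  # route everything to respiration so no receiver bookkeeping interferes
  tr <- default_transfers(0.6)
  tr$slow_soc <- list(to = numeric(0), resp = 1)
  p <- iso_params(k = k, transfers = tr, clay = 0, epsilon_resp = 0)
  out <- decompose_step(st, p, dt = 1)
  expect_equal(out$state$C[, "slow_soc"], rep(100 * exp(-0.01), 3),
               tolerance = 1e-12)
  expect_equal(out$fluxes$respiration_total, 3 * 100 * (1 - exp(-0.01)),
               tolerance = 1e-12)
  # zero rates leave the state untouched
  p0 <- iso_params(k = 0 * k)
  out0 <- decompose_step(st, p0, dt = 1)
  expect_equal(out0$state$C, st$C)
  expect_equal(out0$fluxes$respiration_total, 0)
})

test_that("decomposition conserves both isotopes and sub-steps large k*dt", {
  g <- build_layer_grid(5, 2, 1.4)
  p <- iso_params()
  for (seed in 1:25) {
    st <- random_state(g, seed)
    before <- total_column_carbon(st)
    before13 <- total_column_carbon(st, "c13")
    out <- decompose_step(st, p, dt = 1)  # labile k*dt = 20: forces sub-steps
    expect_budget_closes(before, total_column_carbon(out$state),
                         out$fluxes$respiration_total)
    expect_budget_closes(before13, total_column_carbon(out$state, "c13"),
                         out$fluxes$respiration_c13)
    expect_true(all(out$state$C >= 0))
  }
})

test_that("respired CO2 is depleted and the residue enriched", {
  g <- build_layer_grid(1, 1, 1)
  C <- matrix(0, 1, length(LAYERED_POOLS),
              dimnames = list(NULL, LAYERED_POOLS))
  C[, "labile_doc_free"] <- 100
  st <- column_state(g, C = C, C13 = c13_stock_from_total(C, 0))
  p <- iso_params(epsilon_resp = 0.1)
  # dt small enough for a single internal sub-step: the whole respired flux
  # then carries the pre-step substrate signature
  out <- decompose_step(st, p, dt = 1 / 24)
  resp_delta <- delta_of_stock_pair(out$fluxes$respiration_total,
                                    out$fluxes$respiration_c13)
  expect_equal(resp_delta, -0.1, tolerance = 1e-9)
  # residue (still in the column) is correspondingly enriched
  res_delta <- delta_of_stock_pair(total_column_carbon(out$state),
                                   total_column_carbon(out$state, "c13"))
  expect_gt(res_delta, 0)
  # with epsilon = 0 everything stays at the substrate delta
  p0 <- iso_params(epsilon_resp = 0)
  out0 <- decompose_step(st, p0, dt = 1 / 24)
  expect_equal(delta_of_stock_pair(out0$fluxes$respiration_total,
                                   out0$fluxes$respiration_c13), 0,
               tolerance = 1e-9)
})

test_that("DOC partitioning is an exact equilibrium split", {
  tot <- stock_pair(80, c13_stock_from_total(80, -26))
  p0 <- partition_doc(tot, 0)
  expect_equal(p0$free$c_total, 80)
  expect_equal(p0$adsorbed$c_total, 0)
  p1 <- partition_doc(tot, 1)
  expect_equal(p1$free$c_total, 40)
  expect_equal(p1$adsorbed$c_total, 40)
  for (kd in c(0.3, 2, 17)) {
    pp <- partition_doc(tot, kd)
    expect_equal(pp$adsorbed$c_total / pp$free$c_total, kd)
    expect_equal(pp$free$c_total + pp$adsorbed$c_total, tot$c_total)
    expect_equal(pp$free$c13 + pp$adsorbed$c13, tot$c13)
    # no sorption fractionation
    expect_equal(delta_of_stock_pair(pp$free$c_total, pp$free$c13),
                 delta_of_stock_pair(tot$c_total, tot$c13))
  }
  g <- build_layer_grid(4, 1, 1.3)
  st <- random_state(g, 3)
  st2 <- equilibrate_sorption(st, 5)
  expect_equal(total_column_carbon(st2), total_column_carbon(st))
  expect_equal(st2$C[, "labile_doc_ads"] / st2$C[, "labile_doc_free"],
               rep(5, 4))
})

test_that("diffusion coefficient profile e-folds with depth", {
  g <- build_layer_grid(11, 2, 1.53)
  D <- diffusion_coefficient_profile(1e-3, 0.5, g)
  z <- g$boundaries[2:11]
  expect_equal(unname(D), 1e-3 * exp(-z / 0.5))
  expect_equal(unname(diffusion_coefficient_profile(1e-3, Inf, g)),
               rep(1e-3, 10))
  # e-folding definition at z = d_efold on a grid with an interface there
  g2 <- build_layer_grid(2, 1, 1)
  D2 <- diffusion_coefficient_profile(2e-3, 0.5, g2)
  expect_equal(unname(D2), 2e-3 / exp(1))
})

test_that("implicit diffusion conserves mass and smooths toward uniform", {
  g <- build_layer_grid(6, 2, 1.4)
  st <- random_state(g, 11)
  before <- total_column_carbon(st)
  before13 <- total_column_carbon(st, "c13")
  st2 <- diffuse(st, iso_params(), dt = 0.5)
  expect_equal(total_column_carbon(st2), before, tolerance = 1e-12)
  expect_equal(total_column_carbon(st2, "c13"), before13, tolerance = 1e-12)
  # a uniform concentration profile is a fixed point
  C <- outer(g$thickness, rep(10, length(LAYERED_POOLS)))
  colnames(C) <- LAYERED_POOLS
  stu <- column_state(g, C = C, C13 = 0.011 * C)
  stu2 <- diffuse(stu, iso_params(d_efold = Inf), dt = 1)
  expect_equal(stu2$C, stu$C, tolerance = 1e-10)
})

test_that("implicit diffusion matches a fine-step explicit oracle", {
  g <- build_layer_grid(3, 1, 1)
  D <- rep(0.05, 2)
  C <- matrix(0, 3, length(LAYERED_POOLS),
              dimnames = list(NULL, LAYERED_POOLS))
  C[2, "active_soc"] <- 90   # single-layer spike
  st <- column_state(g, C = C)
  dt <- 0.01
  for (i in 1:100) st <- diffuse(st, dt = dt, D_int = D)
  oracle <- explicit_diffuse(c(0, 90, 0), g, D, total_time = 1,
                             n_fine = 20000)
  expect_equal(st$C[, "active_soc"], oracle, tolerance = 0.01)
})

test_that("DOC advection is conservative upwind transport with bottom export", {
  g <- build_layer_grid(4, 1, 1.2)
  st <- random_state(g, 5)
  before <- total_column_carbon(st)
  out <- advect_doc(st, rates = 0, dt = 1)
  expect_equal(out$state$C, st$C)
  expect_equal(out$export$c_total, 0)
  out2 <- advect_doc(st, rates = c(0.5, 0.4, 0.3, 0.6), dt = 0.25)
  expect_budget_closes(before, total_column_carbon(out2$state),
                       out2$export$c_total)
  expect_budget_closes(total_column_carbon(st, "c13"),
                       total_column_carbon(out2$state, "c13"),
                       out2$export$c13)
  # only free DOC moves
  solid <- setdiff(LAYERED_POOLS, c("labile_doc_free", "stable_doc_free"))
  expect_equal(out2$state$C[, solid], st$C[, solid])
  # CFL sub-stepping keeps stocks positive at rate*dt > 1
  out3 <- advect_doc(st, rates = 8, dt = 1)
  expect_true(all(out3$state$C >= 0))
  expect_budget_closes(before, total_column_carbon(out3$state),
                       out3$export$c_total)
})

test_that("steady advection profile matches a brute-force fine-step run", {
  g <- build_layer_grid(2, 1, 1)
  rates <- c(0.5, 0.5)
  dt <- 0.01
  input <- 10  # g C m-2 yr-1 into the top layer's labile free DOC
  C <- matrix(0, 2, length(LAYERED_POOLS),
              dimnames = list(NULL, LAYERED_POOLS))
  st <- column_state(g, C = C)
  nsteps <- 1500  # 15 years, several transport e-folding times
  for (i in seq_len(nsteps)) {
    st$C[1, "labile_doc_free"] <- st$C[1, "labile_doc_free"] + input * dt
    st <- advect_doc(st, rates, dt)$state
  }
  oracle <- explicit_advect(c(0, 0), rates, input, total_time = nsteps * dt,
                            n_fine = nsteps * 25)
  expect_equal(st$C[, "labile_doc_free"], oracle, tolerance = 0.01)
})

test_that("transfer fractions must close to one per donor", {
  tr <- default_transfers(0.6)
  tr$active_soc$to <- c(labile_doc_free = 1.2)
  expect_error(iso_params(transfers = tr), "active_soc")
  tr2 <- default_transfers(0.6)
  tr2$slow_soc$to <- c(not_a_pool = 1)
  expect_error(iso_params(transfers = tr2), "unknown pool")
})
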