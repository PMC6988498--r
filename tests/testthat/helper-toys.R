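# Shared fixtures: small fast columns, random states, and independent
# fine-step explicit oracles for the transport operators.

# rate constants fast enough that a toy column equilibrates in decades
fast_k <- c(
  metabolic_ag_litter = 8, structural_ag_litter = 2.5,
  metabolic_bg_litter = 8, structural_bg_litter = 2.5,
  active_soc = 1, slow_soc = 0.3, passive_soc = 0.05,
  labile_doc_free = 20, stable_doc_free = 5
)

toy_config <- function(n_layers = 3, params = iso_params(k = fast_k),
                       constant_delta = TRUE, ...) {
  scen <- if (constant_delta) {
    scenario_spec(reference_delta = -27, reference_year = 1901,
                  suess_on = FALSE, co2_effect_on = FALSE)
  } else {
    scenario_spec(reference_delta = -27, reference_year = 2005)
  }
  iso_config(grid = build_layer_grid(n_layers, 1, 1.5), params = params,
             scenario = scen, ...)
}

# a strictly positive random column state with plausible isotopic ratios
random_state <- function(grid, seed) {
  withr::with_seed(seed, {
    n <- grid$n_layers
    C <- matrix(stats::runif(n * length(LAYERED_POOLS), 0.1, 500),
                n, length(LAYERED_POOLS),
                dimnames = list(NULL, LAYERED_POOLS))
    deltas <- matrix(stats::runif(n * length(LAYERED_POOLS), -30, 0),
                     n, length(LAYERED_POOLS))
    C13 <- c13_stock_from_total(C, deltas)
    surface <- stats::setNames(stats::runif(2, 0.1, 500), SURFACE_POOLS)
    sdelta <- stats::runif(2, -30, 0)
    column_state(grid, C = C, C13 = C13, surface = surface,
                 surface13 = c13_stock_from_total(surface, sdelta))
  })
}

# forward-Euler diffusion of a stock vector on the package grid geometry,
# run at a fine time step: the brute-force oracle for the implicit operator
explicit_diffuse <- function(stocks, grid, D_int, total_time, n_fine) {
  n <- grid$n_layers
  h <- grid$thickness
  g <- D_int / diff(grid$node_depth)
  dtf <- total_time / n_fine
  for (s in seq_len(n_fine)) {
    conc <- stocks / h
    flux <- g * (conc[-n] - conc[-1])   # downward-positive interface fluxes
    stocks <- stocks + dtf * (c(0, flux) - c(flux, 0))
  }
  stocks
}

# brute-force upwind DOC advection with per-sub-step input, at a fine step
explicit_advect <- function(stocks, rates, input_rate, total_time, n_fine) {
  n <- length(stocks)
  dtf <- total_time / n_fine
  for (s in seq_len(n_fine)) {
    stocks[1] <- stocks[1] + input_rate * dtf
    out <- stocks * rates * dtf
    stocks <- stocks - out
    if (n > 1) stocks[2:n] <- stocks[2:n] + out[1:(n - 1)]
  }
  stocks
}

expect_budget_closes <- function(before, after, boundary_out, tol = 1e-10) {
  scale <- max(abs(before), 1)
  expect_lt(abs((before - after) - boundary_out), tol * scale)
}
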