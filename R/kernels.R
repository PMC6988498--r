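# Local biogeochemistry kernels and vertical transport operators.
#
# All kernels conserve total C and 13C exactly up to their declared boundary
# fluxes (respiration, bottom DOC export): every gram removed from a donor is
# accounted for in a receiver pool or an output flux, by construction.

#' Clay modifier of active-pool decomposition
#'
#' Texture slows the decomposition of the active SOC pool; the CENTURY-style
#' form `1 - 0.75 * clay` is used. Applied to the active pool only.
#'
#' @param clay clay mass fraction in `[0, 1]`.
#' @return multiplier in `(0, 1]`, monotone non-increasing in clay.
#' @export
clay_rate_modifier <- function(clay) {
  if (any(!is.finite(clay)) || any(clay < 0) || any(clay > 1)) {
    stop("clay must be in [0, 1]")
  }
  1 - 0.75 * clay
}

# parse the transfers list into index/fraction vectors once
parse_transfers <- function(transfers) {
  lapply(transfers, function(tr) {
    keep <- tr$to[tr$to > 0]
    list(recv = match(names(keep), LAYERED_POOLS),
         frac = unname(keep), resp = tr$resp)
  })
}

# 13C atom fraction of the respired flux given the substrate atom fraction x.
# ratio mode: multiplicative on the 13C/12C ratio (exact mass balance, a
# substrate at 0 permil respires at exactly -epsilon permil);
# linear mode: multiplicative on the atom fraction itself, which makes the
# 13C system exactly linear (used by the direct steady-state solver; differs
# from ratio mode by O(x * epsilon/1000), ~1e-6 relative).
resp_atom_fraction <- function(x, alpha, linear = FALSE) {
  if (linear) return(x * alpha)
  r <- x / (1 - x)
  rf <- r * alpha
  rf / (1 + rf)
}

#' One decomposition step
#'
#' Applies first-order decomposition to every decomposable pool in every
#' layer (and to the surface above-ground litter, whose products enter
#' layer 1): each pool loses `C * (1 - exp(-k * m * dt))` where `m` is the
#' per-layer environmental rate modifier times, for the active pool, the
#' [clay_rate_modifier()]. Fluxes are routed per the transfer topology in
#' `params$transfers`; the respired share leaves as CO2 whose 13C content is
#' depleted by `params$epsilon_resp` (ratio-multiplicative) relative to the
#' substrate, and the 13C excess this leaves behind stays in the donor pool,
#' enriching the residue. 13C otherwise moves in proportion to the donor
#' pool's isotopic ratio.
#'
#' If `k * m * dt >= 1` for any pool the step is internally split into equal
#' sub-steps so every sub-step satisfies the stability bound.
#'
#' @param state a [column_state()].
#' @param params an [iso_params()] object.
#' @param modifiers per-layer environmental rate modifier (dimensionless,
#'   >= 0); scalar or length `n_layers`; default 1.
#' @param dt time step in years.
#' @return list with `state` (updated) and `fluxes`, a list holding
#'   `respiration_total`, `respiration_c13` (g C m-2 over the step),
#'   `respiration_by_layer` (total-C respiration per layer, surface
#'   respiration folded into layer 1).
#' @export
decompose_step <- function(state, params, modifiers = NULL, dt) {
  stopifnot(inherits(state, "column_state"), inherits(params, "iso_params"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  plan <- make_decomp_plan(state$grid, params, modifiers, dt)
  res <- decompose_core(state$C, state$C13, state$surface, state$surface13,
                        plan)
  state$C <- res$C; state$C13 <- res$C13
  state$surface <- res$surface; state$surface13 <- res$surface13
  validate_state(state)
  list(state = state,
       fluxes = list(respiration_total = res$resp,
                     respiration_c13 = res$resp13,
                     respiration_by_layer = res$resp_by_layer))
}

make_decomp_plan <- function(grid, params, modifiers, dt) {
  n <- grid$n_layers
  if (is.null(modifiers)) modifiers <- 1
  if (length(modifiers) == 1) modifiers <- rep(modifiers, n)
  if (length(modifiers) != n || any(modifiers < 0)) {
    stop("modifiers must be a scalar or per-layer vector of values >= 0")
  }
  kl <- params$k[DECOMPOSABLE_LAYERED]
  rate <- outer(modifiers, kl)           # n x 7 effective rates
  colnames(rate) <- DECOMPOSABLE_LAYERED
  rate[, "active_soc"] <- rate[, "active_soc"] * clay_rate_modifier(params$clay)
  ks <- params$k[SURFACE_POOLS] * modifiers[1]
  maxkdt <- max(c(rate, ks), 0) * dt
  nsub <- max(1L, ceiling(maxkdt / 0.999))
  dts <- dt / nsub
  list(
    n = n, nsub = nsub,
    frac = 1 - exp(-rate * dts),
    frac_surf = 1 - exp(-ks * dts),
    routes = parse_transfers(params$transfers),
    alpha = 1 - params$epsilon_resp / 1000
  )
}

# core decomposition cascade on raw matrices; linear toggles the 13C
# respiration form (see resp_atom_fraction)
decompose_core <- function(C, C13, surface, surface13, plan, linear = FALSE) {
  n <- plan$n
  resp <- 0; resp13 <- 0
  resp_by_layer <- numeric(n)
  for (s in seq_len(plan$nsub)) {
    Fd <- C[, DECOMPOSABLE_LAYERED, drop = FALSE] * plan$frac
    F13 <- C13[, DECOMPOSABLE_LAYERED, drop = FALSE] * plan$frac
    C[, DECOMPOSABLE_LAYERED] <- C[, DECOMPOSABLE_LAYERED] - Fd
    C13[, DECOMPOSABLE_LAYERED] <- C13[, DECOMPOSABLE_LAYERED] - F13
    for (d in DECOMPOSABLE_LAYERED) {
      rt <- plan$routes[[d]]
      f <- Fd[, d]; f13 <- F13[, d]
      if (rt$resp > 0) {
        fr <- f * rt$resp
        x <- ifelse(f > 0, f13 / f, 0)
        fr13 <- fr * resp_atom_fraction(x, plan$alpha, linear)
        resp <- resp + sum(fr); resp13 <- resp13 + sum(fr13)
        resp_by_layer <- resp_by_layer + fr
        f <- f - fr
        # transferred 13C stays proportional; the discrimination excess
        # (proportional - depleted respired share) remains in the donor
        # pool, enriching the residue
        f13_new <- f * x
        C13[, d] <- C13[, d] + (f13 - fr13 - f13_new)
        f13 <- f13_new
      }
      if (length(rt$recv)) {
        share <- rt$frac / sum(rt$frac)
        for (j in seq_along(rt$recv)) {
          C[, rt$recv[j]] <- C[, rt$recv[j]] + f * share[j]
          C13[, rt$recv[j]] <- C13[, rt$recv[j]] + f13 * share[j]
        }
      }
    }
    # surface above-ground litter: products delivered to layer 1
    fs <- surface * plan$frac_surf
    fs13 <- surface13 * plan$frac_surf
    surface <- surface - fs; surface13 <- surface13 - fs13
    for (d in SURFACE_POOLS) {
      rt <- plan$routes[[d]]
      f <- fs[[d]]; f13 <- fs13[[d]]
      if (rt$resp > 0) {
        fr <- f * rt$resp
        x <- if (f > 0) f13 / f else 0
        fr13 <- fr * resp_atom_fraction(x, plan$alpha, linear)
        resp <- resp + fr; resp13 <- resp13 + fr13
        resp_by_layer[1] <- resp_by_layer[1] + fr
        f <- f - fr
        f13_new <- f * x
        surface13[[d]] <- surface13[[d]] + (f13 - fr13 - f13_new)
        f13 <- f13_new
      }
      if (length(rt$recv)) {
        share <- rt$frac / sum(rt$frac)
        for (j in seq_along(rt$recv)) {
          C[1, rt$recv[j]] <- C[1, rt$recv[j]] + f * share[j]
          C13[1, rt$recv[j]] <- C13[1, rt$recv[j]] + f13 * share[j]
        }
      }
    }
  }
  list(C = C, C13 = C13, surface = surface, surface13 = surface13,
       resp = resp, resp13 = resp13, resp_by_layer = resp_by_layer)
}

#' Equilibrium partition of DOC between free and adsorbed phases
#'
#' Instantaneous sorption equilibrium: `adsorbed / free = kd` exactly, so
#' `free = total / (1 + kd)`. Both isotopes are partitioned with the same
#' fraction (no sorption fractionation); the sum is conserved to machine
#' precision.
#'
#' @param total a [stock_pair()] (or a plain numeric total stock) of DOC in
#'   one reactivity class.
#' @param kd dimensionless partition coefficient, >= 0.
#' @return list with `free` and `adsorbed`, each a [stock_pair()].
#' @export
partition_doc <- function(total, kd) {
  if (!is.numeric(kd) || any(kd < 0)) stop("kd must be >= 0")
  if (!inherits(total, "stock_pair")) total <- stock_pair(total, 0 * total)
  f <- 1 / (1 + kd)
  list(free = stock_pair(total$c_total * f, total$c13 * f),
       adsorbed = stock_pair(total$c_total * (1 - f), total$c13 * (1 - f)))
}

# re-equilibrate both DOC classes of a state in place
equilibrate_sorption_core <- function(C, C13, kd) {
  f <- 1 / (1 + kd)
  for (cls in c("labile", "stable")) {
    fr <- paste0(cls, "_doc_free"); ad <- paste0(cls, "_doc_ads")
    tot <- C[, fr] + C[, ad]
    tot13 <- C13[, fr] + C13[, ad]
    C[, fr] <- tot * f; C[, ad] <- tot * (1 - f)
    C13[, fr] <- tot13 * f; C13[, ad] <- tot13 * (1 - f)
  }
  list(C = C, C13 = C13)
}

#' Re-equilibrate DOC sorption in a column state
#'
#' Applies [partition_doc()] to both DOC reactivity classes in every layer.
#'
#' @param state a [column_state()].
#' @param kd dimensionless partition coefficient.
#' @return the updated state.
#' @export
equilibrate_sorption <- function(state, kd) {
  res <- equilibrate_sorption_core(state$C, state$C13, kd)
  state$C <- res$C; state$C13 <- res$C13
  state
}

#' Depth profile of the diffusion coefficient
#'
#' `D(z) = d0 * exp(-z / d_efold)` evaluated at the internal layer
#' interfaces. `d_efold = Inf` gives a depth-constant coefficient, the
#' behaviour of models with a single bioturbation diffusivity.
#'
#' @param d0 surface diffusion coefficient, m2 yr-1, >= 0.
#' @param d_efold e-folding depth in m (> 0, may be `Inf`).
#' @param grid a [build_layer_grid()] grid.
#' @return numeric of length `n_layers - 1`, named by interface depth (m).
#' @export
diffusion_coefficient_profile <- function(d0, d_efold, grid) {
  if (d0 < 0) stop("d0 must be >= 0")
  if (d_efold <= 0) stop("d_efold must be > 0")
  z <- grid$boundaries[seq(2, grid$n_layers)]
  if (grid$n_layers == 1) return(stats::setNames(numeric(0), character(0)))
  D <- if (is.infinite(d_efold)) rep(d0, length(z)) else d0 * exp(-z / d_efold)
  stats::setNames(D, format(signif(z, 6)))
}

# Implicit (backward Euler) step matrix for the conservative finite-volume
# discretisation of d(c)/dt = d/dz (D(z) dc/dz) on the non-uniform grid,
# acting on per-layer *stocks* (g C m-2). Zero-flux at top and bottom; the
# columns of the generator sum to zero, so the implicit step conserves column
# mass to solver precision and is unconditionally stable.
diffusion_step_matrix <- function(grid, D_int, dt) {
  n <- grid$n_layers
  if (n == 1) return(matrix(1, 1, 1))
  h <- grid$thickness
  dz <- diff(grid$node_depth)
  g <- D_int / dz                       # interface conductances
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    A[i, i] <- A[i, i] - g[i] / h[i]
    A[i, i + 1] <- A[i, i + 1] + g[i] / h[i + 1]
    A[i + 1, i] <- A[i + 1, i] + g[i] / h[i]
    A[i + 1, i + 1] <- A[i + 1, i + 1] - g[i] / h[i + 1]
  }
  solve(diag(n) - dt * A)
}

#' Diffuse solid pools and free DOC vertically
#'
#' Implicit (unconditionally stable) step of Fick's second law with a
#' depth-dependent coefficient and zero-flux boundaries, applied to the
#' below-ground litter, SOC, and free DOC pools (adsorbed DOC is
#' immobilised). Column totals of both isotopes are conserved.
#'
#' @param state a [column_state()].
#' @param params an [iso_params()] (supplies `d0`, `d_efold`); ignored if
#'   `D_int` is given.
#' @param dt time step, yr.
#' @param D_int optional diffusion coefficients at the internal interfaces
#'   (length `n_layers - 1`), overriding the parameterised profile.
#' @param pools layered pools to diffuse; default the standard set.
#' @return the updated state.
#' @export
diffuse <- function(state, params = NULL, dt, D_int = NULL,
                    pools = DIFFUSING_POOLS) {
  g <- state$grid
  if (is.null(D_int)) {
    stopifnot(inherits(params, "iso_params"))
    D_int <- diffusion_coefficient_profile(params$d0, params$d_efold, g)
  }
  if (any(D_int < 0)) stop("diffusion coefficients must be >= 0")
  M <- diffusion_step_matrix(g, D_int, dt)
  state$C[, pools] <- M %*% state$C[, pools, drop = FALSE]
  state$C13[, pools] <- M %*% state$C13[, pools, drop = FALSE]
  state
}

# upwind advection core; returns updated matrices and per-pool export pairs
advect_core <- function(C, C13, rates, dt, max_substeps = 10000L) {
  n <- nrow(C)
  nsub <- max(1L, ceiling(max(rates) * dt))
  if (nsub > max_substeps) {
    stop("advection CFL sub-stepping exceeds max_substeps; reduce dt or rates")
  }
  dts <- dt / nsub
  f <- rates * dts                      # per-sub-step fractional throughput
  exp_tot <- stats::setNames(numeric(length(ADVECTING_POOLS)), ADVECTING_POOLS)
  exp_13 <- exp_tot
  for (s in seq_len(nsub)) {
    for (p in ADVECTING_POOLS) {
      out <- C[, p] * f
      out13 <- C13[, p] * f
      C[, p] <- C[, p] - out
      C13[, p] <- C13[, p] - out13
      if (n > 1) {
        C[2:n, p] <- C[2:n, p] + out[1:(n - 1)]
        C13[2:n, p] <- C13[2:n, p] + out13[1:(n - 1)]
      }
      exp_tot[p] <- exp_tot[p] + out[n]
      exp_13[p] <- exp_13[p] + out13[n]
    }
  }
  list(C = C, C13 = C13, export_total = exp_tot, export_c13 = exp_13)
}

#' Advect free DOC downward with the soil-water flux
#'
#' Upwind transport: the flux out of layer `i` over a sub-step is the free
#' DOC stock times the fractional water throughput `rate(i)`, delivered to
#' layer `i + 1`; the bottom-layer flux leaves the column as export. The step
#' is split into sub-steps so that `rate * dt_sub <= 1` (CFL). Column change
#' plus export is zero for both isotopes.
#'
#' @param state a [column_state()].
#' @param rates per-layer fractional throughput (yr-1), scalar or length
#'   `n_layers`, >= 0.
#' @param dt time step, yr.
#' @return list with `state` and `export`, the latter a list with
#'   `c_total` and `c13` bottom-export totals (g C m-2 per step, summed over
#'   the two free DOC pools) plus per-pool vectors.
#' @export
advect_doc <- function(state, rates, dt) {
  n <- state$grid$n_layers
  if (length(rates) == 1) rates <- rep(rates, n)
  if (length(rates) != n || any(rates < 0)) {
    stop("rates must be a scalar or per-layer vector of values >= 0")
  }
  res <- advect_core(state$C, state$C13, rates, dt)
  state$C <- res$C; state$C13 <- res$C13
  list(state = state,
       export = list(c_total = sum(res$export_total),
                     c13 = sum(res$export_c13),
                     by_pool_total = res$export_total,
                     by_pool_c13 = res$export_c13))
}
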