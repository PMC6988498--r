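# Pool enumeration. Above-ground litter lives in a surface compartment (not
# layered); everything else exists in every layer. Adsorbed DOC is immobilised:
# it neither decomposes nor moves.

#' Pool names of the layered compartments
#' @export
LAYERED_POOLS <- c(
  "metabolic_bg_litter", "structural_bg_litter",
  "active_soc", "slow_soc", "passive_soc",
  "labile_doc_free", "labile_doc_ads",
  "stable_doc_free", "stable_doc_ads"
)

#' Pool names of the surface (above-ground litter) compartments
#' @export
SURFACE_POOLS <- c("metabolic_ag_litter", "structural_ag_litter")

# pools subject to each process
DECOMPOSABLE_LAYERED <- c(
  "metabolic_bg_litter", "structural_bg_litter",
  "active_soc", "slow_soc", "passive_soc",
  "labile_doc_free", "stable_doc_free"
)
DIFFUSING_POOLS <- c(
  "metabolic_bg_litter", "structural_bg_litter",
  "active_soc", "slow_soc", "passive_soc",
  "labile_doc_free", "stable_doc_free"
)
ADVECTING_POOLS <- c("labile_doc_free", "stable_doc_free")
SOC_POOLS <- c("active_soc", "slow_soc", "passive_soc")
DOC_POOLS <- c("labile_doc_free", "labile_doc_ads",
               "stable_doc_free", "stable_doc_ads")

#' Build the vertical layer grid
#'
#' Discretises a soil column into `n_layers` layers of geometrically
#' increasing thickness: `thickness(i+1) = ratio * thickness(i)`, summing
#' exactly to `total_depth`. The default 11 layers over 2 m with ratio 1.53
#' give a top layer of about 1 cm, resolving the steep near-surface carbon
#' gradient while keeping deep layers coarse.
#'
#' @param n_layers number of layers (>= 1); default 11.
#' @param total_depth column depth in m (> 0); default 2.
#' @param ratio geometric thickness ratio (>= 1); 1 gives uniform layers.
#' @return A list of class `layer_grid` with `n_layers`, `total_depth`,
#'   `ratio`, `boundaries` (length `n_layers + 1`, starting at 0),
#'   `thickness`, and `node_depth` (layer midpoints), all in m, depth
#'   positive downward from the soil surface.
#' @export
build_layer_grid <- function(n_layers = 11, total_depth = 2, ratio = 1.53) {
  if (!is.numeric(n_layers) || length(n_layers) != 1 || n_layers < 1 ||
      n_layers != round(n_layers)) {
    stop("n_layers must be a positive integer")
  }
  if (!is.numeric(total_depth) || total_depth <= 0) {
    stop("total_depth must be > 0")
  }
  if (!is.numeric(ratio) || ratio < 1) stop("ratio must be >= 1")
  n_layers <- as.integer(n_layers)
  if (ratio == 1) {
    h1 <- total_depth / n_layers
  } else {
    h1 <- total_depth * (ratio - 1) / (ratio^n_layers - 1)
  }
  thickness <- h1 * ratio^(seq_len(n_layers) - 1)
  # absorb floating-point residue into the bottom layer so the column closes
  thickness[n_layers] <- thickness[n_layers] +
    (total_depth - sum(thickness))
  boundaries <- c(0, cumsum(thickness))
  structure(
    list(
      n_layers = n_layers, total_depth = total_depth, ratio = ratio,
      boundaries = boundaries, thickness = thickness,
      node_depth = (boundaries[-1] + boundaries[-(n_layers + 1)]) / 2
    ),
    class = "layer_grid"
  )
}

#' @export
print.layer_grid <- function(x, ...) {
  cat("<layer_grid>", x$n_layers, "layers to", x$total_depth,
      "m, ratio", x$ratio, "\n")
  cat("  thickness (m):", paste(signif(x$thickness, 3), collapse = " "), "\n")
  invisible(x)
}

#' Construct an empty or pre-filled column state
#'
#' The state carries, per layer and per layered pool, a paired stock of total
#' carbon and 13C (g C m-2 per layer), plus the two surface above-ground
#' litter pools and the model time in years.
#'
#' @param grid a [build_layer_grid()] grid.
#' @param C optional `n_layers x 9` matrix of total C stocks (columns
#'   [LAYERED_POOLS]); default all zero.
#' @param C13 optional matrix of 13C stocks, same shape; default all zero.
#' @param surface optional named numeric of surface total C for
#'   [SURFACE_POOLS]; default zero.
#' @param surface13 optional matching surface 13C stocks; default zero.
#' @param time model time in years; default 0.
#' @return A list of class `column_state`.
#' @export
column_state <- function(grid, C = NULL, C13 = NULL,
                         surface = NULL, surface13 = NULL, time = 0) {
  stopifnot(inherits(grid, "layer_grid"))
  n <- grid$n_layers
  zero <- matrix(0, n, length(LAYERED_POOLS),
                 dimnames = list(NULL, LAYERED_POOLS))
  if (is.null(C)) C <- zero
  if (is.null(C13)) C13 <- zero
  C <- as.matrix(C); C13 <- as.matrix(C13)
  stopifnot(identical(dim(C), dim(zero)), identical(dim(C13), dim(zero)))
  colnames(C) <- LAYERED_POOLS; colnames(C13) <- LAYERED_POOLS
  zs <- stats::setNames(numeric(length(SURFACE_POOLS)), SURFACE_POOLS)
  if (is.null(surface)) surface <- zs
  if (is.null(surface13)) surface13 <- zs
  surface <- surface[SURFACE_POOLS]; surface13 <- surface13[SURFACE_POOLS]
  names(surface) <- SURFACE_POOLS; names(surface13) <- SURFACE_POOLS
  st <- structure(
    list(grid = grid, C = C, C13 = C13,
         surface = surface, surface13 = surface13, time = time),
    class = "column_state"
  )
  validate_state(st)
  st
}

# invariant guard used after operations in user-facing paths
validate_state <- function(state, tol = 1e-9) {
  with(state, {
    if (any(C < -tol) || any(C13 < -tol) ||
        any(surface < -tol) || any(surface13 < -tol)) {
      stop("negative stock in column state")
    }
    if (any(C13 > C * (1 + 1e-12) + tol) ||
        any(surface13 > surface * (1 + 1e-12) + tol)) {
      stop("13C stock exceeds total carbon stock")
    }
  })
  invisible(state)
}

#' @export
print.column_state <- function(x, ...) {
  cat("<column_state> t =", x$time, "yr;",
      x$grid$n_layers, "layers; total C =",
      format(signif(total_column_carbon(x), 6)), "g C m-2\n")
  invisible(x)
}

#' Total column carbon (layered pools plus surface litter)
#'
#' @param state a [column_state()].
#' @param isotope `"total"` or `"c13"`.
#' @return total stock in g C m-2.
#' @export
total_column_carbon <- function(state, isotope = c("total", "c13")) {
  isotope <- match.arg(isotope)
  if (isotope == "total") sum(state$C) + sum(state$surface)
  else sum(state$C13) + sum(state$surface13)
}

#' Integrate layered stocks down to a given depth
#'
#' Sums the stocks of the requested pools over all layers lying fully above
#' `depth`, plus a thickness-proportional share of the layer straddling it
#' (stocks are taken as uniform within a layer). Surface litter pools are not
#' included.
#'
#' @param state a [column_state()].
#' @param pools character vector of layered pool names; default the three
#'   SOC pools.
#' @param depth integration depth in m, in `(0, total_depth]`; default 1.
#' @param isotope `"total"` or `"c13"`.
#' @return integrated stock in kg C m-2.
#' @export
stock_to_depth <- function(state, pools = SOC_POOLS, depth = 1,
                           isotope = c("total", "c13")) {
  isotope <- match.arg(isotope)
  g <- state$grid
  if (!is.numeric(depth) || depth <= 0 || depth > g$total_depth + 1e-12) {
    stop("depth must be in (0, total_depth]")
  }
  bad <- setdiff(pools, LAYERED_POOLS)
  if (length(bad)) stop("unknown layered pool(s): ", paste(bad, collapse = ", "))
  M <- if (isotope == "total") state$C else state$C13
  per_layer <- rowSums(M[, pools, drop = FALSE])
  top <- g$boundaries[-(g$n_layers + 1)]
  bot <- g$boundaries[-1]
  frac <- pmax(0, pmin(depth - top, bot - top)) / (bot - top)
  sum(per_layer * frac) / 1000
}

#' Default pool groupings for delta-13C profiles
#'
#' `total` is all layered pools (litter + SOC + DOC); the remaining groups
#' follow the conventional output decomposition: each SOC pool separately,
#' below-ground litter, and DOC.
#' @return named list of character vectors of pool names.
#' @export
default_pool_groups <- function() {
  list(
    total = LAYERED_POOLS,
    active_soc = "active_soc",
    slow_soc = "slow_soc",
    passive_soc = "passive_soc",
    bg_litter = c("metabolic_bg_litter", "structural_bg_litter"),
    doc = DOC_POOLS
  )
}

#' Per-layer delta-13C profile by pool group
#'
#' Pools the paired stocks within each group per layer (mixing happens on the
#' stocks, i.e. on ratio-weighted isotope masses) and converts to delta.
#' Layers where a group holds no carbon are flagged `NA` (undefined delta).
#'
#' @param state a [column_state()].
#' @param pool_groups named list of pool-name vectors; default
#'   [default_pool_groups()].
#' @return A data.frame with columns `layer`, `depth` (node depth, m),
#'   `group`, `c_total`, `c13`, `delta13c`.
#' @export
delta_profile <- function(state, pool_groups = default_pool_groups()) {
  stopifnot(is.list(pool_groups), !is.null(names(pool_groups)))
  g <- state$grid
  out <- lapply(names(pool_groups), function(nm) {
    pools <- pool_groups[[nm]]
    bad <- setdiff(pools, LAYERED_POOLS)
    if (length(bad)) stop("unknown pool(s) in group '", nm, "': ",
                          paste(bad, collapse = ", "))
    ct <- rowSums(state$C[, pools, drop = FALSE])
    c13 <- rowSums(state$C13[, pools, drop = FALSE])
    data.frame(
      layer = seq_len(g$n_layers), depth = g$node_depth, group = nm,
      c_total = ct, c13 = c13,
      delta13c = delta_of_stock_pair(ct, c13),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Flatten a column state to a tidy data.frame
#'
#' One row per (layer, pool) plus the surface pools (layer `NA`), with
#' columns `time`, `layer`, `depth`, `pool`, `c_total`, `c13`, `delta13c`.
#'
#' @param state a [column_state()].
#' @return a data.frame in the package's tidy snapshot convention.
#' @export
state_to_df <- function(state) {
  g <- state$grid
  lay <- expand.grid(layer = seq_len(g$n_layers), pool = LAYERED_POOLS,
                     stringsAsFactors = FALSE)
  lay$depth <- g$node_depth[lay$layer]
  lay$c_total <- as.vector(state$C)
  lay$c13 <- as.vector(state$C13)
  surf <- data.frame(layer = NA_integer_, pool = SURFACE_POOLS,
                     depth = NA_real_,
                     c_total = unname(state$surface),
                     c13 = unname(state$surface13),
                     stringsAsFactors = FALSE)
  df <- rbind(lay, surf)
  df$delta13c <- delta_of_stock_pair(df$c_total, df$c13)
  df$time <- state$time
  df[, c("time", "layer", "depth", "pool", "c_total", "c13", "delta13c")]
}
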