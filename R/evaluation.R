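# Model-data comparison on depth profiles: interval harmonisation, and the
# mean squared deviation decomposition used to rank simulations.

#' Construct an observed depth-profile table
#'
#' @param depth_top,depth_bottom interval bounds in m (non-overlapping,
#'   increasing).
#' @param soc_stock optional SOC stock per interval, kg C m-2.
#' @param delta13c optional delta-13C per interval, per mil.
#' @param sd optional standard deviation of the measurement.
#' @return data.frame of class `c("observed_profile", "data.frame")`.
#' @export
observed_profile <- function(depth_top, depth_bottom, soc_stock = NULL,
                             delta13c = NULL, sd = NULL) {
  n <- length(depth_top)
  stopifnot(length(depth_bottom) == n)
  if (any(depth_bottom <= depth_top)) stop("intervals must have bottom > top")
  if (n > 1 && any(depth_top[-1] < depth_bottom[-n])) {
    stop("intervals must be non-overlapping and increasing")
  }
  if (is.null(soc_stock) && is.null(delta13c)) {
    stop("at least one of soc_stock, delta13c must be given")
  }
  df <- data.frame(
    depth_top = depth_top, depth_bottom = depth_bottom,
    soc_stock = if (is.null(soc_stock)) NA_real_ else soc_stock,
    delta13c = if (is.null(delta13c)) NA_real_ else delta13c,
    sd = if (is.null(sd)) NA_real_ else sd
  )
  class(df) <- c("observed_profile", "data.frame")
  df
}

#' Harmonise a simulated profile onto observed depth intervals
#'
#' Linearly interpolates the simulated profile (given at layer node depths)
#' to the midpoints of the observation intervals, restricted to the depth
#' range the simulation covers; observation intervals whose midpoint falls
#' outside that range, or with missing values, are dropped and counted.
#'
#' @param sim_depth simulated node depths (m), increasing.
#' @param sim_value simulated values at those depths.
#' @param obs an [observed_profile()] (or data.frame with `depth_top`,
#'   `depth_bottom` and the target variable).
#' @param variable observed column to pair against, `"delta13c"` or
#'   `"soc_stock"`.
#' @return data.frame with `depth` (interval midpoint), `sim`, `obs`;
#'   attribute `n_dropped` counts discarded intervals.
#' @export
harmonize_profiles <- function(sim_depth, sim_value, obs,
                               variable = c("delta13c", "soc_stock")) {
  variable <- match.arg(variable)
  stopifnot(length(sim_depth) == length(sim_value))
  if (is.unsorted(sim_depth, strictly = TRUE)) {
    stop("sim_depth must be strictly increasing")
  }
  mid <- (obs$depth_top + obs$depth_bottom) / 2
  y <- obs[[variable]]
  inside <- mid >= min(sim_depth) & mid <= max(sim_depth) & !is.na(y)
  ok <- !is.na(sim_value)
  if (!any(inside)) stop("no overlap between simulated and observed depths")
  si <- stats::approx(sim_depth[ok], sim_value[ok], xout = mid[inside],
                      method = "linear", rule = 1)$y
  keep <- !is.na(si)
  out <- data.frame(depth = mid[inside][keep], sim = si[keep],
                    obs = y[inside][keep])
  attr(out, "n_dropped") <- nrow(obs) - nrow(out)
  out
}

#' Mean squared deviation and its decomposition
#'
#' With `x` the simulated and `y` the measured values over `N` paired
#' points: `MSD = mean((x - y)^2)` decomposes additively (Gauch-Hwang-Fick)
#' into the squared bias `SB = (mean(x) - mean(y))^2`, the non-unity slope
#' `NU = (1 - b)^2 * mean((x - mean(x))^2)` with `b` the slope of the
#' regression of measurements on simulations, and the lack of correlation
#' `LC = (1 - r^2) * mean((y - mean(y))^2)`. SB measures the mean bias,
#' NU the ability to reproduce the magnitude of fluctuations, LC the
#' ability to reproduce the shape; lower is better for all.
#'
#' @param sim,obs paired numeric vectors, `n >= 3`.
#' @return list of class `msd_result` with `msd`, `sb`, `nu`, `lc`,
#'   `n_points`, and `degenerate` (`TRUE` when the simulation has zero
#'   variance, in which case NU and LC are `NA` and `msd = sb +`
#'   observation variance).
#' @export
msd_decomposition <- function(sim, obs) {
  stopifnot(is.numeric(sim), is.numeric(obs), length(sim) == length(obs))
  keep <- !is.na(sim) & !is.na(obs)
  x <- sim[keep]; y <- obs[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired values")
  msd <- mean((x - y)^2)
  sb <- (mean(x) - mean(y))^2
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx == 0) {
    return(structure(
      list(msd = msd, sb = sb, nu = NA_real_, lc = NA_real_,
           n_points = n, degenerate = TRUE),
      class = "msd_result"
    ))
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  r2 <- if (syy == 0) 1 else sxy^2 / (sxx * syy)
  structure(
    list(msd = msd, sb = sb, nu = (1 - b)^2 * sxx / n,
         lc = (1 - r2) * syy / n, n_points = n, degenerate = FALSE),
    class = "msd_result"
  )
}

#' @export
print.msd_result <- function(x, ...) {
  cat("<msd_result> MSD =", signif(x$msd, 4), "= SB", signif(x$sb, 4),
      "+ NU", signif(x$nu, 4), "+ LC", signif(x$lc, 4),
      paste0("(n = ", x$n_points, ")"), "\n")
  invisible(x)
}

#' Rank simulations by goodness of fit
#'
#' @param results named list of [msd_decomposition()] results (names are the
#'   simulation labels), or a list of `(label, result)` pairs.
#' @return data.frame ordered by ascending MSD (alphabetical label
#'   tie-break) with columns `label`, `msd`, `sb`, `nu`, `lc`, `n_points`.
#' @export
rank_simulations <- function(results) {
  if (!length(results)) stop("results must be non-empty")
  if (is.null(names(results))) stop("results must be a named list")
  df <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(label = nm, msd = r$msd, sb = r$sb, nu = r$nu, lc = r$lc,
               n_points = r$n_points, stringsAsFactors = FALSE)
  }))
  df[order(df$msd, df$label), , drop = FALSE]
}

#' Generate a synthetic observed profile from a known configuration
#'
#' Runs the simulator at `true_config` (steady state, plus the historical
#' period when `historical = TRUE`), samples the delta-13C and SOC-stock
#' profiles onto a site-like set of depth intervals, and adds Gaussian
#' noise. Used for parameter-recovery tests; the output is synthetic, not a
#' field measurement.
#'
#' @param true_config an [iso_config()] describing the generating model.
#' @param noise_sd Gaussian noise standard deviation added to the delta
#'   values (per mil) and, scaled by the local stock, to the stocks.
#' @param seed integer seed making the noise reproducible.
#' @param intervals data.frame with `depth_top`, `depth_bottom` (m); default
#'   eight intervals to 1.6 m.
#' @param historical run the historical period after the steady state.
#' @return an [observed_profile()] with both `soc_stock` and `delta13c`.
#' @export
synthesize_observed_profile <- function(true_config, noise_sd = 0.1,
                                        seed = 1, intervals = NULL,
                                        historical = FALSE) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(intervals)) {
    edges <- c(0, 0.05, 0.1, 0.2, 0.4, 0.6, 0.9, 1.2, 1.6)
    intervals <- data.frame(depth_top = edges[-length(edges)],
                            depth_bottom = edges[-1])
  }
  state <- solve_steady_state(true_config)
  if (historical) {
    res <- run_historical(true_config, state)
    state <- res$snapshots[[length(res$snapshots)]]
  }
  prof <- delta_profile(state, pool_groups = list(total = LAYERED_POOLS))
  mid <- (intervals$depth_top + intervals$depth_bottom) / 2
  dlt <- stats::approx(prof$depth, prof$delta13c, xout = mid, rule = 2)$y
  stocks <- vapply(seq_len(nrow(intervals)), function(i) {
    stock_to_depth(state, pools = LAYERED_POOLS,
                   depth = min(intervals$depth_bottom[i],
                               state$grid$total_depth)) -
      if (intervals$depth_top[i] > 0) {
        stock_to_depth(state, pools = LAYERED_POOLS,
                       depth = intervals$depth_top[i])
      } else 0
  }, numeric(1))
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, list(
      d = stats::rnorm(length(mid), 0, noise_sd),
      s = stats::rnorm(length(mid), 0, noise_sd)
    ))
    dlt <- dlt + noise$d
    stocks <- pmax(stocks * (1 + 0.01 * noise$s), 0)
  }
  observed_profile(intervals$depth_top, intervals$depth_bottom,
                   soc_stock = stocks, delta13c = dlt)
}
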