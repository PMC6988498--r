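# Configuration parsing, CSV readers/writers, and the run manifest.
# CSV is the canonical interchange format: human-checkable and diff-able.

config_template <- function() {
  list(
    grid = list(n_layers = 11, total_depth = 2, ratio = 1.53),
    params = list(
      k = as.list(eval(formals(iso_params)$k)),
      resp_frac_doc = 0.6, clay = 0.2, kd_doc = 5, enrich = 1.0,
      epsilon_resp = 0.1, d0 = 5e-4, d_efold = 0.3, root_efold = 0.3,
      advection = 0.2, metabolic_frac = 0.5
    ),
    forcing = list(
      flux_above = 200, flux_below = 200,
      record_csv = NULL,
      scenario = list(reference_delta = -27, reference_year = 2005,
                      suess_on = TRUE, co2_effect_on = TRUE,
                      co2_slope = -0.02, switch_year = NULL,
                      switch_delta = -12.8, post_switch_trend = TRUE)
    ),
    run = list(dt = 1 / 12, start_year = 1901, end_year = 2011,
               output_every = 1, modifiers = 1),
    spinup = list(tol = 1e-3, window = 10, max_years = 20000),
    seed = 1
  )
}

check_known_keys <- function(user, template, path = "") {
  unknown <- setdiff(names(user), names(template))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        is.list(user[[nm]])) {
      check_known_keys(user[[nm]], template[[nm]], paste0(path, nm, "$"))
    }
  }
  invisible(TRUE)
}

#' Load and validate a YAML simulation configuration
#'
#' Reads a structured-text (YAML) config, rejects unknown keys by name,
#' fills defaults, and builds a fully validated [iso_config()]. See
#' `config_template()` in the package source for the accepted structure;
#' every [iso_params()] invariant is enforced.
#'
#' @param path path to a YAML file.
#' @return an [iso_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  tmpl <- config_template()
  check_known_keys(user, tmpl)
  cfg <- utils::modifyList(tmpl, user)
  k <- unlist(cfg$params$k)
  params <- iso_params(
    k = k, resp_frac_doc = cfg$params$resp_frac_doc,
    clay = cfg$params$clay, kd_doc = cfg$params$kd_doc,
    enrich = cfg$params$enrich, epsilon_resp = cfg$params$epsilon_resp,
    d0 = cfg$params$d0, d_efold = cfg$params$d_efold,
    root_efold = cfg$params$root_efold,
    advection = unlist(cfg$params$advection),
    metabolic_frac = cfg$params$metabolic_frac
  )
  grid <- build_layer_grid(cfg$grid$n_layers, cfg$grid$total_depth,
                           cfg$grid$ratio)
  sc <- cfg$forcing$scenario
  scenario <- scenario_spec(
    reference_delta = sc$reference_delta, reference_year = sc$reference_year,
    suess_on = sc$suess_on, co2_effect_on = sc$co2_effect_on,
    co2_slope = sc$co2_slope, switch_year = sc$switch_year,
    switch_delta = sc$switch_delta, post_switch_trend = sc$post_switch_trend
  )
  record <- if (!is.null(cfg$forcing$record_csv)) {
    read_atmospheric_csv(cfg$forcing$record_csv)
  } else NULL
  iso_config(
    grid = grid, params = params, record = record, scenario = scenario,
    flux_above = cfg$forcing$flux_above, flux_below = cfg$forcing$flux_below,
    modifiers = unlist(cfg$run$modifiers), dt = cfg$run$dt,
    start_year = cfg$run$start_year, end_year = cfg$run$end_year,
    output_every = cfg$run$output_every, spinup = cfg$spinup,
    seed = cfg$seed
  )
}

#' Read an atmospheric record CSV
#'
#' Expects columns `year`, `delta13c_atm`, `pco2`. Missing (gap) years are
#' filled by linear interpolation with a message; non-monotone years or
#' missing headers are format errors.
#'
#' @param path CSV path.
#' @return an atmospheric-record data.frame.
#' @export
read_atmospheric_csv <- function(path) {
  if (!file.exists(path)) stop("atmospheric record file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("year", "delta13c_atm", "pco2")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("atmospheric record is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) < 2) stop("atmospheric record must have at least 2 rows")
  if (any(diff(df$year) <= 0)) {
    stop("atmospheric record years must be strictly increasing")
  }
  years <- seq(min(df$year), max(df$year))
  if (length(years) > nrow(df)) {
    message("atmospheric record: interpolating ",
            length(years) - nrow(df), " missing year(s)")
    df <- data.frame(
      year = years,
      delta13c_atm = stats::approx(df$year, df$delta13c_atm, years)$y,
      pco2 = stats::approx(df$year, df$pco2, years)$y
    )
  }
  class(df) <- c("atmospheric_record", "data.frame")
  validate_record(df)
}

#' Read an observed depth-profile CSV
#'
#' Expects columns `depth_top`, `depth_bottom` and at least one of
#' `soc_stock`, `delta13c`; `sd` is optional.
#'
#' @param path CSV path.
#' @return an [observed_profile()].
#' @export
read_observed_profile_csv <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("depth_top", "depth_bottom")
  if (!all(need %in% names(df))) {
    stop("profile is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  observed_profile(
    df$depth_top, df$depth_bottom,
    soc_stock = if ("soc_stock" %in% names(df)) df$soc_stock else NULL,
    delta13c = if ("delta13c" %in% names(df)) df$delta13c else NULL,
    sd = if ("sd" %in% names(df)) df$sd else NULL
  )
}

#' Write a column-state snapshot as tidy CSV
#'
#' Columns: `time`, `layer`, `depth`, `pool`, `c_total`, `c13`, `delta13c`
#' (surface pools with `layer = NA`).
#'
#' @param state a [column_state()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_state_csv <- function(state, path) {
  utils::write.csv(state_to_df(state), path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy column-state CSV back into a column state
#'
#' Inverse of [write_state_csv()]; the grid must be supplied (the CSV stores
#' stocks, not the grid geometry).
#'
#' @param path CSV path.
#' @param grid the [build_layer_grid()] the snapshot was written from.
#' @return a [column_state()].
#' @export
read_state_csv <- function(path, grid) {
  df <- utils::read.csv(path)
  need <- c("time", "layer", "pool", "c_total", "c13")
  if (!all(need %in% names(df))) {
    stop("state CSV is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  n <- grid$n_layers
  C <- matrix(0, n, length(LAYERED_POOLS),
              dimnames = list(NULL, LAYERED_POOLS))
  C13 <- C
  lay <- df[!is.na(df$layer), ]
  C[cbind(lay$layer, match(lay$pool, LAYERED_POOLS))] <- lay$c_total
  C13[cbind(lay$layer, match(lay$pool, LAYERED_POOLS))] <- lay$c13
  surf <- df[is.na(df$layer), ]
  surface <- stats::setNames(surf$c_total[match(SURFACE_POOLS, surf$pool)],
                             SURFACE_POOLS)
  surface13 <- stats::setNames(surf$c13[match(SURFACE_POOLS, surf$pool)],
                               SURFACE_POOLS)
  column_state(grid, C = C, C13 = C13, surface = surface,
               surface13 = surface13, time = df$time[1])
}

#' Write a simulation result to a directory
#'
#' Emits `annual_fluxes.csv`, one tidy `state_<year>.csv` per snapshot, and
#' a JSON run manifest listing them.
#'
#' @param result a `sim_result` from [run_historical()].
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the manifest.
#' @return the manifest list, invisibly.
#' @export
write_result <- function(result, dir, seed = result$config$seed) {
  stopifnot(inherits(result, "sim_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- "annual_fluxes.csv"
  utils::write.csv(result$annual, file.path(dir, "annual_fluxes.csv"),
                   row.names = FALSE)
  for (y in names(result$snapshots)) {
    f <- paste0("state_", y, ".csv")
    write_state_csv(result$snapshots[[y]], file.path(dir, f))
    files <- c(files, f)
  }
  manifest <- run_manifest(result$config, seed = seed, files = files,
                           start_year = result$config$start_year,
                           end_year = result$config$end_year)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  missing_files <- files[!file.exists(file.path(dir, files))]
  if (length(missing_files)) {
    stop("manifest lists files that were not written: ",
         paste(missing_files, collapse = ", "))
  }
  invisible(manifest)
}

#' Build a run manifest
#'
#' A small JSON-serialisable record of a run: a deterministic digest of the
#' configuration, the seed, the model-year span, an optional convergence
#' summary, and the output file inventory.
#'
#' @param config an [iso_config()].
#' @param seed the seed used.
#' @param files character vector of output file names.
#' @param start_year,end_year model-year span.
#' @param convergence optional `spinup_report`.
#' @return a named list.
#' @export
run_manifest <- function(config, seed, files = character(),
                         start_year = config$start_year,
                         end_year = config$end_year, convergence = NULL) {
  list(
    config_digest = rlang::hash(config_comparable(config)),
    package_version = as.character(utils::packageVersion("isocolumn")),
    seed = seed,
    start_year = start_year,
    end_year = end_year,
    convergence = if (!is.null(convergence)) {
      list(converged = convergence$converged,
           years_run = convergence$years_run,
           max_drift = max(convergence$final_drift))
    },
    files = as.list(files)
  )
}
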