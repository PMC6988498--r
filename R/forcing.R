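# Litter-input forcing: the model's only carbon entry point. Litter delta-13C
# is imposed directly (no vegetation model): a yearly series reconstructed
# from the atmospheric Suess effect plus a CO2-fertilization discrimination
# trend, anchored at a site reference measurement, optionally interrupted by
# an abrupt C3 -> C4 vegetation switch.

#' Scenario specification for the litter delta-13C series
#'
#' @param reference_delta litter delta-13C (per mil) at the reference year —
#'   typically a leaf or topsoil measurement.
#' @param reference_year year the reference value anchors; must lie within
#'   the atmospheric record.
#' @param suess_on include the atmospheric Suess-effect component.
#' @param co2_effect_on include the CO2-fertilization discrimination
#'   component.
#' @param co2_slope discrimination slope in per mil per ppm, <= 0; the
#'   default -0.02 encodes a 2 per mil depletion per 100 ppm pCO2 increase.
#' @param switch_year optional first year of C4 vegetation (e.g. a maize
#'   crop); `NULL` for no switch.
#' @param switch_delta litter delta-13C of the C4 vegetation, default -12.8.
#' @param post_switch_trend if `TRUE` (default) the post-switch series keeps
#'   following the Suess/CO2 adjustments relative to the switch year; if
#'   `FALSE` it is held flat at `switch_delta`.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(reference_delta = -27, reference_year = 2005,
                          suess_on = TRUE, co2_effect_on = TRUE,
                          co2_slope = -0.02, switch_year = NULL,
                          switch_delta = -12.8, post_switch_trend = TRUE) {
  if (co2_slope > 0) stop("co2_slope must be <= 0 (depletion with rising pCO2)")
  if (reference_delta <= -1000) stop("reference_delta must be > -1000")
  structure(
    list(reference_delta = reference_delta, reference_year = reference_year,
         suess_on = isTRUE(suess_on), co2_effect_on = isTRUE(co2_effect_on),
         co2_slope = co2_slope, switch_year = switch_year,
         switch_delta = switch_delta,
         post_switch_trend = isTRUE(post_switch_trend)),
    class = "scenario_spec"
  )
}

validate_record <- function(record) {
  need <- c("year", "delta13c_atm", "pco2")
  if (!is.data.frame(record) || !all(need %in% names(record))) {
    stop("atmospheric record needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(record) < 2 || any(diff(record$year) <= 0)) {
    stop("atmospheric record years must be strictly increasing (n >= 2)")
  }
  if (any(record$pco2 <= 0)) stop("pco2 must be > 0")
  invisible(record)
}

#' Synthetic atmospheric delta-13C / pCO2 record
#'
#' A deterministic, smooth, seed-reproducible stand-in for the historical
#' atmospheric record (which the user can supply instead as a CSV): pCO2
#' rises from ~285 to ~390 ppm and atmospheric delta-13C declines from
#' ~-6.4 to ~-8.4 per mil over an 1850-2011-like span, following an
#' accelerating (power-law) trajectory with small seeded increment jitter
#' that preserves strict monotonicity and the endpoint values. This file is
#' synthetic: it emulates the shape of the observed record, not its values
#' year by year.
#'
#' @param start_year,end_year span of the record (start < end).
#' @param seed integer seed for the increment jitter.
#' @return data.frame with columns `year`, `delta13c_atm` (per mil),
#'   `pco2` (ppm); class `c("atmospheric_record", "data.frame")`.
#' @export
fixture_atmospheric_record <- function(start_year = 1850, end_year = 2011,
                                       seed = 1) {
  if (start_year >= end_year) stop("start_year must be < end_year")
  years <- seq(start_year, end_year)
  s <- (years - start_year) / (end_year - start_year)
  base <- s^2.5                         # slow onset, accelerating rise
  inc <- diff(base)
  jitter <- withr::with_seed(seed, stats::runif(length(inc), -0.3, 0.3))
  inc <- inc * (1 + jitter)             # jittered but strictly positive
  shape <- c(0, cumsum(inc)) / sum(inc) # renormalised to [0, 1]
  rec <- data.frame(
    year = years,
    delta13c_atm = -6.4 - 2.0 * shape,
    pco2 = 285 + 105 * shape
  )
  class(rec) <- c("atmospheric_record", "data.frame")
  validate_record(rec)
}

lookup_record <- function(record, years, what) {
  idx <- match(years, record$year)
  if (anyNA(idx)) {
    stop("year(s) outside the atmospheric record span: ",
         paste(years[is.na(idx)], collapse = ", "))
  }
  record[[what]][idx]
}

#' Build the yearly litter delta-13C series
#'
#' For each year of the atmospheric record,
#' `delta(y) = reference_delta + suess(y) + co2(y)` where
#' `suess(y) = delta13c_atm(y) - delta13c_atm(ref)` (if enabled) and
#' `co2(y) = co2_slope * (pCO2(y) - pCO2(ref))` (if enabled). The series
#' passes through `(reference_year, reference_delta)` exactly, and the two
#' components are returned separately so they can be plotted or summed
#' independently (component additivity is exact).
#'
#' @param record an atmospheric record data.frame (`year`, `delta13c_atm`,
#'   `pco2`).
#' @param spec a [scenario_spec()].
#' @return data.frame with columns `year`, `delta13c`, `suess_component`,
#'   `co2_component`.
#' @export
build_litter_delta_series <- function(record, spec) {
  validate_record(record)
  stopifnot(inherits(spec, "scenario_spec"))
  if (!spec$reference_year %in% record$year) {
    stop("reference_year ", spec$reference_year,
         " is outside the atmospheric record")
  }
  d_ref <- lookup_record(record, spec$reference_year, "delta13c_atm")
  p_ref <- lookup_record(record, spec$reference_year, "pco2")
  suess <- if (spec$suess_on) record$delta13c_atm - d_ref else 0 * record$year
  co2 <- if (spec$co2_effect_on) {
    spec$co2_slope * (record$pco2 - p_ref)
  } else 0 * record$year
  data.frame(
    year = record$year,
    delta13c = spec$reference_delta + suess + co2,
    suess_component = suess,
    co2_component = co2
  )
}

#' Impose an abrupt C3 -> C4 vegetation switch on a litter delta series
#'
#' From `switch_year` onward the series takes the C4 litter value
#' `switch_delta`; with `post_switch_trend = TRUE` the Suess/CO2 adjustments
#' continue relative to the switch year (the post-switch line keeps its
#' slow drift), otherwise the plateau is flat. Years before the switch are
#' unchanged. A `NULL` `switch_year` returns the series as is.
#'
#' @param series output of [build_litter_delta_series()].
#' @param spec a [scenario_spec()] carrying `switch_year`, `switch_delta`,
#'   `post_switch_trend`.
#' @return the modified series data.frame.
#' @export
apply_vegetation_switch <- function(series, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(spec$switch_year)) return(series)
  sw <- spec$switch_year
  if (sw > max(series$year)) {
    stop("switch_year is after the end of the series")
  }
  post <- series$year >= sw
  if (!any(post)) return(series)
  if (spec$post_switch_trend && sw >= min(series$year)) {
    i0 <- which(series$year == max(series$year[series$year <= sw]))
    drift <- (series$suess_component[post] - series$suess_component[i0]) +
      (series$co2_component[post] - series$co2_component[i0])
  } else {
    drift <- 0
  }
  series$delta13c[post] <- spec$switch_delta + drift
  series
}

#' Split a litter delta series into above- and below-ground values
#'
#' Below-ground litter (roots) is enriched relative to above-ground litter
#' (leaves) by the fixed `enrich` parameter: `delta_below = delta + enrich`,
#' `delta_above = delta`, every year.
#'
#' @param series data.frame with a `delta13c` column.
#' @param enrich enrichment in per mil (default +1).
#' @return the series with added `delta_above` and `delta_below` columns.
#' @export
split_above_below <- function(series, enrich = 1) {
  series$delta_above <- series$delta13c
  series$delta_below <- series$delta13c + enrich
  series
}

#' Assemble the complete yearly litter forcing
#'
#' Builds the delta series from the atmospheric record and scenario, applies
#' the optional vegetation switch and the root-enrichment split, and attaches
#' constant (or per-year) litter carbon fluxes.
#'
#' @param record atmospheric record data.frame.
#' @param spec a [scenario_spec()].
#' @param flux_above,flux_below above-/below-ground litter carbon input
#'   (g C m-2 yr-1); scalars or vectors over the record years.
#' @param enrich root enrichment, per mil.
#' @return data.frame of class `c("litter_forcing", "data.frame")` with
#'   columns `year`, `flux_above`, `flux_below`, `delta_above`,
#'   `delta_below` (plus the component columns).
#' @export
make_litter_forcing <- function(record, spec, flux_above = 200,
                                flux_below = 200, enrich = 1) {
  if (any(flux_above < 0) || any(flux_below < 0)) {
    stop("litter fluxes must be >= 0")
  }
  ser <- build_litter_delta_series(record, spec)
  ser <- apply_vegetation_switch(ser, spec)
  ser <- split_above_below(ser, enrich)
  ser$flux_above <- rep_len(flux_above, nrow(ser))
  ser$flux_below <- rep_len(flux_below, nrow(ser))
  out <- ser[, c("year", "flux_above", "flux_below", "delta_above",
                 "delta_below", "delta13c", "suess_component",
                 "co2_component")]
  class(out) <- c("litter_forcing", "data.frame")
  out
}

# constant forcing row used during spin-up: the series value at `year`
# (by default the first year), fluxes held constant
forcing_at_year <- function(forcing, year) {
  i <- match(year, forcing$year)
  if (is.na(i)) stop("forcing does not cover year ", year)
  forcing[i, , drop = FALSE]
}
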