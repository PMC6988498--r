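# Default flux topology: all decomposed litter and SOC enter the free DOC
# pools (labile for metabolic litter and active SOC, stable for structural
# litter and the slow/passive pools); decomposed DOC is partly respired and
# the remainder returned to the SOC pools — labile DOC to the active pool,
# stable DOC split 90/10 between the slow and passive pools, so every SOC
# pool has a supply pathway. Each donor's receiver fractions plus its
# respired fraction must sum to 1.
default_transfers <- function(resp_frac_doc = 0.6) {
  ret <- 1 - resp_frac_doc
  list(
    metabolic_ag_litter  = list(to = c(labile_doc_free = 1), resp = 0),
    structural_ag_litter = list(to = c(stable_doc_free = 1), resp = 0),
    metabolic_bg_litter  = list(to = c(labile_doc_free = 1), resp = 0),
    structural_bg_litter = list(to = c(stable_doc_free = 1), resp = 0),
    active_soc           = list(to = c(labile_doc_free = 1), resp = 0),
    slow_soc             = list(to = c(stable_doc_free = 1), resp = 0),
    passive_soc          = list(to = c(stable_doc_free = 1), resp = 0),
    labile_doc_free      = list(to = c(active_soc = ret),
                                resp = resp_frac_doc),
    stable_doc_free      = list(to = c(slow_soc = 0.9 * ret,
                                       passive_soc = 0.1 * ret),
                                resp = resp_frac_doc)
  )
}

#' Model parameters
#'
#' Bundles every tunable of the column model. The base decomposition rate
#' constants and DOC coefficients are order-of-magnitude CENTURY-like
#' defaults, deliberately uncalibrated (the package's behaviour is checked by
#' structural properties, not stock matching); they all sit here so a site
#' parameterisation is one object.
#'
#' @param k named numeric of base first-order rate constants (yr-1) for the
#'   decomposable pools: the four litter pools, three SOC pools, and the two
#'   free DOC pools.
#' @param resp_frac_doc fraction of decomposed DOC respired as CO2 (the rest
#'   returns to SOC per the transfer topology), in `[0, 1]`.
#' @param transfers flux-routing list: per donor pool a named `to` vector of
#'   receiver fractions and a `resp` respired fraction summing to 1; default
#'   built from `resp_frac_doc`.
#' @param clay soil clay mass fraction in `[0, 1]`; slows active-pool
#'   decomposition via [clay_rate_modifier()].
#' @param kd_doc dimensionless equilibrium sorption partition coefficient,
#'   adsorbed/free DOC at equilibrium, >= 0.
#' @param enrich root (below-ground litter) delta-13C enrichment relative to
#'   leaves, per mil; default +1.
#' @param epsilon_resp respiration discrimination factor, per mil: respired
#'   CO2 is depleted by this amount relative to its substrate; default 0.1.
#' @param d0 surface diffusion coefficient (bioturbation proxy), m2 yr-1.
#' @param d_efold e-folding depth (m) of the diffusion coefficient;
#'   `Inf` recovers a depth-constant coefficient.
#' @param root_efold e-folding depth (m) of the below-ground litter input
#'   profile.
#' @param advection per-layer fractional water throughput of free DOC
#'   (yr-1); a scalar is recycled over layers.
#' @param metabolic_frac fraction of litter input entering the metabolic
#'   (vs structural) pools, in `[0, 1]`.
#' @return a validated list of class `iso_params`.
#' @export
iso_params <- function(
    k = c(metabolic_ag_litter = 8, structural_ag_litter = 2.5,
          metabolic_bg_litter = 8, structural_bg_litter = 2.5,
          active_soc = 1.0, slow_soc = 0.03, passive_soc = 0.001,
          labile_doc_free = 20, stable_doc_free = 5),
    resp_frac_doc = 0.6,
    transfers = default_transfers(resp_frac_doc),
    clay = 0.20,
    kd_doc = 5,
    enrich = 1.0,
    epsilon_resp = 0.1,
    d0 = 5e-4,
    d_efold = 0.3,
    root_efold = 0.3,
    advection = 0.2,
    metabolic_frac = 0.5) {
  defaults <- eval(formals(iso_params)$k)
  if (is.null(names(k)) || !setequal(names(k), names(defaults))) {
    stop("k must be named for every decomposable pool: ",
         paste(names(defaults), collapse = ", "))
  }
  k <- k[names(defaults)]
  if (any(k < 0)) stop("rate constants must be >= 0")
  if (resp_frac_doc < 0 || resp_frac_doc > 1) stop("resp_frac_doc in [0,1]")
  if (clay < 0 || clay > 1) stop("clay must be in [0, 1]")
  if (kd_doc < 0) stop("kd_doc must be >= 0")
  if (epsilon_resp < 0 || epsilon_resp >= 1000) {
    stop("epsilon_resp must be in [0, 1000) per mil")
  }
  if (d0 < 0) stop("d0 must be >= 0")
  if (d_efold <= 0) stop("d_efold must be > 0 (use Inf for constant D)")
  if (root_efold <= 0) stop("root_efold must be > 0")
  if (any(advection < 0)) stop("advection rates must be >= 0")
  if (metabolic_frac < 0 || metabolic_frac > 1) stop("metabolic_frac in [0,1]")
  validate_transfers(transfers, names(defaults))
  structure(
    list(k = k, resp_frac_doc = resp_frac_doc, transfers = transfers,
         clay = clay, kd_doc = kd_doc, enrich = enrich,
         epsilon_resp = epsilon_resp, d0 = d0, d_efold = d_efold,
         root_efold = root_efold, advection = advection,
         metabolic_frac = metabolic_frac),
    class = "iso_params"
  )
}

validate_transfers <- function(transfers, donors) {
  if (!setequal(names(transfers), donors)) {
    stop("transfers must name every decomposable pool as donor")
  }
  receivers <- c(LAYERED_POOLS)
  for (d in names(transfers)) {
    tr <- transfers[[d]]
    if (is.null(tr$to) || is.null(tr$resp)) {
      stop("transfer entry for '", d, "' needs 'to' and 'resp'")
    }
    bad <- setdiff(names(tr$to), receivers)
    if (length(bad)) {
      stop("transfer for donor '", d, "' routes to unknown pool(s): ",
           paste(bad, collapse = ", "))
    }
    if (any(tr$to < 0) || tr$resp < 0) {
      stop("transfer fractions for donor '", d, "' must be >= 0")
    }
    s <- sum(tr$to) + tr$resp
    if (abs(s - 1) > 1e-10) {
      stop("transfer fractions + respired fraction for donor '", d,
           "' must sum to 1 (got ", format(s), ")")
    }
  }
  invisible(TRUE)
}

#' @export
print.iso_params <- function(x, ...) {
  cat("<iso_params>\n")
  cat("  k (yr-1):", paste(names(x$k), signif(x$k, 3), sep = "=",
                           collapse = " "), "\n")
  cat("  clay =", x$clay, " kd_doc =", x$kd_doc,
      " resp_frac_doc =", x$resp_frac_doc, "\n")
  cat("  enrich =", x$enrich, "permil  epsilon_resp =", x$epsilon_resp,
      "permil\n")
  cat("  d0 =", x$d0, "m2/yr  d_efold =", x$d_efold,
      "m  root_efold =", x$root_efold, "m  advection =",
      paste(signif(x$advection, 3), collapse = " "), "yr-1\n")
  invisible(x)
}
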