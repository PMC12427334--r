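#' Cradle-to-farm-gate carbon footprint components
#'
#' Five linear emission components — feed production, transport, enteric
#' fermentation, energy use and manure management — summed into a total
#' and normalised per kilogram of live weight produced. All results are
#' in kg CO2-eq.
#'
#' @name carbon_lca
NULL

n2o_n_to_co2eq <- function(n2o_n_kg, gwp_n2o) {
  n2o_n_kg * 44 / 28 * gwp_n2o
}

#' Feed production and processing emissions
#'
#' Aggregate mode multiplies each ingredient's mass by its per-kg carbon
#' intensity. Detailed mode rebuilds the cultivation term from field
#' inputs (fertilizer production, N2O from applied N, urea, pesticide,
#' film, irrigation electricity, machinery fuel — all per hectare,
#' converted through user-supplied crop yields) plus a processing term
#' with energy-based by-product allocation; it exists for sensitivity
#' work and needs `crop_params`.
#'
#' @param ledger An `activity_ledger`.
#' @param factors An `emission_factors` set.
#' @param mode `"aggregate"` (default) or `"detailed"`.
#' @param crop_params For detailed mode: a data frame with columns `crop`,
#'   `ingredient`, `yield_t_per_ha`, `n_fert_t_per_ha`, `p_fert_t_per_ha`,
#'   `k_fert_t_per_ha`, `urea_t_per_ha`, `pesticide_t_per_ha`,
#'   `film_t_per_ha`, `processing_mj_per_kg`, `allocation_share`.
#' @return kg CO2-eq.
#' @export
cf_forage <- function(ledger, factors = default_emission_factors(),
                      mode = c("aggregate", "detailed"),
                      crop_params = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(ledger, "activity_ledger"))
  feed <- ledger$feed
  if (nrow(feed) == 0) return(0)
  if (mode == "aggregate") {
    missing <- setdiff(unique(feed$ingredient),
                       names(factors$feed_cf_per_kg))
    abort_if(length(missing) > 0, "no feed CF factor for: ",
             paste(missing, collapse = ", "))
    return(sum(feed$tonnes * 1000 *
                 factors$feed_cf_per_kg[feed$ingredient]))
  }
  abort_if(is.null(crop_params),
           "detailed mode requires 'crop_params' (incl. yield_t_per_ha)")
  total <- 0
  by_ing <- stats::aggregate(tonnes ~ ingredient, feed, sum)
  for (i in seq_len(nrow(by_ing))) {
    cp <- crop_params[crop_params$ingredient == by_ing$ingredient[i], ]
    abort_if(nrow(cp) != 1, "crop_params must cover ingredient '",
             by_ing$ingredient[i], "'")
    mass_t <- by_ing$tonnes[i]
    ha <- mass_t / cp$yield_t_per_ha
    n_applied <- cp$n_fert_t_per_ha * ha
    cultivation_t <- # everything in t CO2-eq
      n_applied * factors$fertilizer_production[["N"]] +
      cp$p_fert_t_per_ha * ha * factors$fertilizer_production[["P"]] +
      cp$k_fert_t_per_ha * ha * factors$fertilizer_production[["K"]] +
      n2o_n_to_co2eq(n_applied * factors$n2o_direct_factor,
                     factors$gwp[["N2O"]]) +
      n2o_n_to_co2eq(n_applied * factors$volatilization_rate_cultivation *
                       factors$n2o_indirect_factor, factors$gwp[["N2O"]]) +
      cp$urea_t_per_ha * ha * factors$urea_co2 +
      cp$pesticide_t_per_ha * ha * factors$pesticide_cf +
      cp$film_t_per_ha * ha * factors$film_cf +
      factors$irrigation_kwh_per_ha[[cp$crop]] / 1000 * ha *
        factors$energy_cf[["electricity"]] +
      factors$fuel_l_per_ha[[cp$crop]] * factors$diesel_kg_per_l / 1000 *
        ha * factors$energy_cf[["diesel"]]
    processing_t <- cp$processing_mj_per_kg * mass_t * 1000 / 3600 / 1000 *
      factors$energy_cf[["electricity"]]  # MJ -> MWh x EF
    total <- total + (cultivation_t + processing_t) * cp$allocation_share
  }
  total * 1000  # t -> kg CO2-eq
}

#' Energy-allocation share of a co-product
#'
#' Splits a process's emissions among its co-products in proportion to
#' energy content: the share of a by-product is its energy output over
#' the total product energy output.
#'
#' @param product_energy_mj Energy output of the product of interest, MJ.
#' @param total_energy_mj Total energy output of all co-products, MJ.
#' @return Fraction in `[0, 1]`.
#' @export
allocation_share <- function(product_energy_mj, total_energy_mj) {
  abort_if(total_energy_mj <= 0, "total energy output must be > 0")
  abort_if(product_energy_mj < 0 || product_energy_mj > total_energy_mj,
           "product energy must lie within [0, total]")
  product_energy_mj / total_energy_mj
}

#' Transport emissions
#'
#' Sum over legs of distance x tonnage x vehicle factor; the vehicle
#' factors (kg CO2-eq/km for a loaded vehicle class) are applied per
#' tonne-kilometre.
#'
#' @inheritParams cf_forage
#' @return kg CO2-eq.
#' @export
cf_transport <- function(ledger, factors = default_emission_factors()) {
  tr <- ledger$transport
  if (is.null(tr) || nrow(tr) == 0) return(0)
  unknown <- setdiff(unique(tr$vehicle), names(factors$transport_ef))
  abort_if(length(unknown) > 0, "unknown vehicle class: ",
           paste(unknown, collapse = ", "), " (valid: ",
           paste(names(factors$transport_ef), collapse = ", "), ")")
  sum(tr$distance_km * tr$tonnes * factors$transport_ef[tr$vehicle])
}

#' Weight-scaled enteric methane emission factor
#'
#' The baseline factor for a market pig at the reference weight is scaled
#' linearly by the breed's average body weight:
#' `EF(W) = baseline x W / W_ref`.
#'
#' @param avg_weight Average body weight, kg (> 0).
#' @param factors An `emission_factors` set.
#' @return kg CH4 / head / year.
#' @export
enteric_factor <- function(avg_weight, factors = default_emission_factors()) {
  abort_if(any(avg_weight <= 0), "avg_weight must be > 0")
  factors$enteric_baseline * avg_weight / factors$reference_weight
}

#' Enteric fermentation emissions
#'
#' Per breed: head count x weight-scaled CH4 factor x GWP(CH4), prorated
#' by days on farm over the year.
#'
#' @param inventory Data frame with `head`, `avg_weight_kg`, `days` (an
#'   `activity_ledger` may be passed directly).
#' @inheritParams cf_transport
#' @return kg CO2-eq.
#' @export
cf_enteric <- function(inventory, factors = default_emission_factors()) {
  if (inherits(inventory, "activity_ledger")) inventory <- inventory$inventory
  stopifnot(all(c("head", "avg_weight_kg", "days") %in% names(inventory)))
  abort_if(any(inventory$days < 0), "days on farm must be >= 0")
  sum(enteric_factor(inventory$avg_weight_kg, factors) * inventory$head *
        factors$gwp[["CH4"]] * inventory$days / 365)
}

#' Energy use emissions
#'
#' Sum over carriers of consumption x carrier factor (electricity in MWh,
#' coal and diesel in tonnes; factors in t CO2-eq per unit).
#'
#' @inheritParams cf_transport
#' @return kg CO2-eq.
#' @export
cf_energy <- function(ledger, factors = default_emission_factors()) {
  en <- if (inherits(ledger, "activity_ledger")) ledger$energy else ledger
  if (is.null(en) || nrow(en) == 0) return(0)
  unknown <- setdiff(unique(en$carrier), names(factors$energy_cf))
  abort_if(length(unknown) > 0, "unknown energy carrier: ",
           paste(unknown, collapse = ", "))
  sum(en$quantity * factors$energy_cf[en$carrier]) * 1000  # t -> kg
}

#' Manure management emissions
#'
#' Methane term: managed N x CH4 factor x GWP(CH4) (`strict_paper = TRUE`
#' instead applies GWP(N2O) to the methane term, reproducing the formula
#' as printed in the source methodology). Direct N2O: managed N allocated
#' over management systems x the per-system N2O-N factor. Indirect N2O:
#' volatilised and leached N x their respective N2O-N factors. All N2O-N
#' masses are converted to N2O by 44/28 before applying GWP(N2O).
#'
#' @param manure Data frame with `n_excreted_kg` (an `activity_ledger`
#'   may be passed directly, supplying its management fractions).
#' @param factors An `emission_factors` set.
#' @param management_fractions Named fractions over manure systems
#'   summing to 1 (taken from the ledger when one is passed).
#' @param strict_paper Logical; see above.
#' @return kg CO2-eq.
#' @export
cf_manure <- function(manure, factors = default_emission_factors(),
                      management_fractions = NULL, strict_paper = FALSE) {
  if (inherits(manure, "activity_ledger")) {
    management_fractions <- management_fractions %||%
      manure$management_fractions
    manure <- manure$manure
  }
  stopifnot("n_excreted_kg" %in% names(manure))
  abort_if(is.null(management_fractions) ||
             length(management_fractions) == 0,
           "management-system fractions are required")
  abort_if(abs(sum(management_fractions) - 1) > 1e-6,
           "management-system fractions must sum to 1")
  unknown <- setdiff(names(management_fractions),
                     names(factors$manure_n2o_direct_by_system))
  abort_if(length(unknown) > 0, "unknown manure system: ",
           paste(unknown, collapse = ", "), " (valid: ",
           paste(names(factors$manure_n2o_direct_by_system),
                 collapse = ", "), ")")
  n_total <- sum(manure$n_excreted_kg)
  gwp_ch4_term <- if (strict_paper) factors$gwp[["N2O"]] else
    factors$gwp[["CH4"]]
  ch4 <- factors$manure_ch4_factor * n_total * gwp_ch4_term
  n_by_system <- n_total * management_fractions
  direct <- n2o_n_to_co2eq(
    sum(n_by_system *
          factors$manure_n2o_direct_by_system[names(management_fractions)]),
    factors$gwp[["N2O"]])
  indirect <- n2o_n_to_co2eq(
    n_total * factors$volatilization_rate_manure *
      factors$n2o_indirect_factor +
      n_total * factors$leaching_rate_manure * factors$leaching_n2o_factor,
    factors$gwp[["N2O"]])
  ch4 + direct + indirect
}

#' Assemble the footprint breakdown
#'
#' Exact sum of the five components and normalisation by live weight.
#'
#' @param cf_forage,cf_transport,cf_enteric,cf_energy,cf_manure Component
#'   emissions, kg CO2-eq.
#' @param live_weight Total live weight produced, kg (> 0).
#' @return Object of class `footprint_breakdown` with the five
#'   components, `cf_total` and `cf_per_kg`.
#' @export
total_footprint <- function(cf_forage = 0, cf_transport = 0,
                            cf_enteric = 0, cf_energy = 0, cf_manure = 0,
                            live_weight) {
  abort_if(missing(live_weight) || live_weight <= 0,
           "live_weight must be > 0")
  comps <- c(forage = cf_forage, transport = cf_transport,
             enteric = cf_enteric, energy = cf_energy, manure = cf_manure)
  total <- sum(comps)
  structure(list(components = comps, cf_total = total,
                 live_weight = live_weight,
                 cf_per_kg = total / live_weight),
            class = "footprint_breakdown")
}

#' Full footprint of an activity ledger
#'
#' Convenience wrapper computing all five components and assembling the
#' breakdown.
#'
#' @inheritParams cf_forage
#' @param strict_paper Passed to [cf_manure()].
#' @return A `footprint_breakdown`.
#' @export
footprint_from_ledger <- function(ledger,
                                  factors = default_emission_factors(),
                                  mode = "aggregate", crop_params = NULL,
                                  strict_paper = FALSE) {
  total_footprint(
    cf_forage = cf_forage(ledger, factors, mode = mode,
                          crop_params = crop_params),
    cf_transport = cf_transport(ledger, factors),
    cf_enteric = cf_enteric(ledger, factors),
    cf_energy = cf_energy(ledger, factors),
    cf_manure = cf_manure(ledger, factors, strict_paper = strict_paper),
    live_weight = ledger$total_live_weight_kg)
}

#' @export
print.footprint_breakdown <- function(x, ...) {
  cat("Cradle-to-farm-gate carbon footprint\n")
  for (nm in names(x$components)) {
    cat(sprintf("  %-10s %12.1f kg CO2-eq\n", nm, x$components[[nm]]))
  }
  cat(sprintf("  %-10s %12.1f kg CO2-eq\n", "total", x$cf_total))
  cat(sprintf("  live weight %10.1f kg -> %.3f kg CO2-eq/kg\n",
              x$live_weight, x$cf_per_kg))
  invisible(x)
}

#' Standard error of the mean
#'
#' @param x Numeric vector.
#' @return `sd(x) / sqrt(n)`.
#' @export
sem <- function(x) stats::sd(x) / sqrt(length(x))
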