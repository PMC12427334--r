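#' Default emission-factor set
#'
#' Cradle-to-farm-gate factors for pig production: IPCC AR5 100-year
#' global-warming potentials, per-kg feed carbon intensities, fertilizer /
#' field-input factors for the detailed cultivation model, energy-carrier
#' and transport factors, the weight-scaled enteric-methane baseline, and
#' manure-management CH4/N2O parameters including the per-system direct
#' N2O factor table. Values outside the core printed set (the
#' `compound_and_other` and `fishmeal` feed factors and the manure
#' leaching-N2O factor) are package defaults, configurable like all
#' others.
#'
#' @return Object of class `emission_factors` (a named list).
#' @export
default_emission_factors <- function() {
  validate_emission_factors(structure(list(
    gwp = c(CO2 = 1, CH4 = 28, N2O = 298),
    feed_cf_per_kg = c(corn = 0.37, soybean_meal = 0.11, wheat_bran = 0.26,
                       compound_and_other = 0.55, fishmeal = 1.78),
    fertilizer_production = c(N = 2.12, P = 0.64, K = 0.18),  # t CO2-eq/t
    n2o_direct_factor = 0.01,        # t N2O-N / t applied N
    n2o_indirect_factor = 0.003,     # t N2O-N / t volatile N
    volatilization_rate_cultivation = 0.05,
    urea_co2 = 0.02,                 # t CO2 / t urea
    pesticide_cf = 12.44,            # t CO2-eq / t
    film_cf = 22.72,                 # t CO2-eq / t
    irrigation_kwh_per_ha = c(corn = 368.7, soybean = 38.7, wheat = 839.4),
    fuel_l_per_ha = c(corn = 67.85, soybean = 45.96, wheat = 78.8),
    diesel_kg_per_l = 0.84,
    energy_cf = c(electricity = 0.88,  # t CO2-eq / MWh
                  coal = 2.05,         # t CO2-eq / t
                  diesel = 3.18),      # t CO2-eq / t
    byproduct_energy_mj_per_kg = c(soybean_meal = 13.82, wheat_bran = 4.15),
    transport_ef = c(light = 0.185, medium = 0.197, heavy = 0.321),
    # kg CO2-eq per tonne-km
    enteric_baseline = 1.00,         # kg CH4 / head / year
    reference_weight = 105,          # kg, market-pig reference
    manure_ch4_factor = 0.005,       # kg CH4 / kg N (upper end of 0-0.005)
    manure_n2o_direct_by_system = c(
      open_lagoon = 0, indoor_storage = 0.002, solid_storage = 0.005,
      liquid_slurry_crust = 0.005, liquid_slurry_no_crust = 0,
      anaerobic_digester = 0, aerobic_natural = 0.01,
      aerobic_forced = 0.005, composting_container = 0.006,
      composting_intensive = 0.1, composting_passive = 0.01),
    volatilization_rate_manure = 0.01,
    leaching_rate_manure = 0.05,
    leaching_n2o_factor = 0.0075),   # kg N2O-N / kg leached N
    class = "emission_factors"))
}

#' Validate an emission-factor set
#'
#' Dimension/consistency audit applied at load time: every factor must be
#' present, numeric and non-negative; GWPs must cover CO2/CH4/N2O;
#' per-system manure N2O factors must be named. Any mismatch is a hard
#' error.
#'
#' @param factors A candidate `emission_factors` list.
#' @return The validated object, invisibly classed.
#' @export
validate_emission_factors <- function(factors) {
  required <- c("gwp", "feed_cf_per_kg", "fertilizer_production",
                "n2o_direct_factor", "n2o_indirect_factor",
                "volatilization_rate_cultivation", "urea_co2",
                "pesticide_cf", "film_cf", "irrigation_kwh_per_ha",
                "fuel_l_per_ha", "energy_cf", "byproduct_energy_mj_per_kg",
                "transport_ef", "enteric_baseline", "reference_weight",
                "manure_ch4_factor", "manure_n2o_direct_by_system",
                "volatilization_rate_manure", "leaching_rate_manure",
                "leaching_n2o_factor")
  missing <- setdiff(required, names(factors))
  abort_if(length(missing) > 0,
           "emission-factor set is missing: ", paste(missing, collapse = ", "))
  for (nm in required) {
    v <- factors[[nm]]
    abort_if(!is.numeric(v) || any(!is.finite(v)) || any(v < 0),
             "factor '", nm, "' must be finite, numeric and >= 0")
  }
  abort_if(!all(c("CO2", "CH4", "N2O") %in% names(factors$gwp)),
           "gwp must name CO2, CH4 and N2O")
  abort_if(factors$reference_weight <= 0, "reference_weight must be > 0")
  abort_if(is.null(names(factors$manure_n2o_direct_by_system)),
           "manure_n2o_direct_by_system must be a named vector")
  structure(factors, class = "emission_factors")
}

#' Read / write an emission-factor set as YAML
#'
#' @param path YAML file path.
#' @param factors An `emission_factors` object.
#' @return `read_emission_factors()` returns a validated
#'   `emission_factors`; `write_emission_factors()` returns `path`
#'   invisibly.
#' @export
read_emission_factors <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- lapply(raw, function(v) {
    if (is.list(v)) unlist(v) else v
  })
  validate_emission_factors(raw)
}

#' @rdname read_emission_factors
#' @export
write_emission_factors <- function(factors, path) {
  stopifnot(inherits(factors, "emission_factors"))
  yaml::write_yaml(lapply(unclass(factors), function(v) {
    if (!is.null(names(v))) as.list(v) else v
  }), path)
  invisible(path)
}
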