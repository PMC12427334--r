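#' Build a ration
#'
#' Ingredient percentages plus the daily feeding frequency. Components
#' must sum to 100% (within 0.01).
#'
#' @param corn,soybean_meal,wheat_bran,compound_and_other,fishmeal
#'   Percentages of the diet.
#' @param feeds_per_day Feeding frequency, times/day.
#' @return Object of class `ration`.
#' @export
ration <- function(corn, soybean_meal, wheat_bran, compound_and_other,
                   fishmeal = 0, feeds_per_day = 3) {
  comps <- c(corn = unname(corn), soybean_meal = unname(soybean_meal),
             wheat_bran = unname(wheat_bran),
             compound_and_other = unname(compound_and_other),
             fishmeal = unname(fishmeal))
  abort_if(any(comps < 0), "ration components must be >= 0")
  abort_if(abs(sum(comps) - 100) > 0.01,
           "ration components must sum to 100% (got ", sum(comps), ")")
  structure(c(as.list(comps), list(feeds_per_day = feeds_per_day)),
            class = "ration")
}

ration_components <- function(r) {
  unlist(r[c("corn", "soybean_meal", "wheat_bran", "compound_and_other",
             "fishmeal")])
}

#' Growth-stage ration table
#'
#' Stage-specific base diets and feeding frequencies, from weaning to
#' late fattening. The printed stage boundaries leave small gaps
#' (15.0 to 15.1 kg etc.); intervals here are half-open `[lo, hi)`
#' centred on those gaps so every weight maps to exactly one stage.
#'
#' @return Data frame with columns `stage`, `lo`, `hi` and a list-column
#'   `ration`.
#' @export
default_stage_table <- function() {
  tab <- data.frame(
    stage = c("Weaning Period", "Fattening Stage I", "Fattening Stage II",
              "Fattening Stage III"),
    lo = c(7.0, 15.05, 40.05, 80.05),
    hi = c(15.05, 40.05, 80.05, Inf))
  tab$ration <- list(
    ration(60, 20, 5, 15, feeds_per_day = 7),  # weaning fed 6-8x; midpoint
    ration(60, 22, 10, 8, feeds_per_day = 3),
    ration(65, 18, 13, 4, feeds_per_day = 3),
    ration(67, 15, 14, 4, feeds_per_day = 3))
  tab
}

#' Map a weight to its growth stage
#'
#' Half-open intervals make the mapping total and unique on (0, Inf);
#' weights below the first interval are assigned to the first stage with
#' `below_range = TRUE`.
#'
#' @param weight Live weight, kg (> 0).
#' @param table A stage table as from [default_stage_table()].
#' @return List with `stage`, `ration`, `interval` and `below_range`.
#' @export
classify_stage <- function(weight, table = default_stage_table()) {
  abort_if(!is.numeric(weight) || weight <= 0, "weight must be positive")
  below <- weight < table$lo[1]
  idx <- if (below) 1L else which(weight >= table$lo & weight < table$hi)
  stopifnot(length(idx) == 1)
  list(stage = table$stage[idx], ration = table$ration[[idx]],
       interval = c(table$lo[idx], table$hi[idx]), below_range = below)
}

#' Average daily gain from a weight series
#'
#' Ordinary least-squares slope of weight against day over a trailing
#' window (default: all records within the last 14 days of the series).
#' If the window holds fewer than two distinct days, the full series is
#' used instead.
#'
#' @param days Numeric observation days.
#' @param weights Weights, kg (same length).
#' @param window_days Trailing window length, days.
#' @return Slope in kg/day.
#' @export
daily_gain <- function(days, weights, window_days = 14) {
  stopifnot(length(days) == length(weights))
  abort_if(length(unique(days)) < 2,
           "daily gain undefined: need >= 2 records with distinct days")
  keep <- days >= max(days) - window_days
  if (length(unique(days[keep])) < 2) keep <- rep(TRUE, length(days))
  d <- days[keep]; w <- weights[keep]
  unname(stats::coef(stats::lm(w ~ d))[2])
}

# Re-balance the untouched components pro-rata so the total is 100.
rebalance <- function(comps, fixed_names) {
  free <- setdiff(names(comps), fixed_names)
  target <- 100 - sum(comps[fixed_names])
  flagged <- FALSE
  if (target < 0) {
    # adjusted components alone exceed 100%; nothing sensible to do
    stop("adjusted components exceed 100%", call. = FALSE)
  }
  cur <- sum(comps[free])
  if (cur <= 0) {
    # no mass to redistribute proportionally; park the residual in
    # compound_and_other
    comps[free] <- 0
    comps["compound_and_other"] <- comps["compound_and_other"] + target
    flagged <- TRUE
  } else {
    comps[free] <- comps[free] * target / cur
    if (any(comps[free] < 0)) {
      neg <- free[comps[free] < 0]
      residual <- -sum(comps[neg])
      comps[neg] <- 0
      biggest <- free[which.max(comps[free])]
      comps[biggest] <- comps[biggest] - residual
      flagged <- TRUE
    }
  }
  list(comps = comps, flagged = flagged)
}

#' Dynamic precision-feeding ration adjustment
#'
#' Two rules, driven by the live-weight estimate and the recent average
#' daily gain:
#' \itemize{
#'   \item rapid-growth band (30-80 kg): corn raised to 68% and soybean
#'     meal to 19% (midpoint of the 18-20% target band);
#'   \item slow grower (ADG < 0.6 kg/day): soybean meal raised to 20%
#'     with 2% fishmeal added. This corrective rule takes precedence when
#'     both fire.
#' }
#' The remaining mass is re-balanced pro-rata across the untouched
#' ingredients so the total stays at 100%. The operation is idempotent.
#'
#' @param stage_ration A [ration()] (the stage's base diet).
#' @param weight Live weight estimate, kg.
#' @param adg Recent average daily gain, kg/day.
#' @param sbm_band_target Soybean-meal percentage for the rapid-growth
#'   rule (default 19, the midpoint of 18-20).
#' @return Adjusted `ration`, with attributes `rule` (one of `"none"`,
#'   `"rapid_growth"`, `"slow_grower"`) and `clamped` (logical, `TRUE`
#'   when re-balancing had to clamp a component at zero).
#' @export
adjust_ration <- function(stage_ration, weight, adg, sbm_band_target = 19) {
  stopifnot(inherits(stage_ration, "ration"))
  comps <- ration_components(stage_ration)
  rule <- "none"; flagged <- FALSE
  if (adg < 0.6) {
    rule <- "slow_grower"
    comps["soybean_meal"] <- 20
    comps["fishmeal"] <- 2
    rb <- rebalance(comps, c("corn", "soybean_meal", "fishmeal"))
    comps <- rb$comps; flagged <- rb$flagged
  } else if (weight >= 30 && weight <= 80) {
    rule <- "rapid_growth"
    comps["corn"] <- 68
    comps["soybean_meal"] <- sbm_band_target
    rb <- rebalance(comps, c("corn", "soybean_meal", "fishmeal"))
    comps <- rb$comps; flagged <- rb$flagged
  }
  out <- ration(comps["corn"], comps["soybean_meal"], comps["wheat_bran"],
                comps["compound_and_other"], comps["fishmeal"],
                feeds_per_day = stage_ration$feeds_per_day)
  attr(out, "rule") <- rule
  attr(out, "clamped") <- flagged
  out
}

#' Default daily feed allowance curve
#'
#' Piecewise-linear daily allowance (kg/day) keyed by live weight (kg),
#' for a finishing diet of about 12 MJ/kg. The intake function itself is
#' a configurable extension point, not a mechanistic model.
#'
#' @return Named numeric vector (names = weights in kg).
#' @export
default_allowance <- function() {
  c(`6` = 0.3, `15` = 0.8, `30` = 1.4, `80` = 2.6, `120` = 3.2)
}

#' Planned daily feed quantity
#'
#' Linear interpolation of the allowance curve at the given weight
#' (clamped at the curve's ends), scaled by `12 / energy_density` so a
#' denser diet plans proportionally less mass for the same energy.
#'
#' @param weight Live weight, kg (> 0).
#' @param stage Stage label (recorded in plans; the allowance curve is
#'   keyed by weight).
#' @param energy_density Diet energy density, MJ/kg (default 12).
#' @param allowance Named allowance curve; names are weights in kg.
#' @return Daily allowance, kg/day.
#' @export
plan_feed_quantity <- function(weight, stage = NULL, energy_density = 12,
                               allowance = default_allowance()) {
  abort_if(weight <= 0, "weight must be positive")
  abort_if(length(allowance) == 0,
           "missing feed allowance table (config key 'allowance')")
  w <- as.numeric(names(allowance))
  abort_if(anyNA(w), "allowance table names must be numeric weights")
  if (length(allowance) == 1) return(unname(allowance) * 12 / energy_density)
  ord <- order(w)
  stats::approx(w[ord], allowance[ord], xout = weight, rule = 2)$y *
    12 / energy_density
}

#' Per-pig feeding plans for the latest observation of each animal
#'
#' For every pig: classify the stage from the latest weight estimate,
#' compute the trailing-window ADG, apply the dynamic adjustment rules
#' and plan the daily allowance.
#'
#' @param records Data frame with `pig_id`, `day` and `weight_kg`.
#' @param stage_table,allowance,window_days Configuration of the rules.
#' @return Data frame, one row per pig: stage, rule applied, ration
#'   components, feeds per day and planned kg/day.
#' @export
feeding_plan <- function(records, stage_table = default_stage_table(),
                         allowance = default_allowance(),
                         window_days = 14) {
  stopifnot(all(c("pig_id", "day", "weight_kg") %in% names(records)))
  do.call(rbind, lapply(split(records, records$pig_id), function(d) {
    d <- d[order(d$day), ]
    w <- d$weight_kg[nrow(d)]
    adg <- if (length(unique(d$day)) >= 2) {
      daily_gain(d$day, d$weight_kg, window_days)
    } else {
      NA_real_
    }
    st <- classify_stage(w, stage_table)
    r <- if (is.na(adg)) st$ration else adjust_ration(st$ration, w, adg)
    data.frame(pig_id = d$pig_id[1], day = d$day[nrow(d)], weight_kg = w,
               adg = adg, stage = st$stage,
               rule = attr(r, "rule") %||% "none", t(ration_components(r)),
               feeds_per_day = r$feeds_per_day,
               feed_kg_day = plan_feed_quantity(w, st$stage,
                                                allowance = allowance),
               row.names = NULL)
  }))
}
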