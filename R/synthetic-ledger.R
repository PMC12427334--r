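#' Per-breed manure and excretion parameters
#'
#' Manure yield, nitrogen excretion and greenhouse-gas output per head and
#' day for the three breeds of the reference herd, used when turning a
#' growth cohort into a farm activity ledger.
#'
#' @return Data frame with columns `breed`, `manure_kg_day`, `n_g_day`,
#'   `ghg_kg_day`, `n_excretion_rate`.
#' @export
breed_manure_table <- function() {
  data.frame(
    breed = c("Landrace", "Jinfen White", "Duroc"),
    manure_kg_day = c(3.3, 3.8, 2.8),
    n_g_day = c(26, 33, 22),
    ghg_kg_day = c(0.34, 0.42, 0.30),
    n_excretion_rate = c(0.55, 0.58, 0.52))  # kg N / 1000 kg mass / day
}

default_management_fractions <- function() {
  c(anaerobic_digester = 0.5, solid_storage = 0.3,
    composting_container = 0.2)
}

#' Build a farm activity ledger from a growth cohort
#'
#' Aggregates a cohort into the activity data a cradle-to-farm-gate
#' footprint needs: feed tonnage per ingredient and breed (daily intake
#' from the stage allowance curve, split by the stage ration), transport
#' legs (feed haulage in, live pigs out), pig inventory (head, average
#' weight, days on farm per breed), energy carriers, and manure nitrogen
#' flows with an explicit management-system allocation.
#'
#' @param cohort Output of [generate_cohort()].
#' @param stage_table A [default_stage_table()] or compatible.
#' @param allowance Named allowance curve for [plan_feed_quantity()]
#'   (kg/day keyed by weight kg).
#' @param management_fractions Named fractions over manure-management
#'   systems, summing to 1.
#' @param feed_distance_km,pig_distance_km Transport leg lengths.
#' @param electricity_mwh_per_head_cycle,diesel_t_per_100head Energy-use
#'   intensities of the housing and machinery.
#' @param seed Integer seed (reserved; the ledger is deterministic given
#'   the cohort).
#' @return Object of class `activity_ledger`: list of data frames `feed`,
#'   `transport`, `inventory`, `energy`, `manure`, plus
#'   `management_fractions` and `total_live_weight_kg`.
#' @export
generate_ledger <- function(cohort,
                            stage_table = default_stage_table(),
                            allowance = default_allowance(),
                            management_fractions =
                              default_management_fractions(),
                            feed_distance_km = 100,
                            pig_distance_km = 150,
                            electricity_mwh_per_head_cycle = 0.035,
                            diesel_t_per_100head = 0.2,
                            seed = 1L) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  abort_if(length(management_fractions) == 0 ||
             abs(sum(management_fractions) - 1) > 1e-6,
           "management-system fractions must be non-empty and sum to 1")

  pigs <- split(cohort, cohort$pig_id)
  per_pig <- do.call(rbind, lapply(pigs, function(d) {
    d <- d[order(d$day), ]
    days_on <- max(d$day) - min(d$day) + 1
    # daily intake integrated over the trajectory at the observation grid
    intake <- vapply(seq_len(nrow(d)), function(i) {
      w <- d$true_weight[i]
      st <- classify_stage(w, stage_table)
      plan_feed_quantity(w, st$stage, allowance = allowance)
    }, numeric(1))
    step <- diff(c(d$day, max(d$day) + 1))
    feed_kg <- sum(intake * step)
    # feed split by the ration of the stage occupied on each interval
    split_kg <- rep(0, 5)
    names(split_kg) <- c("corn", "soybean_meal", "wheat_bran",
                         "compound_and_other", "fishmeal")
    for (i in seq_len(nrow(d))) {
      r <- classify_stage(d$true_weight[i], stage_table)$ration
      split_kg <- split_kg + intake[i] * step[i] *
        c(r$corn, r$soybean_meal, r$wheat_bran, r$compound_and_other,
          r$fishmeal) / 100
    }
    data.frame(breed = d$breed[1], days = days_on,
               avg_weight = mean(d$true_weight),
               final_weight = max(d$true_weight),
               feed_kg = feed_kg, t(split_kg))
  }))

  inv <- do.call(rbind, lapply(split(per_pig, per_pig$breed), function(g) {
    data.frame(breed = g$breed[1], head = nrow(g),
               avg_weight_kg = mean(g$avg_weight),
               days = mean(g$days))
  }))
  rownames(inv) <- NULL

  bt <- breed_manure_table()
  manure <- do.call(rbind, lapply(split(per_pig, per_pig$breed), function(g) {
    b <- bt[bt$breed == g$breed[1], ]
    head_days <- sum(g$days)
    data.frame(breed = g$breed[1], head_days = head_days,
               manure_kg = b$manure_kg_day * head_days,
               n_excreted_kg = b$n_g_day * head_days / 1000)
  }))
  rownames(manure) <- NULL

  feed <- do.call(rbind, lapply(split(per_pig, per_pig$breed), function(g) {
    data.frame(breed = g$breed[1],
               ingredient = c("corn", "soybean_meal", "wheat_bran",
                              "compound_and_other", "fishmeal"),
               tonnes = c(sum(g$corn), sum(g$soybean_meal),
                          sum(g$wheat_bran), sum(g$compound_and_other),
                          sum(g$fishmeal)) / 1000)
  }))
  feed <- feed[feed$tonnes > 0, ]
  rownames(feed) <- NULL

  total_feed_t <- sum(feed$tonnes)
  total_out_kg <- sum(per_pig$final_weight)
  transport <- data.frame(
    leg = c("feed_in", "pigs_out"),
    distance_km = c(feed_distance_km, pig_distance_km),
    tonnes = c(total_feed_t, total_out_kg / 1000),
    vehicle = c("medium", "heavy"))

  n_head <- nrow(per_pig)
  energy <- data.frame(
    carrier = c("electricity", "diesel"),
    quantity = c(electricity_mwh_per_head_cycle * n_head,
                 diesel_t_per_100head * n_head / 100),
    unit = c("MWh", "t"))

  # internal consistency: excreted N must not exceed a crude feed-N proxy
  feed_n_kg <- sum(per_pig$feed_kg) * 0.025  # ~16% CP / 6.25
  stopifnot(sum(manure$n_excreted_kg) <= feed_n_kg)

  structure(list(feed = feed, transport = transport, inventory = inv,
                 energy = energy, manure = manure,
                 management_fractions = management_fractions,
                 total_live_weight_kg = total_out_kg),
            class = "activity_ledger")
}

#' Merge or scale activity ledgers
#'
#' Every footprint component is linear in activity data, so merged
#' ledgers give summed footprints and scaled ledgers scale them —
#' properties the test suite exercises.
#'
#' @param a,b `activity_ledger` objects (same management fractions).
#' @return `merge_ledgers()`: a combined ledger; `scale_ledger()`: `a`
#'   with all activity quantities multiplied by `k`.
#' @export
merge_ledgers <- function(a, b) {
  stopifnot(inherits(a, "activity_ledger"), inherits(b, "activity_ledger"))
  abort_if(!identical(a$management_fractions, b$management_fractions),
           "ledgers use different management-system allocations")
  structure(list(feed = rbind(a$feed, b$feed),
                 transport = rbind(a$transport, b$transport),
                 inventory = rbind(a$inventory, b$inventory),
                 energy = rbind(a$energy, b$energy),
                 manure = rbind(a$manure, b$manure),
                 management_fractions = a$management_fractions,
                 total_live_weight_kg =
                   a$total_live_weight_kg + b$total_live_weight_kg),
            class = "activity_ledger")
}

#' @rdname merge_ledgers
#' @param k Positive scale factor.
#' @export
scale_ledger <- function(a, k) {
  stopifnot(inherits(a, "activity_ledger"), k >= 0)
  out <- a
  out$feed$tonnes <- a$feed$tonnes * k
  out$transport$tonnes <- a$transport$tonnes * k
  out$inventory$head <- a$inventory$head * k
  out$energy$quantity <- a$energy$quantity * k
  out$manure$head_days <- a$manure$head_days * k
  out$manure$manure_kg <- a$manure$manure_kg * k
  out$manure$n_excreted_kg <- a$manure$n_excreted_kg * k
  out$total_live_weight_kg <- a$total_live_weight_kg * k
  out
}

#' Write / read an activity ledger as a directory of CSV files
#'
#' `feed.csv`, `transport.csv`, `inventory.csv`, `energy.csv`,
#' `manure.csv` and `meta.csv` (management fractions and total live
#' weight) under `dir`.
#'
#' @param ledger An `activity_ledger`.
#' @param dir Directory (created if missing).
#' @return `write_ledger()` returns `dir` invisibly; `read_ledger()`
#'   returns the `activity_ledger`.
#' @export
write_ledger <- function(ledger, dir) {
  stopifnot(inherits(ledger, "activity_ledger"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("feed", "transport", "inventory", "energy", "manure")) {
    utils::write.csv(ledger[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  meta <- data.frame(
    key = c(paste0("fraction.", names(ledger$management_fractions)),
            "total_live_weight_kg"),
    value = c(unname(ledger$management_fractions),
              ledger$total_live_weight_kg))
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(dir) {
  abort_if(!dir.exists(dir), "ledger directory not found: ", dir)
  read1 <- function(nm) utils::read.csv(file.path(dir, paste0(nm, ".csv")))
  meta <- read1("meta")
  fr <- meta$value[startsWith(meta$key, "fraction.")]
  names(fr) <- sub("^fraction\\.", "", meta$key[startsWith(meta$key,
                                                           "fraction.")])
  structure(list(feed = read1("feed"), transport = read1("transport"),
                 inventory = read1("inventory"), energy = read1("energy"),
                 manure = read1("manure"),
                 management_fractions = fr,
                 total_live_weight_kg =
                   meta$value[meta$key == "total_live_weight_kg"]),
            class = "activity_ledger")
}
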