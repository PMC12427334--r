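ef <- default_emission_factors()

one_feed_ledger <- function(ingredient, tonnes) {
  structure(list(
    feed = data.frame(breed = rep("x", length(ingredient)),
                      ingredient = ingredient, tonnes = tonnes),
    transport = data.frame(), inventory = data.frame(), energy = data.frame(),
    manure = data.frame(n_excreted_kg = 0),
    management_fractions = c(anaerobic_digester = 1),
    total_live_weight_kg = 1), class = "activity_ledger")
}

test_that("aggregate feed emissions apply the per-kg factors", {
  expect_equal(cf_forage(one_feed_ledger("corn", 1)), 370)
  expect_equal(cf_forage(one_feed_ledger(character(0), numeric(0))), 0)
  expect_error(cf_forage(one_feed_ledger("barley", 1)), "barley")
})

test_that("the applied-N chain reproduces the chained hand arithmetic", {
  # 1 t N -> 0.01 t N2O-N direct -> x 44/28 -> x 298 = 4.683 t CO2-eq
  f <- ef
  f$fertilizer_production <- c(N = 0, P = 0, K = 0)
  f$volatilization_rate_cultivation <- 0
  f$irrigation_kwh_per_ha <- c(corn = 0, soybean = 0, wheat = 0)
  f$fuel_l_per_ha <- c(corn = 0, soybean = 0, wheat = 0)
  cp <- data.frame(crop = "corn", ingredient = "corn", yield_t_per_ha = 1,
                   n_fert_t_per_ha = 1, p_fert_t_per_ha = 0,
                   k_fert_t_per_ha = 0, urea_t_per_ha = 0,
                   pesticide_t_per_ha = 0, film_t_per_ha = 0,
                   processing_mj_per_kg = 0, allocation_share = 1)
  got <- cf_forage(one_feed_ledger("corn", 1), f, mode = "detailed",
                   crop_params = cp)
  expect_equal(got, 0.01 * 44 / 28 * 298 * 1000, tolerance = 1e-10)
})

test_that("detailed mode demands crop parameters", {
  expect_error(cf_forage(one_feed_ledger("corn", 1), ef, mode = "detailed"),
               "crop_params")
})

test_that("energy-allocation shares are well-behaved fractions", {
  expect_equal(allocation_share(13.82, 13.82 + 30), 13.82 / 43.82)
  expect_error(allocation_share(5, 0), "total")
  expect_error(allocation_share(10, 5), "within")
})

test_that("transport emissions are per tonne-kilometre and additive", {
  leg <- function(d, t, v) data.frame(distance_km = d, tonnes = t,
                                      vehicle = v)
  led <- structure(list(transport = leg(100, 2, "heavy")),
                   class = "activity_ledger")
  expect_equal(cf_transport(led), 100 * 2 * 0.321)
  led$transport <- leg(0, 5, "light")
  expect_equal(cf_transport(led), 0)
  led$transport <- rbind(leg(100, 2, "heavy"), leg(100, 2, "heavy"))
  expect_equal(cf_transport(led), 2 * 64.2)
  led$transport <- leg(10, 1, "bicycle")
  expect_error(cf_transport(led), "light, medium, heavy")
})

test_that("the enteric factor scales linearly from the reference pig", {
  expect_equal(enteric_factor(75, ef), 75 / 105)
  expect_identical(enteric_factor(105, ef), 1.00)
  expect_equal(enteric_factor(76, ef), 76 / 105)
  k <- 1.7
  expect_equal(enteric_factor(k * 60, ef), k * enteric_factor(60, ef))
  expect_error(enteric_factor(0, ef), "> 0")
})

test_that("enteric emissions prorate head-days at GWP(CH4)", {
  inv <- data.frame(head = 10, avg_weight_kg = 105, days = 365)
  expect_equal(cf_enteric(inv, ef), 10 * 1.00 * 28)
  inv$days <- 0
  expect_equal(cf_enteric(inv, ef), 0)
  inv$days <- 182.5
  expect_equal(cf_enteric(inv, ef), 10 * 28 / 2)
  inv$days <- -1
  expect_error(cf_enteric(inv, ef), ">= 0")
})

test_that("energy emissions multiply consumption by carrier factors", {
  en <- data.frame(carrier = "electricity", quantity = 10, unit = "MWh")
  expect_equal(cf_energy(en, ef), 8800)
  en <- data.frame(carrier = "diesel", quantity = 1, unit = "t")
  expect_equal(cf_energy(en, ef), 3180)
  expect_equal(cf_energy(data.frame(), ef), 0)
  en <- data.frame(carrier = "petrol", quantity = 1, unit = "t")
  expect_error(cf_energy(en, ef), "petrol")
})

test_that("anaerobic digestion contributes no direct N2O", {
  f <- ef
  f$manure_ch4_factor <- 0
  f$volatilization_rate_manure <- 0
  f$leaching_rate_manure <- 0
  m <- data.frame(n_excreted_kg = 500)
  expect_equal(cf_manure(m, f, c(anaerobic_digester = 1)), 0)
  # intensive-turned composting: 100 kg N x 0.1 x 44/28 x 298
  expect_equal(cf_manure(data.frame(n_excreted_kg = 100), f,
                         c(composting_intensive = 1)),
               100 * 0.1 * 44 / 28 * 298, tolerance = 1e-10)
  expect_equal(cf_manure(data.frame(n_excreted_kg = 0), ef,
                         c(solid_storage = 1)), 0)
  expect_error(cf_manure(m, ef, c(moon_pool = 1)), "moon_pool")
})

test_that("strict-paper mode applies GWP(N2O) to the manure CH4 term", {
  f <- ef
  f$volatilization_rate_manure <- 0
  f$leaching_rate_manure <- 0
  m <- data.frame(n_excreted_kg = 100)
  fr <- c(anaerobic_digester = 1)
  default <- cf_manure(m, f, fr)
  strict <- cf_manure(m, f, fr, strict_paper = TRUE)
  expect_equal(default, 100 * 0.005 * 28)
  expect_equal(strict, 100 * 0.005 * 298)
})

test_that("the footprint total is the exact component sum, normalised", {
  fp <- total_footprint(cf_forage = 4.15, cf_enteric = 2.65,
                        cf_manure = 1.50, live_weight = 1)
  expect_equal(fp$cf_total, 8.30)
  expect_equal(fp$cf_per_kg, 8.30)
  expect_equal(fp$cf_total, sum(fp$components))
  zero <- total_footprint(live_weight = 10)
  expect_equal(zero$cf_total, 0)
  expect_error(total_footprint(cf_forage = 1, live_weight = 0), "> 0")
  # homogeneity: doubling activities and live weight fixes the intensity
  dbl <- total_footprint(cf_forage = 8.30, cf_enteric = 5.30,
                         cf_manure = 3.00, live_weight = 2)
  expect_equal(dbl$cf_total, 2 * fp$cf_total)
  expect_equal(dbl$cf_per_kg, fp$cf_per_kg)
})

test_that("emission factors survive a YAML round trip and are validated", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_emission_factors(ef, path)
  back <- read_emission_factors(path)
  expect_equal(unclass(back), unclass(ef))
  bad <- unclass(ef)
  bad$gwp <- c(CO2 = 1)
  expect_error(validate_emission_factors(bad), "CH4")
  bad2 <- unclass(ef)
  bad2$enteric_baseline <- -1
  expect_error(validate_emission_factors(bad2), "enteric_baseline")
  bad3 <- unclass(ef)
  bad3$transport_ef <- NULL
  expect_error(validate_emission_factors(bad3), "transport_ef")
})

test_that("scenario comparison reports percentage reductions", {
  base <- total_footprint(cf_forage = 4.15, cf_enteric = 2.65,
                          cf_manure = 1.50, live_weight = 1)
  same <- compare_scenarios(base, base)
  expect_true(all(same$per_component == 0))
  expect_equal(same$total_pct, 0)

  opt <- total_footprint(cf_forage = 4.15 * 0.9, cf_enteric = 2.65 * 0.9,
                         cf_manure = 1.50 * 0.9, live_weight = 1)
  expect_equal(compare_scenarios(base, opt)$total_pct, 10.0)

  # total reduction is the share-weighted mean of component reductions
  opt2 <- total_footprint(cf_forage = 3.88, cf_enteric = 2.54,
                          cf_manure = 1.42, live_weight = 1)
  cmp <- compare_scenarios(base, opt2)
  shares <- base$components / base$cf_total
  expect_equal(cmp$total_pct, sum(shares * cmp$per_component))
})
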