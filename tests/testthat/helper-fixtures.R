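# Constructed masks and small random generators shared across tests.

# Blank canvas with a filled axis-aligned rectangle of w x h pixels.
rect_mask <- function(w, h, canvas = c(w + 20, h + 20),
                      origin = c(11, 11)) {
  m <- matrix(0L, canvas[1], canvas[2])
  m[origin[1]:(origin[1] + w - 1), origin[2]:(origin[2] + h - 1)] <- 1L
  m
}

# Quick analytic ellipse raster without boundary noise.
ellipse_mask <- function(a, b, canvas = 640, angle = 0) {
  render_mask(silhouette_spec(a, b, orientation_deg = angle,
                              canvas_w = canvas, canvas_h = canvas))$mask
}

# Small random activity ledger for linearity/homogeneity property tests.
random_ledger <- function(seed) {
  set.seed(seed)
  feed <- data.frame(
    breed = "Landrace",
    ingredient = sample(c("corn", "soybean_meal", "wheat_bran"), 3),
    tonnes = runif(3, 0, 50))
  transport <- data.frame(
    leg = c("a", "b"), distance_km = runif(2, 10, 500),
    tonnes = runif(2, 0.5, 30),
    vehicle = sample(c("light", "medium", "heavy"), 2, replace = TRUE))
  inventory <- data.frame(
    breed = c("Landrace", "Duroc"), head = sample(5:80, 2),
    avg_weight_kg = runif(2, 20, 120), days = sample(30:365, 2))
  energy <- data.frame(
    carrier = c("electricity", "coal", "diesel"),
    quantity = runif(3, 0, 20), unit = c("MWh", "t", "t"))
  manure <- data.frame(breed = c("Landrace", "Duroc"),
                       head_days = runif(2, 100, 5000),
                       manure_kg = runif(2, 100, 5000),
                       n_excreted_kg = runif(2, 1, 150))
  structure(list(feed = feed, transport = transport, inventory = inventory,
                 energy = energy, manure = manure,
                 management_fractions = c(anaerobic_digester = 0.4,
                                          solid_storage = 0.35,
                                          composting_container = 0.25),
                 total_live_weight_kg = runif(1, 1000, 10000)),
            class = "activity_ledger")
}

# Cohort-like feature table with a known monotone single-feature signal.
monotone_feature_set <- function(n = 200) {
  ra <- seq(0.1, 0.5, length.out = n)
  data.frame(pig_id = sprintf("p%02d", rep(1:20, each = n / 20)),
             weight_kg = 40 + 200 * ra,
             RA = ra, CP = 120, BL = 100, BW = 50, E = 0.5)
}
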