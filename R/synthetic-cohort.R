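#' Specify a synthetic growth cohort
#'
#' Emulates the longitudinal structure of a farrow-to-finish monitoring
#' campaign: each pig gains weight linearly at its own average daily gain
#' (ADG), observations are scheduled every 3 days during the piglet phase
#' and every 7 days during finishing, and morphometric features are linked
#' to weight by a fixed allometric rule so that recovery by the weight
#' model is checkable against known ground truth.
#'
#' @param n_pigs Number of animals.
#' @param breeds Named numeric vector of breed proportions (summing to 1).
#' @param start_weight_range,end_weight_range Weaning-weight and
#'   market-target ranges, kg; targets are drawn uniformly and observation
#'   stops once a pig's true weight reaches its target.
#' @param adg_mean,adg_sd Mean and between-pig SD of ADG, kg/day.
#' @param n_days Length of the monitoring window, days.
#' @param piglet_threshold_kg Weight below which the 3-day observation
#'   interval applies; 7 days above it.
#' @param noise_sd_weight Additive observation noise on weight, kg
#'   (default 0.5, the accuracy class of a farm platform scale).
#' @param feature_cv Multiplicative (lognormal) noise coefficient of
#'   variation on RA, CP, BL, BW.
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pigs = 63,
                        breeds = c(Landrace = 0.35, `Jinfen White` = 0.25,
                                   Duroc = 0.40),
                        start_weight_range = c(6, 25),
                        end_weight_range = c(100, 121.7),
                        adg_mean = 0.65, adg_sd = 0.06,
                        n_days = 150,
                        piglet_threshold_kg = 30,
                        noise_sd_weight = 0.5,
                        feature_cv = 0.03,
                        seed = 1L) {
  abort_if(n_pigs <= 0, "n_pigs must be positive")
  abort_if(n_days <= 0, "n_days must be positive")
  abort_if(any(start_weight_range <= 0) || any(end_weight_range <= 0),
           "weights must be strictly positive")
  abort_if(abs(sum(breeds) - 1) > 1e-6, "breed proportions must sum to 1")
  structure(list(n_pigs = as.integer(n_pigs), breeds = breeds,
                 start_weight_range = start_weight_range,
                 end_weight_range = end_weight_range,
                 adg_mean = adg_mean, adg_sd = adg_sd,
                 n_days = as.integer(n_days),
                 piglet_threshold_kg = piglet_threshold_kg,
                 noise_sd_weight = noise_sd_weight,
                 feature_cv = feature_cv, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Allometric link between live weight and the five features. Area-like RA
# scales as W^(2/3), length-like CP/BL/BW as W^(1/3) (isometric scaling);
# coefficients place the features in realistic spans for finisher pigs
# (RA as a frame fraction, lengths in cm). E is drawn independently of
# weight. These are generator-internal ground truth, not claims about pigs.
allometric_coefficients <- function() {
  c(RA = 0.45 / 121.7^(2 / 3),  # RA at 121.7 kg = 0.45
    CP = 127.6 / 74.9^(1 / 3),  # CP at 74.9 kg = 127.6 cm
    BL = 98.7 / 74.9^(1 / 3),
    BW = 53.9 / 74.9^(1 / 3))
}

allometric_features <- function(weight) {
  k <- allometric_coefficients()
  data.frame(RA = k[["RA"]] * weight^(2 / 3),
             CP = k[["CP"]] * weight^(1 / 3),
             BL = k[["BL"]] * weight^(1 / 3),
             BW = k[["BW"]] * weight^(1 / 3))
}

#' Generate a longitudinal growth cohort with linked features
#'
#' Per-pig trajectories are linear in time with an ADG drawn once per
#' animal; observed weights carry additive Gaussian noise, features carry
#' multiplicative lognormal noise around the allometric link, and E is
#' uniform on `[0.21, 0.79]` independent of weight. The generating
#' parameters are attached as attributes so recovery is checkable.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame (one row per observation) with columns `pig_id`,
#'   `breed`, `day`, `true_weight`, `weight_kg` (observed), `RA`, `CP`,
#'   `BL`, `BW`, `E`, plus attributes `adg` (per-pig ADG), `allometry`
#'   and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    breed <- sample(names(spec$breeds), spec$n_pigs, replace = TRUE,
                    prob = spec$breeds)
    w0 <- stats::runif(spec$n_pigs, spec$start_weight_range[1],
                       spec$start_weight_range[2])
    target <- stats::runif(spec$n_pigs, spec$end_weight_range[1],
                           spec$end_weight_range[2])
    adg <- pmax(stats::rnorm(spec$n_pigs, spec$adg_mean, spec$adg_sd), 0.05)

    rows <- lapply(seq_len(spec$n_pigs), function(i) {
      days <- c()
      d <- 0
      repeat {
        w <- w0[i] + adg[i] * d
        if (d > spec$n_days || w > target[i]) break
        days <- c(days, d)
        d <- d + if (w < spec$piglet_threshold_kg) 3 else 7
      }
      w_true <- w0[i] + adg[i] * days
      data.frame(pig_id = sprintf("pig%03d", i), breed = breed[i],
                 day = days, true_weight = w_true)
    })
    out <- do.call(rbind, rows)
    n <- nrow(out)
    # scale readings cannot be non-positive: clamp at a 0.5 kg floor
    out$weight_kg <- pmax(out$true_weight +
                            stats::rnorm(n, 0, spec$noise_sd_weight), 0.5)
    feats <- allometric_features(out$true_weight)
    for (f in names(feats)) {
      out[[f]] <- feats[[f]] *
        stats::rlnorm(n, -spec$feature_cv^2 / 2, spec$feature_cv)
    }
    out$E <- stats::runif(n, 0.21, 0.79)
    attr(out, "adg") <- stats::setNames(adg, sprintf("pig%03d",
                                                     seq_len(spec$n_pigs)))
    attr(out, "allometry") <- allometric_coefficients()
    attr(out, "spec") <- spec
    rownames(out) <- NULL
    out
  })
}

#' Silhouette specs for every observation of a cohort
#'
#' Maps each record's body length/width (cm) to superellipse semi-axes in
#' pixels via `px_per_cm`, for rendering a mask per observation in the
#' end-to-end pipeline.
#'
#' @param cohort Output of [generate_cohort()].
#' @param px_per_cm Pixel calibration.
#' @param canvas Canvas side, pixels.
#' @param shape_exponent,boundary_noise_sd Passed to [silhouette_spec()].
#' @param seed Integer seed controlling per-mask orientation and noise.
#' @return List of `silhouette_spec` objects, one per cohort row.
#' @export
cohort_silhouettes <- function(cohort, px_per_cm = 2, canvas = 512,
                               shape_exponent = 2.5,
                               boundary_noise_sd = 1.5, seed = 1L) {
  stopifnot(all(c("BL", "BW") %in% names(cohort)))
  n <- nrow(cohort)
  with_seed(seed, {
    orient <- stats::runif(n, -45, 45)
    sub_seeds <- sample.int(2^30, n)
    lapply(seq_len(n), function(i) {
      silhouette_spec(
        semi_major_px = cohort$BL[i] / 2 * px_per_cm,
        semi_minor_px = cohort$BW[i] / 2 * px_per_cm,
        orientation_deg = orient[i],
        shape_exponent = shape_exponent,
        boundary_noise_sd = boundary_noise_sd,
        canvas_w = canvas, canvas_h = canvas,
        seed = sub_seeds[i])
    })
  })
}
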