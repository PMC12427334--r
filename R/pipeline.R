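#' Pipeline run configuration
#'
#' Bundles every knob of the closed loop — synthetic cohort size, mask
#' rendering geometry, morphometric parameters, the hyperparameter grid,
#' feeding configuration and LCA flags — with a single seed.
#'
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory for artifacts.
#' @param n_pigs Cohort size of the demonstration run.
#' @param px_per_cm,canvas Mask rendering calibration and canvas side.
#' @param closing_radius,ecc_variant Morphometric parameters.
#' @param grid A [search_grid()].
#' @param test_fraction Animal-level hold-out fraction.
#' @param stage_table,allowance Feeding configuration.
#' @param factors Emission factors.
#' @param strict_paper LCA manure-formula flag.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("pigloop_run_"),
                       n_pigs = 12, px_per_cm = 2, canvas = 512,
                       closing_radius = 3, ecc_variant = "standard",
                       grid = search_grid(n_trees_options = c(100, 200),
                                          max_depth_options = c(10, 0),
                                          min_split_options = c(2, 5),
                                          cv_folds = 5, seed = seed),
                       test_fraction = 0.2,
                       stage_table = default_stage_table(),
                       allowance = default_allowance(),
                       factors = default_emission_factors(),
                       strict_paper = FALSE) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_pigs = n_pigs, px_per_cm = px_per_cm, canvas = canvas,
                 closing_radius = closing_radius, ecc_variant = ecc_variant,
                 grid = grid, test_fraction = test_fraction,
                 stage_table = stage_table, allowance = allowance,
                 factors = factors, strict_paper = strict_paper),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  x <- unclass(config)
  x$out_dir <- NULL  # hash the scientific config, not the output location
  # version = 2 keeps serialization stable across R versions
  saveRDS(x, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

write_stamped_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pigloop run config_hash=%s seed=%d", hash, seed),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the closed loop end to end on synthetic data
#'
#' Simulates a growth cohort, renders one dorsal mask per observation,
#' extracts morphometric features from the masks, fits the random-forest
#' weight model on an animal-level split, evaluates it on the held-out
#' pigs, derives per-pig feeding plans from the predicted weights, builds
#' the farm activity ledger and computes the carbon footprint. All
#' tabular artifacts are stamped with the configuration hash and listed
#' in a manifest with their MD5 sums; identical configurations reproduce
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return List with `features`, `eval`, `plans`, `footprint`,
#'   `manifest`, and the paths of the written artifacts.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- simulate ------------------------------------------------------------
  cohort <- generate_cohort(cohort_spec(n_pigs = config$n_pigs,
                                        seed = config$seed))
  specs <- cohort_silhouettes(cohort, px_per_cm = config$px_per_cm,
                              canvas = config$canvas,
                              seed = config$seed + 1L)

  # -- features ------------------------------------------------------------
  feats <- do.call(rbind, lapply(seq_along(specs), function(i) {
    fv <- tryCatch(
      extract_features(render_mask(specs[[i]])$mask,
                       closing_radius = config$closing_radius,
                       scale = 1 / config$px_per_cm,
                       ecc_variant = config$ecc_variant),
      error = function(e) stop("stage 'features' failed on record ", i,
                               " (", cohort$pig_id[i], " day ",
                               cohort$day[i], "): ", conditionMessage(e),
                               call. = FALSE))
    data.frame(pig_id = cohort$pig_id[i], breed = cohort$breed[i],
               day = cohort$day[i], weight_kg = cohort$weight_kg[i],
               true_weight = cohort$true_weight[i], t(fv))
  }))
  features_csv <- file.path(config$out_dir, "features.csv")
  write_stamped_csv(feats, features_csv, hash, config$seed)

  # -- weight model --------------------------------------------------------
  parts <- split_by_pig(feats, config$test_fraction, seed = config$seed)
  model <- fit_weight_model(parts$train, config$grid)
  preds <- predict(model, parts$test)
  report <- evaluate_weights(preds, parts$test$true_weight)
  pred_df <- data.frame(parts$test[, c("pig_id", "day", "true_weight")],
                        predicted_kg = preds)
  predictions_csv <- file.path(config$out_dir, "predictions.csv")
  write_stamped_csv(pred_df, predictions_csv, hash, config$seed)
  eval_json <- file.path(config$out_dir, "eval.json")
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed,
         metrics = unclass(report)[c("MAE", "RMSE", "MAPE", "R2")],
         hyperparameters = model$hyperparameters,
         feature_importances = as.list(feature_importances(model))),
    eval_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- feeding plans (from model-estimated weights) ------------------------
  est <- feats
  est$weight_kg <- predict(model, feats)
  plans <- feeding_plan(est, config$stage_table, config$allowance)
  plans_csv <- file.path(config$out_dir, "plans.csv")
  write_stamped_csv(plans, plans_csv, hash, config$seed)

  # -- footprint -----------------------------------------------------------
  ledger <- generate_ledger(cohort, stage_table = config$stage_table,
                            allowance = config$allowance)
  ledger_dir <- file.path(config$out_dir, "ledger")
  write_ledger(ledger, ledger_dir)
  fp <- footprint_from_ledger(ledger, config$factors,
                              strict_paper = config$strict_paper)
  footprint_json <- file.path(config$out_dir, "footprint.json")
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed,
         components = as.list(fp$components), cf_total = fp$cf_total,
         live_weight_kg = fp$live_weight, cf_per_kg = fp$cf_per_kg),
    footprint_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- manifest ------------------------------------------------------------
  artifacts <- c(features_csv, predictions_csv, eval_json, plans_csv,
                 footprint_json,
                 list.files(ledger_dir, full.names = TRUE))
  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)))
  manifest_json <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(list(config_hash = hash, seed = config$seed,
                            files = manifest),
                       manifest_json, auto_unbox = TRUE, pretty = TRUE)

  list(features = feats, model = model, eval = report, plans = plans,
       footprint = fp, manifest = manifest, config_hash = hash,
       paths = c(features = features_csv, predictions = predictions_csv,
                 eval = eval_json, plans = plans_csv,
                 footprint = footprint_json, manifest = manifest_json))
}

#' Compare two footprint scenarios
#'
#' Percentage reductions, `(base - opt) / base x 100`, per component and
#' in total, on the per-kg functional unit. This is a pure function of
#' two breakdowns; it does not model the biological effect of an
#' intervention.
#'
#' @param baseline,optimized `footprint_breakdown` objects on the same
#'   functional unit (kg CO2-eq per kg live weight).
#' @return List with `per_component` (percent reductions), `total_pct`,
#'   and the two per-kg totals.
#' @export
compare_scenarios <- function(baseline, optimized) {
  stopifnot(inherits(baseline, "footprint_breakdown"),
            inherits(optimized, "footprint_breakdown"))
  abort_if(!identical(names(baseline$components),
                      names(optimized$components)),
           "breakdowns have mismatched component sets")
  abort_if(baseline$live_weight <= 0 || optimized$live_weight <= 0,
           "mismatched functional units: live weights must be positive")
  base_pk <- baseline$components / baseline$live_weight
  opt_pk <- optimized$components / optimized$live_weight
  per_comp <- ifelse(base_pk > 0, (base_pk - opt_pk) / base_pk * 100, 0)
  total_pct <- (baseline$cf_per_kg - optimized$cf_per_kg) /
    baseline$cf_per_kg * 100
  list(per_component = per_comp, total_pct = total_pct,
       baseline_per_kg = baseline$cf_per_kg,
       optimized_per_kg = optimized$cf_per_kg)
}
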