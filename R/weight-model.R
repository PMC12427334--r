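#' Animal-level train/test split
#'
#' Assigns whole pigs (every record of a `pig_id`) to either the training
#' or the test side, preventing the leakage that record-level splits of
#' repeated measures would cause. The test side receives the number of
#' pigs closest to `test_fraction` of the herd (round half away handled by
#' [round()]); the assignment is deterministic in `seed`.
#'
#' @param records Data frame with at least a `pig_id` column (one row per
#'   observation).
#' @param test_fraction Fraction of pigs held out, in (0, 1).
#' @param seed Integer seed.
#' @return List with data frames `train` and `test`.
#' @export
split_by_pig <- function(records, test_fraction = 0.2, seed = 1L) {
  stopifnot(is.data.frame(records), "pig_id" %in% names(records))
  ids <- unique(records$pig_id)
  abort_if(length(ids) < 5, "need at least 5 distinct pig_ids")
  abort_if(test_fraction <= 0 || test_fraction >= 1,
           "test_fraction must be in (0, 1)")
  n_test <- round(length(ids) * test_fraction)
  abort_if(n_test == 0 || n_test == length(ids),
           "test_fraction leaves one side empty")
  test_ids <- with_seed(seed, sample(ids, n_test))
  out <- list(train = records[!records$pig_id %in% test_ids, , drop = FALSE],
              test = records[records$pig_id %in% test_ids, , drop = FALSE])
  overlap <- intersect(unique(out$train$pig_id), unique(out$test$pig_id))
  stopifnot(length(overlap) == 0)  # leakage guard
  out
}

#' Hyperparameter grid for the random-forest weight model
#'
#' Defaults mirror the search protocol used for dorsal-feature weight
#' estimation: forest size, maximum tree depth (0 = unbounded) and the
#' minimum node size eligible for splitting, tuned by pig-level k-fold
#' cross-validation.
#'
#' @param n_trees_options,max_depth_options,min_split_options Candidate
#'   values; `max_depth_options` uses 0 for unbounded depth.
#' @param cv_folds Number of pig-level folds (>= 2).
#' @param seed Integer seed for fold assignment and forest growth.
#' @return Object of class `search_grid`.
#' @export
search_grid <- function(n_trees_options = c(50, 100, 200, 500),
                        max_depth_options = c(10, 20, 30, 0),
                        min_split_options = c(2, 5, 10),
                        cv_folds = 5, seed = 1L) {
  abort_if(length(n_trees_options) == 0 || length(max_depth_options) == 0 ||
             length(min_split_options) == 0, "all option lists must be non-empty")
  abort_if(cv_folds < 2, "cv_folds must be >= 2")
  structure(list(n_trees_options = n_trees_options,
                 max_depth_options = max_depth_options,
                 min_split_options = min_split_options,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "search_grid")
}

feature_cols <- c("RA", "CP", "BL", "BW", "E")

fit_one_rf <- function(data, n_trees, max_depth, min_split, seed) {
  ranger::ranger(
    dependent.variable.name = "weight_kg",
    data = data[, c(feature_cols, "weight_kg")],
    num.trees = n_trees,
    max.depth = if (max_depth == 0) NULL else max_depth,
    min.node.size = min_split,
    importance = "impurity",
    seed = seed,
    num.threads = 1)
}

#' Fit the random-forest weight model with pig-level CV grid search
#'
#' Exhaustive search over the grid; cross-validation folds are built at
#' the pig level (no animal contributes records to two folds), the
#' selection criterion is the lowest mean CV mean-absolute-error, ties
#' broken towards the smaller forest, then the shallower depth, then the
#' smaller split threshold. The winning configuration is refit on the full
#' training set.
#'
#' @param train Data frame with columns `pig_id`, `weight_kg` and the five
#'   features `RA, CP, BL, BW, E`.
#' @param grid A [search_grid()].
#' @return Object of class `weight_model`: the fitted ranger forest, the
#'   chosen hyperparameters, the CV table, and the training target range.
#' @export
fit_weight_model <- function(train, grid = search_grid()) {
  stopifnot(is.data.frame(train),
            all(c("pig_id", "weight_kg", feature_cols) %in% names(train)))
  abort_if(nrow(train) == 0, "empty training set")
  abort_if(any(!is.finite(train$weight_kg)) || any(train$weight_kg <= 0),
           "training weights must be positive and finite")

  ids <- unique(train$pig_id)
  abort_if(length(ids) < grid$cv_folds,
           "fewer pigs than cv_folds; cannot build pig-level folds")
  # pig-level folds: shuffle ids once, deal round-robin
  fold_of <- with_seed(grid$seed, {
    shuffled <- sample(ids)
    stats::setNames(rep_len(seq_len(grid$cv_folds), length(shuffled)),
                    as.character(shuffled))
  })
  fold <- fold_of[as.character(train$pig_id)]

  configs <- expand.grid(n_trees = grid$n_trees_options,
                         max_depth = grid$max_depth_options,
                         min_split = grid$min_split_options,
                         KEEP.OUT.ATTRS = FALSE)
  cv_mae <- vapply(seq_len(nrow(configs)), function(i) {
    cfg <- configs[i, ]
    maes <- vapply(seq_len(grid$cv_folds), function(k) {
      tr <- train[fold != k, , drop = FALSE]
      va <- train[fold == k, , drop = FALSE]
      if (nrow(va) == 0 || nrow(tr) == 0) return(NA_real_)
      fit <- tryCatch(
        fit_one_rf(tr, cfg$n_trees, cfg$max_depth, cfg$min_split, grid$seed),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      pred <- stats::predict(fit, va[, feature_cols])$predictions
      mean(abs(pred - va$weight_kg))
    }, numeric(1))
    if (anyNA(maes)) NA_real_ else mean(maes)
  }, numeric(1))
  abort_if(all(is.na(cv_mae)), "every grid configuration failed to fit")

  tab <- cbind(configs, cv_mae = cv_mae)
  # depth 0 (unbounded) is the deepest option for tie-breaking purposes
  depth_rank <- ifelse(tab$max_depth == 0, Inf, tab$max_depth)
  ord <- order(tab$cv_mae, tab$n_trees, depth_rank, tab$min_split)
  best <- tab[ord[1], ]

  forest <- fit_one_rf(train, best$n_trees, best$max_depth, best$min_split,
                       grid$seed)
  structure(list(forest = forest,
                 hyperparameters = list(n_trees = best$n_trees,
                                        max_depth = best$max_depth,
                                        min_split = best$min_split),
                 cv_table = tab,
                 cv_mae = best$cv_mae,
                 target_range = range(train$weight_kg),
                 seed = grid$seed),
            class = "weight_model")
}

#' Predict live weight from morphometric features
#'
#' Ensemble-mean prediction of the fitted forest; each prediction is a
#' convex combination of training targets and therefore bounded by their
#' range.
#'
#' @param object A `weight_model`.
#' @param newdata Data frame (or named vector) with columns
#'   `RA, CP, BL, BW, E`.
#' @param ... Unused.
#' @return Numeric vector of weights in kg.
#' @export
predict.weight_model <- function(object, newdata, ...) {
  if (is.numeric(newdata) && !is.null(names(newdata))) {
    newdata <- as.data.frame(as.list(newdata))
  }
  stopifnot(all(feature_cols %in% names(newdata)))
  x <- newdata[, feature_cols, drop = FALSE]
  abort_if(any(!is.finite(as.matrix(x))),
           "feature vectors contain non-finite entries")
  stats::predict(object$forest, x)$predictions
}

#' Normalised feature importances of a fitted weight model
#'
#' @param model A `weight_model`.
#' @return Named numeric vector over `RA, CP, BL, BW, E` summing to 1.
#' @export
feature_importances <- function(model) {
  stopifnot(inherits(model, "weight_model"))
  imp <- model$forest$variable.importance[feature_cols]
  imp / sum(imp)
}

#' Regression evaluation report
#'
#' MAE, RMSE, MAPE (in percent; zero-truth records are excluded with a
#' warning count) and the coefficient of determination R^2 = 1 - SSE/SST.
#'
#' @param preds,truth Equal-length numeric vectors (n >= 2), kg.
#' @return List of class `eval_report` with `MAE`, `RMSE`, `MAPE`, `R2`
#'   and `n_mape_excluded`.
#' @export
evaluate_weights <- function(preds, truth) {
  stopifnot(length(preds) == length(truth), length(truth) >= 2)
  e <- preds - truth
  nz <- truth != 0
  if (any(!nz)) {
    warning(sum(!nz), " zero-truth record(s) excluded from MAPE")
  }
  structure(list(
    MAE = mean(abs(e)),
    RMSE = sqrt(mean(e^2)),
    MAPE = mean(abs(e[nz]) / truth[nz]) * 100,
    R2 = 1 - sum(e^2) / sum((truth - mean(truth))^2),
    n_mape_excluded = sum(!nz)), class = "eval_report")
}
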