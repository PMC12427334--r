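#!/usr/bin/env Rscript
# Random-forest live-weight estimation on the simulated cohort:
# animal-level 80/20 split, pig-level 5-fold cross-validated grid search,
# held-out evaluation and feature importances.

suppressMessages(library(pigloop))
seed <- 1L

cohort <- read.csv("results/cohort.csv")
parts <- split_by_pig(cohort, test_fraction = 0.2, seed = seed)
cat(sprintf("split: %d train / %d test pigs (no overlap)\n",
            length(unique(parts$train$pig_id)),
            length(unique(parts$test$pig_id))))

grid <- search_grid(n_trees_options = c(100, 200),
                    max_depth_options = c(10, 0),
                    min_split_options = c(2, 5),
                    cv_folds = 5, seed = seed)
model <- fit_weight_model(parts$train, grid)
cat(sprintf("grid search over %d configurations; winner: %d trees, depth %s, min split %d (CV MAE %.2f kg)\n",
            nrow(model$cv_table), model$hyperparameters$n_trees,
            ifelse(model$hyperparameters$max_depth == 0, "unbounded",
                   model$hyperparameters$max_depth),
            model$hyperparameters$min_split, model$cv_mae))
write.csv(model$cv_table, "results/cv_table.csv", row.names = FALSE)

preds <- predict(model, parts$test)
report <- evaluate_weights(preds, parts$test$true_weight)
cat(sprintf("held-out pigs: MAE %.2f kg, RMSE %.2f kg, MAPE %.2f%%, R2 %.3f\n",
            report$MAE, report$RMSE, report$MAPE, report$R2))
imp <- sort(feature_importances(model), decreasing = TRUE)
cat("feature importances:",
    paste(sprintf("%s %.1f%%", names(imp), imp * 100), collapse = ", "),
    "\n")

write.csv(data.frame(parts$test[, c("pig_id", "day", "true_weight")],
                     predicted_kg = preds),
          "results/predictions.csv", row.names = FALSE)
jsonlite::write_json(
  list(metrics = unclass(report)[c("MAE", "RMSE", "MAPE", "R2")],
       hyperparameters = model$hyperparameters,
       feature_importances = as.list(imp)),
  "results/weight_eval.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
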