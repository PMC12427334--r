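test_that("animal-level splits keep whole pigs on one side", {
  co <- generate_cohort(cohort_spec(n_pigs = 63, seed = 1))
  parts <- split_by_pig(co, 0.2, seed = 2)
  expect_length(unique(parts$test$pig_id), 13)  # round(63 * 0.2)
  expect_length(intersect(unique(parts$train$pig_id),
                          unique(parts$test$pig_id)), 0)
  parts2 <- split_by_pig(co, 0.2, seed = 2)
  expect_identical(sort(unique(parts$test$pig_id)),
                   sort(unique(parts2$test$pig_id)))
})

test_that("degenerate split fractions are rejected", {
  co <- generate_cohort(cohort_spec(n_pigs = 10, seed = 1))
  expect_error(split_by_pig(co, 0), "test_fraction")
  expect_error(split_by_pig(co, 1), "test_fraction")
  expect_error(split_by_pig(co[co$pig_id %in% unique(co$pig_id)[1:3], ],
                            0.2), "at least 5")
})

test_that("a single-cell grid is returned unchanged and refits match", {
  co <- generate_cohort(cohort_spec(n_pigs = 12, seed = 4,
                                    noise_sd_weight = 2))
  g <- search_grid(n_trees_options = 100, max_depth_options = 10,
                   min_split_options = 5, cv_folds = 3, seed = 9)
  m1 <- fit_weight_model(co, g)
  expect_equal(m1$hyperparameters,
               list(n_trees = 100, max_depth = 10, min_split = 5))
  m2 <- fit_weight_model(co, g)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_identical(m1$cv_mae, m2$cv_mae)
})

test_that("grid-search tie-breaking prefers the simpler forest", {
  tab <- data.frame(n_trees = c(500, 50), max_depth = c(0, 10),
                    min_split = c(2, 2), cv_mae = c(1, 1))
  depth_rank <- ifelse(tab$max_depth == 0, Inf, tab$max_depth)
  ord <- order(tab$cv_mae, tab$n_trees, depth_rank, tab$min_split)
  expect_equal(tab$n_trees[ord[1]], 50)
})

test_that("predictions stay within the training target range", {
  co <- generate_cohort(cohort_spec(n_pigs = 12, seed = 4))
  g <- search_grid(100, 10, 5, cv_folds = 3, seed = 9)
  m <- fit_weight_model(co, g)
  p <- predict(m, co)
  expect_true(all(p >= m$target_range[1] - 1e-9))
  expect_true(all(p <= m$target_range[2] + 1e-9))
  expect_error(predict(m, data.frame(RA = NA, CP = 1, BL = 1, BW = 1,
                                     E = 0.5)), "non-finite")
})

test_that("duplicating the training set barely moves predictions", {
  co <- generate_cohort(cohort_spec(n_pigs = 15, seed = 6,
                                    noise_sd_weight = 1))
  g <- search_grid(500, 0, 5, cv_folds = 3, seed = 2)
  m1 <- fit_weight_model(co, g)
  m2 <- fit_weight_model(rbind(co, co), g)
  p1 <- predict(m1, co); p2 <- predict(m2, co)
  expect_lt(mean(abs(p1 - p2)), 1.5)  # resampling noise only
})

test_that("predictions are monotone when the signal is monotone", {
  d <- monotone_feature_set()
  g <- search_grid(300, 0, 2, cv_folds = 4, seed = 1)
  m <- fit_weight_model(d, g)
  grid <- d[order(d$RA), ]
  p <- predict(m, grid)
  expect_true(all(diff(p) >= -1e-9))
})

test_that("evaluation metrics match hand arithmetic", {
  r <- evaluate_weights(c(98, 114), c(100, 110))
  expect_equal(r$MAE, 3.0)
  expect_equal(r$RMSE, sqrt((4 + 16) / 2))
  expect_equal(r$MAPE, mean(c(2 / 100, 4 / 110)) * 100)

  perfect <- evaluate_weights(c(50, 60, 70), c(50, 60, 70))
  expect_equal(perfect$MAE, 0)
  expect_equal(perfect$R2, 1)

  truth <- c(80, 90, 100, 110)
  const <- evaluate_weights(rep(mean(truth), 4), truth)
  expect_equal(const$R2, 0)
})

test_that("RMSE never falls below MAE", {
  set.seed(42)
  for (i in 1:20) {
    t <- runif(30, 40, 120)
    p <- t + rnorm(30, 0, 5)
    r <- evaluate_weights(p, t)
    expect_gte(r$RMSE, r$MAE)
  }
})

test_that("zero-truth records are excluded from MAPE with a warning", {
  expect_warning(r <- evaluate_weights(c(1, 2, 3), c(0, 2, 3)),
                 "excluded")
  expect_equal(r$n_mape_excluded, 1)
  expect_equal(r$MAPE, 0)
})
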