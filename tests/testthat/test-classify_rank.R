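make_task_table <- function(n = 30, seed = 21) {
  sig <- feature_names()[seq(1, 452, by = 23)]  # 20 spread-out features
  synth_signal_table(c(control = n, DR = n), sig, 3, seed = seed)
}

test_that("the stratified split partitions deterministically", {
  tab <- make_task_table(50, seed = 4)
  sp <- split_train_test(tab, 0.75, seed = 3)
  expect_identical(nrow(sp$train) + nrow(sp$test), 100L)
  cls <- table(sp$train$label)
  expect_true(all(cls >= 37 & cls <= 38))
  expect_length(intersect(sp$train$eye_id, sp$test$eye_id), 0)
  expect_setequal(c(sp$train$eye_id, sp$test$eye_id), tab$eye_id)
  sp2 <- split_train_test(tab, 0.75, seed = 3)
  expect_identical(sp$train$eye_id, sp2$train$eye_id)
  tiny <- tab[c(1:2, 51:60), ]
  expect_error(split_train_test(tiny, 0.75, 1), "at least 4 samples")
})

test_that("grid search is exhaustive, deterministic and tie-stable", {
  tab <- make_task_table(20, seed = 7)
  tm <- retquant:::table_matrix(tab)
  y <- factor(ifelse(tm$label == "control", "control", "disease"))
  x <- tm$x[, 1:40]
  f1 <- nested_fit(x, y, "random_forest",
                   grid = list(ntree = 200, mtry = 1), seed = 11)
  expect_identical(f1$best_params, list(ntree = 200, mtry = 6))
  expect_gte(f1$cv_accuracy, 0.95)  # separable synthetic cohort
  f2 <- nested_fit(x, y, "random_forest",
                   grid = list(ntree = 200, mtry = 1), seed = 11)
  expect_identical(predict(f1, x), predict(f2, x))
  expect_identical(feature_importance(f1), feature_importance(f2))
  expect_error(nested_fit(x, y, "no_such_model"), "unknown model")
})

test_that("every registry model fits and predicts a separable cohort", {
  tab <- make_task_table(16, seed = 31)
  tm <- retquant:::table_matrix(tab)
  y <- factor(ifelse(tm$label == "control", "control", "disease"))
  x <- tm$x[, 1:30]
  for (m in c("random_forest", "gradient_boosted_trees", "extra_trees",
              "svm")) {
    grid <- switch(m,
                   random_forest = list(ntree = 100, mtry = 1),
                   gradient_boosted_trees = list(nrounds = 30,
                                                 max_depth = 2, eta = 0.3),
                   extra_trees = list(num.trees = 100),
                   svm = list(cost = 1))
    f <- nested_fit(x, y, m, grid = grid, inner_folds = 3, seed = 5)
    expect_gte(mean(predict(f, x) == y), 0.9, label = m)
  }
})

test_that("importance pruning keeps signal and is a no-op when idle", {
  tab <- make_task_table(25, seed = 13)
  tm <- retquant:::table_matrix(tab)
  y <- factor(ifelse(tm$label == "control", "control", "disease"))
  sig <- feature_names()[seq(1, 452, by = 23)]
  fit <- nested_fit(tm$x, y, "random_forest",
                    grid = list(ntree = 300, mtry = 1), seed = 2)
  pruned <- prune_retrain(fit, tm$x, y, threshold = 0.001)
  expect_true(all(sig %in% pruned$features))
  expect_lt(length(pruned$features), 452)
  # threshold 0 is a no-op returning the same fit
  expect_identical(prune_retrain(fit, tm$x, y, threshold = 0), fit)
  # when every importance clears the threshold nothing is retrained
  xs <- tm$x[, sig, drop = FALSE]
  fs <- nested_fit(xs, y, "random_forest",
                   grid = list(ntree = 300, mtry = 1), seed = 4)
  expect_identical(prune_retrain(fs, xs, y, threshold = 1e-9), fs)
  # svm has no importances: warn and pass through
  sf <- nested_fit(tm$x[, 1:20], y, "svm", grid = list(cost = 1), seed = 2)
  expect_warning(ps <- prune_retrain(sf, tm$x[, 1:20], y), "no importances")
  expect_identical(ps, sf)
})

test_that("confusion-count metrics follow the defining arithmetic", {
  perfect <- evaluate(rep(c("disease", "control"), c(5, 5)),
                      rep(c("disease", "control"), c(5, 5)), "2class")
  expect_equal(unlist(perfect[c("accuracy", "precision", "sensitivity",
                                "f1")]),
               c(accuracy = 1, precision = 1, sensitivity = 1, f1 = 1))
  # TP=3 FP=1 FN=1 TN=5
  truth <- c(rep("disease", 4), rep("control", 6))
  pred <- c("disease", "disease", "disease", "control",
            "disease", rep("control", 5))
  r <- evaluate(pred, truth, "2class")
  expect_identical(r$confusion[["TP"]], 3L)
  expect_equal(r$precision, 0.75)
  expect_equal(r$sensitivity, 0.75)
  expect_equal(r$f1, 0.75)
  expect_equal(r$accuracy, 0.8)
  # metrics are recomputable from the stored counts, exactly
  expect_identical(metrics_from_confusion(r$confusion, "2class"),
                   r[c("accuracy", "precision", "sensitivity", "f1")])
  expect_error(evaluate(character(0), character(0), "2class"),
               "empty predictions")
})

test_that("weighted recall equals accuracy identically in the 4-class task", {
  withr::with_seed(55, {
    for (rep in 1:10) {
      truth <- sample(c("control", "AMD", "DR", "other"), 40, replace = TRUE)
      pred <- sample(c("control", "AMD", "DR", "other"), 40, replace = TRUE)
      r <- evaluate(pred, truth, "4class")
      expect_equal(r$sensitivity, r$accuracy, tolerance = 1e-15)
      expect_identical(metrics_from_confusion(r$confusion, "4class"),
                       r[c("accuracy", "precision", "sensitivity", "f1")])
    }
  })
})

test_that("type contributions are importance sums in percent", {
  nm <- feature_names()
  uniform <- stats::setNames(rep(1 / 452, 452), nm)
  pct <- group_contribution(uniform)
  expect_equal(unname(pct["LBP_OCT"]), 100 * 177 / 452, tolerance = 1e-9)
  expect_equal(sum(pct), 100, tolerance = 1e-9)
  point <- stats::setNames(c(rep(0, 451), 1), nm)  # all mass on FAZ_angle
  pp <- group_contribution(point)
  expect_equal(unname(pp["FAZ"]), 100)
  expect_error(group_contribution(c(bogus_feature = 1)), "unmapped")
})

test_that("the full pipeline classifies a separable synthetic cohort", {
  tab <- make_task_table(24, seed = 99)
  out <- run_pipeline(tab, task = "2class", seed = 17,
                      grid = list(ntree = 300, mtry = 1))
  expect_s3_class(out$result, "cv_result")
  expect_gte(out$result$accuracy, 0.9)
  expect_equal(sum(out$ranking$importance), 1, tolerance = 1e-9)
  expect_equal(sum(out$contribution), 100, tolerance = 1e-6)
})
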