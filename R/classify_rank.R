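# ---- model registry ------------------------------------------------------

# Each entry: fit(x, y, params, seed) -> model; predict(model, x) -> factor
# levels of y; importance(model, feature_names) -> named nonnegative vector
# or NULL (no importances); default_grid: named list of candidate values.
model_registry <- function() {
  list(
    random_forest = list(
      fit = function(x, y, params, seed) {
        withr::with_seed(seed, randomForest::randomForest(
          x = x, y = y,
          ntree = params$ntree %||% 500,
          mtry = params$mtry %||% max(1, floor(sqrt(ncol(x))))))
      },
      predict = function(model, x) predict(model, x),
      importance = function(model, feature_names) {
        imp <- randomForest::importance(model, type = 2)[, 1]
        imp[feature_names]
      },
      default_grid = list(ntree = 500, mtry = c(0.5, 1, 2))
      # mtry entries are multipliers of floor(sqrt(p)), resolved at fit time
    ),
    gradient_boosted_trees = list(
      fit = function(x, y, params, seed) {
        model <- xgboost::xgboost(
          x, y,
          nrounds = params$nrounds %||% 100,
          max_depth = params$max_depth %||% 3,
          learning_rate = params$eta %||% 0.1,
          nthreads = 1, verbosity = 0, seed = seed)
        attr(model, "levels") <- levels(y)
        model
      },
      predict = function(model, x) {
        lev <- attr(model, "levels")
        p <- predict(model, x)
        if (is.matrix(p))  # multiclass: one probability column per class
          factor(colnames(p)[max.col(p, ties.method = "first")],
                 levels = lev)
        else               # binary: probability of the second level
          factor(lev[1 + (p > 0.5)], levels = lev)
      },
      importance = function(model, feature_names) {
        tab <- xgboost::xgb.importance(model = model)
        imp <- stats::setNames(rep(0, length(feature_names)), feature_names)
        imp[tab$Feature] <- tab$Gain
        imp
      },
      default_grid = list(nrounds = 100, max_depth = c(2, 4), eta = 0.1)
    ),
    extra_trees = list(
      fit = function(x, y, params, seed) {
        df <- data.frame(x, check.names = FALSE)
        df$.outcome <- y
        ranger::ranger(dependent.variable.name = ".outcome", data = df,
                       num.trees = params$num.trees %||% 500,
                       mtry = params$mtry %||% NULL,
                       splitrule = "extratrees",
                       importance = "impurity",
                       seed = seed, num.threads = 1)
      },
      predict = function(model, x)
        predict(model, data.frame(x, check.names = FALSE),
                num.threads = 1)$predictions,
      importance = function(model, feature_names)
        ranger::importance(model)[feature_names],
      default_grid = list(num.trees = 500)
    ),
    svm = list(
      fit = function(x, y, params, seed) {
        withr::with_seed(seed, e1071::svm(
          x = x, y = y, kernel = "radial",
          cost = params$cost %||% 1,
          gamma = params$gamma %||% (1 / ncol(x)),
          scale = apply(x, 2, sd) > 0))
      },
      predict = function(model, x) predict(model, x),
      importance = NULL,
      default_grid = list(cost = c(0.1, 1, 10))
    )
  )
}

resolve_params <- function(model_name, params, p) {
  # random_forest's mtry grid entries are sqrt(p) multipliers
  if (model_name == "random_forest" && !is.null(params$mtry)) {
    params$mtry <- max(1, min(p, round(params$mtry * floor(sqrt(p)))))
  }
  params
}

# Stratified fold ids (1..k), deterministic given seed.
stratified_folds <- function(y, k, seed) {
  withr::with_seed(seed, {
    f <- integer(length(y))
    for (cl in levels(y)) {
      i <- which(y == cl)
      f[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    f
  })
}

#' Stratified train/test split of a feature table
#'
#' @param table Feature table ([build_feature_table()]).
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.75; per-class counts are rounded).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with `train` and `test` feature tables (disjoint, their
#'   union is the input).
#' @export
split_train_test <- function(table, train_fraction = 0.75, seed = 1) {
  validate_feature_table(table)
  y <- factor(table$label)
  if (any(table(y) < 4))
    stop("every class needs at least 4 samples to split", call. = FALSE)
  idx <- withr::with_seed(seed, {
    tr <- integer(0)
    for (cl in levels(y)) {
      i <- which(y == cl)
      tr <- c(tr, sample(i, round(train_fraction * length(i))))
    }
    sort(tr)
  })
  list(train = table[idx, , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), idx), , drop = FALSE])
}

#' Grid-searched model fit with inner cross-validation
#'
#' Exhaustive grid search over stratified `inner_folds`-fold
#' cross-validation on the training data, maximising pooled accuracy; ties
#' are broken by grid order (first wins). The winning grid point is refit
#' on the full training set.
#'
#' @param x Numeric feature matrix (training rows, selected features).
#' @param y Factor of class labels.
#' @param model One of `"random_forest"`, `"gradient_boosted_trees"`,
#'   `"extra_trees"`, `"svm"`.
#' @param grid Named list of candidate hyperparameter values; defaults to a
#'   small model-specific grid.
#' @param inner_folds Number of inner folds (default 5).
#' @param seed Integer seed controlling folds and the fits.
#' @return Object of class `retquant_fit`: list with the fitted `model`,
#'   `model_name`, `best_params`, `cv_accuracy`, `grid_results` (one row
#'   per grid point) and `features` (column names of `x`).
#' @export
nested_fit <- function(x, y, model = "random_forest", grid = NULL,
                       inner_folds = 5, seed = 1) {
  reg <- model_registry()
  if (!model %in% names(reg))
    stop("unknown model '", model, "'", call. = FALSE)
  spec <- reg[[model]]
  y <- droplevels(factor(y))
  grid <- grid %||% spec$default_grid
  pts <- expand.grid(grid, stringsAsFactors = FALSE)
  attr(pts, "out.attrs") <- NULL
  if (nrow(pts) == 0) stop("empty hyperparameter grid", call. = FALSE)
  folds <- stratified_folds(y, inner_folds, seed)
  use <- which(tabulate(folds, inner_folds) > 0)  # small cohorts can
  # leave a fold empty after per-class assignment; skip it
  for (f in use) {
    if (nlevels(droplevels(y[folds != f])) < nlevels(y))
      stop("degenerate inner fold (a class is absent): the cohort is too ",
           "small for ", inner_folds, "-fold tuning", call. = FALSE)
  }
  acc <- numeric(nrow(pts))
  for (g in seq_len(nrow(pts))) {
    params <- resolve_params(model, as.list(pts[g, , drop = FALSE]),
                             ncol(x))
    correct <- 0L
    for (f in use) {
      m <- spec$fit(x[folds != f, , drop = FALSE], y[folds != f],
                    params, seed)
      pred <- spec$predict(m, x[folds == f, , drop = FALSE])
      correct <- correct + sum(pred == y[folds == f])
    }
    acc[g] <- correct / sum(folds %in% use)
  }
  best <- which.max(acc)  # first maximum = first grid point on ties
  best_params <- resolve_params(model, as.list(pts[best, , drop = FALSE]),
                                ncol(x))
  structure(list(model = spec$fit(x, y, best_params, seed),
                 model_name = model, best_params = best_params,
                 cv_accuracy = acc[best],
                 grid_results = cbind(pts, cv_accuracy = acc),
                 features = colnames(x), levels = levels(y), seed = seed),
            class = "retquant_fit")
}

#' @export
print.retquant_fit <- function(x, ...) {
  cat(sprintf("<retquant_fit> %s on %d features; inner-CV accuracy %.3f\n",
              x$model_name, length(x$features), x$cv_accuracy))
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object A `retquant_fit`.
#' @param newdata Feature matrix (or feature table) containing at least the
#'   fitted features.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.retquant_fit <- function(object, newdata, ...) {
  if (is.data.frame(newdata) && "eye_id" %in% names(newdata))
    newdata <- table_matrix(newdata)$x
  reg <- model_registry()[[object$model_name]]
  reg$predict(object$model, newdata[, object$features, drop = FALSE])
}

#' Normalised feature importances of a fitted model
#'
#' @param fit A `retquant_fit` for a tree model.
#' @return Named nonnegative numeric vector over the fitted features,
#'   summing to 1.
#' @export
feature_importance <- function(fit) {
  reg <- model_registry()[[fit$model_name]]
  if (is.null(reg$importance))
    stop("model '", fit$model_name, "' exposes no feature importances",
         call. = FALSE)
  imp <- reg$importance(fit$model, fit$features)
  imp[!is.finite(imp) | imp < 0] <- 0
  if (sum(imp) == 0) return(imp)
  imp / sum(imp)
}

#' Importance-threshold pruning with retraining
#'
#' Drops features whose normalised importance is below `threshold` and
#' refits the model with the winning hyperparameters on the surviving
#' features. If nothing falls below the threshold the original fit is
#' returned unchanged. For models without importances (svm) this is a
#' no-op with a warning.
#'
#' @param fit A `retquant_fit`.
#' @param x,y The training matrix and labels the model was fit on.
#' @param threshold Importance cutoff (default 0.001).
#' @return A `retquant_fit` on the surviving feature set.
#' @export
prune_retrain <- function(fit, x, y, threshold = 0.001) {
  reg <- model_registry()[[fit$model_name]]
  if (is.null(reg$importance)) {
    warning("model '", fit$model_name,
            "' has no importances; pruning skipped", call. = FALSE)
    return(fit)
  }
  if (threshold <= 0) return(fit)
  imp <- feature_importance(fit)
  keep <- names(imp)[imp >= threshold]
  if (length(keep) == 0)
    stop("importance pruning dropped every feature", call. = FALSE)
  if (length(keep) == length(fit$features)) return(fit)
  y <- droplevels(factor(y))
  x2 <- x[, keep, drop = FALSE]
  structure(list(model = reg$fit(x2, y, fit$best_params, fit$seed),
                 model_name = fit$model_name,
                 best_params = fit$best_params,
                 cv_accuracy = fit$cv_accuracy,
                 grid_results = fit$grid_results,
                 features = keep, levels = levels(y), seed = fit$seed),
            class = "retquant_fit")
}

# ---- metrics -------------------------------------------------------------

#' Classification metrics from predictions
#'
#' For the 2-class task (`control` vs `disease`, positive class `disease`)
#' the four confusion counts give
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `precision = TP/(TP+FP)`,
#' `sensitivity = TP/(TP+FN)` and the F1 score, the harmonic mean of
#' precision and sensitivity. For the 4-class task, accuracy is the overall
#' fraction correct and precision / sensitivity / F1 are support-weighted
#' averages of the per-class one-vs-rest values (with this weighting,
#' sensitivity equals accuracy identically).
#'
#' @param predictions,truth Vectors (or factors) of class labels of equal
#'   length.
#' @param task `"2class"` or `"4class"`.
#' @param positive Positive class for the 2-class task (default
#'   `"disease"`).
#' @return Object of class `cv_result`: list with `task`, `confusion`
#'   (counts), `accuracy`, `precision`, `sensitivity`, `f1`.
#' @export
evaluate <- function(predictions, truth, task = c("2class", "4class"),
                     positive = "disease") {
  task <- match.arg(task)
  if (length(predictions) == 0)
    stop("empty predictions", call. = FALSE)
  if (length(predictions) != length(truth))
    stop("predictions and truth differ in length", call. = FALSE)
  lev <- sort(unique(c(as.character(truth), as.character(predictions))))
  predictions <- factor(as.character(predictions), levels = lev)
  truth <- factor(as.character(truth), levels = lev)
  cm <- table(truth = truth, predicted = predictions)
  if (task == "2class") {
    if (!positive %in% lev)
      stop("positive class '", positive, "' absent from labels",
           call. = FALSE)
    counts <- c(TP = sum(predictions == positive & truth == positive),
                TN = sum(predictions != positive & truth != positive),
                FP = sum(predictions == positive & truth != positive),
                FN = sum(predictions != positive & truth == positive))
    metrics <- metrics_from_confusion(counts, "2class")
  } else {
    metrics <- metrics_from_confusion(cm, "4class")
    counts <- cm
  }
  structure(c(list(task = task, confusion = counts), metrics),
            class = "cv_result")
}

#' Recompute metrics from stored confusion counts
#'
#' @param confusion For `"2class"`, a named vector with `TP`, `TN`, `FP`,
#'   `FN`; for `"4class"`, a square confusion matrix (rows = truth).
#' @param task `"2class"` or `"4class"`.
#' @return List with `accuracy`, `precision`, `sensitivity`, `f1`.
#' @export
metrics_from_confusion <- function(confusion, task = c("2class", "4class")) {
  task <- match.arg(task)
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  if (task == "2class") {
    tp <- confusion[["TP"]]; tn <- confusion[["TN"]]
    fp <- confusion[["FP"]]; fn <- confusion[["FN"]]
    acc <- safe_div(tp + tn, tp + tn + fp + fn)
    prec <- safe_div(tp, tp + fp)
    sens <- safe_div(tp, tp + fn)
    f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
    list(accuracy = acc, precision = prec, sensitivity = sens, f1 = f1)
  } else {
    cm <- as.matrix(confusion)
    n <- sum(cm)
    support <- rowSums(cm)
    w <- support / n
    prec_k <- vapply(seq_len(nrow(cm)), function(k)
      safe_div(cm[k, k], sum(cm[, k])), numeric(1))
    sens_k <- vapply(seq_len(nrow(cm)), function(k)
      safe_div(cm[k, k], sum(cm[k, ])), numeric(1))
    f1_k <- ifelse(prec_k + sens_k == 0, 0,
                   2 * prec_k * sens_k / (prec_k + sens_k))
    list(accuracy = sum(diag(cm)) / n,
         precision = sum(w * prec_k),
         sensitivity = sum(w * sens_k),
         f1 = sum(w * f1_k))
  }
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s  acc %.3f  prec %.3f  sens %.3f  F1 %.3f\n",
              x$task, x$accuracy, x$precision, x$sensitivity, x$f1))
  invisible(x)
}

#' Per-feature-type contribution percentages
#'
#' Sums the normalised importances within each feature type and reports
#' them as percentages (summing to 100 over the ranked features).
#'
#' @param importance Named, normalised importance vector
#'   ([feature_importance()]).
#' @param type_map Named character vector mapping feature name to type;
#'   defaults to [feature_types()].
#' @return Named numeric vector of percentages, one per feature type,
#'   sorted decreasing.
#' @export
group_contribution <- function(importance, type_map = feature_types()) {
  unmapped <- setdiff(names(importance), names(type_map))
  if (length(unmapped) > 0)
    stop("unmapped feature name(s): ",
         paste(head(unmapped, 3), collapse = ", "), call. = FALSE)
  total <- sum(importance)
  if (total <= 0) stop("importances sum to zero", call. = FALSE)
  types <- type_map[names(importance)]
  pct <- 100 * tapply(importance / total, types, sum)
  sort(c(pct), decreasing = TRUE)
}

#' Importance ranking table
#'
#' @param fit A fitted tree model (`retquant_fit`).
#' @param type_map Named character vector mapping feature to type.
#' @return Data frame sorted by decreasing importance with columns
#'   `feature`, `importance`, `feature_type`.
#' @export
rank_features <- function(fit, type_map = feature_types()) {
  imp <- feature_importance(fit)
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    feature_type = unname(type_map[names(imp)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' End-to-end classification pipeline
#'
#' Convenience wrapper chaining the stratified 75/25 split, univariate
#' feature selection, inner-5-fold grid search, importance-threshold
#' pruning, holdout evaluation and importance ranking.
#'
#' @param table Cohort feature table.
#' @param task `"2class"` or `"4class"`.
#' @param model Registry model name (default `"random_forest"`).
#' @param seed Integer seed for split, folds and fits.
#' @param alpha Selection threshold (default 0.05).
#' @param selection_scope `"train"` (leakage-free, default) computes the
#'   univariate selection on the training split only; `"cohort"` computes
#'   it on the full cohort.
#' @param prune_threshold Importance pruning cutoff (default 0.001).
#' @param train_fraction Training fraction of the outer split.
#' @param grid Optional hyperparameter grid.
#' @return List with `selection`, `fit`, `result` (a `cv_result`),
#'   `ranking` and `contribution`.
#' @export
run_pipeline <- function(table, task = c("2class", "4class"),
                         model = "random_forest", seed = 1, alpha = 0.05,
                         selection_scope = c("train", "cohort"),
                         prune_threshold = 0.001, train_fraction = 0.75,
                         grid = NULL) {
  task <- match.arg(task)
  selection_scope <- match.arg(selection_scope)
  mode <- if (task == "2class") "two_group" else "four_group"
  sp <- split_train_test(table, train_fraction, seed)
  sel_tab <- if (selection_scope == "train") sp$train else table
  selection <- select_features(sel_tab, mode = mode, alpha = alpha)
  feats <- selection$feature[selection$selected]
  if (length(feats) == 0)
    stop("no feature passed selection at alpha = ", alpha, call. = FALSE)
  ytr <- selection_groups(sp$train$label, mode)
  yte <- selection_groups(sp$test$label, mode)
  xtr <- table_matrix(sp$train)$x[, feats, drop = FALSE]
  xte <- table_matrix(sp$test)$x[, feats, drop = FALSE]
  fit <- nested_fit(xtr, ytr, model = model, grid = grid, seed = seed)
  reg <- model_registry()[[model]]
  if (!is.null(reg$importance))
    fit <- prune_retrain(fit, xtr, ytr, threshold = prune_threshold)
  pred <- predict(fit, xte)
  result <- evaluate(pred, yte, task = task)
  ranking <- if (!is.null(reg$importance)) rank_features(fit) else NULL
  contribution <- if (!is.null(ranking))
    group_contribution(feature_importance(fit)) else NULL
  list(selection = selection, fit = fit, result = result,
       ranking = ranking, contribution = contribution)
}
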