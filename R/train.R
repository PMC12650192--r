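#' Classifier specification
#'
#' The three model families evaluated for fit detection: random forest,
#' RBF-kernel support vector machine and gradient-boosted trees. `params`
#' overrides the family defaults; `grid` (a data frame of candidate
#' parameter combinations, e.g. [default_grid()]) switches on nested grid
#' search inside [evaluate()].
#'
#' Family defaults: random forest — 100 trees, unbounded depth, minimum
#' node size 1; SVM — `cost = 1`, `gamma = NA` (the `1/p` heuristic);
#' gradient-boosted trees — learning rate 0.1, depth 3, 100 rounds,
#' subsample 1.
#'
#' @param family One of `"random_forest"`, `"svm_rbf"`,
#'   `"gradient_boosted_trees"`.
#' @param params Named list of hyperparameter overrides.
#' @param grid Optional data frame of hyperparameter candidates for grid
#'   search; its row order is the documented tie-break order.
#' @param seed Integer seed controlling every random element of training.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("gradient_boosted_trees",
                                  "random_forest", "svm_rbf"),
                       params = list(), grid = NULL, seed = 1) {
  family <- match.arg(family)
  defaults <- switch(family,
    random_forest = list(num_trees = 100, max_depth = 0,
                         min_node_size = 1),
    svm_rbf = list(cost = 1, gamma = NA),
    gradient_boosted_trees = list(eta = 0.1, max_depth = 3, nrounds = 100,
                                  subsample = 1))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    bf_stop(paste("unknown hyperparameter(s):",
                  paste(unknown, collapse = ", ")), "bf_config_error")
  defaults[names(params)] <- params
  if (!is.null(grid) && (!is.data.frame(grid) || nrow(grid) == 0L))
    bf_stop("grid must be a non-empty data frame", "bf_config_error")
  structure(list(family = family, params = defaults, grid = grid,
                 seed = as.integer(seed)), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s)%s, seed %d\n", x$family,
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", "),
              if (is.null(x$grid)) "" else
                sprintf(", grid of %d", nrow(x$grid)), x$seed))
  invisible(x)
}

#' Default hyperparameter grids
#'
#' Small, desk-scale search grids per family. Row order is the tie-break
#' order used by [grid_search()]. `max_depth = 0` means unbounded;
#' `gamma = NA` is the `1/p` kernel-width heuristic.
#'
#' @param family As in [model_spec()].
#' @return Data frame of hyperparameter combinations.
#' @export
default_grid <- function(family = c("gradient_boosted_trees",
                                    "random_forest", "svm_rbf")) {
  family <- match.arg(family)
  switch(family,
    random_forest = expand.grid(num_trees = c(100, 300),
                                max_depth = c(0, 10),
                                min_node_size = c(1, 5)),
    svm_rbf = expand.grid(cost = c(0.1, 1, 10),
                          gamma = c(NA, 0.01, 0.1)),
    gradient_boosted_trees = expand.grid(eta = c(0.05, 0.1),
                                         max_depth = c(3, 6),
                                         nrounds = c(100, 300),
                                         subsample = c(0.8, 1)))
}

class_levels <- c("fit", "poor_fit")

#' Train a fit classifier on a feature matrix
#'
#' Low-level trainer behind [fitdetect()] and [evaluate()]. Deterministic
#' given `seed` (single-threaded tree growing, seeded subsampling). The
#' returned handle predicts classes and poor-fit scores via
#' [predict_scores()].
#'
#' @param spec A [model_spec()] (its `grid` is ignored here).
#' @param X Numeric feature matrix.
#' @param y Labels over `{fit, poor_fit}`.
#' @param params Optional override of `spec$params` (used by grid search).
#' @return An object of class `bf_model`.
#' @export
train_classifier <- function(spec, X, y, params = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2L)
    bf_stop("training labels contain a single class", "bf_training_error")
  if (!all(y %in% class_levels))
    bf_stop("labels must be 'fit' or 'poor_fit'", "bf_vocab_error")
  p <- spec$params
  if (!is.null(params)) p[names(params)] <- params
  yf <- factor(y, class_levels)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(spec$seed)
  fit <- switch(spec$family,
    random_forest = ranger::ranger(
      x = as.data.frame(X), y = yf, num.trees = p$num_trees,
      max.depth = p$max_depth, min.node.size = p$min_node_size,
      probability = TRUE, num.threads = 1, seed = spec$seed),
    svm_rbf = e1071::svm(
      x = X, y = yf, kernel = "radial", cost = p$cost,
      gamma = if (is.na(p$gamma)) 1 / ncol(X) else p$gamma,
      scale = TRUE),
    gradient_boosted_trees = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = p$eta,
                    max_depth = p$max_depth, subsample = p$subsample,
                    nthread = 1, seed = spec$seed),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(yf == "poor_fit"),
                                  nthread = 1),
      nrounds = p$nrounds, verbose = 0))
  structure(list(family = spec$family, fit = fit, params = p,
                 feature_names = colnames(X)), class = "bf_model")
}

#' Class predictions and poor-fit scores
#'
#' @param model A [train_classifier()] handle.
#' @param X Numeric feature matrix with the training columns.
#' @return List with `class` (character) and `score` (numeric; larger
#'   means more poor-fit-like: a class probability for the tree ensembles,
#'   an oriented decision value for the SVM).
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "bf_model"))
  X <- as.matrix(X)[, model$feature_names, drop = FALSE]
  if (model$family == "random_forest") {
    pr <- stats::predict(model$fit, data = as.data.frame(X),
                         num.threads = 1)$predictions[, "poor_fit"]
    list(class = ifelse(pr >= 0.5, "poor_fit", "fit"), score = pr)
  } else if (model$family == "svm_rbf") {
    pred <- stats::predict(model$fit, X, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    sign <- if (startsWith(colnames(dv)[1], "poor_fit")) 1 else -1
    list(class = as.character(pred), score = sign * as.numeric(dv))
  } else {
    pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1))
    list(class = ifelse(pr >= 0.5, "poor_fit", "fit"), score = pr)
  }
}

#' Fit a respirator-fit detector to a feature table
#'
#' The top-level modelling interface: takes a labeled feature table (22
#' cycle features or 18 window features per row), optionally balances the
#' classes with SMOTE, optionally resolves hyperparameters by grid search
#' with inner cross-validation, and trains the requested classifier. Use
#' [evaluate()] for honest k-fold / leave-one-subject-out performance
#' estimates; `fitdetect()` trains on everything it is given.
#'
#' @param data Feature table from [build_feature_table()] (or any data
#'   frame with a `label` column plus numeric feature columns).
#' @param family Model family, see [model_spec()].
#' @param params,grid,seed Passed to [model_spec()].
#' @param smote Balance classes with [smote_balance()] before training
#'   (default `TRUE`).
#' @param k_neighbors SMOTE neighbor count.
#' @return An object of class `fitdetect` with `print`, `summary`,
#'   `predict` and `plot` methods.
#' @export
#' @examples
#' cfg <- synth_config(n_subjects = 2, seed = 7,
#'                     session_plan = default_session_plan()[1:10, ])
#' tab <- cohort_feature_table(simulate_cohort(cfg), mode = "cycles")
#' fit <- fitdetect(tab, family = "random_forest", seed = 7)
#' fit
#' head(predict(fit, tab))
fitdetect <- function(data, family = c("gradient_boosted_trees",
                                       "random_forest", "svm_rbf"),
                      params = list(), grid = NULL, smote = TRUE,
                      k_neighbors = 5, seed = 1) {
  spec <- model_spec(family, params, grid, seed)
  X <- as.matrix(data[feature_columns(data)])
  y <- as.character(data$label)
  if (!is.null(spec$grid)) {
    gs <- grid_search(spec, X, y, smote = smote,
                      k_neighbors = k_neighbors)
    spec$params[names(gs$params)] <- gs$params
    spec$grid <- NULL
  }
  train <- list(X = X, y = y)
  if (smote) {
    bal <- smote_balance(X, y, k_neighbors, seed = seed)
    train <- list(X = bal$X, y = bal$y)
  }
  model <- train_classifier(spec, train$X, train$y)
  pred <- predict_scores(model, X)
  structure(list(model = model, spec = spec, smote = smote,
                 k_neighbors = k_neighbors,
                 train_metrics = compute_metrics(y, pred$class,
                                                 pred$score),
                 X = X, y = y, call = match.call()),
            class = "fitdetect")
}

#' @export
print.fitdetect <- function(x, ...) {
  cat(sprintf("<fitdetect> %s on %d rows x %d features%s\n",
              x$spec$family, nrow(x$X), ncol(x$X),
              if (x$smote) " (SMOTE-balanced training)" else ""))
  cat("  params:", paste(names(x$model$params), unlist(x$model$params),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fitdetect <- function(object, ...) {
  m <- object$train_metrics
  cat(sprintf("Respirator-fit detector (%s)\n", object$spec$family))
  cat(sprintf("Training rows: %d (%s)\n", length(object$y),
              paste(names(table(object$y)), table(object$y), sep = ": ",
                    collapse = ", ")))
  cat(sprintf("Apparent (training) F1 for poor_fit: %.4f, ROC-AUC: %.4f\n",
              m$f1, m$roc_auc))
  print(m$confusion)
  invisible(object)
}

#' @export
#' @rdname fitdetect
#' @param object,newdata,type `predict` arguments: a fitted detector, a
#'   feature table or matrix, and `"class"` or `"score"` (poor-fit score).
#' @param ... Unused.
predict.fitdetect <- function(object, newdata,
                              type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- if (is.data.frame(newdata))
    as.matrix(newdata[intersect(object$model$feature_names,
                                names(newdata))])
  else as.matrix(newdata)
  out <- predict_scores(object$model, X)
  if (type == "class") out$class else out$score
}

#' @export
#' @rdname fitdetect
#' @param x A `fitdetect` object (for `plot`).
#' @param n_repeats,top Permutation-importance repeats and number of
#'   features shown.
plot.fitdetect <- function(x, n_repeats = 5, top = 10, ...) {
  imp <- permutation_importance(x, n_repeats = n_repeats,
                                seed = x$spec$seed)
  imp <- imp[seq_len(min(top, nrow(imp))), ]
  graphics::barplot(rev(imp$mean_drop), names.arg = rev(imp$feature),
                    horiz = TRUE, las = 1, col = "steelblue",
                    xlab = "mean F1 drop when permuted",
                    main = sprintf("Permutation importance (%s)",
                                   x$spec$family), ...)
  invisible(imp)
}
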