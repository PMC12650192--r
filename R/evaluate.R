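#' Grid search over hyperparameters
#'
#' Scores every row of `spec$grid` by mean inner-fold F1 (stratified
#' k-fold on the supplied training rows, SMOTE applied to the inner
#' training portions only) and returns the best row; ties go to the first
#' row in grid order. Intended for nested use on the training portion of
#' an outer fold — never on test rows.
#'
#' @param spec A [model_spec()] with a non-`NULL` `grid`.
#' @param X,y Training feature matrix and labels.
#' @param inner_k Inner fold count (default 3).
#' @param smote,k_neighbors Inner-fold SMOTE settings.
#' @return List with `params` (best row as a named list) and `scores`
#'   (mean inner F1 per grid row).
#' @export
grid_search <- function(spec, X, y, inner_k = 3, smote = TRUE,
                        k_neighbors = 5) {
  if (is.null(spec$grid) || nrow(spec$grid) == 0L)
    bf_stop("grid search requires a non-empty grid", "bf_config_error")
  X <- as.matrix(X)
  y <- as.character(y)
  folds <- stratified_kfold(y, inner_k, spec$seed)
  scores <- vapply(seq_len(nrow(spec$grid)), function(g) {
    params <- as.list(spec$grid[g, , drop = FALSE])
    f1 <- vapply(folds, function(test) {
      tr <- setdiff(seq_along(y), test)
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      if (smote) {
        bal <- smote_balance(Xtr, ytr, k_neighbors, seed = spec$seed)
        Xtr <- bal$X; ytr <- bal$y
      }
      m <- train_classifier(spec, Xtr, ytr, params = params)
      pr <- predict_scores(m, X[test, , drop = FALSE])
      compute_metrics(y[test], pr$class)$f1
    }, numeric(1))
    mean(f1)
  }, numeric(1))
  best <- which.max(scores)   # which.max takes the first maximum: tie rule
  list(params = as.list(spec$grid[best, , drop = FALSE]), scores = scores)
}

#' Cross-validated evaluation of a fit classifier
#'
#' Runs the full validation loop the way it must be run to avoid leakage:
#' folds are resolved by [make_folds()]; SMOTE (when enabled) and grid
#' search (when `spec$grid` is set) see only the training portion of each
#' fold; the test fold is never resampled. Two audits run on every fold
#' and abort on violation: under LOSO the held-out subject must be absent
#' from the training rows, and the test rows must be the untouched
#' original rows (row-identity check against the input table).
#'
#' @param table A labeled feature table.
#' @param spec A [model_spec()].
#' @param plan A [fold_plan()].
#' @param smote Apply SMOTE to each training fold (default `TRUE`).
#' @param k_neighbors SMOTE neighbor count.
#' @return An object of class `fit_eval`: per-fold F1 / ROC-AUC /
#'   confusion counts, pooled confusion matrix, and the mean and SD of F1
#'   across folds.
#' @export
evaluate <- function(table, spec = model_spec(), plan = fold_plan(),
                     smote = TRUE, k_neighbors = 5) {
  if (is.null(plan$folds)) plan <- make_folds(table, plan)
  X <- as.matrix(table[feature_columns(table)])
  y <- as.character(table$label)
  res <- lapply(seq_along(plan$folds), function(f) {
    test <- plan$folds[[f]]
    train <- setdiff(seq_len(nrow(X)), test)
    if (plan$scheme == "loso" &&
        length(intersect(table$subject_id[train],
                         table$subject_id[test])))
      bf_stop("LOSO leakage: held-out subject present in training rows",
              "bf_leakage_error")
    Xtr <- X[train, , drop = FALSE]; ytr <- y[train]
    params <- NULL
    if (!is.null(spec$grid))
      params <- grid_search(spec, Xtr, ytr, smote = smote,
                            k_neighbors = k_neighbors)$params
    Xte <- X[test, , drop = FALSE]
    if (smote) {
      bal <- smote_balance(Xtr, ytr, k_neighbors,
                           seed = spec$seed + 7919L * f)
      Xtr <- bal$X; ytr <- bal$y
      # row-identity audit: no resampled row may coincide with a test row
      synth_keys <- apply(bal$X[bal$synthetic, , drop = FALSE], 1, paste,
                          collapse = "\r")
      test_keys <- apply(Xte, 1, paste, collapse = "\r")
      if (any(synth_keys %in% test_keys))
        bf_stop("SMOTE leakage: a resampled row is identical to a test row",
                "bf_leakage_error")
    }
    fspec <- spec
    fspec$seed <- spec$seed + f
    m <- train_classifier(fspec, Xtr, ytr, params = params)
    pr <- predict_scores(m, Xte)
    met <- compute_metrics(y[test], pr$class, pr$score)
    list(fold = names(plan$folds)[f], n_test = length(test),
         metrics = met, params = params %||% spec$params)
  })
  folds <- data.frame(
    fold = vapply(res, `[[`, character(1), "fold"),
    n_test = vapply(res, `[[`, integer(1), "n_test"),
    f1 = vapply(res, function(r) r$metrics$f1, numeric(1)),
    roc_auc = vapply(res, function(r) r$metrics$roc_auc, numeric(1)))
  pooled <- Reduce(`+`, lapply(res, function(r) r$metrics$confusion))
  structure(
    list(scheme = plan$scheme, k = plan$k, folds = folds,
         pooled_confusion = pooled,
         summary = list(f1_mean = mean(folds$f1), f1_sd = stats::sd(folds$f1)),
         family = spec$family,
         params = res[[1]]$params, fold_params = lapply(res, `[[`, "params"),
         smote = smote, k_neighbors = k_neighbors, seed = spec$seed),
    class = "fit_eval")
}

#' @export
print.fit_eval <- function(x, ...) {
  cat(sprintf("<fit_eval> %s, %s: %d folds\n", x$family, x$scheme,
              nrow(x$folds)))
  cat(sprintf("  F1 (poor_fit): %.4f +/- %.4f\n", x$summary$f1_mean,
              x$summary$f1_sd))
  auc <- x$folds$roc_auc
  if (any(is.finite(auc)))
    cat(sprintf("  ROC-AUC: %.4f (mean over %d defined folds)\n",
                mean(auc[is.finite(auc)]), sum(is.finite(auc))))
  cat("  pooled confusion (rows = truth):\n")
  print(x$pooled_confusion)
  invisible(x)
}

#' @export
summary.fit_eval <- function(object, ...) {
  print(object)
  cat("\nPer-fold metrics:\n")
  print(object$folds, row.names = FALSE)
  invisible(object)
}

#' Write / read an evaluation report
#'
#' Serializes a [evaluate()] report to structured JSON (fold definitions,
#' per-fold metrics, pooled confusion matrix, resolved hyperparameters,
#' seed), so runs are diffable and archivable.
#'
#' @param report A `fit_eval` object.
#' @param path Output path.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns the parsed list.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "fit_eval"))
  out <- list(scheme = report$scheme, family = report$family,
              params = report$params, smote = report$smote,
              k_neighbors = report$k_neighbors, seed = report$seed,
              f1_mean = report$summary$f1_mean,
              f1_sd = report$summary$f1_sd,
              folds = report$folds,
              pooled_confusion = as.vector(report$pooled_confusion),
              confusion_order = "tp_poor,fn_to_fit,fp_to_poor,tn_fit")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Permutation feature importance
#'
#' Importance of a feature is the drop in poor-fit F1 when that feature's
#' column is randomly permuted, averaged over `n_repeats` permutations.
#' Model-agnostic and computed on the rows supplied (by default the
#' detector's training rows).
#'
#' @param object A [fitdetect()] object.
#' @param X,y Optional evaluation rows; default the stored training rows.
#' @param n_repeats Permutations per feature (default 10).
#' @param seed Integer seed.
#' @return Data frame with `feature`, `mean_drop`, `sd_drop`, sorted by
#'   decreasing mean drop.
#' @export
permutation_importance <- function(object, X = NULL, y = NULL,
                                   n_repeats = 10, seed = 1) {
  stopifnot(inherits(object, "fitdetect"))
  if (n_repeats < 1)
    bf_stop("n_repeats must be >= 1", "bf_config_error")
  X <- as.matrix(X %||% object$X)
  y <- as.character(y %||% object$y)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  base <- compute_metrics(y, predict_scores(object$model, X)$class)$f1
  drops <- vapply(colnames(X), function(j) {
    d <- vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, j] <- Xp[sample.int(nrow(X)), j]
      base - compute_metrics(y, predict_scores(object$model, Xp)$class)$f1
    }, numeric(1))
    c(mean(d), stats::sd(d))
  }, numeric(2))
  out <- data.frame(feature = colnames(X), mean_drop = drops[1, ],
                    sd_drop = drops[2, ])
  out <- out[order(-out$mean_drop), ]
  rownames(out) <- NULL
  out
}
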