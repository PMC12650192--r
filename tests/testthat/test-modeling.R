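make_blobs <- function(n = 60, p = 4, gap = 8, seed = 1) {
  set.seed(seed)
  y <- rep(c("fit", "poor_fit"), length.out = n)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  X[y == "poor_fit", 1] <- X[y == "poor_fit", 1] + gap
  list(X = X, y = y)
}

blob_table <- function(n = 80, subjects = 4, gap = 14, seed = 1) {
  b <- make_blobs(n, 4, gap, seed)
  data.frame(subject_id = rep(sprintf("S%02d", 1:subjects),
                              each = ceiling(n / subjects),
                              length.out = n),
             session_id = "R1", provenance = sprintf("cycle[%d-%d]", 1:n,
                                                     2 * (1:n)),
             label = b$y, b$X)
}

test_that("SMOTE balances classes by minority interpolation", {
  b <- make_blobs(120, 3)
  keep <- c(which(b$y == "fit")[1:60], which(b$y == "poor_fit")[1:40])
  X <- b$X[keep, ]
  y <- b$y[keep]
  bal <- smote_balance(X, y, k_neighbors = 5, seed = 9)
  expect_equal(unname(table(bal$y)["fit"]), 60)
  expect_equal(unname(table(bal$y)["poor_fit"]), 60)
  expect_identical(bal$X[1:100, ], X)       # originals untouched
  expect_equal(sum(bal$synthetic), 20)

  # every synthetic row lies on a segment between a minority row and one
  # of its k nearest minority neighbors
  Xm <- X[y == "poor_fit", ]
  synth <- bal$X[bal$synthetic, , drop = FALSE]
  seg_dist <- function(r, a, b2) {
    ab <- b2 - a
    u <- sum((r - a) * ab) / sum(ab^2)
    if (!is.finite(u)) u <- 0
    u <- min(max(u, 0), 1)
    sqrt(sum((r - (a + u * ab))^2))
  }
  for (i in seq_len(nrow(synth))) {
    d <- Inf
    for (a in seq_len(nrow(Xm))) {
      d2 <- sqrt(colSums((t(Xm) - Xm[a, ])^2))
      d2[a] <- Inf
      for (bn in order(d2)[1:5])
        d <- min(d, seg_dist(synth[i, ], Xm[a, ], Xm[bn, ]))
    }
    expect_lt(d, 1e-9)
  }

  # seeded determinism
  bal2 <- smote_balance(X, y, k_neighbors = 5, seed = 9)
  expect_identical(bal$X, bal2$X)

  expect_error(smote_balance(X, rep("fit", 100)),
               class = "bf_balance_error")
  expect_error(smote_balance(X[1:64, ], y[1:64], k_neighbors = 5),
               class = "bf_neighbor_error")
})

test_that("fold plans partition rows and isolate subjects", {
  tab <- blob_table(1000, subjects = 20, seed = 3)
  plan <- make_folds(tab, fold_plan("kfold", k = 5, seed = 2))
  sizes <- lengths(plan$folds)
  expect_equal(sum(sizes), 1000)
  expect_equal(unname(sizes), rep(200L, 5))
  expect_identical(sort(unname(unlist(plan$folds))), 1:1000)
  # stratification: each fold's label mix within one row of proportional
  for (f in plan$folds) {
    expect_lte(abs(sum(tab$label[f] == "poor_fit") - 100), 1)
  }

  lplan <- make_folds(tab, fold_plan("loso"))
  expect_length(lplan$folds, 20)
  for (s in names(lplan$folds)) {
    test <- lplan$folds[[s]]
    expect_true(all(tab$subject_id[test] == s))
    expect_false(s %in% tab$subject_id[-test])
  }
  one <- tab[tab$subject_id == "S01", ]
  expect_error(make_folds(one, fold_plan("loso")), class = "bf_plan_error")
  expect_error(fold_plan("kfold", k = 1), class = "bf_plan_error")
})

test_that("all three families learn a separable problem perfectly", {
  b <- make_blobs()
  for (fam in c("random_forest", "svm_rbf", "gradient_boosted_trees")) {
    m <- train_classifier(model_spec(fam, seed = 7), b$X, b$y)
    pr <- predict_scores(m, b$X)
    expect_equal(mean(pr$class == b$y), 1, info = fam)
    # scores orient toward poor_fit
    expect_gt(min(pr$score[b$y == "poor_fit"]),
              max(pr$score[b$y == "fit"]))
    m2 <- train_classifier(model_spec(fam, seed = 7), b$X, b$y)
    expect_identical(predict_scores(m2, b$X)$score, pr$score)
  }
  expect_error(train_classifier(model_spec(), b$X, rep("fit", 60)),
               class = "bf_training_error")
})

test_that("grid search picks dominant points and breaks ties first", {
  b <- make_blobs(90, 3, seed = 10)
  one <- model_spec("svm_rbf", grid = data.frame(cost = 1, gamma = NA),
                    seed = 1)
  expect_equal(grid_search(one, b$X, b$y)$params$cost, 1)

  # root-only trees (minimum node size >= n) cannot use the features:
  # dominated by the ordinary forest on every inner fold
  spec <- model_spec("random_forest",
                     grid = data.frame(num_trees = 50, max_depth = 0,
                                       min_node_size = c(500, 1)),
                     seed = 1)
  gs <- grid_search(spec, b$X, b$y)
  expect_equal(gs$params$min_node_size, 1)
  expect_gt(gs$scores[2], gs$scores[1])

  tie <- model_spec("random_forest",
                    grid = data.frame(num_trees = c(50, 50),
                                      max_depth = 0, min_node_size = 1),
                    seed = 1)
  got <- grid_search(tie, b$X, b$y)
  expect_equal(got$scores[1], got$scores[2])
  expect_identical(rownames(as.data.frame(got$params)), "1")
  expect_error(grid_search(model_spec("svm_rbf"), b$X, b$y),
               class = "bf_config_error")
})

test_that("metrics reproduce hand-computed confusion arithmetic", {
  y_true <- c(rep("poor_fit", 136), rep("fit", 134))
  y_pred <- c(rep("poor_fit", 124), rep("fit", 12), rep("fit", 134))
  m <- compute_metrics(y_true, y_pred)
  expect_identical(m$confusion["poor_fit", "poor_fit"], 124L)
  expect_identical(m$confusion["poor_fit", "fit"], 12L)
  expect_identical(m$confusion["fit", "fit"], 134L)
  expect_identical(m$confusion["fit", "poor_fit"], 0L)
  expect_equal(m$fn_rate, 12 / 136)
  expect_equal(round(100 * m$fn_rate, 1), 8.8)
  expect_equal(m$f1, 2 * 124 / (2 * 124 + 0 + 12))
  expect_equal(round(m$f1, 3), 0.954)

  perfect <- compute_metrics(c("fit", "poor_fit", "fit"),
                             c("fit", "poor_fit", "fit"),
                             scores = c(0.1, 0.9, 0.2))
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$roc_auc, 1)
  expect_equal(perfect$fn_rate, 0)
  expect_error(compute_metrics("fit", c("fit", "fit")),
               class = "bf_input_error")
})

test_that("evaluation is deterministic and leak-audited", {
  tab <- blob_table(120, subjects = 4, seed = 6)
  spec <- model_spec("gradient_boosted_trees", seed = 5)
  r1 <- evaluate(tab, spec, fold_plan("loso"))
  r2 <- evaluate(tab, spec, fold_plan("loso"))
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$pooled_confusion, r2$pooled_confusion)
  expect_equal(nrow(r1$folds), 4)
  expect_equal(sum(r1$pooled_confusion), 120)
  expect_gt(r1$summary$f1_mean, 0.95)

  # every subject spans the same feature support, so a wide-margin
  # problem must come out perfect on every fold for every family
  set.seed(14)
  pattern <- rep(seq(-1, 1, length.out = 15), 4)
  grid_tab <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:4), each = 30),
    session_id = "R1", provenance = "x",
    label = rep(c("fit", "poor_fit"), each = 15, times = 4),
    f1 = rep(c(0, 10), each = 15, times = 4) + rep(pattern, 2)[1:120],
    f2 = stats::rnorm(120))
  for (fam in c("random_forest", "svm_rbf", "gradient_boosted_trees")) {
    rp <- evaluate(grid_tab, model_spec(fam, seed = 3), fold_plan("loso"))
    expect_equal(rp$summary$f1_mean, 1, info = fam)
    expect_equal(rp$pooled_confusion["poor_fit", "fit"] +
                   rp$pooled_confusion["fit", "poor_fit"], 0, info = fam)
    expect_true(all(rp$folds$roc_auc == 1), info = fam)
  }

  k <- evaluate(tab, spec, fold_plan("kfold", k = 4, seed = 2),
                smote = FALSE)
  expect_equal(sum(k$folds$n_test), 120)
  expect_true(all(k$folds$f1 >= 0 & k$folds$f1 <= 1))
  expect_true(all(k$folds$roc_auc >= 0 & k$folds$roc_auc <= 1))
})

test_that("single-class test folds keep F1 but mark AUC undefined", {
  tab <- blob_table(90, subjects = 3, seed = 8)
  tab$label[tab$subject_id == "S03"] <- "fit"
  tab[tab$subject_id == "S03", paste0("f", 1:4)] <-
    matrix(stats::rnorm(sum(tab$subject_id == "S03") * 4), ncol = 4)
  r <- evaluate(tab, model_spec("random_forest", seed = 1),
                fold_plan("loso"))
  s3 <- r$folds[r$folds$fold == "S03", ]
  expect_true(is.na(s3$roc_auc))
  expect_false(is.na(s3$f1))  # F1 is still reported for the fold
  expect_false(any(is.na(r$folds$f1[r$folds$fold != "S03"])))
})

test_that("permutation importance isolates the informative feature", {
  set.seed(33)
  n <- 200
  det <- stats::rnorm(n)
  noise <- matrix(stats::rnorm(n * 3), n,
                  dimnames = list(NULL, paste0("noise", 1:3)))
  tab <- data.frame(subject_id = "S01", session_id = "R1",
                    provenance = "cycle[1-2]",
                    label = ifelse(det > 0, "poor_fit", "fit"),
                    det = det, noise)
  fit <- fitdetect(tab, "random_forest", smote = FALSE, seed = 3)
  imp <- permutation_importance(fit, n_repeats = 5, seed = 2)
  expect_identical(imp$feature[1], "det")
  expect_gt(imp$mean_drop[1], 0.3)
  for (j in which(imp$feature != "det"))
    expect_lte(abs(imp$mean_drop[j]), 2 * imp$sd_drop[j] + 1e-9)
  imp2 <- permutation_importance(fit, n_repeats = 5, seed = 2)
  expect_identical(imp, imp2)
  expect_error(permutation_importance(fit, n_repeats = 0),
               class = "bf_config_error")
})

test_that("the fitted-detector interface predicts and summarizes", {
  tab <- blob_table(100, subjects = 4, seed = 12)
  fit <- fitdetect(tab, "svm_rbf", seed = 4)
  expect_s3_class(fit, "fitdetect")
  expect_equal(predict(fit, tab), tab$label)
  sc <- predict(fit, tab, type = "score")
  expect_gt(min(sc[tab$label == "poor_fit"]), max(sc[tab$label == "fit"]))
  expect_output(print(fit), "svm_rbf")
  expect_output(summary(fit), "Training rows")
})
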