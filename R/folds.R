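#' Cross-validation fold plan
#'
#' Two schemes: stratified `kfold` (seeded shuffle, fold sizes differing by
#' at most one, label proportions preserved) and `loso`
#' (leave-one-subject-out: one fold per distinct subject, every row of the
#' held-out subject excluded from training, testing subject-independent
#' generalization).
#'
#' @param scheme `"kfold"` or `"loso"`.
#' @param k Number of folds (kfold only, default 5).
#' @param seed Integer seed for the kfold shuffle.
#' @return An object of class `fold_plan`.
#' @export
fold_plan <- function(scheme = c("kfold", "loso"), k = 5, seed = 1) {
  scheme <- match.arg(scheme)
  if (scheme == "kfold" && (k < 2 || k != round(k)))
    bf_stop("k must be an integer >= 2", "bf_plan_error")
  structure(list(scheme = scheme, k = as.integer(k),
                 seed = as.integer(seed), folds = NULL),
            class = "fold_plan")
}

#' Resolve a fold plan against a feature table
#'
#' @param table A feature table from [build_feature_table()].
#' @param plan A [fold_plan()].
#' @return The plan with `folds` filled in: a named list of test-row index
#'   vectors (fold ids for kfold, held-out subject ids for loso).
#' @export
make_folds <- function(table, plan) {
  stopifnot(inherits(plan, "fold_plan"))
  n <- nrow(table)
  if (plan$scheme == "loso") {
    subjects <- sort(unique(table$subject_id))
    if (length(subjects) < 2L)
      bf_stop("LOSO needs at least 2 subjects", "bf_plan_error")
    plan$folds <- lapply(subjects, function(s)
      which(table$subject_id == s))
    names(plan$folds) <- subjects
  } else {
    plan$folds <- stratified_kfold(table$label, plan$k, plan$seed)
  }
  plan
}

# seeded, stratified k-fold assignment; per-label round-robin with a
# rotating offset keeps both the overall and the per-label fold sizes
# within one of each other
stratified_kfold <- function(labels, k, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  fold_of <- integer(length(labels))
  offset <- 0L
  for (lab in sort(unique(as.character(labels)))) {
    rows <- sample(which(labels == lab))
    fold_of[rows] <- ((seq_along(rows) - 1L + offset) %% k) + 1L
    offset <- (offset + length(rows)) %% k
  }
  folds <- lapply(seq_len(k), function(f) which(fold_of == f))
  names(folds) <- sprintf("fold%d", seq_len(k))
  folds
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %s%s, seed %d%s\n", x$scheme,
              if (x$scheme == "kfold") sprintf(" (k = %d)", x$k) else "",
              x$seed,
              if (is.null(x$folds)) " (unresolved)" else
                sprintf(", %d folds", length(x$folds))))
  invisible(x)
}
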