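#' Assemble and validate a pipeline run configuration
#'
#' A run takes exactly one input source — either `synth` (arguments for
#' [synth_config()]; the session seed is injected from the global `seed`)
#' or `files` (a list with `recording_paths`, optional `subject_ids` /
#' `session_ids`, and a `labels` CSV path) — and carries the parameter
#' blocks of every stage plus one global seed that is expanded into
#' per-stage substreams (simulation, fold shuffling, SMOTE, model
#' training).
#'
#' @param synth Named list of [synth_config()] arguments, or `NULL`.
#' @param files Named list describing input files, or `NULL`.
#' @param mode Segmentation strategy, `"cycles"` or `"windows"`.
#' @param preprocess,segmentation,window Named lists of arguments for
#'   [preprocess_params()], [segmentation_params()], [window_params()].
#' @param model Named list: `family`, optional `params` and `grid`.
#' @param plan Named list: `scheme`, optional `k`.
#' @param smote,k_neighbors,purity Evaluation and labeling settings.
#' @param seed Global integer seed.
#' @param out_dir Artifact directory, or `NULL` to skip writing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synth = list(), files = NULL, mode = "cycles",
                       preprocess = list(), segmentation = list(),
                       window = list(), model = list(), plan = list(),
                       smote = TRUE, k_neighbors = 5, purity = 0.8,
                       seed = 1, out_dir = NULL) {
  if (length(files) == 0) files <- NULL  # {} from a manifest means absent
  if (!is.null(files) && missing(synth)) synth <- NULL
  has_synth <- !is.null(synth)
  has_files <- !is.null(files)
  if (has_synth == has_files)
    bf_stop("exactly one input source required: synth or files",
            "bf_config_error")
  if (has_files && (is.null(files$recording_paths) ||
                    is.null(files$labels)))
    bf_stop("files input needs recording_paths and labels",
            "bf_config_error")
  if (!mode %in% c("cycles", "windows"))
    bf_stop("mode must be 'cycles' or 'windows'", "bf_config_error")
  # resolve every block now so a bad parameter fails at configuration time
  cfg <- list(
    synth = if (has_synth) synth, files = files, mode = mode,
    preprocess = do.call(preprocess_params, preprocess),
    segmentation = do.call(segmentation_params, segmentation),
    window = do.call(window_params, window),
    model = list(family = model$family %||% "gradient_boosted_trees",
                 params = model$params %||% list(),
                 grid = if (length(model$grid)) as.data.frame(model$grid)),
    plan = list(scheme = plan$scheme %||% "loso", k = plan$k %||% 5),
    smote = isTRUE(smote), k_neighbors = k_neighbors, purity = purity,
    seed = as.integer(seed), out_dir = out_dir)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

load_input <- function(cfg) {
  if (!is.null(cfg$synth)) {
    args <- cfg$synth
    args$seed <- cfg$seed
    cohort <- simulate_cohort(do.call(synth_config, args))
    stage_log("simulate", "%d synthetic recording(s), %d ground-truth cycles",
              length(cohort$recordings), nrow(cohort$cycles))
    return(cohort)
  }
  paths <- cfg$files$recording_paths
  ids <- cfg$files$subject_ids %||%
    sub("^rec_([^_]+)_.*$", "\\1", basename(paths))
  sess <- cfg$files$session_ids %||% rep("R1", length(paths))
  recs <- Map(function(p, s, r) read_recording(p, subject_id = s,
                                               session_id = r),
              paths, ids, sess)
  labels <- read_labels(cfg$files$labels)
  stage_log("read", "%d recording(s) read, %d label segment(s)",
            length(recs), nrow(labels))
  list(recordings = unname(recs), labels = labels, cycles = NULL)
}

#' Run the fit-detection pipeline end to end
#'
#' simulate/read -> preprocess -> segment -> featurize -> evaluate, with
#' per-stage log lines, deterministic substreams derived from the single
#' global seed, and (when `out_dir` is set) artifact files: per-session
#' recording and ground-truth CSVs, the labels CSV, the feature table, the
#' evaluation report (JSON) and a run manifest capturing every resolved
#' parameter and the software versions.
#'
#' @param cfg A [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @return The [evaluate()] report, invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  cohort <- load_input(cfg)
  table <- cohort_feature_table(cohort, mode = cfg$mode,
                                pp = cfg$preprocess,
                                sp = cfg$segmentation, wp = cfg$window,
                                purity = cfg$purity)
  stage_log("featurize", "%d labeled %s rows x %d features", nrow(table),
            sub("s$", "", cfg$mode), length(feature_columns(table)))
  spec <- model_spec(cfg$model$family, cfg$model$params, cfg$model$grid,
                     seed = cfg$seed + 1000L)
  plan <- fold_plan(cfg$plan$scheme, cfg$plan$k, seed = cfg$seed + 2000L)
  report <- evaluate(table, spec, plan, smote = cfg$smote,
                     k_neighbors = cfg$k_neighbors)
  stage_log("evaluate", "%s/%s: mean F1 %.4f over %d folds",
            spec$family, plan$scheme, report$summary$f1_mean,
            nrow(report$folds))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- cfg$out_dir
    for (rec in cohort$recordings)
      write_recording(rec, file.path(od, sprintf("rec_%s_%s.csv",
                                                 rec$subject_id,
                                                 rec$session_id)))
    write_labels(cohort$labels, file.path(od, "labels.csv"))
    if (!is.null(cohort$cycles))
      utils::write.csv(cohort$cycles, file.path(od, "cycles_truth.csv"),
                       row.names = FALSE, quote = FALSE)
    write_feature_table(table, file.path(od, "features.csv"))
    write_report(report, file.path(od, "report.json"))
    manifest <- list(config = unclass(strip_resolved(cfg)),
                     versions = list(
                       breathfit = as.character(utils::packageVersion("breathfit")),
                       R = paste(R.version$major, R.version$minor,
                                 sep = ".")),
                     n_feature_rows = nrow(table))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_log("artifacts", "written to %s", od)
    return(invisible(report))
  }
  report
}

# manifest form of the config: parameter objects flattened back to plain
# lists so the manifest can be fed to run_config() again
strip_resolved <- function(cfg) {
  cfg$preprocess <- unclass(cfg$preprocess)
  cfg$segmentation <- unclass(cfg$segmentation)
  cfg$window <- unclass(cfg$window)
  if (!is.null(cfg$synth) && length(cfg$synth) &&
      !is.null(cfg$synth$session_plan))
    cfg$synth$session_plan <- as.list(cfg$synth$session_plan)
  cfg
}

#' Compare segmentation strategies across models and validation schemes
#'
#' The full grid of 3 model families x 2 segmentation strategies
#' (breathing cycles vs sliding windows) x 2 validation schemes (k-fold,
#' LOSO), each cell reporting the mean and SD of per-fold F1. With several
#' seeds the cohort is regenerated per seed and fold-level F1 values are
#' pooled. Cells where the cycle-based variant underperforms its
#' sliding-window counterpart are flagged in the output.
#'
#' @param cfg A [run_config()] with a `synth` input.
#' @param seeds Integer vector of cohort seeds (default the config seed).
#' @return An object of class `strategy_comparison`: data frame with
#'   columns `family`, `scheme`, `segmentation`, `f1_mean`, `f1_sd`,
#'   `n_folds` plus a `cycle_below_window` flag column on cycle rows.
#' @export
compare_strategies <- function(cfg, seeds = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$synth))
    bf_stop("compare_strategies requires a synthetic input config",
            "bf_config_error")
  seeds <- as.integer(seeds %||% cfg$seed)
  families <- c("random_forest", "svm_rbf", "gradient_boosted_trees")
  acc <- list()
  for (sd in seeds) {
    scfg <- cfg
    scfg$seed <- sd
    cohort <- load_input(scfg)
    tabs <- list(
      cycles = cohort_feature_table(cohort, "cycles", cfg$preprocess,
                                    cfg$segmentation, cfg$window,
                                    cfg$purity),
      windows = cohort_feature_table(cohort, "windows", cfg$preprocess,
                                     cfg$segmentation, cfg$window,
                                     cfg$purity))
    for (fam in families) for (scheme in c("kfold", "loso"))
      for (seg in names(tabs)) {
        rep <- evaluate(tabs[[seg]],
                        model_spec(fam, cfg$model$params, seed = sd + 1000L),
                        fold_plan(scheme, cfg$plan$k, seed = sd + 2000L),
                        smote = cfg$smote, k_neighbors = cfg$k_neighbors)
        key <- paste(fam, scheme, seg, sep = ".")
        acc[[key]] <- c(acc[[key]], rep$folds$f1)
        stage_log("compare", "seed %d %s %s %s: F1 %.4f", sd, fam, scheme,
                  seg, mean(rep$folds$f1))
      }
  }
  grid <- expand.grid(segmentation = c("cycles", "windows"),
                      scheme = c("kfold", "loso"), family = families,
                      stringsAsFactors = FALSE)[, 3:1]
  grid$f1_mean <- NA_real_; grid$f1_sd <- NA_real_
  grid$n_folds <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    v <- acc[[paste(grid$family[i], grid$scheme[i], grid$segmentation[i],
                    sep = ".")]]
    grid$f1_mean[i] <- mean(v); grid$f1_sd[i] <- stats::sd(v)
    grid$n_folds[i] <- length(v)
  }
  grid$cycle_below_window <- NA
  for (i in which(grid$segmentation == "cycles")) {
    j <- which(grid$family == grid$family[i] &
                 grid$scheme == grid$scheme[i] &
                 grid$segmentation == "windows")
    grid$cycle_below_window[i] <- grid$f1_mean[i] < grid$f1_mean[j]
  }
  structure(grid, class = c("strategy_comparison", "data.frame"),
            seeds = seeds)
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf("Segmentation-strategy comparison (seeds: %s)\n",
              paste(attr(x, "seeds"), collapse = ", ")))
  cat("F1 for poor_fit, mean +/- SD over folds\n\n")
  wide <- unique(x[, c("family", "scheme")])
  for (i in seq_len(nrow(wide))) {
    rows <- x[x$family == wide$family[i] & x$scheme == wide$scheme[i], ]
    cyc <- rows[rows$segmentation == "cycles", ]
    win <- rows[rows$segmentation == "windows", ]
    cat(sprintf("  %-24s %-6s windows %6.2f +/- %5.2f | cycles %6.2f +/- %5.2f%s\n",
                wide$family[i], wide$scheme[i], 100 * win$f1_mean,
                100 * win$f1_sd, 100 * cyc$f1_mean, 100 * cyc$f1_sd,
                if (isTRUE(cyc$cycle_below_window)) "  [cycle < window]"
                else ""))
  }
  invisible(x)
}
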