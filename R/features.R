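#' Canonical feature schemas
#'
#' `cycle_feature_names()` is the fixed, ordered 22-name per-cycle schema:
#' the inspiratory time proportion, then per channel (pressure, humidity,
#' temperature) the peak-to-peak amplitude, inspiratory-phase mean,
#' expiratory-phase mean, standard deviation, skewness, excess kurtosis and
#' median. The expiratory time proportion is not stored: it is `1 -
#' insp_time_prop` and would be collinear. `window_feature_names()` is the
#' 18-name sliding-window variant: the same six statistics per channel,
#' computed over the whole window, with no phase-based features because an
#' arbitrary window has no reliable phase boundary.
#'
#' @return Character vector of feature names in canonical order.
#' @export
cycle_feature_names <- function() {
  ch <- c("pressure", "humidity", "temperature")
  c("insp_time_prop",
    paste0("ptp_", ch),
    paste0("mean_insp_", ch), paste0("mean_exp_", ch),
    paste0("sd_", ch), paste0("skew_", ch), paste0("kurt_", ch),
    paste0("median_", ch))
}

#' @rdname cycle_feature_names
#' @export
window_feature_names <- function() {
  ch <- c("pressure", "humidity", "temperature")
  c(paste0("ptp_", ch), paste0("mean_", ch), paste0("sd_", ch),
    paste0("skew_", ch), paste0("kurt_", ch), paste0("median_", ch))
}

# population-convention moments; skewness is the Fisher-Pearson
# standardized third moment, kurtosis is excess (normal -> 0)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

channel_stats <- function(x, what) {
  if (pop_sd(x) == 0)
    bf_stop("constant-valued slice: SD, skewness and kurtosis undefined",
            "bf_degenerate_error")
  switch(what,
         ptp = max(x) - min(x),
         sd = pop_sd(x),
         skew = e1071::skewness(x, type = 1),
         kurt = e1071::kurtosis(x, type = 1),
         median = stats::median(x))
}

#' Extract the 22 per-cycle features
#'
#' The inspiratory sub-slice runs from the start peak to the valley and the
#' expiratory sub-slice from the valley to the end peak (both inclusive).
#' Peak-to-peak is max minus min over the full cycle per channel; SD uses
#' the population convention; skewness and kurtosis are the bias-uncorrected
#' population forms (kurtosis as excess).
#'
#' @param cycle One row of a [build_cycles()] table (or any list with
#'   `p_initial`, `v`, `p_final`).
#' @param slices List with numeric `pressure`, `humidity`, `temperature`
#'   slices aligned to `[p_initial, p_final]`.
#' @return Named numeric vector of length 22 in canonical order.
#' @export
extract_cycle_features <- function(cycle, slices) {
  len <- cycle$p_final - cycle$p_initial + 1L
  if (len < 3L || any(lengths(slices[c("pressure", "humidity",
                                       "temperature")]) != len))
    bf_stop("cycle slices must be aligned to [p_initial, p_final] with >= 3 samples",
            "bf_degenerate_error")
  v_rel <- cycle$v - cycle$p_initial + 1L
  ch <- c("pressure", "humidity", "temperature")
  out <- c(insp_time_prop = (cycle$v - cycle$p_initial) /
             (cycle$p_final - cycle$p_initial))
  out <- c(out,
           vapply(ch, function(cc) channel_stats(slices[[cc]], "ptp"),
                  numeric(1)),
           vapply(ch, function(cc) mean(slices[[cc]][1:v_rel]), numeric(1)),
           vapply(ch, function(cc) mean(slices[[cc]][v_rel:len]),
                  numeric(1)),
           vapply(ch, function(cc) channel_stats(slices[[cc]], "sd"),
                  numeric(1)),
           vapply(ch, function(cc) channel_stats(slices[[cc]], "skew"),
                  numeric(1)),
           vapply(ch, function(cc) channel_stats(slices[[cc]], "kurt"),
                  numeric(1)),
           vapply(ch, function(cc) channel_stats(slices[[cc]], "median"),
                  numeric(1)))
  names(out) <- cycle_feature_names()
  out
}

#' Extract the 18 sliding-window features
#'
#' @param slices List with numeric `pressure`, `humidity`, `temperature`
#'   window slices.
#' @param expected_len Required window length in samples (default 50, i.e.
#'   5 s at 10 Hz).
#' @return Named numeric vector of length 18 in canonical order.
#' @export
extract_window_features <- function(slices, expected_len = 50) {
  ch <- c("pressure", "humidity", "temperature")
  if (any(lengths(slices[ch]) != expected_len))
    bf_stop(sprintf("window slices must have exactly %d samples",
                    expected_len), "bf_length_error")
  out <- c(vapply(ch, function(cc) channel_stats(slices[[cc]], "ptp"),
                  numeric(1)),
           vapply(ch, function(cc) mean(slices[[cc]]), numeric(1)),
           vapply(ch, function(cc) channel_stats(slices[[cc]], "sd"),
                  numeric(1)),
           vapply(ch, function(cc) channel_stats(slices[[cc]], "skew"),
                  numeric(1)),
           vapply(ch, function(cc) channel_stats(slices[[cc]], "kurt"),
                  numeric(1)),
           vapply(ch, function(cc) channel_stats(slices[[cc]], "median"),
                  numeric(1)))
  names(out) <- window_feature_names()
  out
}

#' Build a feature table from labeled segments
#'
#' One row per retained labeled segment with subject/session provenance;
#' segments labeled `"other"` never reach the table (they are discarded at
#' labeling time). The feature columns follow the canonical 22-name cycle
#' schema or the 18-name window schema depending on the segment type.
#'
#' @param segs A labeled [segment_cycles()] or [sliding_windows()] result.
#' @return Data frame with columns `subject_id`, `session_id`,
#'   `provenance`, `label` and the canonical feature columns.
#' @export
build_feature_table <- function(segs) {
  if (inherits(segs, "cycle_segments")) {
    if (is.null(segs$cycles$label))
      bf_stop("cycles are unlabeled; run label_cycles() first",
              "bf_schema_error")
    meta <- segs$cycles
    prov <- sprintf("cycle[%d-%d]", meta$p_initial, meta$p_final)
    feats <- lapply(seq_len(nrow(meta)), function(i)
      extract_cycle_features(meta[i, ], segs$slices[[i]]))
  } else if (inherits(segs, "window_segments")) {
    meta <- segs$windows
    prov <- sprintf("window[%d-%d]", meta$start, meta$end)
    feats <- lapply(seq_len(nrow(meta)), function(i)
      extract_window_features(segs$slices[[i]], segs$window_len))
  } else {
    bf_stop("segs must be cycle_segments or window_segments",
            "bf_schema_error")
  }
  keep <- meta$label != "other"
  if (!any(keep))
    bf_stop("no labeled segments left after filtering", "bf_empty_error")
  tab <- data.frame(subject_id = segs$subject_id,
                    session_id = segs$session_id,
                    provenance = prov[keep], label = meta$label[keep],
                    do.call(rbind, feats[keep]))
  rownames(tab) <- NULL
  tab
}

#' Feature columns of a feature table
#' @param table A feature table from [build_feature_table()].
#' @return Character vector of its feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "session_id", "provenance",
                          "label"))
}

#' Write / read a feature table CSV
#'
#' Columns `subject_id,session_id,provenance,label` followed by the
#' canonical feature columns.
#'
#' @param table A feature table.
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the table.
#' @export
write_feature_table <- function(table, path) {
  num <- feature_columns(table)
  out <- table
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject_id = "character",
                                       session_id = "character"))
  nf <- length(feature_columns(df))
  if (!nf %in% c(18L, 22L))
    bf_stop(sprintf("expected 22 cycle or 18 window feature columns, found %d",
                    nf), "bf_schema_error")
  if (any(df$label == "other"))
    bf_stop("feature tables must not contain rows labeled 'other'",
            "bf_vocab_error")
  df
}

#' Featurize a synthetic cohort end to end
#'
#' Preprocesses every recording, expands the label segments to per-sample
#' tracks, segments (breathing cycles or sliding windows), labels the
#' segments and stacks one feature table for the whole cohort.
#'
#' @param cohort A [simulate_cohort()] result (or any list with
#'   `recordings` and `labels`).
#' @param mode `"cycles"` or `"windows"`.
#' @param pp,sp,wp Preprocessing, segmentation and window parameters.
#' @param purity Label purity threshold for cycle labeling.
#' @return A feature table covering all subjects.
#' @export
cohort_feature_table <- function(cohort, mode = c("cycles", "windows"),
                                 pp = preprocess_params(),
                                 sp = segmentation_params(),
                                 wp = window_params(), purity = 0.8) {
  mode <- match.arg(mode)
  tabs <- lapply(cohort$recordings, function(rec) {
    prec <- preprocess_recording(rec, pp)
    track <- sample_labels(prec, cohort$labels)
    segs <- if (mode == "cycles")
      label_cycles(segment_cycles(prec, sp), track, purity)
    else sliding_windows(prec, track, wp)
    build_feature_table(segs)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
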