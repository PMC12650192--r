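#' Label vocabulary for fit-test protocol segments
#'
#' The closed set of segment labels: `fit` (well-sealed), `poor_fit`
#' (leak, loose or displaced respirator) and `other` (transitions,
#' calibration and any unlabeled time).
#'
#' @return Character vector of the three labels.
#' @export
label_vocabulary <- function() c("fit", "poor_fit", "other")

validate_segments <- function(segments) {
  need <- c("subject_id", "session_id", "start_s", "end_s", "label",
            "condition")
  missing <- setdiff(need, names(segments))
  if (length(missing))
    bf_stop(paste("label table missing column(s):",
                  paste(missing, collapse = ", ")), "bf_schema_error")
  bad <- setdiff(unique(segments$label), label_vocabulary())
  if (length(bad))
    bf_stop(paste("unknown label token(s):", paste(bad, collapse = ", ")),
            "bf_vocab_error")
  if (any(segments$start_s < 0) || any(segments$end_s <= segments$start_s))
    bf_stop("segments require 0 <= start_s < end_s", "bf_interval_error")
  for (key in split(segments, paste(segments$subject_id,
                                    segments$session_id))) {
    key <- key[order(key$start_s), ]
    if (nrow(key) > 1L &&
        any(key$start_s[-1L] < key$end_s[-nrow(key)] - 1e-12))
      bf_stop("overlapping label segments within one session",
              "bf_overlap_error")
  }
  segments[order(segments$subject_id, segments$session_id,
                 segments$start_s), , drop = FALSE]
}

#' Read protocol label segments
#'
#' Reads a CSV with columns
#' `subject_id,session_id,start_s,end_s,label,condition`. Segments are
#' validated (closed label vocabulary, `start_s < end_s`, no overlap within
#' a session) and returned sorted by start time. Intervals are half-open
#' `[start_s, end_s)` seconds from session start.
#'
#' @param path File path.
#' @return A data frame of label segments, one row per interval.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject_id = "character",
                                       session_id = "character"))
  rownames(df) <- NULL
  validate_segments(df)
}

#' Write protocol label segments
#' @param segments Data frame as returned by [read_labels()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(segments, path) {
  segments <- validate_segments(segments)
  segments$start_s <- sprintf("%.17g", segments$start_s)
  segments$end_s <- sprintf("%.17g", segments$end_s)
  utils::write.csv(segments, path, row.names = FALSE, quote = FALSE,
                   eol = "\n")
  invisible(path)
}

#' Expand label segments to a per-sample label track
#'
#' Sample `i` (1-based) covers time `t0 + (i - 1) / fs` and takes the label
#' of the enclosing half-open interval `[start_s, end_s)`, or `"other"`
#' where no segment covers it.
#'
#' @param rec A [breath_recording()].
#' @param segments Label segments for this subject/session (other rows are
#'   ignored).
#' @return Character vector of labels, one per sample.
#' @export
sample_labels <- function(rec, segments) {
  stopifnot(inherits(rec, "breath_recording"))
  track <- rep("other", n_samples(rec))
  if (is.null(segments) || nrow(segments) == 0L) return(track)
  segments <- validate_segments(segments)
  segments <- segments[segments$subject_id == rec$subject_id &
                         segments$session_id == rec$session_id, ,
                       drop = FALSE]
  t <- rec_times(rec) - rec$t0
  for (i in seq_len(nrow(segments))) {
    sel <- t >= segments$start_s[i] & t < segments$end_s[i]
    track[sel] <- segments$label[i]
  }
  track
}
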