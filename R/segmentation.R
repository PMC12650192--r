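#' Segmentation parameters
#'
#' Breathing cycles are delimited on the anchor channel (temperature by
#' default: its smooth periodic waveform gives the cleanest extrema). The
#' minimum peak distance `mpd` suppresses spurious extrema closer than
#' `mpd` samples; the default 23 samples at 10 Hz corresponds to 2.3 s,
#' i.e. a ceiling of 26 breaths per minute.
#'
#' @param mpd Minimum peak distance in samples (default 23).
#' @param anchor_channel Channel used for extremum detection (default
#'   `"temperature"`).
#' @param swap_phases If `TRUE`, treat the peak-to-valley limb as the
#'   expiratory phase instead of the inspiratory one (the canonical
#'   convention is peak -> valley = inspiration).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(mpd = 23, anchor_channel = "temperature",
                                swap_phases = FALSE) {
  if (mpd < 1) bf_stop("mpd must be >= 1", "bf_config_error")
  if (!anchor_channel %in% c("pressure", "temperature", "humidity"))
    bf_stop("anchor_channel must be pressure, temperature or humidity",
            "bf_config_error")
  structure(list(mpd = as.integer(mpd), anchor_channel = anchor_channel,
                 swap_phases = isTRUE(swap_phases)),
            class = "segmentation_params")
}

# strict local extrema with plateaus resolved to their first index
local_extrema <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(list(max = integer(0), min = integer(0)))
  starts <- cumsum(r$lengths) - r$lengths + 1L
  mid <- 2:(k - 1L)
  v <- r$values
  is_max <- v[mid] > v[mid - 1L] & v[mid] > v[mid + 1L]
  is_min <- v[mid] < v[mid - 1L] & v[mid] < v[mid + 1L]
  list(max = starts[mid][is_max], min = starts[mid][is_min])
}

# greedy suppression: visit candidates from most to least extreme (ties ->
# earlier index) and keep those >= mpd samples from every kept extremum
greedy_mpd <- function(idx, height, mpd) {
  if (length(idx) == 0L) return(integer(0))
  ord <- order(-height, idx)
  kept <- integer(0)
  for (i in idx[ord]) {
    if (length(kept) == 0L || all(abs(kept - i) >= mpd))
      kept <- c(kept, i)
  }
  sort(kept)
}

#' Detect peaks and valleys
#'
#' Locates strict local maxima and minima (plateaus count once, at their
#' first index), then enforces the minimum peak distance: when candidates
#' conflict within `mpd` samples the larger-amplitude extremum wins, ties
#' broken by earlier index. Valleys are treated symmetrically on the
#' inverted signal with the same `mpd`.
#'
#' @param x Numeric series.
#' @param mpd Minimum peak distance in samples.
#' @return List with sorted integer vectors `peaks` and `valleys`.
#' @export
detect_extrema <- function(x, mpd = 23) {
  if (mpd < 1) bf_stop("mpd must be >= 1", "bf_config_error")
  ex <- local_extrema(as.numeric(x))
  list(peaks = greedy_mpd(ex$max, x[ex$max], mpd),
       valleys = greedy_mpd(ex$min, -x[ex$min], mpd))
}

#' Build validated breathing cycles from extrema
#'
#' Enforces the peak-valley-peak structure: valleys outside the span of the
#' detected peaks are dropped, and a cycle is emitted for a consecutive
#' peak pair only when exactly one retained valley lies strictly between
#' them (intervals with zero or multiple valleys are discarded as
#' artifacts). For each cycle the duration is `(p_final - p_initial) / fs`
#' and the inspiratory/expiratory time ratios split the cycle at the
#' valley; the two ratios sum to one by construction.
#'
#' @param peaks,valleys Sorted index vectors from [detect_extrema()].
#' @param fs Sampling rate, Hz.
#' @param swap_phases See [segmentation_params()].
#' @return Data frame with columns `p_initial`, `v`, `p_final`,
#'   `t_cycle_s`, `delta_insp`, `delta_exp`; zero rows when no valid cycle
#'   exists.
#' @export
build_cycles <- function(peaks, valleys, fs, swap_phases = FALSE) {
  empty <- data.frame(p_initial = integer(0), v = integer(0),
                      p_final = integer(0), t_cycle_s = numeric(0),
                      delta_insp = numeric(0), delta_exp = numeric(0))
  if (length(peaks) < 2L) return(empty)
  valleys <- valleys[valleys > peaks[1] & valleys < peaks[length(peaks)]]
  rows <- lapply(seq_len(length(peaks) - 1L), function(i) {
    vv <- valleys[valleys > peaks[i] & valleys < peaks[i + 1L]]
    if (length(vv) != 1L) return(NULL)
    c(peaks[i], vv, peaks[i + 1L])
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(empty)
  span <- rows[, 3] - rows[, 1]
  dins <- (rows[, 2] - rows[, 1]) / span
  if (swap_phases) dins <- 1 - dins
  data.frame(p_initial = rows[, 1], v = rows[, 2], p_final = rows[, 3],
             t_cycle_s = span / fs, delta_insp = dins,
             delta_exp = 1 - dins)
}

#' Segment a recording into breathing cycles
#'
#' Extrema are found on the anchor channel only; each validated cycle's
#' inclusive index range `[p_initial, p_final]` is then used to slice all
#' three channels, so the segments stay aligned across modalities.
#' Adjacent cycles share their boundary peak.
#'
#' @param rec A (preprocessed) [breath_recording()].
#' @param p A [segmentation_params()].
#' @param per_segment_zscore If `TRUE`, z-score every slice of every
#'   channel individually. Off by default: per-segment standardization
#'   forces the per-channel SD feature to 1 and flattens the phase means,
#'   so the session-level z-score of [preprocess_recording()] is canonical.
#' @return An object of class `cycle_segments`: list with the cycle table
#'   (`cycles`), a list of per-cycle tri-channel `slices`, `fs` and
#'   identity fields.
#' @export
segment_cycles <- function(rec, p = segmentation_params(),
                           per_segment_zscore = FALSE) {
  stopifnot(inherits(rec, "breath_recording"))
  ex <- detect_extrema(rec[[p$anchor_channel]], p$mpd)
  cycles <- build_cycles(ex$peaks, ex$valleys, rec$fs, p$swap_phases)
  slices <- lapply(seq_len(nrow(cycles)), function(i) {
    idx <- cycles$p_initial[i]:cycles$p_final[i]
    sl <- list(pressure = rec$pressure[idx],
               humidity = rec$humidity[idx],
               temperature = rec$temperature[idx])
    if (per_segment_zscore) sl <- lapply(sl, zscore)
    sl
  })
  structure(list(cycles = cycles, slices = slices, fs = rec$fs,
                 subject_id = rec$subject_id, session_id = rec$session_id),
            class = "cycle_segments")
}

#' @export
print.cycle_segments <- function(x, ...) {
  cat(sprintf("<cycle_segments> %s/%s: %d cycle(s)%s\n", x$subject_id,
              x$session_id, nrow(x$cycles),
              if (!is.null(x$cycles$label)) ", labeled" else ""))
  invisible(x)
}

#' Label breathing cycles from a per-sample label track
#'
#' A cycle takes the majority label over its inclusive sample range when
#' the majority fraction reaches `purity`; cycles below the purity
#' threshold (e.g. straddling a protocol transition) and cycles whose
#' majority label is `"other"` are discarded.
#'
#' @param segs A [segment_cycles()] result.
#' @param track Per-sample label track from [sample_labels()].
#' @param purity Minimum majority fraction (default 0.8).
#' @return The `cycle_segments` object restricted to labeled cycles, with a
#'   `label` column added to the cycle table.
#' @export
label_cycles <- function(segs, track, purity = 0.8) {
  stopifnot(inherits(segs, "cycle_segments"))
  lab <- majority_labels(segs$cycles$p_initial, segs$cycles$p_final,
                         track, purity)
  keep <- !is.na(lab)
  segs$cycles <- segs$cycles[keep, , drop = FALSE]
  segs$cycles$label <- lab[keep]
  segs$slices <- segs$slices[keep]
  rownames(segs$cycles) <- NULL
  segs
}

# majority label of [from, to] inclusive, NA when impure or "other"
majority_labels <- function(from, to, track, purity) {
  vapply(seq_along(from), function(i) {
    tab <- table(track[from[i]:to[i]])
    win <- names(tab)[which.max(tab)]
    if (tab[win] / sum(tab) < purity || win == "other") NA_character_
    else win
  }, character(1))
}

#' Sliding-window parameters
#'
#' Fixed-length alternative to cycle segmentation: windows of `window_s`
#' seconds advanced by `window_s - overlap_s` seconds (default 5 s windows,
#' 2 s overlap, i.e. 50 samples per window at 10 Hz and a 3 s step).
#'
#' @param window_s Window duration, seconds.
#' @param overlap_s Overlap between consecutive windows, seconds; must be
#'   shorter than the window.
#' @param label_purity Minimum majority-label fraction for a window to keep
#'   its label (default 0.8).
#' @return An object of class `window_params`.
#' @export
window_params <- function(window_s = 5, overlap_s = 2, label_purity = 0.8) {
  if (overlap_s < 0 || overlap_s >= window_s)
    bf_stop("need 0 <= overlap_s < window_s", "bf_config_error")
  if (label_purity <= 0.5 || label_purity > 1)
    bf_stop("label_purity must lie in (0.5, 1]", "bf_config_error")
  structure(list(window_s = window_s, overlap_s = overlap_s,
                 label_purity = label_purity), class = "window_params")
}

#' Cut a recording into labeled sliding windows
#'
#' Windows start every `window_s - overlap_s` seconds; the window count is
#' `floor((N - W) / S) + 1` for `N` samples, window length `W` and step
#' `S`. Each window is labeled by its majority label when the majority
#' fraction reaches `label_purity`; impure windows and windows labeled
#' `"other"` are discarded.
#'
#' @param rec A (preprocessed) [breath_recording()].
#' @param track Per-sample label track from [sample_labels()].
#' @param p A [window_params()].
#' @return An object of class `window_segments`: list with the window table
#'   (`windows`: `start`, `end`, `label`), per-window tri-channel
#'   `slices`, `fs` and identity fields.
#' @export
sliding_windows <- function(rec, track, p = window_params()) {
  stopifnot(inherits(rec, "breath_recording"))
  n <- n_samples(rec)
  w <- round(p$window_s * rec$fs)
  s <- round((p$window_s - p$overlap_s) * rec$fs)
  if (w > n)
    bf_stop("window longer than the recording", "bf_length_error")
  starts <- seq(1L, n - w + 1L, by = s)
  ends <- starts + w - 1L
  lab <- majority_labels(starts, ends, track, p$label_purity)
  keep <- !is.na(lab)
  windows <- data.frame(start = starts[keep], end = ends[keep],
                        label = lab[keep])
  slices <- lapply(which(keep), function(i) {
    idx <- starts[i]:ends[i]
    list(pressure = rec$pressure[idx], humidity = rec$humidity[idx],
         temperature = rec$temperature[idx])
  })
  structure(list(windows = windows, slices = slices, fs = rec$fs,
                 window_len = w, subject_id = rec$subject_id,
                 session_id = rec$session_id),
            class = "window_segments")
}

#' @export
print.window_segments <- function(x, ...) {
  cat(sprintf("<window_segments> %s/%s: %d labeled window(s) of %d samples\n",
              x$subject_id, x$session_id, nrow(x$windows), x$window_len))
  invisible(x)
}
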