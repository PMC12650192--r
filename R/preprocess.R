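#' Preprocessing parameters
#'
#' The respiratory band is isolated with a fourth-order Butterworth
#' bandpass: very-low-frequency drift below `low_cut_hz` and noise above
#' `high_cut_hz` are suppressed. "Fourth order" is read as total bandpass
#' order 4, realized as a cascade of an order-2 high-pass and an order-2
#' low-pass biquad section (numerically stable second-order form). Each
#' channel is then z-scored (population SD) to zero mean and unit variance.
#'
#' @param low_cut_hz Lower corner frequency, Hz (default 0.1).
#' @param high_cut_hz Upper corner frequency, Hz (default 0.42).
#' @param order Total bandpass order; must be even (default 4).
#' @param zero_phase Apply the filter forward-backward (zero phase lag,
#'   preserves cycle timing; default `TRUE`). `FALSE` gives the causal
#'   single-pass variant for streaming parity.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(low_cut_hz = 0.1, high_cut_hz = 0.42,
                              order = 4, zero_phase = TRUE) {
  if (low_cut_hz <= 0 || high_cut_hz <= low_cut_hz)
    bf_stop("need 0 < low_cut_hz < high_cut_hz", "bf_config_error")
  if (order < 2 || order %% 2 != 0)
    bf_stop("order must be a positive even integer", "bf_config_error")
  structure(list(low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
                 order = order, zero_phase = isTRUE(zero_phase)),
            class = "preprocess_params")
}

#' Bandpass filter design
#'
#' Returns the cascaded second-order-section design used by
#' [bandpass_filter()]: an order `order/2` Butterworth high-pass at
#' `low_cut_hz` followed by an order `order/2` Butterworth low-pass at
#' `high_cut_hz`. Exposed so the transfer function can be evaluated
#' analytically (e.g. to predict steady-state gain at a given frequency).
#'
#' @param fs Sampling rate, Hz.
#' @param p A [preprocess_params()].
#' @return List of stages, each with polynomial coefficients `b` and `a`.
#' @export
bandpass_design <- function(fs, p = preprocess_params()) {
  if (p$high_cut_hz >= fs / 2)
    bf_stop("high_cut_hz must be below the Nyquist frequency fs/2",
            "bf_param_error")
  half <- p$order / 2
  hp <- signal::butter(half, p$low_cut_hz * 2 / fs, type = "high")
  lp <- signal::butter(half, p$high_cut_hz * 2 / fs, type = "low")
  list(hp = list(b = hp$b, a = hp$a), lp = list(b = lp$b, a = lp$a))
}

# one causal pass through the cascade, each stage started at steady state
# for a constant input equal to the first sample (no startup step)
sos_pass <- function(stages, x) {
  for (st in stages) {
    nb <- length(st$b) - 1L
    gain <- sum(st$b) / sum(st$a)
    x <- as.numeric(signal::filter(st$b, st$a, x,
                                   init.x = rep(x[1], nb),
                                   init.y = rep(x[1] * gain,
                                                length(st$a) - 1L)))
  }
  x
}

#' Butterworth bandpass filter
#'
#' Applies the cascaded-biquad bandpass of [bandpass_design()]. In
#' zero-phase mode the signal is padded by odd reflection over `3 * order`
#' samples, filtered forward and backward, and unpadded, so the output has
#' no phase lag and the squared magnitude response of the design.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param p A [preprocess_params()].
#' @return Filtered series of the same length.
#' @export
bandpass_filter <- function(x, fs, p = preprocess_params()) {
  n <- length(x)
  if (n <= 3 * p$order)
    bf_stop(sprintf("series too short to filter (need > %d samples)",
                    3 * p$order), "bf_length_error")
  stages <- bandpass_design(fs, p)
  if (!p$zero_phase) return(sos_pass(stages, x))
  npad <- min(3 * p$order, n - 1L)
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- sos_pass(stages, xp)
  y <- rev(sos_pass(stages, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' z-score normalization
#'
#' Centers to zero mean and scales to unit standard deviation using the
#' population convention (divisor `n`). A constant series has no scale and
#' is rejected explicitly rather than returning `NaN`.
#'
#' @param x Numeric series.
#' @return Standardized series.
#' @export
zscore <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s == 0)
    bf_stop("cannot z-score a zero-variance series", "bf_degenerate_error")
  (x - m) / s
}

#' Preprocess a recording
#'
#' Bandpasses then z-scores each channel; channel order and length are
#' preserved and the recording is flagged as preprocessed.
#'
#' @param rec A [breath_recording()].
#' @param p A [preprocess_params()].
#' @return A preprocessed [breath_recording()].
#' @export
preprocess_recording <- function(rec, p = preprocess_params()) {
  stopifnot(inherits(rec, "breath_recording"))
  one <- function(x) zscore(bandpass_filter(x, rec$fs, p))
  breath_recording(one(rec$pressure), one(rec$temperature),
                   one(rec$humidity), fs = rec$fs,
                   subject_id = rec$subject_id, session_id = rec$session_id,
                   t0 = rec$t0, preprocessed = TRUE)
}
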