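#' Default fit-test session plan
#'
#' One 50-minute session mirroring the block structure of a standard
#' qualitative fit-test protocol: about 21 min of well-fitted breathing
#' (proper fit 6 + 3 min, reading aloud 2 min, passed aerosol test 10 min),
#' about 16 min of compromised fit (5 mm tube leak, loose strap, mask held
#' off the face, failed aerosol test), and about 13 min of unlabeled
#' transition time between blocks. The `leak` column is the leak severity
#' lambda in `[0, 1]` that drives amplitude attenuation and channel
#' decorrelation in [simulate_subject()].
#'
#' @return Data frame with columns `duration_s`, `label`, `condition`,
#'   `leak`.
#' @export
default_session_plan <- function() {
  gap <- function() data.frame(duration_s = 90, label = "other",
                               condition = "transition", leak = 0)
  blk <- function(d, lab, cond, leak)
    data.frame(duration_s = d, label = lab, condition = cond, leak = leak)
  rows <- list(
    data.frame(duration_s = 60, label = "other", condition = "transition",
               leak = 0),
    blk(360, "fit", "proper_fit", 0), gap(),
    blk(180, "fit", "proper_fit", 0), gap(),
    blk(120, "fit", "reading_aloud", 0), gap(),
    blk(600, "fit", "osha_pass", 0), gap(),
    blk(120, "poor_fit", "tube_leak", 0.3), gap(),
    blk(120, "poor_fit", "loose", 0.5), gap(),
    blk(120, "poor_fit", "displaced", 0.7), gap(),
    blk(600, "poor_fit", "osha_fail", 0.4), gap())
  do.call(rbind, rows)
}

#' Configuration for the synthetic intra-mask signal generator
#'
#' The generator emulates the mechanistic structure of intra-mask signals:
#' cycle-synchronous pressure oscillations (sub-ambient inhalation,
#' supra-ambient exhalation, raised-cosine humps per phase), temperature and
#' humidity relaxing first-order toward exhaled-air values (warm, ~33
#' degrees C; near-saturated, ~98 %RH) during expiration and back toward
#' ambient during inspiration, breathing at 12-16 breaths/min with
#' cycle-length jitter, slow random-walk baseline drift and additive white
#' sensor noise. Leak severity `lambda` attenuates every oscillation
#' amplitude by `(1 - lambda)` and adds inter-channel phase jitter of
#' standard deviation `phase_noise_sd_s * lambda`.
#'
#' @param n_subjects Number of subjects in the cohort (default 20).
#' @param session_plan Ordered blocks of `(duration_s, label, condition,
#'   leak)`; default [default_session_plan()].
#' @param rate_range_bpm Subject breathing-rate range, breaths/min; must lie
#'   strictly inside (6, 26) so cycles stay detectable at the default
#'   minimum peak distance.
#' @param insp_fraction_mean,insp_fraction_sd Per-cycle inspiratory time
#'   fraction, drawn Normal and truncated to `[0.2, 0.6]`.
#' @param cycle_jitter_cv Coefficient of variation of cycle length.
#' @param pressure_amp_hpa Half peak-to-peak pressure oscillation, hPa.
#' @param pressure_baseline_hpa Ambient absolute pressure, hPa.
#' @param temp_baseline_c,temp_exhale_c Ambient and exhaled-air temperature
#'   targets, degrees C.
#' @param rh_baseline,rh_exhale Ambient and exhaled-air relative-humidity
#'   targets, %RH.
#' @param microclimate_tau_s First-order rise/decay time constant of the
#'   temperature and humidity response, seconds.
#' @param drift_sd Named numeric (pressure, temperature, humidity):
#'   random-walk step SD per sample per channel.
#' @param noise_sd Named numeric: additive white-noise SD per channel.
#' @param phase_noise_sd_s Leak-induced inter-channel timing jitter SD at
#'   `lambda = 1`, seconds.
#' @param subject_amp_range Range of the per-subject effort factor, a
#'   multiplier drawn uniformly once per subject and applied to the
#'   pressure oscillation amplitude and the microclimate increments;
#'   models inter-individual variation in breathing effort and dead-space
#'   coupling.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed; each subject uses a deterministic substream.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 20,
                         session_plan = default_session_plan(),
                         rate_range_bpm = c(12, 16),
                         insp_fraction_mean = 0.40,
                         insp_fraction_sd = 0.03,
                         cycle_jitter_cv = 0.05,
                         pressure_amp_hpa = 0.6,
                         pressure_baseline_hpa = 1013,
                         temp_baseline_c = 24, temp_exhale_c = 33,
                         rh_baseline = 55, rh_exhale = 98,
                         microclimate_tau_s = 0.4,
                         drift_sd = c(pressure = 0.005, temperature = 0.002,
                                      humidity = 0.02),
                         noise_sd = c(pressure = 0.02, temperature = 0.05,
                                      humidity = 0.5),
                         phase_noise_sd_s = 0.15,
                         subject_amp_range = c(0.6, 1.4),
                         fs = 10, seed = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 0 ||
      n_subjects != round(n_subjects))
    bf_stop("n_subjects must be a non-negative integer", "bf_config_error")
  need <- c("duration_s", "label", "condition", "leak")
  if (!all(need %in% names(session_plan)))
    bf_stop("session_plan needs columns duration_s, label, condition, leak",
            "bf_config_error")
  if (nrow(session_plan) == 0L || any(session_plan$duration_s <= 0))
    bf_stop("session_plan blocks must have positive duration",
            "bf_config_error")
  if (any(!session_plan$label %in% label_vocabulary()))
    bf_stop("session_plan labels must be fit, poor_fit or other",
            "bf_vocab_error")
  if (any(session_plan$leak < 0 | session_plan$leak > 1))
    bf_stop("leak severity must lie in [0, 1]", "bf_config_error")
  if (rate_range_bpm[1] <= 6 || rate_range_bpm[2] >= 26 ||
      rate_range_bpm[1] > rate_range_bpm[2])
    bf_stop("rate_range_bpm must lie strictly inside (6, 26)",
            "bf_config_error")
  sds <- c(insp_fraction_sd, cycle_jitter_cv, drift_sd, noise_sd,
           phase_noise_sd_s)
  if (any(sds < 0))
    bf_stop("all spread parameters must be >= 0", "bf_config_error")
  if (subject_amp_range[1] <= 0 ||
      subject_amp_range[2] < subject_amp_range[1])
    bf_stop("subject_amp_range must be a positive increasing range",
            "bf_config_error")
  if (microclimate_tau_s < 1 / fs)
    bf_stop("microclimate_tau_s must be at least one sample interval",
            "bf_config_error")
  cfg <- as.list(environment())
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("<synth_config> %d subject(s), %.0f s/session, ",
                     "%g-%g bpm, amp %g hPa, seed %d\n"),
              x$n_subjects, sum(x$session_plan$duration_s),
              x$rate_range_bpm[1], x$rate_range_bpm[2],
              x$pressure_amp_hpa, x$seed))
  invisible(x)
}

# raised-cosine hump on [0, 1]: 0 at both ends, 1 at the midpoint
rc_hump <- function(u) 0.5 * (1 - cos(2 * pi * pmin(pmax(u, 0), 1)))

subject_seed <- function(seed, subject_index) {
  as.integer((as.numeric(seed) * 10007 + subject_index) %% 2147483647)
}

#' Simulate one subject's fit-test session
#'
#' Cycles are constructed sequentially: the subject's base rate is drawn
#' from `rate_range_bpm`, each cycle's period is `60/rate * (1 + jitter)`
#' and its inspiratory fraction is drawn Normal and truncated to
#' `[0.2, 0.6]`. Pressure carries a raised-cosine trough during inspiration
#' and hump during expiration with amplitude `pressure_amp_hpa * (1 -
#' lambda)`; temperature and humidity relax toward exhaled-air targets
#' during expiration (increment scaled by `1 - lambda`) and back toward
#' ambient during inspiration, with per-cycle channel timing jitter of SD
#' `phase_noise_sd_s * lambda`. Random-walk drift and white noise are added
#' per channel and labels are emitted from the session plan.
#'
#' @param cfg A [synth_config()].
#' @param subject_index Positive integer; selects the subject's
#'   deterministic random substream.
#' @return A list with elements `recording` ([breath_recording()]),
#'   `labels` (segment data frame) and `cycles` (ground-truth cycle table
#'   with `start_s`, `period_s`, `delta_insp`, `lambda`).
#' @export
simulate_subject <- function(cfg, subject_index = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  plan <- cfg$session_plan
  total <- sum(plan$duration_s)
  block_start <- cumsum(c(0, plan$duration_s))[seq_len(nrow(plan))]
  sid <- sprintf("S%02d", subject_index)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(subject_seed(cfg$seed, subject_index))

  rate <- stats::runif(1, cfg$rate_range_bpm[1], cfg$rate_range_bpm[2])
  effort <- stats::runif(1, cfg$subject_amp_range[1],
                         cfg$subject_amp_range[2])
  cv <- cfg$cycle_jitter_cv
  start <- 0
  cyc <- list()
  while (start < total) {
    jit <- max(min(stats::rnorm(1, 0, cv), 3 * cv), -3 * cv)
    period <- 60 / rate * (1 + jit)
    delta <- min(max(stats::rnorm(1, cfg$insp_fraction_mean,
                                  cfg$insp_fraction_sd), 0.2), 0.6)
    blk <- findInterval(start, block_start)
    lam <- plan$leak[blk]
    jt <- stats::rnorm(1, 0, cfg$phase_noise_sd_s * lam)
    jh <- stats::rnorm(1, 0, cfg$phase_noise_sd_s * lam)
    cyc[[length(cyc) + 1L]] <- c(start, period, delta, lam, jt, jh)
    start <- start + period
  }
  cyc <- do.call(rbind, cyc)
  colnames(cyc) <- c("start_s", "period_s", "delta_insp", "lambda",
                     "jit_t", "jit_h")

  fs <- cfg$fs
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  ci <- findInterval(t, cyc[, "start_s"])
  u <- (t - cyc[ci, "start_s"]) / cyc[ci, "period_s"]
  delta <- cyc[ci, "delta_insp"]
  lam <- cyc[ci, "lambda"]
  amp <- effort * cfg$pressure_amp_hpa * (1 - lam)
  osc <- ifelse(u < delta, -amp * rc_hump(u / delta),
                amp * rc_hump((u - delta) / (1 - delta)))

  exhale_track <- function(jit) {
    us <- (t - jit[ci] - cyc[ci, "start_s"]) / cyc[ci, "period_s"]
    (us %% 1) >= delta
  }
  relax <- function(track, base, exhale_target) {
    target <- base + (exhale_target - base) *
      pmin(effort, 1) * (1 - lam) * track
    alpha <- 1 - exp(-1 / (fs * cfg$microclimate_tau_s))
    as.numeric(stats::filter(alpha * target, 1 - alpha, method = "recursive",
                             init = base))
  }
  channel_noise <- function(ch) {
    cumsum(stats::rnorm(n, 0, cfg$drift_sd[[ch]])) +
      stats::rnorm(n, 0, cfg$noise_sd[[ch]])
  }
  pressure <- cfg$pressure_baseline_hpa + osc + channel_noise("pressure")
  temperature <- relax(exhale_track(cyc[, "jit_t"]), cfg$temp_baseline_c,
                       cfg$temp_exhale_c) + channel_noise("temperature")
  humidity <- relax(exhale_track(cyc[, "jit_h"]), cfg$rh_baseline,
                    cfg$rh_exhale) + channel_noise("humidity")

  rec <- breath_recording(pressure, temperature, humidity, fs = fs,
                          subject_id = sid, session_id = "R1")
  lab <- plan[plan$label != "other", , drop = FALSE]
  labels <- data.frame(subject_id = sid, session_id = "R1",
                       start_s = block_start[plan$label != "other"],
                       end_s = block_start[plan$label != "other"] +
                         lab$duration_s,
                       label = lab$label, condition = lab$condition)
  cycles <- data.frame(subject_id = sid, session_id = "R1",
                       start_s = cyc[, "start_s"],
                       period_s = cyc[, "period_s"],
                       delta_insp = cyc[, "delta_insp"],
                       lambda = cyc[, "lambda"])
  list(recording = rec, labels = validate_segments(labels), cycles = cycles)
}

#' Simulate a labeled cohort
#'
#' Runs [simulate_subject()] for `cfg$n_subjects` subjects, each on its own
#' deterministic random substream, so any subject can be regenerated
#' independently and the cohort is reproducible from the single seed.
#'
#' @param cfg A [synth_config()].
#' @return An object of class `synth_cohort`: list with `recordings` (list
#'   of [breath_recording()]), `labels` (one segment data frame),
#'   `cycles` (one ground-truth cycle table) and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_subjects < 1)
    bf_stop("n_subjects must be >= 1 to simulate a cohort",
            "bf_config_error")
  subs <- lapply(seq_len(cfg$n_subjects), function(i)
    simulate_subject(cfg, i))
  structure(
    list(recordings = lapply(subs, `[[`, "recording"),
         labels = do.call(rbind, lapply(subs, `[[`, "labels")),
         cycles = do.call(rbind, lapply(subs, `[[`, "cycles")),
         config = cfg),
    class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d recording(s), %d ground-truth cycles\n",
              length(x$recordings), nrow(x$cycles)))
  invisible(x)
}
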