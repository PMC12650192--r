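# small session plans and configs used across test files

one_block_plan <- function(duration_s = 60, label = "fit",
                           condition = "proper_fit", leak = 0) {
  data.frame(duration_s = duration_s, label = label, condition = condition,
             leak = leak)
}

# deterministic breathing: fixed rate, no jitter, no noise, no drift
clean_cfg <- function(rate = 12, duration_s = 60, leak = 0, seed = 1,
                      label = "fit", ...) {
  synth_config(
    n_subjects = 1,
    session_plan = one_block_plan(duration_s, label = label, leak = leak),
    rate_range_bpm = c(rate, rate), insp_fraction_sd = 0,
    cycle_jitter_cv = 0,
    drift_sd = c(pressure = 0, temperature = 0, humidity = 0),
    noise_sd = c(pressure = 0, temperature = 0, humidity = 0),
    phase_noise_sd_s = 0, subject_amp_range = c(1, 1), seed = seed, ...)
}

# two-condition plan that yields both classes quickly
two_class_plan <- function(fit_s = 120, poor_s = 120, leak = 0.5) {
  rbind(one_block_plan(fit_s),
        one_block_plan(poor_s, "poor_fit", "loose", leak))
}

small_cohort <- function(n_subjects = 3, seed = 99, ...) {
  simulate_cohort(synth_config(n_subjects = n_subjects,
                               session_plan = two_class_plan(),
                               seed = seed, ...))
}

# z-score channels without bandpassing (keeps waveform corners intact)
zscore_recording <- function(rec) {
  breath_recording(zscore(rec$pressure), zscore(rec$temperature),
                   zscore(rec$humidity), fs = rec$fs,
                   subject_id = rec$subject_id,
                   session_id = rec$session_id, t0 = rec$t0,
                   preprocessed = TRUE)
}
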