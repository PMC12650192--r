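test_that("extrema detection matches textbook cases", {
  t <- seq(0, 59.9, by = 0.1)
  x <- sin(2 * pi * 0.2 * t)
  ex <- detect_extrema(x, mpd = 23)
  expect_length(ex$peaks, 12)
  expect_length(ex$valleys, 12)
  ref <- ref_extrema(x, 23)
  expect_identical(ex$peaks, ref$peaks)
  expect_identical(ex$valleys, ref$valleys)

  expect_identical(detect_extrema(1:50)$peaks, integer(0))
  expect_identical(detect_extrema(1:50)$valleys, integer(0))

  # mpd suppression keeps the taller of two close spikes
  sp <- rep(0, 40)
  sp[10] <- 1.0
  sp[20] <- 0.9
  expect_identical(detect_extrema(sp, 23)$peaks, 10L)
})

test_that("extrema detection agrees exactly with the brute-force oracle", {
  set.seed(123)
  for (i in 1:250) {
    n <- sample(10:200, 1)
    x <- cumsum(stats::rnorm(n))
    if (i %% 3 == 0) x <- round(x, 1)       # force ties and plateaus
    if (i %% 7 == 0) x <- cumsum(sample(c(-1, 0, 1), n, replace = TRUE))
    mpd <- sample(1:30, 1)
    got <- detect_extrema(x, mpd)
    ref <- ref_extrema(x, mpd)
    expect_identical(got$peaks, as.integer(ref$peaks))
    expect_identical(got$valleys, as.integer(ref$valleys))
  }
})

test_that("retained extrema honor the minimum-distance contract", {
  set.seed(5)
  for (i in 1:30) {
    x <- cumsum(stats::rnorm(300))
    mpd <- sample(2:40, 1)
    ex <- detect_extrema(x, mpd)
    if (length(ex$peaks) > 1) expect_gte(min(diff(ex$peaks)), mpd)
    if (length(ex$valleys) > 1) expect_gte(min(diff(ex$valleys)), mpd)
  }
})

test_that("cycle construction enforces peak-valley-peak with one valley", {
  cyc <- build_cycles(c(100, 145), 118, fs = 10)
  expect_equal(nrow(cyc), 1)
  expect_equal(cyc$t_cycle_s, 4.5)
  expect_equal(cyc$delta_insp, 0.4)
  expect_equal(cyc$delta_exp, 0.6)

  # two valleys between a peak pair: the interval is discarded
  expect_equal(nrow(build_cycles(c(10, 60), c(25, 40), 10)), 0)

  # valleys before the first and after the last peak are ignored
  cyc3 <- build_cycles(c(10, 60, 110), c(5, 35, 85, 115), 10)
  expect_equal(nrow(cyc3), 2)
  expect_equal(cyc3$v, c(35, 85))

  expect_equal(nrow(build_cycles(c(10), integer(0), 10)), 0)
})

test_that("inspiratory and expiratory ratios always sum to one", {
  set.seed(11)
  for (i in 1:50) {
    peaks <- sort(sample(1:500, sample(3:12, 1)))
    valleys <- sort(sample(1:500, sample(3:12, 1)))
    cyc <- build_cycles(peaks, valleys, 10)
    if (nrow(cyc)) {
      expect_true(all(abs(cyc$delta_insp + cyc$delta_exp - 1) < 1e-9))
      expect_true(all(cyc$delta_insp > 0 & cyc$delta_insp < 1))
      expect_true(all(cyc$p_initial < cyc$v & cyc$v < cyc$p_final))
      expect_lte(nrow(cyc), length(peaks) - 1)
    }
  }
})

test_that("cycle slices share identical bounds across channels", {
  sub <- simulate_subject(clean_cfg(duration_s = 60), 1)
  segs <- segment_cycles(zscore_recording(sub$recording))
  expect_gte(nrow(segs$cycles), 10)
  for (i in seq_len(nrow(segs$cycles))) {
    len <- segs$cycles$p_final[i] - segs$cycles$p_initial[i] + 1L
    expect_identical(lengths(segs$slices[[i]]),
                     c(pressure = len, humidity = len, temperature = len))
  }
  expect_true(all(abs(segs$cycles$delta_insp - 0.4) <= 0.02))
  # shorter than one breathing cycle: nothing to segment
  tiny <- breath_recording(sin(1:15), cos(1:15), sin(1:15) + 1)
  expect_equal(nrow(segment_cycles(tiny)$cycles), 0)
})

test_that("swap_phases mirrors the phase convention", {
  sub <- simulate_subject(clean_cfg(duration_s = 60), 1)
  rec <- zscore_recording(sub$recording)
  a <- segment_cycles(rec)
  b <- segment_cycles(rec, segmentation_params(swap_phases = TRUE))
  expect_equal(a$cycles$delta_insp, 1 - b$cycles$delta_insp)
})

test_that("sliding windows follow the count formula and purity rule", {
  rec <- breath_recording(1013 + sin(1:600 / 5), 24 + cos(1:600 / 7),
                          55 + sin(1:600 / 9))
  track <- rep("fit", 600)
  win <- sliding_windows(rec, track)
  expect_equal(nrow(win$windows), 19)  # floor((600 - 50) / 30) + 1
  expect_equal(win$window_len, 50)
  expect_true(all(win$windows$end - win$windows$start + 1 == 50))

  # purity exactly at the 0.8 threshold is kept; 50/50 is discarded
  rec50 <- breath_recording(sin(1:50), cos(1:50), sin(1:50) + 2)
  keep <- sliding_windows(rec50, c(rep("fit", 40), rep("poor_fit", 10)))
  expect_equal(keep$windows$label, "fit")
  drop <- sliding_windows(rec50, c(rep("fit", 25), rep("poor_fit", 25)))
  expect_equal(nrow(drop$windows), 0)
  other <- sliding_windows(rec50, rep("other", 50))
  expect_equal(nrow(other$windows), 0)

  expect_error(sliding_windows(rec50, rep("fit", 50),
                               window_params(window_s = 10)),
               class = "bf_length_error")
})

test_that("cycle labeling keeps pure cycles and discards transitions", {
  sub <- simulate_subject(
    synth_config(n_subjects = 1, session_plan = two_class_plan(),
                 seed = 17), 1)
  rec <- zscore_recording(sub$recording)
  track <- sample_labels(rec, sub$labels)
  segs <- label_cycles(segment_cycles(rec), track)
  expect_true(all(segs$cycles$label %in% c("fit", "poor_fit")))
  expect_gt(sum(segs$cycles$label == "fit"), 10)
  expect_gt(sum(segs$cycles$label == "poor_fit"), 10)
  # a cycle straddling the transition at 50/50 purity is discarded
  half <- c(rep("fit", 25), rep("poor_fit", 26))
  one <- segment_cycles(rec)
  one$cycles <- one$cycles[1, ]
  one$slices <- one$slices[1]
  one$cycles$p_initial <- 1
  one$cycles$v <- 21
  one$cycles$p_final <- 51
  expect_equal(nrow(label_cycles(one, c(half, rep("fit", n_samples(rec) -
                                                    51)))$cycles), 0)
})
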