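sin_cycle <- function() {
  # one full period sampled so the quarter points land on the grid
  x <- sin(2 * pi * (0:48) / 48)
  list(cycle = list(p_initial = 1L, v = 21L, p_final = 49L),
       slices = list(pressure = x, humidity = x, temperature = x))
}

test_that("the cycle schema has exactly 22 stable names in order", {
  nm <- cycle_feature_names()
  expect_length(nm, 22)
  expect_identical(nm, c(
    "insp_time_prop",
    "ptp_pressure", "ptp_humidity", "ptp_temperature",
    "mean_insp_pressure", "mean_insp_humidity", "mean_insp_temperature",
    "mean_exp_pressure", "mean_exp_humidity", "mean_exp_temperature",
    "sd_pressure", "sd_humidity", "sd_temperature",
    "skew_pressure", "skew_humidity", "skew_temperature",
    "kurt_pressure", "kurt_humidity", "kurt_temperature",
    "median_pressure", "median_humidity", "median_temperature"))
  expect_length(window_feature_names(), 18)
})

test_that("a unit sinusoid cycle gives the symmetry-forced values", {
  sc <- sin_cycle()
  f <- extract_cycle_features(sc$cycle, sc$slices)
  expect_length(f, 22)
  expect_identical(names(f), cycle_feature_names())
  expect_equal(unname(f["ptp_pressure"]), 2)
  expect_lt(abs(f["skew_temperature"]), 1e-6)
  expect_lt(abs(f["median_humidity"]), 1e-12)
  expect_equal(unname(f["insp_time_prop"]), 20 / 48)
})

test_that("the temporal ratio comes straight from the index triplet", {
  x <- stats::rnorm(46)
  f <- extract_cycle_features(list(p_initial = 100L, v = 118L,
                                   p_final = 145L),
                              list(pressure = x, humidity = x,
                                   temperature = x))
  expect_equal(unname(f["insp_time_prop"]), 0.4)
})

test_that("degenerate slices are rejected, not silently summarized", {
  const <- rep(1.5, 30)
  expect_error(extract_cycle_features(list(p_initial = 1L, v = 10L,
                                           p_final = 30L),
                                      list(pressure = const,
                                           humidity = const,
                                           temperature = const)),
               class = "bf_degenerate_error")
  expect_error(extract_window_features(list(pressure = rep(1, 50),
                                            humidity = rep(1, 50),
                                            temperature = rep(1, 50))),
               class = "bf_degenerate_error")
  expect_error(extract_window_features(list(pressure = stats::rnorm(30),
                                            humidity = stats::rnorm(30),
                                            temperature = stats::rnorm(30))),
               class = "bf_length_error")
})

test_that("window features: half-period cosine and schema length", {
  x <- cos(pi * (0:49) / 49)   # +1 down to -1
  w <- extract_window_features(list(pressure = x, humidity = x,
                                    temperature = x))
  expect_length(w, 18)
  expect_identical(names(w), window_feature_names())
  expect_equal(unname(w["ptp_pressure"]), 2)
  expect_equal(unname(w["median_temperature"]), 0)  # odd symmetry
})

test_that("features obey the scale contracts", {
  set.seed(21)
  for (i in 1:10) {
    x <- list(pressure = stats::rnorm(40), humidity = stats::rnorm(40),
              temperature = stats::rnorm(40))
    cy <- list(p_initial = 1L, v = sample(10:30, 1), p_final = 40L)
    f0 <- extract_cycle_features(cy, x)
    a <- stats::runif(1, 0.5, 3)
    b <- stats::rnorm(1, sd = 10)
    shifted <- lapply(x, `+`, b)
    fs <- extract_cycle_features(cy, shifted)
    affine <- lapply(x, function(v) a * v + b)
    fa <- extract_cycle_features(cy, affine)
    stat <- function(f, what) unname(f[startsWith(names(f), what)])
    # ptp and SD ignore additive offsets
    expect_equal(stat(fs, "ptp_"), stat(f0, "ptp_"), tolerance = 1e-12)
    expect_equal(stat(fs, "sd_"), stat(f0, "sd_"), tolerance = 1e-12)
    # shape statistics and the temporal ratio ignore positive affine maps
    expect_equal(stat(fa, "skew_"), stat(f0, "skew_"), tolerance = 1e-9)
    expect_equal(stat(fa, "kurt_"), stat(f0, "kurt_"), tolerance = 1e-9)
    expect_equal(fa[["insp_time_prop"]], f0[["insp_time_prop"]])
  }
})

test_that("skewness and kurtosis follow the population convention", {
  x <- c(1, 2, 2, 3, 7)
  m <- mean(x)
  mk <- function(k) mean((x - m)^k)
  sl <- list(pressure = x, humidity = x, temperature = x)
  f <- extract_cycle_features(list(p_initial = 1L, v = 3L, p_final = 5L),
                              sl)
  expect_equal(unname(f["skew_pressure"]), mk(3) / mk(2)^1.5)
  expect_equal(unname(f["kurt_pressure"]), mk(4) / mk(2)^2 - 3)
  expect_equal(unname(f["sd_pressure"]), sqrt(mk(2)))
})

test_that("feature tables carry provenance and refuse empty input", {
  co <- small_cohort()
  tab <- cohort_feature_table(co, "cycles")
  expect_identical(feature_columns(tab), cycle_feature_names())
  expect_true(all(tab$label %in% c("fit", "poor_fit")))
  expect_true(all(grepl("^cycle\\[\\d+-\\d+\\]$", tab$provenance)))
  expect_setequal(unique(tab$subject_id), c("S01", "S02", "S03"))

  tabw <- cohort_feature_table(co, "windows")
  expect_identical(feature_columns(tabw), window_feature_names())

  rec <- zscore_recording(co$recordings[[1]])
  segs <- label_cycles(segment_cycles(rec), rep("other", n_samples(rec)))
  expect_error(build_feature_table(segs), class = "bf_empty_error")
  expect_error(build_feature_table(segment_cycles(rec)),
               class = "bf_schema_error")
})

test_that("leak separability shows up in pressure peak-to-peak", {
  cfg <- synth_config(
    n_subjects = 1, seed = 4,
    session_plan = rbind(one_block_plan(180),
                         one_block_plan(180, "poor_fit", "loose", 0.75)))
  tab <- cohort_feature_table(simulate_cohort(cfg), "cycles")
  expect_gt(mean(tab$ptp_pressure[tab$label == "fit"]),
            mean(tab$ptp_pressure[tab$label == "poor_fit"]))
})

test_that("feature tables round-trip through CSV", {
  co <- small_cohort()
  tab <- cohort_feature_table(co, "cycles")
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back, tab)
  bad <- tab
  bad$label[1] <- "other"
  write_feature_table(bad, path)
  expect_error(read_feature_table(path), class = "bf_vocab_error")
})
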