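test_that("onset detection follows the sustained-threshold rule", {
  tt <- seq(0, 20, by = 0.05)
  flat <- make_dff(tt, rep(0, length(tt)))
  expect_true(is.na(detect_onset(flat, after_s = 5)))
  step <- make_dff(tt, ifelse(tt < 7, 0, 30))
  expect_equal(detect_onset(step, after_s = 5), 7, tolerance = 0.051)
  expect_error(detect_onset(step, after_s = 50), "outside")
})

test_that("onset is recovered near insertion + onset delay on a noisy cohort", {
  p <- make_preset("spc")
  co <- simulate_cohort(p, n = 50, seed = 6)
  onsets <- vapply(co, function(b) {
    sub <- subtract_background(b$trace)
    d <- ratiometric_dff(sub, events = b$events)
    detect_onset(d, after_s = b$events$insertion) - b$events$insertion
  }, numeric(1))
  # the threshold rule fires once the rise clears ~2 baseline SDs, so the
  # detected onset trails the true onset by about threshold/slope plus the
  # sustained-run check, and never systematically precedes it
  lag <- mean(onsets, na.rm = TRUE) - p$onset_delay_s
  expect_gt(lag, 0)
  expect_lt(lag, 2 * sqrt(2) * p$noise_sd / p$rise_slope + 0.2)
})

test_that("peak latency is the windowed argmax with earliest-tie rule", {
  p <- noiseless_preset("spc")
  b <- simulate_bout(p, insertion_time_s = 5, duration_s = 40, seed = 1)
  d <- ratiometric_dff(subtract_background(b$trace), events = b$events)
  expect_equal(as.numeric(peak_latency(d, 5)), 1.3, tolerance = 0.051)

  p2 <- noiseless_preset("pca")
  b2 <- simulate_bout(p2, insertion_time_s = 5, duration_s = 40, seed = 1)
  d2 <- ratiometric_dff(subtract_background(b2$trace), events = b2$events)
  expect_equal(as.numeric(peak_latency(d2, 5)), 6.3, tolerance = 0.051)

  # monotone decay peaks at the insertion sample itself
  tt <- seq(0, 20, by = 0.1)
  dec <- make_dff(tt, 100 - 2 * tt)
  expect_equal(as.numeric(peak_latency(dec, 5, search_window_s = 10)), 0)
  expect_warning(peak_latency(dec, 15, search_window_s = 30), "truncated")
})

test_that("peak latency is invariant under positive affine transforms", {
  set.seed(3)
  tt <- seq(0, 30, by = 0.05)
  for (i in 1:10) {
    y <- as.numeric(arima.sim(list(ar = 0.9), length(tt))) +
      50 * exp(-((tt - 12)^2) / 4)
    d <- make_dff(tt, y)
    a <- runif(1, 0.1, 5); b <- runif(1, -100, 100)
    d2 <- make_dff(tt, a * y + b)
    expect_identical(as.numeric(peak_latency(d, 5, search_window_s = 20)),
                     as.numeric(peak_latency(d2, 5, search_window_s = 20)))
  }
})

test_that("rise slope is the OLS slope between onset and peak", {
  tt <- seq(0, 5, by = 0.05)
  ramp <- make_dff(tt, ifelse(tt < 1.3, tt * (60 / 1.3), 60))
  expect_equal(rise_slope(ramp, 0, 1.3), 60 / 1.3, tolerance = 1e-9)
  flat <- make_dff(tt, rep(5, length(tt)))
  expect_equal(rise_slope(flat, 1, 3), 0)
  expect_error(rise_slope(flat, 3, 1), "precede")
  expect_error(rise_slope(flat, 1, 1.01), "fewer than 2")
})

test_that("second-rise features recover biphasic muscle kinetics", {
  p <- noiseless_preset("muscles_biphasic")
  b <- simulate_bout(p, insertion_time_s = 5, duration_s = 40, seed = 1)
  d <- ratiometric_dff(subtract_background(b$trace), events = b$events)
  f <- extract_kinetics(d, 5, biphasic = TRUE)
  expect_false(is.na(f$second_peak_time_s))
  expect_equal(f$second_insertion_to_peak_s, 11, tolerance = 0.051 / 11)
  expect_equal(f$second_rise_slope, 46, tolerance = 0.02)

  pm <- noiseless_preset("muscles_monophasic")
  bm <- simulate_bout(pm, insertion_time_s = 5, duration_s = 40, seed = 1)
  dm <- ratiometric_dff(subtract_background(bm$trace), events = bm$events)
  sr <- second_rise_features(dm, attr(peak_latency(dm, 5), "peak_time_s"))
  expect_true(sr$no_second_rise)
})

test_that("noisy biphasic cohort recovers the second-rise slope", {
  p <- make_preset("muscles_biphasic")
  co <- simulate_cohort(p, n = 30, seed = 9)
  meas <- truth <- numeric(0)
  for (b in co) {
    d <- ratiometric_dff(subtract_background(b$trace), events = b$events)
    # the second peak can sit late enough that < 15 s of trace remain
    f <- suppressWarnings(
      extract_kinetics(d, b$events$insertion, biphasic = TRUE))
    if (is.na(f$second_rise_slope)) next
    meas <- c(meas, f$second_rise_slope)
    truth <- c(truth, b$truth$second_rise$rise_slope)
  }
  expect_gt(length(meas), 20)
  expect_lt(abs(mean(meas) - mean(truth)), 2 * 19 / sqrt(length(meas)) + 2)
})

test_that("post-peak slope is the straight-line fit over the release window", {
  tt <- seq(0, 30, by = 0.05)
  tri <- make_dff(tt, ifelse(tt < 5, 10 * tt, pmax(50 - 2 * (tt - 5), 0)))
  s <- post_peak_15s_slope(tri)
  expect_equal(as.numeric(s), -2, tolerance = 0.05)
  plateau <- make_dff(tt, ifelse(tt < 5, 10 * tt, 50))
  expect_equal(as.numeric(post_peak_15s_slope(plateau)), 0)
  short <- make_dff(seq(0, 10, by = 0.05),
                    ifelse(seq(0, 10, by = 0.05) < 5,
                           10 * seq(0, 10, by = 0.05), 50 - 2))
  expect_warning(post_peak_15s_slope(short), "remain after the peak")
  last_peak <- make_dff(tt, tt)
  expect_error(post_peak_15s_slope(last_peak), "final sample")
})

test_that("slower decay variants keep a less negative post-peak slope", {
  p_fast <- make_preset("valve")            # 6 %/s decline
  p_slow <- make_preset("valve")
  p_slow$decay_rate <- 1.5                  # protracted decline
  sl_fast <- sl_slow <- numeric(30)
  for (i in 1:30) {
    bf <- simulate_bout(p_fast, insertion_time_s = 5, duration_s = 45,
                        seed = i)
    bs <- simulate_bout(p_slow, insertion_time_s = 5, duration_s = 45,
                        seed = i)
    df <- ratiometric_dff(subtract_background(bf$trace), events = bf$events)
    ds <- ratiometric_dff(subtract_background(bs$trace), events = bs$events)
    sl_fast[i] <- as.numeric(post_peak_15s_slope(df))
    sl_slow[i] <- as.numeric(post_peak_15s_slope(ds))
  }
  expect_gt(mean(sl_slow), mean(sl_fast))
  expect_gt(mean(sl_slow > sl_fast), 0.9)
})

test_that("cohort summaries report mean, sample SD and n", {
  f <- function(lat) structure(list(
    onset_s = 0, peak_time_s = 0, insertion_to_peak_s = lat,
    rise_slope = 10, post_peak_15s_slope = -1,
    second_rise_onset_s = NA_real_, second_peak_time_s = NA_real_,
    second_insertion_to_peak_s = NA_real_, second_rise_slope = NA_real_,
    no_transient = FALSE), class = "kinetic_features")
  s1 <- summarize_cohort(list(f(2), f(2), f(2)))
  expect_equal(s1$insertion_to_peak_s_sd, 0)
  s2 <- summarize_cohort(list(f(1), f(2)))
  expect_equal(s2$insertion_to_peak_s_mean, 1.5)
  expect_equal(s2$insertion_to_peak_s_sd, sqrt(0.5), tolerance = 1e-9)
  expect_equal(s2$n, 2)
  expect_error(summarize_cohort(list(f(1))), "n >= 2")
  # noiseless cohort reproduces the tabulated row exactly
  p <- noiseless_preset("spc")
  co <- simulate_cohort(p, n = 5, seed = 1)
  r <- run_pipeline(co)
  expect_equal(r$summary$insertion_to_peak_s_mean, 1.3, tolerance = 0.051)
  expect_lt(r$summary$insertion_to_peak_s_sd, 0.06)
})
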