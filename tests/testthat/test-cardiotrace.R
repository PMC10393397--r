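test_that("Bartlett smoothing preserves a constant signal exactly", {
  tr <- cardiac_trace(seq(0, 10, by = 0.1), rep(3.5, 101), rep(30, 101), 10)
  sm <- bartlett_smooth(tr, 0.5)
  expect_equal(sm$signal_mV, rep(3.5, 101), tolerance = 1e-12)
  expect_identical(sm$temp_C, tr$temp_C)
  expect_identical(sm$time_s, tr$time_s)
})

test_that("a unit impulse smooths to a symmetric unit-sum triangle", {
  sig <- numeric(101)
  sig[51] <- 1
  tr <- cardiac_trace(seq(0, 10, by = 0.1), sig, rep(30, 101), 10)
  sm <- bartlett_smooth(tr, 0.5)  # 5-sample kernel
  out <- sm$signal_mV
  expect_equal(sum(out), 1, tolerance = 1e-12)
  expect_equal(out[49:53], out[53:49], tolerance = 1e-12)  # symmetric
  expect_equal(which.max(out), 51)
  expect_true(all(out[c(1:48, 54:101)] == 0))
})

test_that("Bartlett smoothing is linear", {
  set.seed(5)
  t <- seq(0, 20, by = 0.1)
  a <- rnorm(length(t))
  b <- rnorm(length(t))
  mk <- function(x) cardiac_trace(t, x, rep(30, length(t)), 10)
  sm <- function(x) bartlett_smooth(mk(x), 1)$signal_mV
  expect_equal(sm(a + b), sm(a) + sm(b), tolerance = 1e-10)
})

test_that("smoothing white noise reduces its variance", {
  set.seed(6)
  t <- seq(0, 49.9, by = 0.1)
  reduced <- replicate(100, {
    x <- rnorm(length(t))
    var(bartlett_smooth(cardiac_trace(t, x, rep(30, length(t)), 10),
                        1)$signal_mV) < var(x)
  })
  expect_true(all(reduced))
})

test_that("degenerate smoothing windows are rejected", {
  tr <- cardiac_trace(seq(0, 10, by = 0.1), rnorm(101), rep(30, 101), 10)
  expect_error(bartlett_smooth(tr, 0.1), "3 samples")
  expect_error(bartlett_smooth(tr, 11), "shorter than the trace")
})

test_that("a noise-free 60 bpm trace yields 60 +/- 1 beats in 60 s", {
  tr <- regular_beat_trace(bpm = 60, duration_s = 60)
  beats <- detect_beats(tr, min_prominence = 0.5)
  expect_lte(abs(length(beats) - 60), 1)
})

test_that("pure noise below the prominence threshold yields no beats", {
  set.seed(7)
  t <- seq(0, 60, by = 1 / 40)
  tr <- cardiac_trace(t, rnorm(length(t), 0, 0.1), rep(30, length(t)), 40)
  expect_length(detect_beats(tr, min_prominence = 1), 0)
  # flat trace: no beats, no error
  tr0 <- cardiac_trace(t, rep(0, length(t)), rep(30, length(t)), 40)
  expect_length(detect_beats(tr0), 0)
})

test_that("beat count is non-increasing in the prominence threshold", {
  for (s in 1:5) {
    tr <- regular_beat_trace(bpm = 90, duration_s = 40, noise_sd = 0.3,
                             seed = s)
    counts <- vapply(seq(0.1, 1.2, by = 0.1), function(p)
      length(detect_beats(tr, min_prominence = p)), 1L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("beat times are recovered within 50 ms RMS at 20% noise", {
  tt <- default_truth()
  tr <- simulate_trace(tt, ramp = ramp_protocol(30, 40, 0.5, 40),
                       noise_sd = 0.2, seed = 8)
  truth <- attr(tr, "truth")$beat_times
  beats <- detect_beats(bartlett_smooth(tr, 0.1))
  err <- vapply(truth, function(b) min(abs(beats - b)), 1)
  matched <- err < 0.1
  expect_gt(mean(matched), 0.95)
  expect_lt(sqrt(mean(err[matched]^2)), 0.05)
})

test_that("hr_series implements hr = 60 * n_beats / window", {
  t <- seq(0, 90, by = 1 / 10)
  tr <- cardiac_trace(t, numeric(length(t)), rep(32, length(t)), 10)
  beats <- seq(0.5, 29.5, by = 1)  # 30 beats, all inside the first 30 s
  s <- hr_series(beats, tr, window_s = 30, step_s = 30)
  expect_equal(s$hr_bpm[1], 60)
  expect_equal(s$n_beats[1], 30L)
  expect_equal(s$temp_mid_C[1], 32)
  # no beats at all -> all-zero series
  s0 <- hr_series(numeric(0), tr, window_s = 30, step_s = 30)
  expect_true(all(s0$hr_bpm == 0))
})

test_that("windowed rates track the generating curve within 5% when noise-free", {
  tt <- default_truth()
  tr <- simulate_trace(tt, ramp = small_ramp(), noise_sd = 0, seed = 9)
  beats <- detect_beats(tr)
  s <- hr_series(beats, tr, window_s = 60, step_s = 30)
  keep <- s$temp_mid_C < 51 & s$time_start_s > 60
  expected <- cardioTPC:::.ss_rate_p(tt$params, s$temp_mid_C[keep])
  expect_lt(max(abs(s$hr_bpm[keep] - expected) / expected), 0.05)
})

test_that("flatline is called near the true ULT and only on terminal runs", {
  tt <- default_truth()
  tr <- simulate_trace(tt, ramp = small_ramp(), noise_sd = 0, seed = 10)
  s <- hr_series(detect_beats(tr), tr)
  fl <- detect_flatline(s)
  expect_s3_class(fl, "flatline_call")
  # within one window's temperature span of truth (0.5 degC at 0.5 C/min)
  expect_lt(abs(fl$ult_C - 52), 0.5 + 0.26)
})

test_that("a temporary sub-floor episode with recovery is not a ULT", {
  temp <- seq(30, 50, length.out = 41)
  hr <- rep(80, 41)
  hr[15:18] <- 0       # transient depression
  hr[35:41] <- 0       # terminal flatline
  s <- make_series(temp, hr)
  fl <- detect_flatline(s, hr_floor = 5, sustain_s = 120)
  expect_equal(fl$ult_C, temp[35])
  # never below the floor -> no call
  expect_null(detect_flatline(make_series(temp, rep(80, 41))))
  # all-zero series -> ULT at the first window
  fl0 <- detect_flatline(make_series(temp, rep(0, 41)))
  expect_equal(fl0$ult_C, temp[1])
})

test_that("flatline detection rejects non-monotone temperature series", {
  s <- make_series(c(30, 35, 33, 40), c(60, 60, 0, 0))
  expect_error(detect_flatline(s), "heating ramps")
})

test_that("noise-free end-to-end ULT error is within one window span", {
  for (s in 1:3) {
    tt <- true_traits(topt_C = 44, ult_C = 50 + s)
    tr <- simulate_trace(tt, ramp = small_ramp(), noise_sd = 0, seed = s)
    res <- trace_to_traits(tr, smooth_window_s = NULL, seed = s)
    window_span_C <- 60 * 0.5 / 60  # window_s * rate
    expect_lt(abs(res$ult_C - tt$ult_C), window_span_C + 0.3)
  }
})
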