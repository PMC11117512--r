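preprocess_ecg <- function(session) {
  rec <- ecg_wavelet_reconstruct(remove_powerline(session$ecg))
  if (detect_polarity(rec) == "NEGATIVE") {
    rec <- sampled_signal(-rec$values, rec$fs, rec$channel, rec$side)
  }
  rec
}

test_that("R-peak detection recovers clean generator truth exactly", {
  gen <- generate_session(synth_settings(duration_s = 30, seed = 2), 1.7)
  r <- detect_r_peaks(preprocess_ecg(gen$session))
  truth <- round(gen$truth$beat_times_s * 200) + 1
  expect_equal(length(r), length(truth))
  expect_lte(max(abs(r - truth)), 1)
  # 60 bpm over 30 s: 30 +/- 1 peaks
  expect_true(abs(length(r) - 30) <= 1)
})

test_that("R-peak detection holds across heart rates 40-180 bpm", {
  for (hr in c(40, 75, 120, 180)) {
    gen <- generate_session(synth_settings(duration_s = 30, hr_bpm = hr,
                                           seed = 100 + hr), 1.7)
    r <- detect_r_peaks(preprocess_ecg(gen$session))
    truth <- round(gen$truth$beat_times_s * 200) + 1
    expect_equal(length(r), length(truth), info = paste("hr", hr))
    expect_lte(max(abs(r - truth)), 1)
  }
})

test_that("R-peak detection under mains and 10 dB noise stays within 2 samples", {
  st <- synth_settings(duration_s = 60, seed = 12)
  st$mains_amp <- st$qrs_amp
  st$noise_sigma <- noise_sigma_for_snr(st, 10)
  gen <- generate_session(st, 1.7)
  r <- detect_r_peaks(preprocess_ecg(gen$session))
  truth <- round(gen$truth$beat_times_s * 200) + 1
  expect_equal(length(r), length(truth))   # no spurious, none missed
  expect_lte(max(abs(r - truth)), 2)
})

test_that("R-peak detection contracts: empty input, refractory spacing", {
  expect_identical(detect_r_peaks(as_ecg(rep(0, 1000))), integer(0))
  gen <- generate_session(synth_settings(duration_s = 30, hr_bpm = 180,
                                         seed = 8), 1.7)
  r <- detect_r_peaks(preprocess_ecg(gen$session))
  expect_true(all(diff(r) >= 0.25 * 200))
})

test_that("heart rate follows from mean R-R interval", {
  expect_equal(hrv_bpm(c(0, 200, 400), 200), 60)
  expect_equal(hrv_bpm(c(0, 100, 200), 200), 120)
  expect_error(hrv_bpm(c(100), 200), "at least 2")
  # periodic train recovers the generator rate to 3 decimals
  r <- seq(1, by = 150, length.out = 40)
  expect_equal(hrv_bpm(r, 200), 60 / 0.75, tolerance = 1e-9)
})

test_that("S-peak detection finds systolic peaks at the configured delay", {
  gen <- generate_session(synth_settings(duration_s = 30, seed = 3), 1.7)
  r <- detect_r_peaks(preprocess_ecg(gen$session))
  ppg <- ppg_wavelet_denoise(remove_powerline(gen$session$ppg_hand))
  s <- detect_s_peaks(ppg, r)
  expect_equal(length(s), length(r))
  matched <- !is.na(s)
  expect_gt(mean(matched), 0.9)
  # true PTT 0.2 s = 40 samples at 200 Hz
  expect_true(all(abs(s[matched] - r[matched] - 40) <= 2))
})

test_that("S-peak detection marks flat windows missing and handles empty input", {
  flat <- as_ppg(rep(1, 2000))
  s <- detect_s_peaks(flat, c(100, 500, 900))
  expect_true(all(is.na(s)))
  expect_identical(detect_s_peaks(flat, integer(0)), integer(0))
})

test_that("per-beat PTT arithmetic, missing beats and ordering errors", {
  ptt <- compute_ptt(c(0, 200), c(40, 241), 200)
  expect_equal(as.numeric(ptt), c(0.200, 0.205))
  expect_equal(attr(ptt, "n_used"), 2L)

  ptt2 <- compute_ptt(c(0, 200, 400), c(40, NA, 441), 200)
  expect_length(as.numeric(ptt2), 2)
  expect_equal(attr(ptt2, "beats"), c(1L, 3L))

  expect_error(compute_ptt(c(0, 200), c(40, 200), 200), "beat 2")
  expect_error(compute_ptt(c(0, 200), c(40,  41, 42), 200), "aligned")
})

test_that("PTT is invariant under a common time shift", {
  r <- c(10, 210, 410)
  s <- c(50, 251, 452)
  for (k in c(0, 7, 1000)) {
    expect_identical(as.numeric(compute_ptt(r + k, s + k, 200)),
                     as.numeric(compute_ptt(r, s, 200)))
  }
})

test_that("beat_series assembles and validates the landmark table", {
  bs <- beat_series(c(100, 300), c(140, NA), c(160, 360), 200)
  expect_s3_class(bs, "beat_series")
  expect_equal(bs$ptt_hand_s, c(0.2, NA))
  expect_equal(bs$ptt_foot_s, c(0.3, 0.3))
  expect_equal(bs$r_time_s, c(99, 299) / 200)
  expect_error(beat_series(c(300, 100), c(NA, NA), c(NA, NA), 200),
               "strictly increasing")
  expect_error(beat_series(c(100, 300), c(90, NA), c(NA, NA), 200),
               "follow its R-peak")
})
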