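test_that("notch mode attenuates mains by >= 20 dB and passes 1 Hz within 1%", {
  fs <- 200
  tt <- (0:17999) / fs
  rms <- function(v) sqrt(mean(v^2))

  hum <- as_ecg(sin(2 * pi * 50 * tt))
  out <- remove_powerline(hum, filter_settings())
  expect_lte(rms(out$values), 0.1 * rms(hum$values))

  slow <- as_ecg(sin(2 * pi * 1 * tt))
  out1 <- remove_powerline(slow, filter_settings())
  expect_lt(abs(rms(out1$values) / rms(slow$values) - 1), 0.01)

  zero <- as_ecg(rep(0, 4000))
  expect_equal(remove_powerline(zero, filter_settings())$values, rep(0, 4000))
})

test_that("notch is zero-phase: clean pulse landmark moves by <= 1 sample", {
  fs <- 200
  tt <- (0:7999) / fs
  pulse <- exp(-((tt - 20)^2) / (2 * 0.02^2))
  out <- remove_powerline(as_ecg(pulse), filter_settings())
  expect_lte(abs(which.max(out$values) - which.max(pulse)), 1)
})

test_that("literal high-pass mode removes the sub-50 Hz band as stated", {
  fs <- 200
  tt <- (0:7999) / fs
  st <- filter_settings(mode = "LITERAL_HIGHPASS")
  rms <- function(v) sqrt(mean(v^2))
  low <- remove_powerline(as_ecg(sin(2 * pi * 10 * tt)), st)
  expect_lt(rms(low$values), 0.05)           # 10 Hz almost entirely removed
  high <- remove_powerline(as_ecg(sin(2 * pi * 80 * tt)), st)
  expect_gt(rms(high$values) / rms(sin(2 * pi * 80 * tt)), 0.9)  # 80 Hz passes
})

test_that("powerline removal rejects too-low sampling rates", {
  s <- sampled_signal(rnorm(500), fs = 90, channel = "ECG", side = "RIGHT")
  expect_error(remove_powerline(s, filter_settings()), "too low")
})

test_that("ECG band reconstruction removes baseline drift and keeps linearity", {
  fs <- 200
  dur <- 40
  tt <- (0:(fs * dur - 1)) / fs
  beats <- seq(0.5, dur - 0.5, by = 1)
  qrs <- rowSums(vapply(beats, function(b) exp(-((tt - b)^2) / (2 * 0.02^2)),
                        numeric(length(tt))))
  drift <- 5 * sin(2 * pi * 0.2 * tt)   # 5x QRS amplitude, 0.2 Hz
  out <- ecg_wavelet_reconstruct(as_ecg(qrs + drift), filter_settings())
  # residual baseline: compare against the drift-free reconstruction
  ref <- ecg_wavelet_reconstruct(as_ecg(qrs), filter_settings())
  expect_lt(mean(abs(out$values - ref$values)), 0.05)

  zero <- as_ecg(rep(0, 1000))
  expect_equal(ecg_wavelet_reconstruct(zero)$values, rep(0, 1000))
  expect_error(ecg_wavelet_reconstruct(as_ecg(rnorm(8))), "too short")
})

test_that("polarity detection distinguishes upright and inverted QRS trains", {
  gen <- generate_session(synth_settings(duration_s = 40, seed = 5), 1.7)
  rec <- ecg_wavelet_reconstruct(remove_powerline(gen$session$ecg))
  expect_equal(detect_polarity(rec), "POSITIVE")
  flipped <- sampled_signal(-rec$values, rec$fs, "ECG", "RIGHT")
  expect_equal(detect_polarity(flipped), "NEGATIVE")
  expect_error(detect_polarity(as_ecg(rep(0, 100))), "indeterminate")
  expect_error(detect_polarity(as_ecg(rep(3, 100))), "indeterminate")
})

test_that("PPG denoising reduces noise and passes clean signals unchanged", {
  fs <- 200
  dur <- 30
  tt <- (0:(fs * dur - 1)) / fs
  beats <- seq(0.5, dur - 0.6, by = 1)
  rc <- function(u) ifelse(abs(u) <= 0.15, 0.5 * (1 + cos(2 * pi * u / 0.3)), 0)
  clean <- rowSums(vapply(beats + 0.2, function(b) rc(tt - b), numeric(length(tt))))

  set.seed(99)
  noisy <- clean + rnorm(length(clean), 0, sqrt(mean(clean^2)) * 10^(-10 / 20))
  den <- ppg_wavelet_denoise(as_ppg(noisy), filter_settings())
  rmse <- function(v) sqrt(mean((v - clean)^2))
  expect_lt(rmse(den$values), rmse(noisy))

  den_clean <- ppg_wavelet_denoise(as_ppg(clean), filter_settings())
  expect_gte(cor(den_clean$values, clean), 0.99)
  expect_equal(ppg_wavelet_denoise(as_ppg(rep(0, 1000)))$values, rep(0, 1000))
})

test_that("PPG universal soft-threshold denoise matches the reference values", {
  # frozen from an independent reference implementation (PyWavelets)
  x <- tone_mix_237()
  den <- ppg_wavelet_denoise(as_ppg(x), filter_settings())
  expect_equal(den$values[1:6],
    c(0.255825505995, 0.304171219628, 0.389728641416, 0.516463595161,
      0.652524021981, 0.823752603152), tolerance = 1e-8)
  expect_equal(sum(den$values^2), 142.193320649515, tolerance = 1e-7)
})

test_that("filter settings validate their domains", {
  expect_error(filter_settings(ecg_keep_details = c(2, 5)), "subset of 1..4")
  expect_error(filter_settings(ecg_keep_details = integer(0)), "subset")
  expect_error(filter_settings(wavelet_name = "sym99"), "unsupported")
  expect_s3_class(filter_settings(ecg_levels = 5, ecg_keep_details = 5),
                  "filter_settings")
})
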