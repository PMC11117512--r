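#' Synthetic session generator settings
#'
#' Parameters of the seeded ECG/PPG simulator. The waveform kernels are
#' deliberately simple — a Gaussian QRS spike and a raised-cosine systolic
#' pulse — because the measurement pipeline exploits only peak times; an
#' optional T-wave term is available to stress the R-detector. Defaults
#' reflect the nominal acquisition protocol: 200 Hz sampling, 90 s per side.
#'
#' @param fs Sampling rate in Hz (default 200).
#' @param duration_s Recording duration in seconds (default 90).
#' @param hr_bpm Mean heart rate in beats/min (default 60; allowed 30-220).
#' @param hrv_jitter_s SD in seconds of the zero-mean Gaussian perturbation
#'   of each R-R interval, truncated at three SDs (default 0.02).
#' @param ptt_hand_s,ptt_foot_s True transit times in seconds (defaults
#'   0.2 and 0.3; allowed (0.05, 0.6)).
#' @param qrs_amp QRS peak amplitude (default 1).
#' @param qrs_width_s Gaussian QRS half-width (SD) in seconds (default 0.02).
#' @param qrs_polarity `"POSITIVE"` or `"NEGATIVE"` (inverted lead).
#' @param ppg_pulse_width_s Full width in seconds of the raised-cosine
#'   systolic pulse (default 0.3); the pulse peaks exactly at beat + PTT.
#' @param t_wave_amp Amplitude of an optional T-wave bump 0.3 s after each
#'   R-peak (default 0 = off).
#' @param mains_amp Amplitude of additive 50 Hz mains interference (default 0).
#' @param wander_amp,wander_hz Amplitude and frequency of sinusoidal
#'   baseline wander (defaults 0 and 0.2 Hz).
#' @param noise_sigma SD of additive white Gaussian noise (default 0).
#' @param seed RNG seed; the generator is bit-reproducible given the seed.
#' @return Object of class `synth_settings`.
#' @export
synth_settings <- function(fs = 200, duration_s = 90, hr_bpm = 60,
                           hrv_jitter_s = 0.02, ptt_hand_s = 0.2,
                           ptt_foot_s = 0.3, qrs_amp = 1, qrs_width_s = 0.02,
                           qrs_polarity = c("POSITIVE", "NEGATIVE"),
                           ppg_pulse_width_s = 0.3, t_wave_amp = 0,
                           mains_amp = 0, wander_amp = 0, wander_hz = 0.2,
                           noise_sigma = 0, seed = 1) {
  qrs_polarity <- match.arg(qrs_polarity)
  if (!is.numeric(hr_bpm) || hr_bpm < 30 || hr_bpm > 220) {
    stop("hr_bpm must lie in [30, 220]")
  }
  for (p in c(ptt_hand_s, ptt_foot_s)) {
    if (!is.numeric(p) || p <= 0.05 || p >= 0.6) {
      stop("transit times must lie in (0.05, 0.6) s")
    }
  }
  amps <- c(qrs_amp, ppg_pulse_width_s, t_wave_amp, mains_amp, wander_amp,
            noise_sigma, hrv_jitter_s)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    stop("amplitudes, widths and noise scales must be finite and >= 0")
  }
  stopifnot(fs > 0, duration_s > 0, qrs_width_s > 0, wander_hz > 0)
  structure(list(fs = fs, duration_s = duration_s, hr_bpm = hr_bpm,
                 hrv_jitter_s = hrv_jitter_s, ptt_hand_s = ptt_hand_s,
                 ptt_foot_s = ptt_foot_s, qrs_amp = qrs_amp,
                 qrs_width_s = qrs_width_s, qrs_polarity = qrs_polarity,
                 ppg_pulse_width_s = ppg_pulse_width_s,
                 t_wave_amp = t_wave_amp, mains_amp = mains_amp,
                 wander_amp = wander_amp, wander_hz = wander_hz,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synth_settings")
}

# run expr with a private RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic recording session with ground truth
#'
#' Builds the three channels of one side: the ECG is a train of Gaussian
#' QRS spikes (sign per polarity) at jittered beat times, each PPG a train
#' of raised-cosine systolic pulses delayed by its configured transit time;
#' 50 Hz mains, sinusoidal baseline wander and white noise are added per
#' channel. The returned ground truth carries the exact beat and
#' systolic-peak times (independent of noise settings) and the closed-form
#' ABI implied by the settings, height and length model.
#'
#' @param settings A `synth_settings` object.
#' @param height_m Subject height in metres.
#' @param side `"RIGHT"` or `"LEFT"`.
#' @param model A `length_model` used for the closed-form truth.
#' @return List with `session` (a `recording_session`) and `truth` (list
#'   with `beat_times_s`, `s_hand_times_s`, `s_foot_times_s`, `true_abi`,
#'   `true_ptt_hand_s`, `true_ptt_foot_s`).
#' @examples
#' gen <- generate_session(synth_settings(duration_s = 35), height_m = 1.7)
#' gen$truth$true_abi
#' @export
generate_session <- function(settings, height_m, side = c("RIGHT", "LEFT"),
                             model = default_length_model()) {
  stopifnot(inherits(settings, "synth_settings"))
  side <- match.arg(side)
  s <- settings
  n <- round(s$fs * s$duration_s)
  tt <- (seq_len(n) - 1) / s$fs

  .with_seed(s$seed, {
    rr <- 60 / s$hr_bpm
    beats <- numeric(0)
    t <- 0.5
    margin <- max(s$ptt_foot_s, s$ptt_hand_s) + s$ppg_pulse_width_s / 2
    while (t < s$duration_s - margin) {
      beats <- c(beats, t)
      jit <- stats::rnorm(1, 0, s$hrv_jitter_s)
      jit <- max(-3 * s$hrv_jitter_s, min(3 * s$hrv_jitter_s, jit))
      t <- t + max(rr + jit, 0.26)  # preserve the refractory bound
    }
    if (length(beats) < 2L) stop("settings produce fewer than 2 beats")

    kernel_sum <- function(centers, fun) {
      y <- numeric(n)
      for (b in centers) y <- y + fun(tt - b)
      y
    }
    gauss <- function(u) s$qrs_amp * exp(-u^2 / (2 * s$qrs_width_s^2))
    ecg <- kernel_sum(beats, gauss)
    if (s$t_wave_amp > 0) {
      twave <- function(u) s$t_wave_amp * exp(-(u - 0.3)^2 / (2 * 0.06^2))
      ecg <- ecg + kernel_sum(beats, twave)
    }
    if (s$qrs_polarity == "NEGATIVE") ecg <- -ecg
    rc <- function(u) {
      ifelse(abs(u) <= s$ppg_pulse_width_s / 2,
             0.5 * (1 + cos(2 * pi * u / s$ppg_pulse_width_s)), 0)
    }
    ppg_h <- kernel_sum(beats + s$ptt_hand_s, rc)
    ppg_f <- kernel_sum(beats + s$ptt_foot_s, rc)

    contaminate <- function(x, phase) {
      x + s$mains_amp * sin(2 * pi * 50 * tt + phase) +
        s$wander_amp * sin(2 * pi * s$wander_hz * tt + phase / 2) +
        if (s$noise_sigma > 0) stats::rnorm(n, 0, s$noise_sigma) else 0
    }
    ecg <- contaminate(ecg, 0)
    ppg_h <- contaminate(ppg_h, 1)
    ppg_f <- contaminate(ppg_f, 2)
  })

  session <- recording_session(
    sampled_signal(ecg, s$fs, "ECG", side),
    sampled_signal(ppg_h, s$fs, "PPG_HAND", side),
    sampled_signal(ppg_f, s$fs, "PPG_FOOT", side),
    height_m = height_m, side = side
  )
  len <- composite_lengths(model, height_m)
  l_hand <- if (side == "RIGHT") len$ra_m else len$la_m
  l_foot <- if (side == "RIGHT") len$arf_m else len$alf_m
  truth <- list(
    beat_times_s = beats,
    s_hand_times_s = beats + s$ptt_hand_s,
    s_foot_times_s = beats + s$ptt_foot_s,
    true_ptt_hand_s = s$ptt_hand_s,
    true_ptt_foot_s = s$ptt_foot_s,
    true_abi = (l_foot / s$ptt_foot_s) / (l_hand / s$ptt_hand_s)
  )
  list(session = session, truth = truth)
}

#' Sweep the pipeline over a grid of true transit times
#'
#' Generates one synthetic session per grid cell, runs [process_session()]
#' and tabulates the recovered against the closed-form true ABI.
#'
#' @param ptt_hand_grid,ptt_foot_grid Numeric vectors of true transit times
#'   in seconds; the sweep runs over their Cartesian product.
#' @param height_m Subject height in metres.
#' @param side `"RIGHT"` or `"LEFT"`.
#' @param base_settings A `synth_settings` whose non-PTT fields (noise,
#'   duration, heart rate, seed) apply to every cell; the cell seed is
#'   `seed + cell index - 1`.
#' @param filter,detector,model Pipeline settings, as in [process_session()].
#' @param csv_path Optional path; when given, the result table is written
#'   as CSV.
#' @return Data frame with columns `ptt_hand_s`, `ptt_foot_s`, `seed`,
#'   `true_abi`, `recovered_abi`, `abs_error`.
#' @export
sweep_abi <- function(ptt_hand_grid, ptt_foot_grid, height_m = 1.7,
                      side = "RIGHT", base_settings = synth_settings(),
                      filter = filter_settings(),
                      detector = detector_settings(),
                      model = default_length_model(), csv_path = NULL) {
  if (length(ptt_hand_grid) == 0L || length(ptt_foot_grid) == 0L) {
    stop("the sweep grid must be non-empty")
  }
  grid <- expand.grid(ptt_hand_s = ptt_hand_grid, ptt_foot_s = ptt_foot_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    st <- base_settings
    st$ptt_hand_s <- grid$ptt_hand_s[i]
    st$ptt_foot_s <- grid$ptt_foot_s[i]
    st$seed <- base_settings$seed + i - 1L
    gen <- generate_session(st, height_m, side, model)
    out <- process_session(gen$session, filter, detector, model)
    res[[i]] <- data.frame(
      ptt_hand_s = st$ptt_hand_s, ptt_foot_s = st$ptt_foot_s, seed = st$seed,
      true_abi = gen$truth$true_abi, recovered_abi = out$abi,
      abs_error = abs(out$abi - gen$truth$true_abi)
    )
  }
  tab <- do.call(rbind, res)
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  tab
}

#' Noise level for a target signal-to-noise ratio
#'
#' Converts a target SNR in dB into the white-noise standard deviation to
#' use in [synth_settings()]. SNR is referenced to the mean power of the
#' clean QRS train, which for non-overlapping Gaussian spikes is
#' `qrs_amp^2 * qrs_width_s * sqrt(pi) / RR`.
#'
#' @param settings A `synth_settings` object supplying QRS amplitude, width
#'   and heart rate.
#' @param snr_db Target signal-to-noise ratio in decibels.
#' @return Noise standard deviation.
#' @examples
#' noise_sigma_for_snr(synth_settings(), 10)
#' @export
noise_sigma_for_snr <- function(settings, snr_db) {
  stopifnot(inherits(settings, "synth_settings"), is.numeric(snr_db))
  rms <- settings$qrs_amp *
    sqrt(settings$qrs_width_s * sqrt(pi) * settings$hr_bpm / 60)
  rms * 10^(-snr_db / 20)
}
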