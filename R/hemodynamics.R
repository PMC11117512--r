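#' Pulse wave velocity
#'
#' @param length_m Arterial path length(s) in metres (> 0).
#' @param ptt_s Pulse transit time(s) in seconds (> 0).
#' @return Velocity `length_m / ptt_s` in m/s.
#' @export
pwv <- function(length_m, ptt_s) {
  if (any(!is.finite(length_m)) || any(length_m <= 0)) {
    stop("length_m must be positive and finite")
  }
  if (any(!is.finite(ptt_s)) || any(ptt_s <= 0)) {
    stop("ptt_s must be positive and finite")
  }
  length_m / ptt_s
}

#' Per-beat ankle-brachial index
#'
#' The ABI of one beat is the foot-to-hand pulse wave velocity ratio,
#' algebraically `(length_foot * ptt_hand) / (length_hand * ptt_foot)`.
#'
#' @param pwv_foot,pwv_hand Pulse wave velocities in m/s (> 0).
#' @return Dimensionless ratio `pwv_foot / pwv_hand`.
#' @export
abi_per_beat <- function(pwv_foot, pwv_hand) {
  if (any(!is.finite(pwv_foot)) || any(pwv_foot <= 0) ||
      any(!is.finite(pwv_hand)) || any(pwv_hand <= 0)) {
    stop("pulse wave velocities must be positive and finite")
  }
  pwv_foot / pwv_hand
}

#' Windowed ABI summary
#'
#' The reported ABI is the arithmetic mean of the per-beat ABI values inside
#' one contiguous window (default: the first `window_s` seconds of usable
#' beats, optionally shifted by `start_offset_s` to emulate the operator's
#' interval choice).
#'
#' @param per_beat_abi Per-beat ABI values.
#' @param beat_times_s Beat times in seconds, aligned with `per_beat_abi`.
#' @param window_s Averaging window in seconds (default 30).
#' @param start_offset_s Offset of the window start from the first usable
#'   beat, in seconds (default 0).
#' @return Mean ABI over the window, with attribute `n_beats_used`.
#' @export
abi_summary <- function(per_beat_abi, beat_times_s, window_s = 30,
                        start_offset_s = 0) {
  if (length(per_beat_abi) != length(beat_times_s)) {
    stop("per_beat_abi and beat_times_s must be aligned")
  }
  if (length(per_beat_abi) == 0L) stop("no usable beats")
  if (diff(range(beat_times_s)) < window_s) {
    stop("insufficient duration: beats span ",
         sprintf("%.1f", diff(range(beat_times_s))),
         " s but the averaging window is ", window_s, " s")
  }
  t0 <- min(beat_times_s) + start_offset_s
  sel <- beat_times_s >= t0 & beat_times_s <= t0 + window_s
  if (!any(sel)) stop("no beats fall inside the selected window")
  structure(mean(per_beat_abi[sel]), n_beats_used = sum(sel))
}

#' End-to-end per-side ABI pipeline
#'
#' Runs the full measurement chain on one recording session: powerline
#' removal on all channels, wavelet band reconstruction and polarity
#' correction of the ECG, wavelet denoising of both PPG channels, R- and
#' S-peak detection, per-beat transit times, height-derived path lengths,
#' per-beat pulse wave velocities and ABI, and the windowed ABI mean.
#' Deterministic given inputs and settings.
#'
#' @param session A `recording_session`.
#' @param filter A `filter_settings` object.
#' @param detector A `detector_settings` object.
#' @param model A `length_model`.
#' @param window_s ABI averaging window in seconds (default 30).
#' @param start_offset_s Window start offset in seconds (default 0).
#' @return Object of class `side_result`: list with `side`, `abi`,
#'   `hrv_bpm`, `mean_ptt_hand_s`, `mean_ptt_foot_s`, `pwv_hand_ms`,
#'   `pwv_foot_ms`, `n_beats_used`, `window_s`, `reportable` and `flags`,
#'   plus the `beats` landmark table.
#' @examples
#' \donttest{
#' gen <- generate_session(synth_settings(duration_s = 40, seed = 7), height_m = 1.7)
#' process_session(gen$session)
#' }
#' @export
process_session <- function(session, filter = filter_settings(),
                            detector = detector_settings(),
                            model = default_length_model(),
                            window_s = 30, start_offset_s = 0) {
  stopifnot(inherits(session, "recording_session"))
  if (signal_duration(session$ecg) < window_s) {
    stop("stage session: insufficient duration (",
         sprintf("%.1f", signal_duration(session$ecg)),
         " s recorded, ", window_s, " s required)")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  ecg <- stage("powerline", remove_powerline(session$ecg, filter))
  ph <- stage("powerline", remove_powerline(session$ppg_hand, filter))
  pf <- stage("powerline", remove_powerline(session$ppg_foot, filter))
  ecg <- stage("ecg_wavelet", ecg_wavelet_reconstruct(ecg, filter))
  pol <- stage("polarity", detect_polarity(ecg))
  if (pol == "NEGATIVE") ecg <- with_values(ecg, -ecg$values)
  ph <- stage("ppg_wavelet", ppg_wavelet_denoise(ph, filter))
  pf <- stage("ppg_wavelet", ppg_wavelet_denoise(pf, filter))
  r_idx <- stage("r_peaks", detect_r_peaks(ecg, detector))
  if (length(r_idx) < 2L) {
    stop("stage r_peaks: fewer than 2 R-peaks detected; cannot continue")
  }
  s_hand <- stage("s_peaks", detect_s_peaks(ph, r_idx, detector))
  s_foot <- stage("s_peaks", detect_s_peaks(pf, r_idx, detector))
  beats <- stage("beats", beat_series(r_idx, s_hand, s_foot, session$ecg$fs))
  hr <- stage("hrv", hrv_bpm(r_idx, session$ecg$fs))
  len <- stage("anatomy", composite_lengths(model, session$height_m))
  l_hand <- if (session$side == "RIGHT") len$ra_m else len$la_m
  l_foot <- if (session$side == "RIGHT") len$arf_m else len$alf_m

  # per-beat ABI needs both S-points on the same beat
  both <- !is.na(s_hand) & !is.na(s_foot)
  if (!any(both)) stop("stage abi: no beat has both hand and foot S-points")
  ptt_h <- (s_hand[both] - r_idx[both]) / session$ecg$fs
  ptt_f <- (s_foot[both] - r_idx[both]) / session$ecg$fs
  pwv_h <- pwv(l_hand, ptt_h)
  pwv_f <- pwv(l_foot, ptt_f)
  abi_beats <- abi_per_beat(pwv_f, pwv_h)
  beat_t <- (r_idx[both] - 1) / session$ecg$fs
  abi <- stage("abi_summary",
               abi_summary(abi_beats, beat_t, window_s, start_offset_s))
  n_used <- attr(abi, "n_beats_used")
  win <- beat_t >= min(beat_t) + start_offset_s &
         beat_t <= min(beat_t) + start_offset_s + window_s
  flags <- character(0)
  mean_pwv_h <- mean(pwv_h[win])
  mean_pwv_f <- mean(pwv_f[win])
  if (mean_pwv_h < 0.5 || mean_pwv_h > 30 || mean_pwv_f < 0.5 || mean_pwv_f > 30) {
    flags <- c(flags, "pwv_out_of_physiological_range")
  }
  reportable <- n_used >= 10L
  if (!reportable) flags <- c(flags, "fewer_than_10_beats")
  structure(list(
    side = session$side,
    abi = as.numeric(abi),
    hrv_bpm = hr,
    mean_ptt_hand_s = mean(ptt_h[win]),
    mean_ptt_foot_s = mean(ptt_f[win]),
    pwv_hand_ms = mean_pwv_h,
    pwv_foot_ms = mean_pwv_f,
    n_beats_used = n_used,
    window_s = window_s,
    reportable = reportable,
    flags = flags,
    beats = beats
  ), class = "side_result")
}

#' @export
print.side_result <- function(x, ...) {
  cat(sprintf("<side_result> side %s\n", x$side))
  cat(sprintf("  ABI            %.3f  (%d beats over %g s%s)\n",
              x$abi, x$n_beats_used, x$window_s,
              if (x$reportable) "" else "; NOT reportable"))
  cat(sprintf("  heart rate     %.1f bpm\n", x$hrv_bpm))
  cat(sprintf("  PTT hand/foot  %.3f / %.3f s\n",
              x$mean_ptt_hand_s, x$mean_ptt_foot_s))
  cat(sprintf("  PWV hand/foot  %.2f / %.2f m/s\n",
              x$pwv_hand_ms, x$pwv_foot_ms))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a side result to JSON
#'
#' @param result A `side_result`.
#' @return JSON string with the scalar summary fields.
#' @export
side_result_to_json <- function(result) {
  stopifnot(inherits(result, "side_result"))
  keep <- c("side", "abi", "hrv_bpm", "mean_ptt_hand_s", "mean_ptt_foot_s",
            "pwv_hand_ms", "pwv_foot_ms", "n_beats_used", "window_s",
            "reportable", "flags")
  as.character(jsonlite::toJSON(result[keep], auto_unbox = TRUE, digits = NA))
}
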