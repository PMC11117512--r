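#' Landmark detector settings
#'
#' @param threshold_frac Fraction of the rolling amplitude reference a local
#'   maximum must exceed to count as an R-peak (default 0.6).
#' @param refractory_s Minimum R-R interval in seconds (default 0.25, i.e.
#'   at most 240 bpm).
#' @param min_delay_s Earliest admissible S-point after its R-peak in
#'   seconds (default 0.05), skipping the ECG-coincident artifact region.
#' @param window_s Width in seconds of the rolling window over which the
#'   amplitude reference (99th percentile of |values|) is taken (default 2).
#' @return Object of class `detector_settings`.
#' @export
detector_settings <- function(threshold_frac = 0.6, refractory_s = 0.25,
                              min_delay_s = 0.05, window_s = 2) {
  stopifnot(is.numeric(threshold_frac), length(threshold_frac) == 1L,
            threshold_frac > 0, threshold_frac < 1,
            is.numeric(refractory_s), length(refractory_s) == 1L, refractory_s > 0,
            is.numeric(min_delay_s), length(min_delay_s) == 1L, min_delay_s >= 0,
            is.numeric(window_s), length(window_s) == 1L, window_s > 0)
  structure(list(threshold_frac = threshold_frac, refractory_s = refractory_s,
                 min_delay_s = min_delay_s, window_s = window_s),
            class = "detector_settings")
}

#' Detect R-peaks on a preprocessed ECG
#'
#' An R-peak is a local maximum exceeding `threshold_frac` times the 99th
#' percentile of `|values|` in the surrounding `window_s` seconds. Candidates
#' are accepted in order of decreasing amplitude subject to the refractory
#' constraint, so no two returned peaks are closer than
#' `refractory_s * fs` samples. On a plateau the earlier sample wins.
#'
#' @param ecg A `sampled_signal`, preprocessed and polarity-corrected.
#' @param settings A `detector_settings` object.
#' @return Increasing integer vector of 1-based sample indices (possibly
#'   empty).
#' @export
detect_r_peaks <- function(ecg, settings = detector_settings()) {
  stopifnot(inherits(ecg, "sampled_signal"), inherits(settings, "detector_settings"))
  x <- ecg$values
  n <- length(x)
  if (n < 3L) return(integer(0))
  # local maxima with ties broken toward the earlier sample
  is_max <- x[2:(n - 1L)] > x[3:n] & x[2:(n - 1L)] >= x[1:(n - 2L)]
  cand <- which(is_max) + 1L
  cand <- cand[x[cand] > 0]
  if (length(cand) == 0L) return(integer(0))
  half <- max(1L, round(settings$window_s * ecg$fs / 2))
  ax <- abs(x)
  thr <- vapply(cand, function(i) {
    # keep the full window width near the edges by shifting it inward
    lo <- max(1L, min(i - half, n - 2L * half))
    hi <- min(n, lo + 2L * half)
    settings$threshold_frac * stats::quantile(ax[lo:hi], 0.99, names = FALSE)
  }, numeric(1))
  cand <- cand[x[cand] > thr]
  if (length(cand) == 0L) return(integer(0))
  refr <- settings$refractory_s * ecg$fs
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L || all(abs(kept - i) >= refr)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Heart rate from R-peak indices
#'
#' @param r_indices Increasing sample indices of R-peaks (at least 2).
#' @param fs Sampling rate in Hz.
#' @return Heart rate in beats per minute, `60 / mean(R-R)` with R-R in
#'   seconds.
#' @export
hrv_bpm <- function(r_indices, fs) {
  if (length(r_indices) < 2L) {
    stop("at least 2 R-peaks are required to compute a heart rate")
  }
  60 / mean(diff(r_indices) / fs)
}

#' Detect PPG systolic peaks (S-points) guided by ECG R-peaks
#'
#' For each R-peak at index `r` with successor `r'`, the S-point is the
#' argmax of the PPG strictly inside the window
#' `(r + min_delay_s * fs, r')`. A beat is marked missing (`NA`) when the
#' window contains no interior local maximum (e.g. a flat trace or a maximum
#' pinned to the window edge). The last beat's window extends by the median
#' R-R interval.
#'
#' @param ppg A denoised `sampled_signal`.
#' @param r_indices R-peak indices from the simultaneous ECG.
#' @param settings A `detector_settings` object.
#' @return Integer vector the same length as `r_indices`; `NA` marks a
#'   missing S-point.
#' @export
detect_s_peaks <- function(ppg, r_indices, settings = detector_settings()) {
  stopifnot(inherits(ppg, "sampled_signal"), inherits(settings, "detector_settings"))
  nr <- length(r_indices)
  if (nr == 0L) return(integer(0))
  x <- ppg$values
  n <- length(x)
  med_rr <- if (nr >= 2L) stats::median(diff(r_indices)) else round(ppg$fs)
  delay <- round(settings$min_delay_s * ppg$fs)
  out <- rep(NA_integer_, nr)
  for (k in seq_len(nr)) {
    r <- r_indices[k]
    nxt <- if (k < nr) r_indices[k + 1L] else r + med_rr
    lo <- r + delay + 1L
    hi <- min(nxt - 1L, n)
    if (hi - lo < 2L) next
    w <- x[lo:hi]
    j <- which.max(w)
    idx <- lo + j - 1L
    if (j == 1L || j == length(w)) next               # pinned to window edge
    if (!(x[idx] > x[idx - 1L] || x[idx] > x[idx + 1L])) next  # flat
    out[k] <- idx
  }
  out
}

#' Per-beat pulse transit times
#'
#' `PTT_i = (s_i - r_i) / fs` for each beat whose S-point was found; beats
#' with a missing S-point are excluded.
#'
#' @param r_indices R-peak indices.
#' @param s_indices S-point indices aligned to `r_indices` (`NA` = missing).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of transit times in seconds for the usable beats,
#'   with attributes `beats` (positions within `r_indices`) and `n_used`.
#' @export
compute_ptt <- function(r_indices, s_indices, fs) {
  if (length(r_indices) != length(s_indices)) {
    stop("r_indices and s_indices must be aligned (equal length)")
  }
  usable <- which(!is.na(s_indices))
  bad <- usable[s_indices[usable] <= r_indices[usable]]
  if (length(bad) > 0L) {
    stop("S-point does not follow its R-peak at beat ", bad[1L])
  }
  ptt <- (s_indices[usable] - r_indices[usable]) / fs
  structure(as.numeric(ptt), beats = usable, n_used = length(usable))
}

#' Assemble a per-beat landmark table
#'
#' @param r_indices R-peak indices.
#' @param s_indices_hand,s_indices_foot S-point indices aligned to
#'   `r_indices` (`NA` allowed).
#' @param fs Sampling rate in Hz.
#' @return Object of class `beat_series`: a data frame with one row per beat
#'   (beat, r_index, r_time_s, s_hand_index, s_foot_index, s_hand_time_s,
#'   s_foot_time_s, ptt_hand_s, ptt_foot_s) and attribute `fs`.
#' @export
beat_series <- function(r_indices, s_indices_hand, s_indices_foot, fs) {
  nr <- length(r_indices)
  if (nr > 1L && any(diff(r_indices) <= 0)) stop("r_indices must be strictly increasing")
  if (length(s_indices_hand) != nr || length(s_indices_foot) != nr) {
    stop("S-index vectors must be aligned to r_indices")
  }
  tm <- function(i) (i - 1) / fs
  df <- data.frame(
    beat = seq_len(nr),
    r_index = as.integer(r_indices),
    r_time_s = tm(r_indices),
    s_hand_index = as.integer(s_indices_hand),
    s_foot_index = as.integer(s_indices_foot),
    s_hand_time_s = tm(s_indices_hand),
    s_foot_time_s = tm(s_indices_foot),
    ptt_hand_s = (s_indices_hand - r_indices) / fs,
    ptt_foot_s = (s_indices_foot - r_indices) / fs
  )
  ok <- function(s) is.na(s) | s > r_indices
  if (!all(ok(s_indices_hand)) || !all(ok(s_indices_foot))) {
    stop("every matched S-point must follow its R-peak")
  }
  attr(df, "fs") <- fs
  class(df) <- c("beat_series", "data.frame")
  df
}
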