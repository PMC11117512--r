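#' Uniformly sampled physiological signal
#'
#' Container for one uniformly sampled channel: an ECG lead or a PPG trace
#' from the index fingertip or hallux. Sample `i` (1-based) is at time
#' `t0 + (i - 1) / fs` seconds.
#'
#' @param values Numeric vector of finite sample values (arbitrary units);
#'   length >= 1.
#' @param fs Sampling rate in Hz; default 200.
#' @param channel Channel role: `"ECG"`, `"PPG_HAND"` or `"PPG_FOOT"`.
#' @param side Body side: `"RIGHT"` or `"LEFT"`.
#' @param t0 Start-time offset in seconds (default 0), available for manual
#'   alignment of the two acquisition devices.
#' @return Object of class `sampled_signal`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 1 * (0:399) / 200), fs = 200,
#'                     channel = "ECG", side = "RIGHT")
#' signal_duration(s)
#' @export
sampled_signal <- function(values, fs = 200, channel = c("ECG", "PPG_HAND", "PPG_FOOT"),
                           side = c("RIGHT", "LEFT"), t0 = 0) {
  channel <- match.arg(channel)
  side <- match.arg(side)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("a sampled_signal needs at least one sample")
  if (!all(is.finite(values))) stop("all sample values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)")
  }
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0)) {
    stop("t0 must be a single finite number (seconds)")
  }
  structure(list(values = values, fs = fs, channel = channel, side = side, t0 = t0),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %s (%s), %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              x$channel, x$side, length(x$values), x$fs,
              signal_duration(x), x$t0))
  invisible(x)
}

#' Duration of a sampled signal in seconds
#'
#' @param x A `sampled_signal`.
#' @return Duration `(length - 1) / fs` in seconds.
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  (length(x$values) - 1) / x$fs
}

#' Sample times of a signal
#'
#' @param x A `sampled_signal`.
#' @return Numeric vector of times `t0 + (i - 1) / fs` in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

# Replace the values of a signal, keeping its metadata.
with_values <- function(x, values) {
  sampled_signal(values, fs = x$fs, channel = x$channel, side = x$side, t0 = x$t0)
}

#' One-side recording session
#'
#' Bundles the three clock-synchronised channels acquired on one body side
#' (ECG on the chest, PPG on the index fingertip, PPG on the hallux) with the
#' subject's height. Nominal acquisition is 90 s per side; at least 30 s is
#' required for an ABI summary.
#'
#' @param ecg,ppg_hand,ppg_foot `sampled_signal` objects sharing `fs` and
#'   `side`, with channel roles `"ECG"`, `"PPG_HAND"`, `"PPG_FOOT"`.
#' @param height_m Subject height in metres.
#' @param side Body side; must match the signals'.
#' @return Object of class `recording_session`.
#' @export
recording_session <- function(ecg, ppg_hand, ppg_foot, height_m,
                              side = c("RIGHT", "LEFT")) {
  side <- match.arg(side)
  for (s in list(ecg, ppg_hand, ppg_foot)) {
    if (!inherits(s, "sampled_signal")) stop("all channels must be sampled_signal objects")
  }
  if (ecg$channel != "ECG" || ppg_hand$channel != "PPG_HAND" ||
      ppg_foot$channel != "PPG_FOOT") {
    stop("channel roles must be ECG / PPG_HAND / PPG_FOOT in that order")
  }
  if (length(unique(c(ecg$fs, ppg_hand$fs, ppg_foot$fs))) != 1L) {
    stop("all channels must share the same sampling rate")
  }
  if (any(c(ecg$side, ppg_hand$side, ppg_foot$side) != side)) {
    stop("all channels must be recorded on side ", side)
  }
  if (!is.numeric(height_m) || length(height_m) != 1L || !is.finite(height_m) ||
      height_m <= 0) {
    stop("height_m must be a single positive number (metres)")
  }
  structure(list(ecg = ecg, ppg_hand = ppg_hand, ppg_foot = ppg_foot,
                 height_m = height_m, side = side),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> side %s, fs %g Hz, %.1f s, height %.3f m\n",
              x$side, x$ecg$fs, signal_duration(x$ecg), x$height_m))
  invisible(x)
}

#' Read a sample stream from a plain-text/CSV file
#'
#' One numeric sample per row. Comma- or whitespace-separated; an optional
#' single header line and an optional leading timestamp column are detected
#' and dropped automatically.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz (caller metadata; default 200).
#' @param channel,side Channel role and body side of the stream.
#' @param t0 Start-time offset in seconds.
#' @return A `sampled_signal` with the file's values in order.
#' @export
read_signal_stream <- function(path, fs = 200,
                               channel = c("ECG", "PPG_HAND", "PPG_FOOT"),
                               side = c("RIGHT", "LEFT"), t0 = 0) {
  channel <- match.arg(channel)
  side <- match.arg(side)
  if (!file.exists(path)) stop("signal file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- which(nzchar(trimws(lines)))
  if (length(rows) == 0L) stop("empty signal file: ", path)
  split_row <- function(ln) {
    ln <- trimws(ln)
    if (grepl(",", ln, fixed = TRUE)) trimws(strsplit(ln, ",", fixed = TRUE)[[1L]])
    else strsplit(ln, "[[:space:]]+")[[1L]]
  }
  toks <- lapply(lines[rows], split_row)
  first_numeric <- !anyNA(suppressWarnings(as.numeric(toks[[1L]])))
  if (!first_numeric) {  # header line
    rows <- rows[-1L]
    toks <- toks[-1L]
    if (length(rows) == 0L) stop("signal file ", path, " contains only a header")
  }
  ncols <- lengths(toks)
  if (any(ncols != ncols[1L])) {
    bad <- rows[which(ncols != ncols[1L])[1L]]
    stop("inconsistent column count at row ", bad, " of ", path)
  }
  if (ncols[1L] > 2L) stop("expected 1 or 2 columns (optional timestamp + value) in ", path)
  vals_chr <- vapply(toks, function(tk) tk[length(tk)], character(1))
  vals <- suppressWarnings(as.numeric(vals_chr))
  if (anyNA(vals)) {
    bad <- rows[which(is.na(vals))[1L]]
    stop("non-numeric sample at row ", bad, " of ", path)
  }
  sampled_signal(vals, fs = fs, channel = channel, side = side, t0 = t0)
}

#' Write a sample stream to a plain-text file
#'
#' One sample per line at full double precision, so a round trip through
#' [read_signal_stream()] reproduces the values exactly.
#'
#' @param signal A `sampled_signal`.
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
write_signal_stream <- function(signal, path) {
  stopifnot(inherits(signal, "sampled_signal"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(sprintf("%.17g", signal$values), con)
  invisible(path)
}

#' Load the embedded 22-subject validation table
#'
#' The validation cohort: 22 diabetic subjects (9 female, 13 male) with
#' demographics and ABI values per side from both the traditional
#' Doppler/sphygmomanometer method and the PWV-based system. Subject 11's
#' traditional readings were incompressible-artery results reported only as
#' ">1.30"; they are stored numerically as 1.30 with `trad_censored = TRUE`.
#'
#' @param path Optional override of the embedded CSV (same column layout:
#'   subject_id, sex, age, weight_kg, height_m, abi_trad_right,
#'   abi_trad_left, abi_sys_right, abi_sys_left, trad_censored).
#' @return Data frame of class `subject_table` with 22 rows.
#' @examples
#' t1 <- load_table1()
#' table(t1$sex)
#' @export
load_table1 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_subjects.csv", package = "abipwv",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("subject_id", "sex", "age", "weight_kg", "height_m",
                "abi_trad_right", "abi_trad_left", "abi_sys_right",
                "abi_sys_left", "trad_censored")
  if (!identical(names(df), expected)) {
    stop("subject table has unexpected columns: ", paste(names(df), collapse = ", "))
  }
  if (nrow(df) != 22L) stop("subject table must have 22 records, found ", nrow(df))
  abis <- unlist(df[, c("abi_trad_right", "abi_trad_left",
                        "abi_sys_right", "abi_sys_left")])
  if (any(abis <= 0 | abis >= 2)) stop("ABI values outside (0, 2) in subject table")
  if (any(df$height_m < 1.4 | df$height_m > 2.0)) {
    stop("subject heights outside [1.4, 2.0] m")
  }
  if (!identical(which(df$trad_censored), 11L)) {
    stop("censoring flag must be set for subject 11 only")
  }
  class(df) <- c("subject_table", "data.frame")
  df
}
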