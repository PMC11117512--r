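#' Discrete wavelet transform machinery
#'
#' Minimal orthogonal discrete wavelet transform (DWT) with symmetric
#' (half-point, edge-replicating) boundary extension, plus the zero-phase
#' band transfer functions of the undecimated (maximal-overlap) transform.
#' Conventions match the usual symmetric-mode DWT: one decomposition level
#' maps a length-n signal to approximation/detail vectors of length
#' `floor((n + L - 1) / 2)` where `L` is the filter length, and the inverse
#' reconstructs the original samples exactly.
#'
#' @name wavelet
#' @keywords internal
NULL

# Orthonormal decomposition low-pass filters. The high-pass and the two
# reconstruction filters follow from the quadrature-mirror relations.
.wavelet_dec_lo <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  sym4 = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
           0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
           -0.01260396726203783, 0.03222310060404270)
)

#' Filter bank for a named orthogonal wavelet
#'
#' @param wavelet Wavelet name, one of `"sym4"`, `"db4"`, `"haar"`.
#' @return List with elements `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`
#'   (numeric filter taps) and `len` (filter length).
#' @export
wavelet_filters <- function(wavelet = "sym4") {
  if (!is.character(wavelet) || length(wavelet) != 1L ||
      !wavelet %in% names(.wavelet_dec_lo)) {
    stop("unsupported wavelet '", paste(wavelet, collapse = ","),
         "'; available: ", paste(names(.wavelet_dec_lo), collapse = ", "))
  }
  lo <- .wavelet_dec_lo[[wavelet]]
  hi <- rev(lo) * rep(c(-1, 1), length.out = length(lo))
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi),
       len = length(lo))
}

# Map arbitrary (possibly out-of-range) 1-based positions onto valid indices
# by half-point symmetric reflection with the edge sample repeated.
.sym_reflect <- function(i, n) {
  p <- (i - 1L) %% (2L * n)
  p <- ifelse(p < 0L, p + 2L * n, p)
  ifelse(p < n, p + 1L, 2L * n - p)
}

#' Single-level DWT with symmetric extension
#'
#' @param x Numeric vector, `length(x) >= 2`.
#' @param wavelet Wavelet name (see [wavelet_filters()]).
#' @return List with approximation `ca` and detail `cd` coefficient vectors,
#'   each of length `floor((length(x) + L - 1) / 2)`.
#' @export
wavelet_dwt <- function(x, wavelet = "sym4") {
  fb <- wavelet_filters(wavelet)
  n <- length(x)
  if (n < 2L) stop("signal too short for a wavelet decomposition (length ", n, ")")
  L <- fb$len
  ext <- x[.sym_reflect(seq.int(-(L - 2L), n + L - 1L), n)]
  nc <- (n + L - 1L) %/% 2L
  ca <- numeric(nc)
  cd <- numeric(nc)
  for (k in seq_len(nc)) {
    seg <- ext[2L * k + L - seq_len(L)]
    ca[k] <- sum(fb$dec_lo * seg)
    cd[k] <- sum(fb$dec_hi * seg)
  }
  list(ca = ca, cd = cd)
}

#' Single-level inverse DWT
#'
#' @param ca,cd Approximation and detail coefficients from [wavelet_dwt()].
#' @param out_len Length of the reconstructed signal.
#' @param wavelet Wavelet name.
#' @return Numeric vector of length `out_len`.
#' @export
wavelet_idwt <- function(ca, cd, out_len, wavelet = "sym4") {
  fb <- wavelet_filters(wavelet)
  if (length(ca) != length(cd)) stop("ca and cd must have equal length")
  L <- fb$len
  up <- function(cc) {
    u <- numeric(2L * length(cc) - 1L)
    u[seq(1L, length(u), 2L)] <- cc
    u
  }
  y <- convolve(up(ca), rev(fb$rec_lo), type = "open") +
       convolve(up(cd), rev(fb$rec_hi), type = "open")
  y <- y[(L - 1L):(length(y) - (L - 2L))]
  if (out_len > length(y)) stop("out_len exceeds reconstructable length")
  y[seq_len(out_len)]
}

#' Multilevel DWT decomposition
#'
#' @param x Numeric vector with `length(x) >= 2^level`.
#' @param level Decomposition depth.
#' @param wavelet Wavelet name.
#' @return Object of class `wavelet_dec`: a list with `coefs` (element 1 the
#'   level-`level` approximation, then details from coarsest, level `level`,
#'   down to level 1), `lens` (bookkeeping lengths for exact reconstruction),
#'   `level` and `wavelet`.
#' @export
wavelet_wavedec <- function(x, level, wavelet = "sym4") {
  level <- as.integer(level)
  if (level < 1L) stop("level must be >= 1")
  if (length(x) < 2^level) {
    stop("signal of length ", length(x), " too short for a ", level,
         "-level decomposition (need >= ", 2^level, " samples)")
  }
  coefs <- vector("list", level + 1L)
  lens <- integer(level + 1L)
  cur <- x
  for (j in seq_len(level)) {
    lens[level + 2L - j] <- length(cur)
    d <- wavelet_dwt(cur, wavelet)
    coefs[[level + 2L - j]] <- d$cd
    cur <- d$ca
  }
  coefs[[1L]] <- cur
  lens[1L] <- length(x)
  structure(list(coefs = coefs, lens = lens, level = level, wavelet = wavelet),
            class = "wavelet_dec")
}

#' Multilevel DWT reconstruction
#'
#' Inverse of [wavelet_wavedec()]; with unmodified coefficients the original
#' signal is reproduced to floating-point accuracy.
#'
#' @param dec A `wavelet_dec` object (coefficients may have been modified,
#'   e.g. zeroed or thresholded, but lengths must be preserved).
#' @return Numeric vector with the original signal length.
#' @export
wavelet_waverec <- function(dec) {
  stopifnot(inherits(dec, "wavelet_dec"))
  fb <- wavelet_filters(dec$wavelet)
  a <- dec$coefs[[1L]]
  for (j in seq_len(dec$level)) {
    out_len <- if (j < dec$level) length(dec$coefs[[j + 2L]]) else dec$lens[1L]
    full <- 2L * length(a) - fb$len + 2L
    a <- wavelet_idwt(a, dec$coefs[[j + 1L]], min(full, out_len), dec$wavelet)
  }
  a
}

#' Zero-phase band transfer functions of the undecimated transform
#'
#' Squared-magnitude transfer functions of the maximal-overlap (stationary)
#' wavelet filter cascade, evaluated on the length-`n` DFT grid. The detail
#' transfers `T_1 ... T_level` plus the approximation transfer sum to 1 at
#' every frequency, so retaining a subset of bands is an exact, zero-phase,
#' shift-equivariant band selection.
#'
#' @param n Signal length (DFT size).
#' @param level Decomposition depth.
#' @param wavelet Wavelet name.
#' @return Numeric matrix with `n` rows and `level + 1` columns named
#'   `D1 ... D<level>, A<level>`.
#' @export
wavelet_band_transfer <- function(n, level, wavelet = "sym4") {
  fb <- wavelet_filters(wavelet)
  level <- as.integer(level)
  f <- (seq_len(n) - 1L) / n
  # MODWT-scaled filters: |G|^2 + |H|^2 = 1 on [0, 1)
  resp2 <- function(taps, freq) {
    m <- seq_along(taps) - 1L
    Mod(exp(-2i * pi * outer(freq, m)) %*% taps)^2
  }
  g <- fb$dec_lo / sqrt(2)
  h <- fb$dec_hi / sqrt(2)
  out <- matrix(NA_real_, nrow = n, ncol = level + 1L,
                dimnames = list(NULL, c(paste0("D", seq_len(level)), paste0("A", level))))
  low_cascade <- rep(1, n)
  for (j in seq_len(level)) {
    fj <- (2^(j - 1L) * f) %% 1
    out[, j] <- resp2(h, fj) * low_cascade
    low_cascade <- low_cascade * resp2(g, fj)
  }
  out[, level + 1L] <- low_cascade
  out
}

#' Retain selected detail bands of a signal (undecimated, zero-phase)
#'
#' Projects the signal onto the selected undecimated wavelet detail bands by
#' applying the corresponding zero-phase transfer functions in the frequency
#' domain (circular boundary). Output has the input's length; the
#' approximation band (baseline) and unselected details are removed.
#'
#' @param x Numeric vector.
#' @param keep_details Integer vector of detail levels to retain.
#' @param level Decomposition depth.
#' @param wavelet Wavelet name.
#' @return Numeric vector, same length as `x`.
#' @export
wavelet_band_select <- function(x, keep_details, level, wavelet = "sym4") {
  keep_details <- as.integer(keep_details)
  if (any(keep_details < 1L | keep_details > level)) {
    stop("keep_details must lie in 1..", level)
  }
  n <- length(x)
  if (n < 2^level) {
    stop("signal of length ", n, " too short for a ", level,
         "-level decomposition (need >= ", 2^level, " samples)")
  }
  tr <- wavelet_band_transfer(n, level, wavelet)
  gain <- rowSums(tr[, keep_details, drop = FALSE])
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}
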