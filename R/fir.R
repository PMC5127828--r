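# Least-squares linear-phase FIR design (type I) and zero-phase filtering.
#
# The design minimizes the integrated squared error between the filter's
# amplitude response and a piecewise-linear desired response over the
# specified bands (transition bands are don't-care). For a type-I filter of
# order N (N even, N+1 taps) with amplitude
#   H(f) = a0 + sum_{m=1..M} a_m cos(2 pi m f / fs),  M = N/2,
# the normal equations Q a = d have closed-form band integrals of
# cos products, assembled below as Toeplitz-plus-Hankel terms.

#' Least-squares linear-phase FIR filter design
#'
#' Designs an even-order (type I) linear-phase FIR filter whose amplitude
#' response is the least-squares fit to a piecewise-linear desired
#' response, with don't-care transition bands.
#'
#' @param order filter order (even); the filter has `order + 1` taps.
#' @param bands numeric vector of band edges in Hz, in non-decreasing
#'   pairs, e.g. `c(0, 40, 50, 128)`.
#' @param desired desired amplitude at each band edge (same length as
#'   `bands`); linear interpolation within each band.
#' @param fs sampling rate in Hz.
#' @param dc_zero force an exact zero at 0 Hz by removing the tap mean
#'   (a high-pass should pass no DC at all; the correction perturbs the
#'   response elsewhere by under `sum(h)` times a negligible Dirichlet
#'   factor).
#' @return Numeric vector of `order + 1` filter coefficients (symmetric).
#' @export
#' @examples
#' h <- fir_ls(64, c(0, 20, 30, 64), c(1, 1, 0, 0), fs = 128)
fir_ls <- function(order, bands, desired, fs, dc_zero = FALSE) {
  if (order %% 2 != 0) stop("order must be even (type-I design)")
  if (length(bands) != length(desired) || length(bands) %% 2 != 0) {
    stop("bands and desired must be matching even-length vectors")
  }
  M <- order / 2
  w <- bands / fs * 2 * pi            # rad/sample band edges in [0, pi]
  if (any(diff(bands) < 0) || any(bands < 0) || any(bands > fs / 2)) {
    stop("band edges must be non-decreasing within [0, fs/2]")
  }

  # integral of cos(m w) over [w1, w2]
  ic <- function(m, w1, w2) {
    ifelse(m == 0, w2 - w1, (sin(m * w2) - sin(m * w1)) / m)
  }
  # integral of w cos(m w) over [w1, w2]
  iwc <- function(m, w1, w2) {
    ifelse(m == 0, (w2^2 - w1^2) / 2,
           (cos(m * w2) - cos(m * w1)) / m^2 +
             (w2 * sin(m * w2) - w1 * sin(m * w1)) / m)
  }

  q <- numeric(2 * M + 1)   # q[m+1] = sum over bands of int cos(m w) dw
  d <- numeric(M + 1)
  for (bi in seq(1, length(w), by = 2)) {
    w1 <- w[bi]; w2 <- w[bi + 1]
    if (w2 <= w1) next
    d1 <- desired[bi]; d2 <- desired[bi + 1]
    m <- 0:(2 * M)
    q[m + 1] <- q[m + 1] + ic(m, w1, w2)
    # desired response is linear in w within the band: D(w) = al + be * w
    be <- if (w2 > w1) (d2 - d1) / (w2 - w1) else 0
    al <- d1 - be * w1
    m <- 0:M
    d[m + 1] <- d[m + 1] + al * ic(m, w1, w2) + be * iwc(m, w1, w2)
  }

  # cos(i)cos(j) = (cos|i-j| + cos(i+j))/2: Toeplitz + Hankel structure
  idx <- outer(0:M, 0:M, function(i, j) abs(i - j)) + 1
  Q <- 0.5 * (matrix(q[idx], M + 1, M + 1) +
                matrix(q[outer(0:M, 0:M, `+`) + 1], M + 1, M + 1))
  a <- solve(Q, d)
  # expand cosine-series amplitudes to symmetric impulse response
  h <- c(rev(a[-1]) / 2, a[1], a[-1] / 2)
  if (dc_zero) h <- h - sum(h) / length(h)
  h
}

#' Zero-phase FIR filtering of a multi-channel signal
#'
#' Applies a linear-phase FIR filter with group-delay compensation: the
#' signal is zero-padded, convolved once (via FFT), and the symmetric
#' filter's constant delay of `(length(h) - 1) / 2` samples is removed, so
#' the output is aligned with the input and phase-free.
#'
#' @param x numeric matrix (time x channels) or vector.
#' @param h FIR coefficients (odd length, symmetric).
#' @return Filtered matrix/vector of the same size as `x`.
#' @export
filter_zerophase <- function(x, h) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  L <- length(h)
  if (n <= L) stop("signal shorter than the filter")
  delay <- (L - 1) / 2
  nfft <- stats::nextn(n + L - 1, 2)
  H <- stats::fft(c(h, numeric(nfft - L)))
  out <- apply(x, 2, function(col) {
    X <- stats::fft(c(col, numeric(nfft - n)))
    y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
    y[delay + seq_len(n)]
  })
  if (vec) drop(out) else out
}

# designed filters are deterministic in their arguments: memoize them
.fir_cache <- new.env(parent = emptyenv())

fir_ls_cached <- function(order, bands, desired, fs, dc_zero = FALSE) {
  key <- paste(c(order, bands, desired, fs, dc_zero), collapse = "_")
  if (is.null(.fir_cache[[key]])) {
    .fir_cache[[key]] <- fir_ls(order, bands, desired, fs, dc_zero)
  }
  .fir_cache[[key]]
}

#' Band-pass filter a recording to the analysis band
#'
#' High-pass at `lo` Hz with a least-squares linear-phase FIR of order
#' 1536 and low-pass at `hi` Hz (order 512), both applied zero-phase.
#' The long high-pass is needed for a sharp cutoff at 0.5 Hz; passband
#' ripple of the cascade is below 1% between 1 and 45 Hz at 256 Hz.
#'
#' @param signal an `eeg_signal` at 256 Hz (see [resample_to_256()]).
#' @param lo,hi cutoff frequencies in Hz (defaults 0.5 and 50).
#' @param hp_order,lp_order filter orders (defaults 1536 and 512).
#' @return The filtered `eeg_signal`.
#' @export
bandpass_filter <- function(signal, lo = 0.5, hi = 50,
                            hp_order = 1536, lp_order = 512) {
  stopifnot(inherits(signal, "eeg_signal"))
  fs <- signal$fs
  if (fs != 256) stop("bandpass_filter expects a 256 Hz signal")
  nyq <- fs / 2
  # full-coverage band spec (linear ramp across the transition) keeps the
  # design equations well-conditioned at generous filter orders
  hp <- fir_ls_cached(hp_order,
                      c(0, lo * 0.5, lo * 0.5, lo, lo, nyq),
                      c(0, 0, 0, 1, 1, 1), fs, dc_zero = TRUE)
  lp <- fir_ls_cached(lp_order,
                      c(0, hi, hi, hi * 1.15, hi * 1.15, nyq),
                      c(1, 1, 1, 0, 0, 0), fs)
  x <- filter_zerophase(signal$data, hp)
  x <- filter_zerophase(x, lp)
  signal$data <- x
  signal
}
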