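#' Resample a recording to 256 Hz
#'
#' Band-limited polyphase resampling (via [signal::resample()]) of each
#' channel to the common 256 Hz analysis rate. Recordings already at
#' 256 Hz pass through untouched.
#'
#' @param signal an `eeg_signal` at 128, 256 or 500 Hz.
#' @return The `eeg_signal` at 256 Hz, duration preserved within one
#'   sample.
#' @export
resample_to_256 <- function(signal) {
  stopifnot(inherits(signal, "eeg_signal"))
  fs <- signal$fs
  if (!fs %in% c(128, 256, 500)) stop("unsupported sampling rate: ", fs)
  if (fs == 256) return(signal)
  frac <- if (fs == 128) c(2L, 1L) else c(64L, 125L)   # 256/500 = 64/125
  x <- apply(signal$data, 2, function(col) {
    # d = 10 sidelobes per polyphase branch: passband droop < 0.2%
    signal::resample(col, p = frac[1], q = frac[2], d = 10)
  })
  n_target <- round(nrow(signal$data) * 256 / fs)
  x <- x[seq_len(min(nrow(x), n_target)), , drop = FALSE]
  signal$data <- x
  signal$fs <- 256
  signal$duration_s <- nrow(x) / 256
  signal
}

#' Per-epoch quality measures and artifact rejection
#'
#' Scans the recording in non-overlapping 1-s epochs and drops those that
#' fail any of three criteria, then re-concatenates the survivors into a
#' continuous clean signal:
#'
#' * amplitude: maximum absolute value across channels above
#'   `amp_uv` (default 100 uV);
#' * power: broadband epoch power (mean square over channels) whose
#'   z-score across epochs exceeds `power_z` (default 4);
#' * spatial deviation: the sSTD index — the standard deviation of
#'   per-channel log10 power across the 22 channels — whose z-score across
#'   epochs exceeds `sstd_z` (default 3). Epochs whose spatial power
#'   profile departs from the recording's norm (focal artifacts) are
#'   flagged by this criterion.
#'
#' @param signal an `eeg_signal`.
#' @param amp_uv amplitude threshold in uV.
#' @param power_z,sstd_z rejection thresholds on across-epoch z-scores.
#' @return List with `signal` (clean, survivors concatenated) and
#'   `quality`, a data.frame per 1-s epoch: `epoch`, `max_abs_uv`,
#'   `power_uv2`, `sstd`, `power_zscore`, `sstd_zscore`, `keep`.
#' @export
reject_artifact_epochs <- function(signal, amp_uv = 100, power_z = 4,
                                   sstd_z = 3) {
  stopifnot(inherits(signal, "eeg_signal"))
  fs <- signal$fs
  n_ep <- floor(nrow(signal$data) / fs)
  if (n_ep < 1) stop("signal shorter than one epoch")
  idx <- function(e) ((e - 1) * fs + 1):(e * fs)

  max_abs <- numeric(n_ep)
  pow <- numeric(n_ep)
  sstd <- numeric(n_ep)
  for (e in seq_len(n_ep)) {
    seg <- signal$data[idx(e), , drop = FALSE]
    max_abs[e] <- max(abs(seg))
    chan_pow <- colMeans(seg^2)
    pow[e] <- mean(chan_pow)
    sstd[e] <- stats::sd(log10(pmax(chan_pow, 1e-12)))
  }
  zs <- function(x) {
    s <- stats::sd(x)
    if (s == 0) numeric(length(x)) else (x - mean(x)) / s
  }
  pz <- zs(pow)
  sz <- zs(sstd)
  keep <- max_abs <= amp_uv & pz <= power_z & sz <= sstd_z
  if (!any(keep)) stop("all epochs rejected")

  clean <- signal
  clean$data <- do.call(rbind, lapply(which(keep), function(e) {
    signal$data[idx(e), , drop = FALSE]
  }))
  clean$duration_s <- nrow(clean$data) / fs
  list(signal = clean,
       quality = data.frame(epoch = seq_len(n_ep), max_abs_uv = max_abs,
                            power_uv2 = pow, sstd = sstd,
                            power_zscore = pz, sstd_zscore = sz,
                            keep = keep))
}

#' Segment a recording into overlapping epochs
#'
#' Left-to-right segmentation into `length_s`-second epochs advancing by
#' `length_s - overlap_s` seconds (Welch-style 50% overlap by default):
#' a `d`-second recording yields
#' `floor((d - length_s) / (length_s - overlap_s)) + 1` epochs.
#'
#' @param signal an `eeg_signal`.
#' @param length_s epoch length in seconds (default 2).
#' @param overlap_s overlap between consecutive epochs (default 1;
#'   must be smaller than `length_s`).
#' @return An `epoch_set`: list with `epochs` (array: epochs x samples x
#'   channels), `fs`, `length_s`, `overlap_s`, `channels`.
#' @export
segment_epochs <- function(signal, length_s = 2, overlap_s = 1) {
  stopifnot(inherits(signal, "eeg_signal"), overlap_s < length_s)
  fs <- signal$fs
  nsamp <- round(length_s * fs)
  step <- round((length_s - overlap_s) * fs)
  n <- nrow(signal$data)
  if (n < nsamp) stop("signal shorter than one epoch")
  starts <- seq(1, n - nsamp + 1, by = step)
  ep <- array(0, dim = c(length(starts), nsamp, ncol(signal$data)))
  for (i in seq_along(starts)) {
    ep[i, , ] <- signal$data[starts[i] + 0:(nsamp - 1), ]
  }
  structure(list(epochs = ep, fs = fs, length_s = length_s,
                 overlap_s = overlap_s, channels = signal$channels),
            class = "epoch_set")
}

#' Power spectrum of a single epoch
#'
#' Rectangular-window FFT periodogram of one 2-s epoch, scaled so that
#' the sum of power over all positive-frequency bins equals the epoch's
#' time-domain variance (Parseval convention; power is total power per
#' 0.5-Hz bin, not density). For a 512-sample epoch at 256 Hz the
#' retained band 0.5-50 Hz gives exactly 100 values per channel.
#'
#' @param epoch samples x channels matrix (or vector for one channel).
#' @param fs sampling rate (default 256; epoch length must correspond to
#'   2 s).
#' @param f_lo,f_hi retained band in Hz (defaults 0.5 and 50).
#' @param full if `TRUE`, return all positive-frequency bins up to
#'   Nyquist instead of the retained band.
#' @return List with `freq` and `power` (bins x channels matrix, uV^2).
#' @export
epoch_spectrum <- function(epoch, fs = 256, f_lo = 0.5, f_hi = 50,
                           full = FALSE) {
  if (is.null(dim(epoch))) epoch <- matrix(epoch, ncol = 1)
  n <- nrow(epoch)
  if (n != 2 * fs) stop("epoch must be 2 s long (", 2 * fs, " samples)")
  X <- stats::mvfft(epoch)
  half <- n / 2
  # one-sided |X|^2 scaling: sum over bins 1..n/2 = biased variance
  pw <- abs(X[2:(half + 1), , drop = FALSE])^2 / n^2
  pw[seq_len(half - 1), ] <- 2 * pw[seq_len(half - 1), , drop = FALSE]
  freq <- (1:half) * fs / n
  if (!full) {
    sel <- freq >= f_lo & freq <= f_hi
    pw <- pw[sel, , drop = FALSE]
    freq <- freq[sel]
  }
  list(freq = freq, power = pw)
}

#' Average epoch spectra into a subject's spectrum
#'
#' Arithmetic mean of per-epoch periodograms per channel and frequency
#' bin — together with 2-s/1-s segmentation and rectangular windows this
#' is Welch's estimate with 50% overlap. Optionally truncates to the
#' first `truncate_to` epochs so that the averaged epoch count is the
#' same for every subject in a cohort.
#'
#' @param epochs an `epoch_set` (see [segment_epochs()]).
#' @param truncate_to optional number of leading epochs to use.
#' @param id subject identifier carried into the result.
#' @return A `subject_spectra` object: list with `freq` (100-point 0.5-Hz
#'   grid), `power` (22 x 100 channels-by-bins matrix), `n_epochs`, `id`.
#' @export
average_spectrum <- function(epochs, truncate_to = NULL, id = "s1") {
  stopifnot(inherits(epochs, "epoch_set"))
  n_ep <- dim(epochs$epochs)[1]
  if (!is.null(truncate_to)) {
    if (truncate_to > n_ep) stop("truncate_to exceeds available epochs")
    n_ep <- truncate_to
  }
  acc <- NULL
  for (i in seq_len(n_ep)) {
    sp <- epoch_spectrum(epochs$epochs[i, , ], fs = epochs$fs)
    acc <- if (is.null(acc)) sp$power else acc + sp$power
  }
  freq <- epoch_spectrum(epochs$epochs[1, , ], fs = epochs$fs)$freq
  pow <- t(acc / n_ep)
  rownames(pow) <- epochs$channels
  structure(list(freq = freq, power = pow, n_epochs = n_ep, id = id),
            class = "subject_spectra")
}

#' Full spectra pipeline for one recording
#'
#' Resample to 256 Hz, band-pass 0.5-50 Hz, reject artifactual 1-s
#' epochs, segment into 2-s epochs with 1-s overlap, FFT each epoch and
#' average — yielding the per-channel average power spectra the spectral
#' fit consumes.
#'
#' @param signal an `eeg_signal`.
#' @param truncate_to optional standardized epoch count (e.g. 334).
#' @param id subject identifier.
#' @param amp_uv,power_z,sstd_z rejection thresholds, see
#'   [reject_artifact_epochs()].
#' @return A `subject_spectra`, with the rejection `quality` table
#'   attached as attribute `"quality"`.
#' @export
subject_spectra <- function(signal, truncate_to = NULL, id = "s1",
                            amp_uv = 100, power_z = 4, sstd_z = 3) {
  s <- resample_to_256(signal)
  s <- bandpass_filter(s)
  rej <- reject_artifact_epochs(s, amp_uv = amp_uv, power_z = power_z,
                                sstd_z = sstd_z)
  eps <- segment_epochs(rej$signal)
  out <- average_spectrum(eps, truncate_to = truncate_to, id = id)
  attr(out, "quality") <- rej$quality
  out
}
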