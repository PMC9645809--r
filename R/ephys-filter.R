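# Second-order IIR notch (RBJ biquad), applied forward-backward.
notch_coefs <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + al, -2 * cos(w0), 1 - al)
  list(b = b / a[1], a = a / a[1])
}

#' Notch and bandpass an ephys trace into the LFP band
#'
#' Zero-phase (forward-backward) second-order IIR notches at the power-line
#' harmonics (60 Hz and multiples) and the slice-acquisition harmonics
#' (`slice_hz` and multiples) up to 300 Hz, followed by a zero-phase
#' Butterworth bandpass 0.1-300 Hz (order-2 highpass cascaded with an
#' order-4 lowpass). The trace is demeaned first.
#'
#' @param trace Numeric voltage series.
#' @param fs Sampling rate (Hz); must exceed 600 Hz so the 300 Hz band edge
#'   is resolvable.
#' @param slice_hz Slice-acquisition fundamental (Hz; `n_slices / tr_s`).
#' @param line_hz Power-line fundamental (Hz).
#' @param band Passband (Hz).
#' @param Q Notch quality factor.
#' @return Filtered numeric series (the continuous LFP).
#' @export
notch_and_bandpass <- function(trace, fs, slice_hz = 20, line_hz = 60,
                               band = c(0.1, 300), Q = 30) {
  if (fs <= 2 * band[2]) {
    abort("notch_and_bandpass: fs must exceed twice the upper band edge")
  }
  x <- trace - mean(trace)
  freqs <- sort(unique(c(
    seq(slice_hz, band[2], by = slice_hz),
    seq(line_hz, band[2], by = line_hz)
  )))
  freqs <- freqs[freqs < fs / 2]
  for (f0 in freqs) {
    nf <- notch_coefs(f0, fs, Q)
    x <- signal::filtfilt(nf$b, nf$a, x)
  }
  hp <- signal::butter(2, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(4, band[2] / (fs / 2), type = "low")
  x <- signal::filtfilt(hp, x)
  signal::filtfilt(lp, x)
}

# Short-time power spectrogram: Hann window, one-sided periodogram per
# window. Returns power (not amplitude) per frequency bin and window.
stft_power <- function(x, fs, window_s = 1, step_s = 0.1) {
  win <- round(window_s * fs)
  step <- round(step_s * fs)
  n <- length(x)
  if (n < win) abort("stft_power: series shorter than one window")
  starts <- seq(1L, n - win + 1L, by = step)
  h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / (win - 1)) # Hann
  # windows as columns
  idx <- outer(seq_len(win) - 1L, starts, `+`)
  M <- matrix(x[idx], nrow = win) * h
  sp <- mvfft(M)
  nf <- floor(win / 2) + 1L
  pw <- abs(sp[seq_len(nf), , drop = FALSE])^2
  # one-sided scaling (double interior bins), normalised by window energy
  scale <- rep(2, nf)
  scale[1] <- 1
  if (win %% 2 == 0) scale[nf] <- 1
  pw <- pw * scale / (fs * sum(h^2))
  list(
    freq_hz = (seq_len(nf) - 1) * fs / win,
    time_s = (starts - 1 + win / 2) / fs,
    power = pw # freq x window
  )
}

#' LFP band power envelope
#'
#' Short-time spectrogram (1 s Hann window, 0.1 s step by default) with power
#' summed over the bins inside the band — a 10 Hz band-power envelope
#' timestamped at window centres.
#'
#' @param lfp Numeric LFP series.
#' @param fs Sampling rate (Hz).
#' @param band Two-element Hz interval, or the name of one of [lfp_bands].
#' @param window_s,step_s Spectrogram window and step (seconds).
#' @return A tibble of class `band_power_series` (`time_s`, `power`) with
#'   attributes `band`, `env_fs`.
#' @export
#' @examples
#' x <- sin(2 * pi * 70 * seq(0, 5, by = 1 / 500))
#' bp <- band_power(x, fs = 500, band = "gamma")
#' head(bp)
band_power <- function(lfp, fs, band = "gamma", window_s = 1, step_s = 0.1) {
  if (is.character(band)) band <- lfp_bands[[match.arg(band, names(lfp_bands))]]
  stopifnot(length(band) == 2, band[1] < band[2])
  if (band[2] > fs / 2) abort("band_power: band exceeds the Nyquist frequency")
  sp <- stft_power(lfp, fs, window_s, step_s)
  sel <- sp$freq_hz >= band[1] & sp$freq_hz <= band[2]
  vals <- colSums(sp$power[sel, , drop = FALSE])
  out <- tibble(time_s = sp$time_s, power = vals)
  attr(out, "band") <- band
  attr(out, "env_fs") <- 1 / step_s
  class(out) <- c("band_power_series", class(out))
  out
}

#' Band power of several bands from one spectrogram
#'
#' Computes the short-time spectrogram once and sums it over each requested
#' band — equivalent to calling [band_power()] per band but far cheaper.
#'
#' @param lfp Numeric LFP series.
#' @param fs Sampling rate (Hz).
#' @param bands Named list of Hz intervals (default [lfp_bands]).
#' @param window_s,step_s Spectrogram window and step (seconds).
#' @return Named list of `band_power_series` tibbles.
#' @export
band_power_multi <- function(lfp, fs, bands = lfp_bands, window_s = 1,
                             step_s = 0.1) {
  sp <- stft_power(lfp, fs, window_s, step_s)
  lapply(bands, function(b) {
    if (b[2] > fs / 2) abort("band_power_multi: band exceeds the Nyquist frequency")
    sel <- sp$freq_hz >= b[1] & sp$freq_hz <= b[2]
    out <- tibble(time_s = sp$time_s,
                  power = colSums(sp$power[sel, , drop = FALSE]))
    attr(out, "band") <- b
    attr(out, "env_fs") <- 1 / step_s
    class(out) <- c("band_power_series", class(out))
    out
  })
}

#' Average a band-power envelope within each TR
#'
#' Reduces the 10 Hz envelope to the fMRI analysis grid by averaging samples
#' whose centre falls inside each TR interval.
#'
#' @param bp A `band_power_series` from [band_power()].
#' @param tr_s Repetition time (seconds).
#' @param n_volumes Number of volumes.
#' @param t0 Start of the first volume (seconds).
#' @return Tibble (`time_s`, `power`) on the TR grid.
#' @export
band_power_per_tr <- function(bp, tr_s, n_volumes, t0 = 0) {
  vol <- floor((bp$time_s - t0) / tr_s) + 1L
  ok <- vol >= 1L & vol <= n_volumes
  means <- tapply(bp$power[ok], vol[ok], mean)
  out <- rep(NA_real_, n_volumes)
  out[as.integer(names(means))] <- means
  # fill any empty TRs (edges) by nearest neighbour
  if (anyNA(out)) {
    filled <- approx(which(!is.na(out)), out[!is.na(out)],
                     xout = seq_len(n_volumes), rule = 2)$y
    out <- filled
  }
  tibble(time_s = t0 + (seq_len(n_volumes) - 1) * tr_s, power = out)
}
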