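# Welch segmentation: Hann-tapered, demeaned windows; returns averaged
# auto- and cross-spectra. S_xy = conj(X) * Y, so a delayed second input
# gives negative phase (x leading y => phase < 0), the mscohere/scipy
# convention.
welch_spectra <- function(x, y, fs, window, overlap_frac) {
  n <- length(x)
  stopifnot(length(y) == n)
  window <- min(window, n)
  step <- max(1L, round(window * (1 - overlap_frac)))
  starts <- seq(1L, n - window + 1L, by = step)
  if (length(starts) < 2) {
    abort("welch_spectra: fewer than 2 windows; coherence would be identically 1")
  }
  h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(window) - 1) / (window - 1))
  nf <- floor(window / 2) + 1L
  Sxx <- Syy <- numeric(nf)
  Sxy <- complex(nf)
  for (s in starts) {
    ix <- s:(s + window - 1L)
    xs <- (x[ix] - mean(x[ix])) * h
    ys <- (y[ix] - mean(y[ix])) * h
    X <- fft(xs)[seq_len(nf)]
    Y <- fft(ys)[seq_len(nf)]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + Conj(X) * Y
  }
  K <- length(starts)
  list(
    freq_hz = (seq_len(nf) - 1) * fs / window,
    Sxx = Sxx / K, Syy = Syy / K, Sxy = Sxy / K, n_windows = K
  )
}

#' Magnitude-squared coherence and cross-spectral phase
#'
#' Welch-averaged (Hann-tapered, overlapping, demeaned windows) auto- and
#' cross-spectra; coherence is `|S_xy|^2 / (S_xx S_yy)` and phase is
#' `arg(S_xy)` with `S_xy = conj(X) Y`, so if `y` is `x` delayed by `tau`
#' the phase is `-2 pi f tau`.
#'
#' @param x,y Equal-length numeric series.
#' @param fs Sampling rate (Hz).
#' @param window_s Welch window length (seconds).
#' @param overlap_frac Window overlap fraction.
#' @return A tibble of class `coherence_result` with columns `freq_hz`,
#'   `msc`, `phase_rad`; `attr(, "n_windows")` holds the window count.
#' @export
#' @examples
#' t <- seq(0, 100, by = 0.1)
#' x <- sin(2 * pi * 0.5 * t) + rnorm(length(t), sd = 0.1)
#' coh <- msc(x, x, fs = 10, window_s = 20)
#' all(coh$msc > 0.999)
msc <- function(x, y, fs, window_s = length(x) / fs / 8,
                overlap_frac = 0.5) {
  sp <- welch_spectra(x, y, fs, round(window_s * fs), overlap_frac)
  denom <- sp$Sxx * sp$Syy
  coh <- ifelse(denom > 0, Mod(sp$Sxy)^2 / denom, 0)
  coh <- pmin(pmax(coh, 0), 1)
  out <- tibble(freq_hz = sp$freq_hz, msc = coh, phase_rad = Arg(sp$Sxy))
  attr(out, "n_windows") <- sp$n_windows
  class(out) <- c("coherence_result", class(out))
  out
}

#' @export
glance.coherence_result <- function(x, f_max = Inf, ...) {
  sel <- x$freq_hz > 0 & x$freq_hz <= f_max
  i <- which(sel)[which.max(x$msc[sel])]
  tibble(
    peak_freq_hz = x$freq_hz[i], peak_msc = x$msc[i],
    peak_phase_rad = x$phase_rad[i],
    n_windows = attr(x, "n_windows") %||% NA_integer_
  )
}

#' Coherence between RVT and an LFP band-power envelope
#'
#' Both series are taken on (or reduced to) the TR grid; Welch coherence is
#' computed with 256-sample windows at 50% overlap (frequency resolution
#' about 0.004 Hz at TR = 1 s), and the peak is located below `f_max`
#' (default 0.15 Hz, the slow-respiration range).
#'
#' @param rvt RVT on the TR grid: numeric vector or `rvt_series`.
#' @param bp Band power: numeric vector on the TR grid, or a
#'   `band_power_series` (then reduced with [band_power_per_tr()]).
#' @param tr_s Repetition time (seconds).
#' @param window Welch window (samples on the TR grid).
#' @param overlap_frac Overlap fraction.
#' @param f_max Upper frequency bound for the peak search (Hz).
#' @return A `coherence_result` with extra attribute `peak` (one-row tibble:
#'   `peak_freq_hz`, `peak_msc`, `peak_phase_rad`).
#' @export
rvt_band_coherence <- function(rvt, bp, tr_s = 1, window = 256,
                               overlap_frac = 0.5, f_max = 0.15) {
  if (inherits(rvt, "rvt_series")) {
    tr_s <- attr(rvt, "tr_s") %||% tr_s
    rvt <- rvt$rvt
  }
  if (inherits(bp, "band_power_series")) {
    bp <- band_power_per_tr(bp, tr_s, length(rvt))$power
  } else if (is.data.frame(bp)) {
    bp <- bp$power
  }
  stopifnot(length(bp) == length(rvt))
  out <- msc(rvt, bp, fs = 1 / tr_s, window_s = window * tr_s, overlap_frac)
  attr(out, "peak") <- glance(out, f_max = f_max)
  out
}

#' Coherence of RVT with every conventional LFP band
#'
#' Loops [band_power()] + [rvt_band_coherence()] over delta, theta, alpha,
#' beta, gamma — the band-specificity contrast.
#'
#' @param rvt RVT on the TR grid.
#' @param lfp Numeric LFP series.
#' @param fs LFP sampling rate (Hz).
#' @param tr_s,n_volumes TR grid description.
#' @param ... Passed to [rvt_band_coherence()].
#' @return Named list of `coherence_result`s, one per band.
#' @export
all_band_coherence <- function(rvt, lfp, fs, tr_s = 1,
                               n_volumes = length(rvt), ...) {
  bps <- band_power_multi(lfp, fs)
  lapply(bps, function(bp) rvt_band_coherence(rvt, bp, tr_s = tr_s, ...))
}

#' Phase-randomised surrogate null for coherence peaks
#'
#' Destroys cross-series phase relations by randomising the Fourier phases
#' of the second series (amplitude spectrum preserved), recomputes the peak
#' coherence below `f_max` each time, and returns the null peak
#' distribution.
#'
#' @param rvt,bp TR-grid series as in [rvt_band_coherence()].
#' @param n_surrogates Number of surrogates.
#' @param tr_s,window,overlap_frac,f_max As in [rvt_band_coherence()].
#' @param seed RNG seed.
#' @return Numeric vector of null peak-msc values.
#' @export
coherence_null <- function(rvt, bp, n_surrogates = 100, tr_s = 1,
                           window = 256, overlap_frac = 0.5, f_max = 0.15,
                           seed = NULL) {
  if (inherits(rvt, "rvt_series")) rvt <- rvt$rvt
  if (is.data.frame(bp)) bp <- bp$power
  n <- length(bp)
  X <- fft(bp - mean(bp))
  with_seed(seed, {
    vapply(seq_len(n_surrogates), function(i) {
      ph <- runif(n, 0, 2 * pi)
      # keep conjugate symmetry so the surrogate is real
      half <- 2:ceiling((n + 1) / 2)
      Xs <- X
      Xs[half] <- Mod(X[half]) * exp(1i * ph[half])
      Xs[n + 2 - half] <- Conj(Xs[half])
      surr <- Re(fft(Xs, inverse = TRUE)) / n
      co <- msc(rvt, surr, fs = 1 / tr_s, window_s = window * tr_s,
                overlap_frac)
      max(co$msc[co$freq_hz > 0 & co$freq_hz <= f_max])
    }, numeric(1))
  })
}

#' Welch power spectrum
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length (seconds).
#' @param overlap_frac Overlap fraction.
#' @return Tibble (`freq_hz`, `power`).
#' @export
power_spectrum <- function(x, fs, window_s = length(x) / fs / 8,
                           overlap_frac = 0.5) {
  sp <- welch_spectra(x, x, fs, round(window_s * fs), overlap_frac)
  tibble(freq_hz = sp$freq_hz, power = sp$Sxx)
}

#' Log-log spectral slope
#'
#' Least-squares slope of log10(power) on log10(frequency) over a frequency
#' range — ~0 for white noise, ~-1 for 1/f (pink) series.
#'
#' @param spec Tibble from [power_spectrum()].
#' @param f_range Frequency range (Hz) to fit over.
#' @return Scalar slope.
#' @export
spectral_slope <- function(spec, f_range = c(-Inf, Inf)) {
  sel <- spec$freq_hz > 0 & spec$power > 0 &
    spec$freq_hz >= f_range[1] & spec$freq_hz <= f_range[2]
  fit <- lm(log10(power) ~ log10(freq_hz), data = spec[sel, ])
  unname(coef(fit)[2])
}
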