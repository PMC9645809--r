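#' Pink (1/f) noise
#'
#' White Gaussian noise shaped in the frequency domain so its power
#' spectrum falls off as `1/f^exponent`, normalised to unit variance.
#'
#' @param n Number of samples.
#' @param exponent Power-spectral exponent (1 = pink).
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, exponent = 1) {
  x <- rnorm(n)
  X <- fft(x)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) # symmetric frequency index, DC at 0
  scale <- c(0, 1 / f[-1]^(exponent / 2)) # amplitude ~ f^(-exp/2) => power ~ 1/f^exp
  y <- Re(fft(X * scale, inverse = TRUE)) / n
  y / sd(y)
}

# Bandpass white noise via zero-phase Butterworth.
bandlimited_noise <- function(n, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x / sd(x)
}

#' Generate a synthetic LFP recording
#'
#' Builds a single-channel local field potential on the ephys sampling grid:
#' a 1/f background, a constant-amplitude oscillation phase-locked to the
#' respiratory cycle, and a gamma-band carrier whose amplitude envelope is
#' `1 + coupling_strength * z(rvt)` delayed by `coupling_lag_s` — the
#' generative analog of gamma power cohering with RVT at the slow-modulation
#' frequency with zero phase lag. In the isoelectric condition all neural
#' terms are silenced and only sensor noise remains.
#'
#' @param cfg A [sim_config()].
#' @param resp_sim Output of [gen_respiration()] run with the same `cfg`.
#' @param n_channels Number of identical-signal channels to emit (each gets
#'   independent sensor noise); 1 returns a vector in `lfp`.
#' @return A list with `lfp` (numeric vector, ephys grid), `fs`,
#'   `gamma_envelope` (tibble on the TR grid — ground-truth gamma amplitude
#'   envelope), and `components` (list of the separate terms, for oracles).
#' @export
gen_lfp <- function(cfg, resp_sim, n_channels = 1) {
  validate_sim_config(cfg)
  stopifnot(!is.null(resp_sim$rvt_envelope), !is.null(resp_sim$slow_mod))
  with_seed(cfg$seed + 1L, {
    fs <- cfg$ephys_fs
    n <- round(cfg$duration_s * fs)
    t <- (seq_len(n) - 1) / fs

    # re-derive the respiratory carrier phase on the ephys grid from the
    # slow modulator sampled by gen_respiration
    m <- approx(resp_sim$slow_mod$time_s, resp_sim$slow_mod$m,
                xout = t, rule = 2)$y
    rate <- cfg$base_resp_rate_hz * (1 + cfg$rate_mod_depth * m)
    resp_phase <- 2 * pi * cumsum(rate) / fs

    # gamma envelope: 1 + c * standardized RVT, delayed, on the ephys grid
    env_tr <- resp_sim$rvt_envelope
    z <- env_tr$rvt - mean(env_tr$rvt)
    zsd <- sd(z)
    if (zsd > 0) z <- z / zsd
    env <- approx(env_tr$time_s + cfg$coupling_lag_s, z, xout = t, rule = 2)$y
    env <- pmax(0, 1 + cfg$coupling_strength * env)

    neural_gain <- if (cfg$condition == "isoelectric") 0 else 1
    background <- neural_gain * pink_noise(n)
    resp_osc <- neural_gain * 0.5 * sin(resp_phase)
    carrier <- bandlimited_noise(n, fs, cfg$gamma_band)
    gamma <- neural_gain * 0.5 * carrier * env
    sensor <- matrix(rnorm(n * n_channels, sd = 0.05), n, n_channels)

    signal_part <- background + resp_osc + gamma
    lfp <- if (n_channels == 1) signal_part + sensor[, 1] else
      t(sweep(sensor, 1, signal_part, `+`)) # channel x sample

    # ground-truth envelope on the TR grid
    z_tr <- approx(env_tr$time_s + cfg$coupling_lag_s, z,
                   xout = env_tr$time_s, rule = 2)$y
    gamma_env_tr <- pmax(0, 1 + cfg$coupling_strength * z_tr)

    list(
      lfp = lfp, fs = fs,
      gamma_envelope = tibble(time_s = env_tr$time_s, env = gamma_env_tr),
      components = list(background = background, resp_osc = resp_osc,
                        gamma = gamma)
    )
  })
}
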