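# Slow modulator m(t): unit-amplitude sinusoid at slow_mod_freq_hz, or
# band-limited Gaussian noise below 0.15 Hz rescaled to unit amplitude.
slow_modulator <- function(t, cfg) {
  if (cfg$slow_mod_mode == "sinusoid") {
    sin(2 * pi * cfg$slow_mod_freq_hz * t)
  } else {
    n <- length(t)
    fs <- 1 / (t[2] - t[1])
    x <- rnorm(n)
    X <- fft(x)
    f <- seq(0, fs, length.out = n + 1)[1:n]
    f <- pmin(f, fs - f) # two-sided frequency axis
    X[f > 0.15] <- 0
    m <- Re(fft(X, inverse = TRUE)) / n
    m <- m - mean(m)
    m / max(abs(m))
  }
}

#' Generate a synthetic respiration recording
#'
#' Produces a chest-sensor-like waveform: a ~1.1 Hz breathing carrier whose
#' depth (and optionally rate) is slowly modulated below 0.15 Hz, plus white
#' sensor noise. The instantaneous depth/rate laws are also returned as an
#' analytic respiration-volume-per-time (RVT) envelope on the TR grid — the
#' ground truth against which [compute_rvt()] can be validated.
#'
#' The waveform is `depth(t) * sin(phi(t))` with
#' `depth(t) = 1 + slow_mod_depth * m(t)`,
#' `phi(t)` the accumulated phase of `rate(t) = base * (1 + rate_mod_depth * m(t))`,
#' and `m(t)` the unit-amplitude slow modulator. For a sinusoid of depth `d`
#' and period `1/rate` a breath's peak-to-trough over period ratio is
#' `2 d * rate`, so the analytic RVT envelope is `2 * depth(t) * rate(t)`.
#'
#' @param cfg A [sim_config()].
#' @return A list with
#'   \describe{
#'     \item{resp}{[resp_trace()] waveform}
#'     \item{rvt_envelope}{tibble (`time_s`, `rvt`) — analytic RVT on the TR grid}
#'     \item{depth,rate}{tibbles of the instantaneous laws on the TR grid}
#'     \item{condition}{the config condition (respiration is identical across
#'       conditions under the same seed)}
#'   }
#' @export
#' @examples
#' sim <- gen_respiration(sim_config(n_volumes = 60, seed = 2))
#' range(sim$resp$value)
gen_respiration <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    n <- round(cfg$duration_s * cfg$resp_fs)
    t <- (seq_len(n) - 1) / cfg$resp_fs
    m <- slow_modulator(t, cfg)
    depth <- 1 + cfg$slow_mod_depth * m
    rate <- cfg$base_resp_rate_hz * (1 + cfg$rate_mod_depth * m)
    phase <- 2 * pi * cumsum(rate) / cfg$resp_fs
    wave <- depth * sin(phase) + rnorm(n, sd = cfg$resp_noise_sd)

    tr_t <- (seq_len(cfg$n_volumes) - 1) * cfg$tr_s
    m_tr <- approx(t, m, xout = tr_t, rule = 2)$y
    phase_tr <- approx(t, phase, xout = tr_t, rule = 2)$y %% (2 * pi)
    depth_tr <- 1 + cfg$slow_mod_depth * m_tr
    rate_tr <- cfg$base_resp_rate_hz * (1 + cfg$rate_mod_depth * m_tr)

    list(
      resp = resp_trace(wave, fs = cfg$resp_fs),
      rvt_envelope = tibble(time_s = tr_t, rvt = 2 * depth_tr * rate_tr),
      depth = tibble(time_s = tr_t, depth = depth_tr),
      rate = tibble(time_s = tr_t, rate_hz = rate_tr),
      slow_mod = tibble(time_s = t, m = m),
      resp_phase = tibble(time_s = tr_t, phase = phase_tr),
      condition = cfg$condition
    )
  })
}
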