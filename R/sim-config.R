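#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: a resting-state scan
#' with simultaneous respiration and electrophysiology, breathing at
#' ~1.1 Hz whose depth (and optionally rate) is slowly modulated below
#' 0.15 Hz, gamma-band LFP power amplitude-coupled to the respiration
#' volume per time (RVT) envelope, and BOLD volumes carrying an
#' HRF-convolved neural component plus respiration-derived artifact
#' components.
#'
#' @param duration_s Scan length in seconds. Defaults to
#'   `n_volumes * tr_s`.
#' @param resp_fs Respiration sensor sampling rate (Hz).
#' @param ephys_fs Electrophysiology sampling rate (Hz). The acquisition
#'   default is 24,414 Hz; analyses in this package are routinely run on a
#'   decimated 1,000 Hz grid, which comfortably covers the 40-100 Hz gamma
#'   band.
#' @param tr_s fMRI repetition time (seconds).
#' @param n_volumes Number of fMRI volumes.
#' @param n_slices Slices per volume (sets the slice-artifact rate,
#'   `n_slices / tr_s` Hz).
#' @param grid_shape Integer vector of 3 voxel counts.
#' @param base_resp_rate_hz Carrier breathing rate (Hz).
#' @param slow_mod_freq_hz Frequency of the slow depth/rate modulation (Hz);
#'   must be below the BOLD Nyquist `0.5 / tr_s`.
#' @param slow_mod_depth Fractional depth modulation in `[0, 1)`.
#' @param rate_mod_depth Fractional breathing-rate modulation (same slow
#'   modulator); 0 disables it.
#' @param slow_mod_mode `"sinusoid"` (sharp line at `slow_mod_freq_hz`, the
#'   default, best for parameter-recovery checks) or `"noise"`
#'   (band-limited noise below 0.15 Hz, more like real breathing).
#' @param coupling_strength Dimensionless gain of the RVT -> gamma-power
#'   amplitude coupling (0 = no coupling).
#' @param coupling_lag_s Lag (seconds) of the gamma envelope behind RVT.
#' @param gamma_band Two-element Hz interval of the gamma carrier.
#' @param noise_sd SD of additive white noise in BOLD voxel series
#'   (signal units).
#' @param resp_noise_sd SD of respiration sensor noise, as a fraction of
#'   the unit carrier amplitude.
#' @param artifact_amplitude MR gradient artifact amplitude for
#'   [inject_mr_artifact()] (signal units).
#' @param beta_neural,beta_artifact,beta_cyclic BOLD component gains:
#'   HRF-convolved gamma envelope in network voxels, RRF-convolved RVT in
#'   artifact voxels, and aliased cyclic-respiration sin/cos terms in
#'   artifact voxels.
#' @param condition `"light_sedation"` or `"isoelectric"`. The isoelectric
#'   condition silences all neural terms (LFP reduced to sensor noise,
#'   `beta_neural = 0`) while leaving respiration generation untouched.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_volumes = 300, seed = 1)
#' cfg$slow_mod_freq_hz
sim_config <- function(duration_s = NULL,
                       resp_fs = 225,
                       ephys_fs = 24414,
                       tr_s = 1,
                       n_volumes = 1200,
                       n_slices = 20,
                       grid_shape = c(32L, 32L, 4L),
                       base_resp_rate_hz = 1.1,
                       slow_mod_freq_hz = 0.035,
                       slow_mod_depth = 0.3,
                       rate_mod_depth = 0,
                       slow_mod_mode = c("sinusoid", "noise"),
                       coupling_strength = 0.5,
                       coupling_lag_s = 0,
                       gamma_band = c(40, 100),
                       noise_sd = 1,
                       resp_noise_sd = 0.01,
                       artifact_amplitude = 10,
                       beta_neural = 1,
                       beta_artifact = 1,
                       beta_cyclic = 0.5,
                       condition = c("light_sedation", "isoelectric"),
                       seed = 1L) {
  slow_mod_mode <- match.arg(slow_mod_mode)
  condition <- match.arg(condition)
  if (is.null(duration_s)) duration_s <- n_volumes * tr_s
  cfg <- list(
    duration_s = duration_s, resp_fs = resp_fs, ephys_fs = ephys_fs,
    tr_s = tr_s, n_volumes = as.integer(n_volumes),
    n_slices = as.integer(n_slices),
    grid_shape = as.integer(grid_shape),
    base_resp_rate_hz = base_resp_rate_hz,
    slow_mod_freq_hz = slow_mod_freq_hz,
    slow_mod_depth = slow_mod_depth,
    rate_mod_depth = rate_mod_depth,
    slow_mod_mode = slow_mod_mode,
    coupling_strength = coupling_strength,
    coupling_lag_s = coupling_lag_s,
    gamma_band = gamma_band,
    noise_sd = noise_sd, resp_noise_sd = resp_noise_sd,
    artifact_amplitude = artifact_amplitude,
    beta_neural = beta_neural, beta_artifact = beta_artifact,
    beta_cyclic = beta_cyclic,
    condition = condition, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$duration_s > 0, cfg$resp_fs > 0, cfg$ephys_fs > 0,
    cfg$tr_s > 0, cfg$n_volumes > 0, cfg$n_slices > 0,
    all(cfg$grid_shape > 0), length(cfg$grid_shape) == 3
  )
  if (cfg$slow_mod_freq_hz >= 0.5 / cfg$tr_s) {
    abort("slow_mod_freq_hz must be below the BOLD Nyquist (0.5 / tr_s)")
  }
  if (cfg$base_resp_rate_hz >= cfg$resp_fs / 2) {
    abort("base_resp_rate_hz must be below the respiration Nyquist (resp_fs / 2)")
  }
  if (cfg$slow_mod_depth >= 1 || cfg$slow_mod_depth < 0) {
    abort("slow_mod_depth must lie in [0, 1): a depth >= 1 would let the breathing envelope cross zero")
  }
  if (cfg$gamma_band[1] <= 0 || cfg$gamma_band[2] >= cfg$ephys_fs / 2) {
    abort("gamma_band must lie inside (0, ephys_fs / 2)")
  }
  if (abs(cfg$coupling_lag_s) >= cfg$duration_s) {
    abort("coupling_lag_s must be smaller than the scan duration")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$condition, "\n")
  cat(sprintf("  %g s, TR %g s x %d volumes, grid %s\n",
              x$duration_s, x$tr_s, x$n_volumes,
              paste(x$grid_shape, collapse = "x")))
  cat(sprintf("  resp %g Hz (carrier %g Hz, mod %g Hz depth %g, %s)\n",
              x$resp_fs, x$base_resp_rate_hz, x$slow_mod_freq_hz,
              x$slow_mod_depth, x$slow_mod_mode))
  cat(sprintf("  ephys %g Hz, gamma %g-%g Hz, coupling %g @ lag %g s\n",
              x$ephys_fs, x$gamma_band[1], x$gamma_band[2],
              x$coupling_strength, x$coupling_lag_s))
  invisible(x)
}

#' Read or write a simulation config as YAML
#'
#' @param path File path.
#' @return `read_sim_config()` returns a [sim_config()] object;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

#' @param cfg A [sim_config()] object.
#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
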