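#' Run the full analysis on one synthetic scan
#'
#' Generates a scan under `cfg`, then runs the complete analysis chain the
#' package implements: extrema/RVT extraction from the respiration waveform,
#' gamma band power from the LFP, RVT-gamma coherence, the RVT-BOLD
#' correlation map, and the gamma-regression mediation contrast.
#'
#' @param cfg A [sim_config()].
#' @param bands Bands for the coherence loop (names of [lfp_bands]).
#' @return A list with `sim` (generator output incl. ground truth), `rvt`
#'   (computed `rvt_series`), `gamma_tr` (TR-gridded gamma power),
#'   `coherence` (named list of `coherence_result`s), `rvt_map`
#'   ([stat_map()]), and `mediation` (see [mediation_analysis()]).
#' @export
run_study <- function(cfg, bands = "gamma") {
  sim <- simulate_study(cfg)
  ext <- detect_extrema(sim$resp$resp)
  rvt <- compute_rvt(ext, tr_s = cfg$tr_s, n_volumes = cfg$n_volumes)
  coh <- list()
  gamma_tr <- NULL
  for (b in bands) {
    bp <- band_power(sim$lfp$lfp, fs = sim$lfp$fs, band = b)
    bp_tr <- band_power_per_tr(bp, cfg$tr_s, cfg$n_volumes)
    if (b == "gamma") gamma_tr <- bp_tr
    coh[[b]] <- rvt_band_coherence(rvt, bp_tr, tr_s = cfg$tr_s)
  }
  rvt_map <- voxelwise_corr(sim$bold, rvt$rvt)
  med <- if (!is.null(gamma_tr)) {
    mediation_analysis(sim$bold, rvt, gamma_tr$power)
  } else NULL
  list(sim = sim, rvt = rvt, gamma_tr = gamma_tr, coherence = coh,
       rvt_map = rvt_map, mediation = med)
}

#' Write a coherence result as CSV
#'
#' Columns `freq_hz`, `msc`, `phase_rad` (phase is `arg(conj(X) Y)`:
#' negative when the second series lags).
#'
#' @param coh A `coherence_result`.
#' @param path Output path.
#' @export
write_coherence_csv <- function(coh, path) {
  write.csv(as.data.frame(coh), path, row.names = FALSE)
  invisible(path)
}

#' Write a time/value series as CSV
#'
#' Two headed columns, `time_s` and `value`.
#'
#' @param time_s,value Numeric vectors (or a data frame in `time_s`).
#' @param path Output path.
#' @export
write_series_csv <- function(time_s, value = NULL, path) {
  df <- if (is.data.frame(time_s)) {
    stats::setNames(as.data.frame(time_s[, 1:2]), c("time_s", "value"))
  } else data.frame(time_s = time_s, value = value)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
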