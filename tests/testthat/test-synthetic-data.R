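test_that("generators are bit-identical under the same config and seed", {
  cfg <- quick_cfg()
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$resp$resp$value, b$resp$resp$value)
  expect_identical(a$lfp$lfp, b$lfp$lfp)
  expect_identical(a$bold$data, b$bold$data)
})

test_that("unmodulated breathing has constant amplitude and a spectral line at the carrier", {
  cfg <- sim_config(n_volumes = 120, slow_mod_depth = 0, resp_noise_sd = 0,
                    seed = 1)
  sim <- gen_respiration(cfg)
  x <- sim$resp$value
  # per-breath peak-to-trough is constant
  ext <- detect_extrema(sim$resp)
  pk <- ext$value[ext$type == "peak"]
  tr <- ext$value[ext$type == "trough"]
  expect_lt(diff(range(pk)) , 1e-3)
  expect_lt(diff(range(-tr)), 1e-3)
  sp <- power_spectrum(x, fs = 225, window_s = 40)
  expect_equal(sp$freq_hz[which.max(sp$power)], 1.1, tolerance = 0.05)
})

test_that("depth modulation puts the analytic RVT envelope's spectral peak at the modulation frequency", {
  cfg <- sim_config(n_volumes = 600, slow_mod_depth = 0.3,
                    slow_mod_freq_hz = 0.035, seed = 2)
  sim <- gen_respiration(cfg)
  sp <- power_spectrum(sim$rvt_envelope$rvt, fs = 1, window_s = 300)
  pk <- sp$freq_hz[sp$freq_hz > 0][which.max(sp$power[sp$freq_hz > 0])]
  expect_lt(abs(pk - 0.035), 1 / 300 + 1e-9) # within one frequency bin
})

test_that("an envelope-crossing modulation depth is rejected", {
  expect_error(sim_config(slow_mod_depth = 1), "slow_mod_depth")
  expect_error(sim_config(slow_mod_depth = 1.5), "slow_mod_depth")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(slow_mod_freq_hz = 0.6, tr_s = 1), "Nyquist")
  expect_error(sim_config(base_resp_rate_hz = 200), "Nyquist")
  expect_error(sim_config(coupling_lag_s = 1e5), "coupling_lag_s")
})

test_that("zero coupling leaves no RVT-gamma coherence above the surrogate null", {
  cfg <- sim_config(n_volumes = 600, ephys_fs = 500, coupling_strength = 0,
                    seed = 3)
  sim <- simulate_study(cfg)
  rvt <- compute_rvt(detect_extrema(sim$resp$resp), tr_s = 1, n_volumes = 600)
  bp <- band_power_per_tr(band_power(sim$lfp$lfp, 500, "gamma"), 1, 600)
  coh <- rvt_band_coherence(rvt, bp)
  nul <- coherence_null(rvt$rvt, bp, n_surrogates = 60, seed = 4)
  expect_lt(attr(coh, "peak")$peak_msc, quantile(nul, 0.95))
})

test_that("with zero-lag coupling the gamma envelope cross-correlates with RVT maximally at lag 0", {
  cfg <- sim_config(n_volumes = 600, coupling_strength = 0.5,
                    coupling_lag_s = 0, seed = 5)
  rs <- gen_respiration(cfg)
  lf <- gen_lfp(cfg, rs)
  cc <- stats::ccf(lf$gamma_envelope$env, rs$rvt_envelope$rvt, lag.max = 20,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("isoelectric LFP variance is under 1% of the light-sedation variance", {
  cfg_l <- quick_cfg()
  cfg_i <- quick_cfg(condition = "isoelectric")
  rs_l <- gen_respiration(cfg_l)
  rs_i <- gen_respiration(cfg_i)
  v_l <- var(gen_lfp(cfg_l, rs_l)$lfp)
  v_i <- var(gen_lfp(cfg_i, rs_i)$lfp)
  expect_lt(v_i / v_l, 0.01)
})

test_that("isoelectric mode preserves the respiration waveform exactly", {
  a <- gen_respiration(quick_cfg())
  b <- gen_respiration(quick_cfg(condition = "isoelectric"))
  expect_identical(a$resp$value, b$resp$value)
})

test_that("artifact injection with amplitude 0 is the identity and a huge artifact dominates the slice band", {
  cfg <- quick_cfg()
  rs <- gen_respiration(cfg)
  lf <- gen_lfp(cfg, rs)
  sched <- schedule_from_config(cfg)
  inj0 <- inject_mr_artifact(lf$lfp, cfg$ephys_fs, sched, amplitude = 0)
  expect_identical(inj0$contaminated, lf$lfp)
  expect_error(inject_mr_artifact(lf$lfp, cfg$ephys_fs, sched, amplitude = -1),
               "amplitude")
  injL <- inject_mr_artifact(lf$lfp, cfg$ephys_fs, sched, amplitude = 100)
  sp <- power_spectrum(injL$contaminated, cfg$ephys_fs, window_s = 10)
  # gradient-artifact content lives at its 130/210 Hz carriers, far above
  # the pink-noise-dominated LFP band
  harm <- sp$freq_hz > 100
  expect_gt(sum(sp$power[harm]) / sum(sp$power), 0.9)
})

test_that("BOLD generator honours its null and noiseless constructions", {
  cfg <- quick_cfg(beta_neural = 0, beta_artifact = 0, beta_cyclic = 0)
  sim <- simulate_study(cfg)
  sp <- power_spectrum(sim$bold$data[6, 6, 1, ], fs = 1, window_s = 40)
  expect_lt(abs(spectral_slope(sp)), 0.35) # flat: white noise only
  cfg2 <- quick_cfg(noise_sd = 0, beta_artifact = 0, beta_cyclic = 0)
  sim2 <- simulate_study(cfg2)
  nm <- which(sim2$truth$network_mask, arr.ind = TRUE)
  v <- sim2$bold$data[nm[1, 1], nm[1, 2], nm[1, 3], ]
  pred <- sim2$truth$neural_ts * cfg2$beta_neural
  expect_equal(v, pred, tolerance = 1e-12)
})

test_that("network voxels correlate with RVT more than non-network brain voxels", {
  cfg <- sim_config(n_volumes = 400, ephys_fs = 500,
                    grid_shape = c(16L, 16L, 2L), seed = 7)
  sim <- simulate_study(cfg)
  m <- voxelwise_corr(sim$bold, sim$resp$rvt_envelope$rvt)
  net <- sim$truth$network_mask
  other <- sim$bold$mask & !net & !sim$truth$artifact_mask
  expect_gt(mean(m$r_map[net]), mean(m$r_map[other]))
})

test_that("computed RVT tracks the analytic envelope across modulation depths", {
  for (d in c(0.1, 0.3, 0.5)) {
    cfg <- sim_config(n_volumes = 300, slow_mod_depth = d, seed = 11)
    rs <- gen_respiration(cfg)
    rvt <- compute_rvt(detect_extrema(rs$resp), tr_s = 1, n_volumes = 300)
    expect_gt(cor(rvt$rvt, rs$rvt_envelope$rvt), 0.95)
  }
})

test_that("band-limited-noise modulation mode stays below 0.15 Hz", {
  cfg <- sim_config(n_volumes = 600, slow_mod_mode = "noise", seed = 13)
  rs <- gen_respiration(cfg)
  sp <- power_spectrum(rs$rvt_envelope$rvt - mean(rs$rvt_envelope$rvt),
                       fs = 1, window_s = 128)
  inband <- sp$freq_hz <= 0.16
  expect_gt(sum(sp$power[inband]) / sum(sp$power), 0.95)
})

test_that("config YAML round-trips", {
  cfg <- quick_cfg(coupling_strength = 0.25)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(unclass(cfg), unclass(cfg2)[names(unclass(cfg))])
})
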