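test_that("channel alignment recovers known lags and sums correctly", {
  set.seed(1)
  fs <- 500
  x <- as.numeric(stats::filter(rnorm(5000), rep(1, 5) / 5, sides = 2))
  x[is.na(x)] <- 0
  # two identical channels: zero lags, doubled output
  rec <- ephys_rec(rbind(x, x), fs = fs)
  al <- align_and_sum_channels(rec)
  expect_equal(al$lags, c(0L, 0L))
  expect_equal(al$summed, 2 * x)
  # delayed copy: lag recovered, equal to the brute-force oracle
  y <- c(rep(0, 5), x[1:(length(x) - 5)]) # x delayed by 5 samples
  rec2 <- ephys_rec(rbind(x, y), fs = fs)
  al2 <- align_and_sum_channels(rec2)
  expect_equal(al2$lags[2], 5L)
  expect_equal(al2$lags[2], lag_oracle(x, y, round(0.01 * fs)))
  # single channel passes through
  al3 <- align_and_sum_channels(ephys_rec(x, fs = fs))
  expect_identical(al3$summed, x)
  # zero channel warns, lag 0
  expect_warning(al4 <- align_and_sum_channels(ephys_rec(rbind(x, 0 * x), fs)),
                 "zero variance")
  expect_equal(al4$lags[2], 0L)
})

test_that("templates equal the artifact for a pure periodic artifact and shrink as 1/n_volumes", {
  fs <- 1000
  n_slices <- 4
  shape_len <- round(1 / n_slices * fs)
  build_trace <- function(n_volumes, noise_sd) {
    sched <- slice_schedule(1, n_slices, n_volumes)
    base <- rnorm(n_volumes * fs, sd = noise_sd)
    inj <- inject_mr_artifact(base, fs, sched, amplitude = 2)
    list(trace = inj$contaminated, sched = sched,
         shapes = t(vapply(1:n_slices, function(s)
           2 * respnet:::artifact_shape(s, shape_len, fs), numeric(shape_len))))
  }
  set.seed(2)
  pure <- build_trace(10, 0)
  tm <- build_templates(pure$trace, fs, pure$sched, align_pass = FALSE)
  expect_equal(tm$templates, pure$shapes, tolerance = 1e-12)
  # single volume: template is the single segment
  one <- build_trace(1, 0.5)
  tm1 <- build_templates(one$trace, fs, one$sched, align_pass = FALSE)
  expect_equal(tm1$templates[2, ], one$trace[(shape_len + 1):(2 * shape_len)])
  # template MSE decreases ~ 1/n_volumes
  mse <- vapply(c(10, 100, 400), function(nv) {
    tr <- build_trace(nv, 1)
    t2 <- build_templates(tr$trace, fs, tr$sched, align_pass = FALSE)
    mean((t2$templates - tr$shapes)^2)
  }, numeric(1))
  expect_gt(mse[1] / mse[2], 5)   # x10 volumes ~ x10 less MSE
  expect_gt(mse[2] / mse[3], 2)   # x4 volumes ~ x4 less
})

test_that("template regression removes a pure artifact and ignores orthogonal templates", {
  fs <- 1000
  sched <- slice_schedule(1, 4, 20)
  art <- inject_mr_artifact(numeric(20 * fs), fs, sched, amplitude = 3)
  tm <- build_templates(art$contaminated, fs, sched)
  out <- regress_templates(art$contaminated, tm, sched)
  expect_lt(sqrt(mean(out^2)) / sqrt(mean(art$contaminated^2)), 0.01)
  # clean sinusoid vs orthogonal templates: fit coefficient ~ 0
  t <- (seq_len(20 * fs) - 1) / fs
  clean <- sin(2 * pi * 2 * t) # 2 Hz, orthogonal-ish to the 130/210 Hz shapes
  out2 <- regress_templates(clean, tm, sched, max_lag = 0)
  expect_gt(cor(out2, clean), 0.999)
  # zero-amplitude artifact: near-zero template, trace unchanged
  art0 <- inject_mr_artifact(clean, fs, sched, amplitude = 0)
  expect_warning(
    tm0 <- build_templates(art0$contaminated - clean, fs, sched),
    NA
  )
})

test_that("denoising is idempotent to first order and does not invent signal", {
  cfg <- quick_cfg(ephys_fs = 1000)
  rs <- gen_respiration(cfg)
  lf <- gen_lfp(cfg, rs)
  sched <- schedule_from_config(cfg)
  inj <- inject_mr_artifact(lf$lfp, 1000, sched, amplitude = 10)
  den <- denoise_mr_artifact(ephys_rec(inj$contaminated, 1000), sched)
  twice <- regress_templates(den$denoised, den$templates, sched)
  expect_lt(abs(sd(twice) - sd(den$denoised)) / sd(den$denoised), 0.01)
  # out-of-artifact-band power is not increased by more than 5%
  ps_clean <- power_spectrum(inj$clean, 1000, window_s = 10)
  ps_den <- power_spectrum(den$denoised, 1000, window_s = 10)
  off <- abs(ps_clean$freq_hz - round(ps_clean$freq_hz / 20) * 20) > 1 &
    ps_clean$freq_hz < 300
  expect_lt(sum(ps_den$power[off]), 1.05 * sum(ps_clean$power[off]))
})

test_that("notch cascade suppresses line/slice harmonics and passes the LFP band", {
  fs <- 2000
  t <- (seq_len(20 * fs) - 1) / fs
  core <- (5 * fs):(15 * fs) # avoid filtfilt edge transients
  x60 <- sin(2 * pi * 60 * t)
  y60 <- notch_and_bandpass(x60, fs)
  atten_db <- 10 * log10(mean(x60[core]^2) / mean(y60[core]^2))
  expect_gt(atten_db, 40)
  x35 <- sin(2 * pi * 35 * t)
  y35 <- notch_and_bandpass(x35, fs)
  expect_lt(abs(sd(y35[core]) / sd(x35[core]) - 1), 0.05)
  # DC offset removed by the 0.1 Hz highpass edge
  ydc <- notch_and_bandpass(x35 + 7, fs)
  expect_lt(abs(mean(ydc[core])), 0.01)
  expect_error(notch_and_bandpass(x35, fs = 500), "fs")
})

test_that("band power separates bands and tracks amplitude modulation", {
  fs <- 500
  t <- (seq_len(60 * fs) - 1) / fs
  pure <- sin(2 * pi * 70 * t)
  g <- band_power(pure, fs, "gamma")
  d <- band_power(pure, fs, "delta")
  expect_lt(sd(g$power) / mean(g$power), 0.01) # constant gamma power
  expect_lt(mean(d$power), 0.01 * mean(g$power))
  # AM carrier: gamma power tracks the squared modulation envelope
  env <- 1 + 0.5 * sin(2 * pi * 0.05 * t)
  am <- env * sin(2 * pi * 70 * t)
  bp <- band_power(am, fs, "gamma")
  env_c <- 1 + 0.5 * sin(2 * pi * 0.05 * bp$time_s)
  expect_gt(cor(bp$power, env_c^2), 0.95)
  # zero signal gives zero power
  z <- band_power(numeric(10 * fs), fs, "beta")
  expect_true(all(z$power == 0))
  expect_error(band_power(pure, fs, band = c(10, 400)), "Nyquist")
})

test_that("multi-band power equals per-band computation", {
  cfg <- quick_cfg(ephys_fs = 500)
  sim <- simulate_study(cfg)
  multi <- band_power_multi(sim$lfp$lfp, 500)
  single <- band_power(sim$lfp$lfp, 500, "theta")
  expect_equal(multi$theta$power, single$power)
})

test_that("injected artifact is removed end-to-end with high fidelity", {
  cfg <- sim_config(duration_s = 60, n_volumes = 60, ephys_fs = 1000,
                    seed = 21)
  rs <- gen_respiration(cfg)
  lf <- gen_lfp(cfg, rs)
  sched <- schedule_from_config(cfg)
  inj <- inject_mr_artifact(lf$lfp, 1000, sched, amplitude = 10)
  den <- denoise_mr_artifact(ephys_rec(inj$contaminated, 1000), sched)
  expect_gt(cor(den$denoised, inj$clean), 0.99)
})
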