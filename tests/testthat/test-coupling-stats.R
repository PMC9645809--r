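test_that("coherence of a series with itself is 1 and a pure delay gives phase -2 pi f tau", {
  set.seed(3)
  x <- as.numeric(stats::filter(rnorm(4096), rep(1, 3) / 3, sides = 1))
  x[is.na(x)] <- 0
  co <- msc(x, x, fs = 1, window_s = 256)
  expect_true(all(abs(co$msc[co$freq_hz > 0] - 1) < 1e-9))
  # delay by 4 samples: coherence stays ~1, phase slope = -2 pi f * 4
  tau <- 4
  y <- c(rep(0, tau), x[1:(length(x) - tau)])
  co2 <- msc(x, y, fs = 1, window_s = 256)
  lowf <- co2$freq_hz > 0 & co2$freq_hz < 0.1
  expect_gt(min(co2$msc[lowf]), 0.95)
  pred <- -2 * pi * co2$freq_hz[lowf] * tau
  err <- Arg(exp(1i * (co2$phase_rad[lowf] - pred)))
  expect_lt(max(abs(err)), 0.05)
})

test_that("independent white noise shows only the 1/K coherence bias floor", {
  set.seed(8)
  n <- 4096
  co <- msc(rnorm(n), rnorm(n), fs = 1, window_s = 128)
  K <- attr(co, "n_windows")
  # E[msc] ~ 1/K for independent series; allow generous slack
  expect_lt(mean(co$msc[co$freq_hz > 0]), 3 / K)
  expect_error(msc(rnorm(50), rnorm(50), fs = 1, window_s = 50),
               "fewer than 2 windows")
})

test_that("the HRF kernel peaks at its analytic mode and is peak-normalised and causal", {
  tg <- seq(0, 30, by = 0.001)
  # gamma(shape 3, scale 0.8) has mode (3 - 1) * 0.8 = 1.6 s
  dens <- dgamma(tg, shape = 3, scale = 0.8)
  expect_equal(tg[which.max(dens)], 1.6, tolerance = 1e-9)
  k <- hrf_kernel(tr_s = 0.001)
  expect_equal(max(k), 1)
  expect_equal((which.max(k) - 1) * 0.001, 1.6, tolerance = 0.002)
  expect_equal(k[1], 0)
  # impulse response of the convolution is the kernel itself
  x <- c(1, rep(0, 49))
  y <- hrf_convolve(x, tr_s = 1)
  kk <- hrf_kernel(tr_s = 1)
  expect_equal(y[seq_along(kk)], kk, tolerance = 1e-10)
  expect_true(all(abs(y[-seq_along(kk)]) < 1e-12))
  # DC gain: a constant input maps to a constant scaled by sum(kernel)
  const <- hrf_convolve(rep(2, 100), tr_s = 1)
  expect_equal(const[60], 2 * sum(hrf_kernel(tr_s = 1)), tolerance = 1e-10)
})

test_that("voxelwise correlation reproduces exact constructions", {
  nt <- 80
  set.seed(12)
  reg <- rnorm(nt)
  arr <- array(rnorm(3 * 3 * 1 * nt, sd = 0.5), c(3, 3, 1, nt))
  arr[1, 1, 1, ] <- 2 * reg + 1   # r = +1
  arr[2, 1, 1, ] <- -reg          # r = -1
  arr[3, 1, 1, ] <- 7             # zero variance -> r = 0, flagged
  b <- bold_data(arr, 1)
  m <- voxelwise_corr(b, reg)
  expect_equal(m$r_map[1, 1, 1], 1)
  expect_equal(m$r_map[2, 1, 1], -1)
  expect_equal(m$r_map[3, 1, 1], 0)
  expect_gte(attr(m, "n_flagged"), 1)
  # agrees with stats::cor voxel by voxel
  expect_equal(m$r_map[1, 2, 1], cor(arr[1, 2, 1, ], reg), tolerance = 1e-12)
})

test_that("regress_out removes exactly the fitted component", {
  set.seed(13)
  conf <- rnorm(100)
  sig <- 3 * conf + rnorm(100)
  res <- regress_out(sig, conf)
  expect_lt(abs(cor(res, conf)), 1e-10)
  expect_lt(abs(mean(res)), 1e-10)
  expect_warning(r2 <- regress_out(sig, rep(1, 100)), "constant confound")
  expect_equal(r2, sig - mean(sig))
})

test_that("seed maps behave on trivial seeds", {
  set.seed(14)
  arr <- array(rnorm(2 * 2 * 1 * 60), c(2, 2, 1, 60))
  b <- bold_data(arr, 1)
  seed <- array(FALSE, c(2, 2, 1)); seed[1, 1, 1] <- TRUE
  m <- seedmap(b, seed)
  expect_equal(m$r_map[1, 1, 1], 1) # seed voxel correlates 1 with itself
  expect_equal(m$r_map[2, 2, 1], cor(arr[1, 1, 1, ], arr[2, 2, 1, ]),
               tolerance = 1e-12)
  expect_error(seedmap(b, array(FALSE, c(2, 2, 1))), "empty seed")
})

test_that("RSFC matrix matches the double-loop oracle and stays near zero for independent noise", {
  set.seed(15)
  ts <- matrix(rnorm(5 * 400), 5, 400)
  R <- rsfc_matrix(ts)
  expect_equal(R, rsfc_oracle(ts), tolerance = 1e-12)
  expect_true(isSymmetric(R))
  expect_equal(diag(R), rep(1, 5))
  off <- R[upper.tri(R)]
  expect_lt(max(abs(off)), 4 / sqrt(400)) # ~4 SE bound for independent series
  # identical pair gives exactly 1
  R2 <- rsfc_matrix(rbind(ts[1, ], ts[1, ]))
  expect_equal(R2[1, 2], 1)
})

test_that("spatial map correlation hits the exact poles", {
  A <- array(rnorm(27), c(3, 3, 3))
  mask <- array(TRUE, c(3, 3, 3))
  expect_equal(spatial_map_corr(A, 2 * A + 1, mask), 1)
  expect_equal(spatial_map_corr(A, -A, mask), -1)
  expect_error(spatial_map_corr(A, A, array(FALSE, c(3, 3, 3))), "empty mask")
})

test_that("Fisher-z round-trips and paired group t equals the one-sample t on differences", {
  r <- c(-0.9, -0.2, 0, 0.4, 0.99)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-10)
  set.seed(16)
  dims <- c(4, 4, 1)
  mask <- array(TRUE, dims)
  mk <- function() stat_map(mask, r_map = array(runif(16, -0.5, 0.5), dims))
  mapsA <- replicate(6, mk(), simplify = FALSE)
  mapsB <- replicate(6, mk(), simplify = FALSE)
  paired <- group_ttest_maps(mapsA, mapsB)
  # one-sample on per-scan z differences, done by hand
  ZA <- sapply(mapsA, function(m) fisher_z(m$r_map[mask]))
  ZB <- sapply(mapsB, function(m) fisher_z(m$r_map[mask]))
  D <- ZA - ZB
  t_hand <- apply(D, 1, function(d) mean(d) / (sd(d) / sqrt(length(d))))
  expect_equal(paired$t_map[mask], t_hand, tolerance = 1e-10)
  expect_equal(paired$df, 5)
  # one-sample path: constant maps across scans give zero-variance warning
  same <- replicate(3, mapsA[[1]], simplify = FALSE)
  expect_warning(group_ttest_maps(same), "zero-variance")
})

test_that("BH-FDR flags match the exhaustive step-up oracle on randomised instances", {
  set.seed(17)
  for (i in 1:200) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1) # skew toward small values sometimes
    a <- runif(1, 0.01, 0.2)
    expect_identical(fdr_bh(p, a), bh_oracle(p, a))
  }
  expect_identical(fdr_bh(numeric(0)), logical(0))
  expect_identical(fdr_bh(c(0.001, 0.9)), c(TRUE, FALSE))
  expect_error(fdr_bh(c(0.5, 1.2)), ".")
})

test_that("correlation p-values match frozen analytic references", {
  # r = 0.5, n = 10: t = 0.5 sqrt(8 / 0.75); frozen via 2*pt(.) in a
  # separate session
  expect_equal(pearson_pvalue(0.5, 10), 0.1411132813, tolerance = 1e-9)
  expect_equal(pearson_pvalue(0, 50), 1)
  expect_equal(pearson_pvalue(1, 10), 0)
  expect_equal(pearson_pvalue(-0.3, 20), pearson_pvalue(0.3, 20))
  expect_equal(t_pvalue(0, 10), 1)
  expect_error(pearson_pvalue(0.5, 2), "n")
})

test_that("two-sample pooled t reproduces hand arithmetic and stats::t.test", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 3, 4, 5)
  res <- two_sample_t(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(res$df, 6)
  expect_warning(z <- two_sample_t(c(1, 1), c(1, 1)), "zero pooled variance")
  expect_equal(z$t, 0)
})

test_that("circular mean handles wraparound that the arithmetic mean gets wrong", {
  phi <- c(pi - 0.1, -pi + 0.1) # both near +/- pi; arithmetic mean ~ 0
  expect_equal(abs(circular_mean(phi)), pi, tolerance = 1e-9)
  expect_equal(circular_mean(c(0.3, 0.3, 0.3)), 0.3, tolerance = 1e-12)
})

test_that("spectral slope separates white from pink noise", {
  with_seed(19, {
    w <- rnorm(2^15)
    p <- pink_noise(2^15)
  })
  sw <- spectral_slope(power_spectrum(w, fs = 1, window_s = 1024),
                       f_range = c(0.01, 0.4))
  sp <- spectral_slope(power_spectrum(p, fs = 1, window_s = 1024),
                       f_range = c(0.01, 0.4))
  expect_lt(abs(sw), 0.2)
  expect_lt(abs(sp + 1), 0.2)
})

test_that("mediation collapses a purely neurally mediated map and spares a vascular one", {
  # direct construction: voxel = HRF(gamma), RVT shares the same slow source
  set.seed(20)
  nt <- 400
  slow <- sin(2 * pi * 0.035 * (0:(nt - 1))) +
    0.3 * sin(2 * pi * 0.01 * (0:(nt - 1)))
  rvt <- slow + rnorm(nt, sd = 0.1)
  gamma <- slow + rnorm(nt, sd = 0.1)
  arr <- array(rnorm(2 * 2 * 1 * nt, sd = 0.2), c(2, 2, 1, nt))
  h <- hrf_convolve(gamma, tr_s = 1)
  arr[1, 1, 1, ] <- arr[1, 1, 1, ] + as.numeric(scale(h))        # mediated
  rrf_ts <- rrf_convolve(rvt, tr_s = 1)
  arr[2, 2, 1, ] <- arr[2, 2, 1, ] + as.numeric(scale(rrf_ts))   # vascular
  b <- bold_data(arr, 1)
  med <- mediation_analysis(b, rvt, gamma)
  m_med <- array(FALSE, c(2, 2, 1)); m_med[1, 1, 1] <- TRUE
  expect_gt(med$reduction(m_med), 0.6)
  expect_equal(med$diff_map, med$pre$r_map - med$post$r_map)
  # control: gamma power unrelated to RVT leaves the vascular (RRF-pathway)
  # correlation essentially untouched
  gamma_ind <- as.numeric(stats::filter(rnorm(nt), rep(1, 8) / 8,
                                        sides = 1))
  gamma_ind[is.na(gamma_ind)] <- 0
  med2 <- mediation_analysis(b, rvt, gamma_ind)
  expect_lt(abs(abs(med2$pre$r_map[2, 2, 1]) -
                abs(med2$post$r_map[2, 2, 1])), 0.1)
})
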