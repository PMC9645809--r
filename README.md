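# respnet

Analysis of the coupling between slow respiration variations, gamma-band
local field potential (LFP) power, and resting-state BOLD fMRI — with a
fully ground-truthed synthetic-data generator for end-to-end validation.

## The science

In lightly sedated resting-state recordings, breathing depth drifts slowly
(≲ 0.15 Hz). These slow respiration variations — quantified as *respiration
volume per time* (RVT: breath depth divided by breath period, per breath) —
track the amplitude envelope of gamma-band (40–100 Hz) LFP activity, and
both correlate with widespread BOLD fluctuations. The key question is
whether the RVT–BOLD correlation is *neurally mediated* (respiration ↔
gamma activity → hemodynamics) or a vascular/motion artifact of breathing
itself. `respnet` implements the full computational chain behind that
question:

- **Ephys preprocessing** — MR gradient-artifact removal by slice-locked
  template regression (channel alignment, per-slice template averaging with
  a jitter-robust refinement pass, scaled subtraction), zero-phase notch
  cascades, band-pass filtering, and STFT band power.
- **Respiration metrics** — prominence-based peak/trough detection, RVT on
  the TR grid, instantaneous respiration rate, RETROICOR phase regressors,
  and the respiration response function (RRF)
  `0.6 t^2.1 e^(−t/1.6) − 0.0023 t^3.54 e^(−t/4.25)`.
- **fMRI preprocessing** — framewise displacement, motion scrubbing,
  voxel-wise nuisance regression, mask-normalised Gaussian smoothing, ROI
  extraction.
- **Coupling statistics** — Welch magnitude-squared coherence with
  cross-spectral phase, phase-randomised surrogate nulls, HRF convolution,
  voxel-wise correlation maps, the gamma-regression mediation analysis,
  seed maps, ROI×ROI connectivity, Fisher-z group t-tests with
  Benjamini–Hochberg FDR.
- **Synthetic data** — a generator whose defaults mirror the study
  conditions (225 Hz respiration at ~1.1 Hz with 0.035 Hz depth
  modulation, 24,414 Hz nominal ephys, TR = 1 s × 1200 volumes, 32×32×4
  grid), with analytic RVT, true gamma envelope, component masks, and an
  isoelectric (flat-LFP, matched-respiration) control condition.

Tabular results are tibbles; models expose `tidy()`/`glance()` methods and
`autoplot()` visualisations.

## Worked example

Simulate a 600-volume scan, recover RVT, compute RVT–gamma coherence, and
run the mediation analysis:

```r
library(respnet)

cfg <- sim_config(n_volumes = 600, ephys_fs = 1000, seed = 1)
sim <- simulate_study(cfg)

ext <- detect_extrema(sim$resp$resp)
rvt <- compute_rvt(ext, tr_s = cfg$tr_s, n_volumes = cfg$n_volumes)
glance(rvt)
#> # A tibble: 1 × 4
#>   mean_rvt sd_rvt     n  tr_s
#>      <dbl>  <dbl> <int> <dbl>
#> 1     2.23  0.465   600     1

bp <- band_power_per_tr(band_power(sim$lfp$lfp, fs = 1000, band = "gamma"),
                        cfg$tr_s, cfg$n_volumes)
coh <- rvt_band_coherence(rvt, bp)
attr(coh, "peak")
#> # A tibble: 1 × 4
#>   peak_freq_hz peak_msc peak_phase_rad n_windows
#>          <dbl>    <dbl>          <dbl>     <int>
#> 1       0.0352    0.999         0.0488         3
```

The coherence peak lands at the configured 0.035 Hz depth-modulation
frequency (one 1/256 Hz bin away), with near-zero phase at the true
zero-lag coupling.

```r
map <- voxelwise_corr(sim$bold, rvt$rvt)
mean(abs(map$r_map[sim$truth$network_mask]))
#> [1] 0.586

med <- mediation_analysis(sim$bold, rvt, bp$power)
med$reduction(sim$truth$network_mask)
#> [1] 0.891
```

Regressing gamma power out of RVT (and its HRF convolution out of the BOLD
series) removes 89% of the RVT–BOLD correlation in the neurally coupled
block — the mediation signature. Analytic statistics are also exposed
directly:

```r
pearson_pvalue(0.086, 1200)
#> [1] 0.002867952
```

A thin CLI wrapping the same functions is installed at
`system.file("cli", "respnet", package = "respnet")` with subcommands
`simulate`, `rvt`, `band-power`, `coherence`, `corr-map`, `mediate`, and
`group-stats`.

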