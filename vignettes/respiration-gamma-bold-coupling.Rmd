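---
title: "Methods: respiration-gamma-BOLD coupling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respiration-gamma-BOLD coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`respnet` implements an analysis chain for studying the coupling between
slow respiration variations, gamma-band local field potential (LFP) power,
and resting-state BOLD fMRI, together with a synthetic-data generator that
reproduces the generative structure of that coupling. This vignette
documents the underlying model, the estimators, the numerical choices, and
the limitations.

## 1. The generative model

The generator produces three jointly coupled modalities from one
`sim_config()`.

### Respiration

The respiration waveform is a sinusoid at the base breathing rate
$f_r$ (default 1.1 Hz, sampled at 225 Hz) whose *depth* is modulated by a
slow process $m(t)$:

$$x(t) = \big(1 + d\, m(t)\big)\, \sin(2\pi f_r t) + \varepsilon(t)$$

where $d$ is `slow_mod_depth` (default 0.3, must be < 1 so breaths never
invert), $m(t)$ is either a sinusoid at `slow_mod_freq_hz` (default
0.035 Hz) or band-limited Gaussian noise confined below 0.15 Hz, and
$\varepsilon$ is small sensor noise. Because breath depth is
$2(1 + d\,m(t))$ and the breath period is $1/f_r$, the analytic
respiration-volume-per-time (RVT) envelope is available in closed form,
$\mathrm{RVT}(t) = 2 f_r (1 + d\, m(t))$, and is returned as ground truth.

### LFP

The LFP (nominal 24,414 Hz; any rate is accepted) is the sum of

* pink background noise with power $\propto 1/f$,
* a respiration-entrained oscillation, $0.5 \sin\phi(t)$ with $\phi$ the
  instantaneous respiratory phase,
* a gamma-band carrier (40-100 Hz band-limited noise) whose amplitude
  envelope follows the RVT envelope:
  $0.5\,c(t)\,\big(1 + \kappa\, z(\mathrm{RVT}(t - \tau))\big)$, where
  $\kappa$ is `coupling_strength`, $\tau$ is `coupling_lag_s`, and $z$
  denotes standardisation,
* white sensor noise (SD 0.05).

In the `isoelectric` condition all neural terms are zeroed while the
respiration trace is kept bit-identical — the flat-LFP control with matched
breathing.

### BOLD

Each voxel series on the configurable grid (default 32 x 32 x 4, TR = 1 s,
1200 volumes) sums

* $\beta_n\, z(\mathrm{HRF} \ast \text{gamma envelope})$ in a "network"
  voxel block (zeroed when isoelectric),
* $\beta_a\, z(\mathrm{RRF} \ast \mathrm{RVT}) + \beta_c (\sin\phi +
  \cos\phi)/\sqrt 2$ in a disjoint "artifact" block — the non-neural
  respiratory pathway (slow vascular response plus aliased cyclic motion),
* white noise everywhere inside a rectangular brain mask.

The defaults mirror a light-sedation resting-state rodent protocol: 225 Hz
respiration monitoring, TR 1 s, 1200 volumes, ~1.1 Hz breathing with
~0.035 Hz depth modulation, gamma defined as 40-100 Hz.

### Kernels

The respiration response function is

$$\mathrm{RRF}(t) = 0.6\, t^{2.1} e^{-t/1.6} - 0.0023\, t^{3.54} e^{-t/4.25}$$

with a peak at 3.07 s and an undershoot minimum near 15.4 s; it is sampled
on the TR grid over a 60 s support. The HRF is a gamma density (shape 3,
scale 0.8 s, mode 1.6 s), peak-normalised so regression coefficients keep
amplitude units, truncated at 30 s.

## 2. Estimators

**Ephys preprocessing.** MR gradient artifacts are removed by template
regression: channels are aligned by bounded cross-correlation and summed;
per-slice segment averages form templates (with one refinement pass that
re-aligns each segment to the first-pass template before re-averaging,
which makes the template robust to onset jitter); each segment is then
fitted by a least-squares-scaled, +/-3-sample-aligned template and the fit
subtracted. Filtering uses zero-phase (forward-backward) RBJ biquad notches
(Q = 30) at the slice and line frequencies and their harmonics up to
300 Hz, plus a 0.1-300 Hz Butterworth band (order 2 high-pass, order 4
low-pass). Band power comes from a short-time Fourier transform (1 s Hann
window, 0.1 s step, one-sided periodogram summed within band) and is
averaged within each TR to reach the 1 Hz analysis grid.

**Respiration metrics.** Extrema are detected with a topographic-prominence
threshold (10% of the waveform IQR), a minimum spacing of one
maximum-rate period, and strict peak/trough alternation. RVT at peak $i$ is
(peak minus following trough) / (time to next peak), timestamped at the
peak and linearly interpolated to the TR grid with held edges.
RETROICOR-style regressors are harmonics $\sin k\phi, \cos k\phi$ of the
linearly interpolated respiratory phase.

**Coherence.** Magnitude-squared coherence uses Welch averaging with
Hann-tapered, demeaned, 50%-overlapping windows;
$S_{xy} = \overline{X} Y$, so a delayed second series gives negative phase.
On the TR grid the window is 256 samples, resolving the 0.035 Hz
modulation with ~0.004 Hz bins. Significance is assessed against a
phase-randomised surrogate null that preserves the amplitude spectrum of
the band-power series.

**fMRI preprocessing.** Framewise displacement is the sum of absolute
translation differences plus 5 mm (rodent head radius) times the rotation
differences; volumes with FD > 0.25 mm are scrubbed together with their
immediate neighbours. Nuisance regression is voxel-wise OLS via a QR
decomposition. Spatial smoothing is mask-normalised separable Gaussian
smoothing (data and mask smoothed separately and divided) with each
volume's in-mask mean restored exactly afterwards, so smoothing never
shifts regional means.

**Coupling statistics.** Voxel-wise Pearson maps, seed maps, and ROI x ROI
correlation matrices are vectorised but verified against brute-force
loops. The mediation analysis regresses the gamma-power regressor out of
RVT and the *HRF-convolved* gamma power out of every voxel series, then
recomputes the map: a neurally mediated RVT-BOLD correlation collapses
while an RRF-pathway correlation survives. The HRF-convolved default
matters because BOLD lags neural activity; removing the raw envelope
leaves a correlated quadrature residual and understates mediation (a raw
variant is available via `hrf_convolve_gamma = FALSE`). Group inference
Fisher-z transforms correlation maps before one-sample or paired t-tests
with Benjamini-Hochberg FDR control; per-scan cross-spectral phases are
pooled with a circular mean.

## 3. Numerical choices

* Signals are demeaned before zero-phase filtering, and filter quality is
  assessed away from the filtfilt edge transients.
* Welch windows are demeaned individually, which suppresses DC leakage into
  the lowest bins.
* `band_power_multi()` computes one STFT and integrates all bands from it.
* Analyses in the examples run the LFP at 1000 Hz. All gamma-band
  information lives below 100 Hz, so analysis at 1 kHz is equivalent to
  analysis of a decimated 24,414 Hz acquisition while keeping runtimes
  small; every routine accepts the full rate.
* The two-sample t-test uses the pooled-variance form with
  $\mathrm{df} = n_1 + n_2 - 2$.

## 4. Scope of the generator

The generator is a *mechanistic sanity model*, not a biophysical
simulation: breathing is sinusoidal rather than physiologically shaped,
neural background is stationary pink noise, the BOLD geometry is
rectangular blocks, and head motion is absent (motion utilities are
exercised with synthetic motion tables). It is designed so every analysis
stage has known ground truth — the analytic RVT envelope, the true gamma
envelope, the component masks, and the injected artifact — which is what
the test suite checks against.

## 5. Worked example

```{r example, eval = FALSE}
library(respnet)

cfg <- sim_config(n_volumes = 600, ephys_fs = 1000, seed = 1)
sim <- simulate_study(cfg)

rvt <- compute_rvt(detect_extrema(sim$resp$resp), tr_s = cfg$tr_s,
                   n_volumes = cfg$n_volumes)
bp <- band_power_per_tr(band_power(sim$lfp$lfp, 1000, "gamma"),
                        cfg$tr_s, cfg$n_volumes)
coh <- rvt_band_coherence(rvt, bp)
attr(coh, "peak")

med <- mediation_analysis(sim$bold, rvt, bp$power)
med$reduction(sim$truth$network_mask)
```

## 6. Limitations

* RVT edge handling (holding the first/last breath value) biases the first
  and last few seconds of the regressor; with 1200-volume runs this is
  negligible but matters for very short segments.
* The surrogate null randomises the band-power series only; it tests the
  cross-series relation given the observed spectra, not generator
  misspecification.
* The rank of the mediation contrast depends on the RVT estimator quality;
  heavily noise-corrupted respiration traces degrade the reduction even
  when the underlying coupling is perfect.
* Coherence windows of 256 s mean runs shorter than ~384 volumes at
  TR = 1 s cannot be analysed with the default window; pass a smaller
  `window` explicitly for short runs.
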