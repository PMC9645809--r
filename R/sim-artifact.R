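#' Slice-acquisition schedule
#'
#' Onset times of every fMRI slice acquisition, used both to inject a
#' synthetic MR gradient artifact into electrophysiology and to build the
#' per-slice artifact templates that remove it.
#'
#' @param tr_s Repetition time (seconds).
#' @param n_slices Slices per volume.
#' @param n_volumes Number of volumes.
#' @param t0 Time of the first slice onset (seconds).
#' @return A tibble of class `slice_schedule` with columns `volume`,
#'   `slice`, `onset_s`; attributes `tr_s`, `n_slices`, `n_volumes`.
#' @export
slice_schedule <- function(tr_s, n_slices, n_volumes, t0 = 0) {
  stopifnot(tr_s > 0, n_slices >= 1, n_volumes >= 1)
  grid <- expand.grid(slice = seq_len(n_slices), volume = seq_len(n_volumes))
  out <- tibble(
    volume = grid$volume,
    slice = grid$slice,
    onset_s = t0 + (grid$volume - 1) * tr_s + (grid$slice - 1) * tr_s / n_slices
  )
  stopifnot(!is.unsorted(out$onset_s, strictly = TRUE))
  attr(out, "tr_s") <- tr_s
  attr(out, "n_slices") <- n_slices
  attr(out, "n_volumes") <- n_volumes
  class(out) <- c("slice_schedule", class(out))
  out
}

#' @param cfg A [sim_config()]; its `tr_s`, `n_slices`, `n_volumes` are used.
#' @rdname slice_schedule
#' @export
schedule_from_config <- function(cfg) {
  slice_schedule(cfg$tr_s, cfg$n_slices, cfg$n_volumes)
}

# samples per slice-acquisition segment
segment_length <- function(schedule, fs) {
  round(attr(schedule, "tr_s") / attr(schedule, "n_slices") * fs)
}

# Fixed gradient-like waveform for a given slice index: fast oscillation
# burst with a slice-dependent phase so templates differ across slices.
artifact_shape <- function(slice, len, fs) {
  tau <- (seq_len(len) - 1) / fs
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1)) # Hann-like taper
  (sin(2 * pi * 130 * tau + slice) + 0.5 * sin(2 * pi * 210 * tau + 2 * slice)) * w
}

#' Inject a synthetic MR gradient artifact into an ephys trace
#'
#' Adds a fixed artifact waveform (identical shape per slice index, optional
#' small onset jitter) at every slice-acquisition onset, retaining the clean
#' trace so denoising can be validated against an exact oracle.
#'
#' @param trace Numeric voltage series.
#' @param fs Sampling rate (Hz).
#' @param schedule A [slice_schedule()] covering the trace duration.
#' @param amplitude Artifact amplitude (signal units, `>= 0`).
#' @param jitter_samples Maximum absolute onset jitter (samples); per-segment
#'   jitter is drawn uniformly from `-jitter_samples .. jitter_samples`.
#' @param seed Optional seed for the jitter draw.
#' @return A list with `contaminated`, `clean`, `artifact` (all numeric
#'   vectors of the input length) and `fs`.
#' @export
inject_mr_artifact <- function(trace, fs, schedule, amplitude,
                               jitter_samples = 0, seed = NULL) {
  if (amplitude < 0) abort("inject_mr_artifact: amplitude must be >= 0")
  n <- length(trace)
  len <- segment_length(schedule, fs)
  art <- numeric(n)
  with_seed(seed, {
    jit <- if (jitter_samples > 0) {
      sample(seq(-jitter_samples, jitter_samples), nrow(schedule),
             replace = TRUE)
    } else rep(0L, nrow(schedule))
    for (i in seq_len(nrow(schedule))) {
      start <- floor(schedule$onset_s[i] * fs) + 1L + jit[i]
      idx <- start:(start + len - 1L)
      keep <- idx >= 1L & idx <= n
      if (!any(keep)) next
      art[idx[keep]] <- art[idx[keep]] +
        amplitude * artifact_shape(schedule$slice[i], len, fs)[keep]
    }
  })
  list(contaminated = trace + art, clean = trace, artifact = art, fs = fs)
}
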