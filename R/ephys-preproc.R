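#' Electrophysiology recording container
#'
#' @param channels Numeric matrix, channel x sample (a vector is treated as
#'   one channel).
#' @param fs Sampling rate (Hz).
#' @param t0 Time of the first sample relative to fMRI start (seconds).
#' @return An object of class `ephys_rec`.
#' @export
ephys_rec <- function(channels, fs, t0 = 0) {
  if (is.vector(channels)) channels <- matrix(channels, nrow = 1)
  stopifnot(is.matrix(channels), fs > 0)
  structure(list(channels = channels, fs = fs, t0 = t0), class = "ephys_rec")
}

#' @export
print.ephys_rec <- function(x, ...) {
  cat(sprintf("<ephys_rec> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$channels), ncol(x$channels), x$fs,
              ncol(x$channels) / x$fs))
  invisible(x)
}

# integer-lag cross-correlation of y against x over lags -max_lag..max_lag;
# returns the lag maximising sum(x[t] * y[t + lag])
best_lag <- function(x, y, max_lag) {
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      n <- length(x) - l
      sum(x[seq_len(n)] * y[seq_len(n) + l])
    } else {
      n <- length(x) + l
      sum(x[seq_len(n) - l] * y[seq_len(n)])
    }
  }, numeric(1))
  lags[which.max(cc)]
}

shift_series <- function(y, lag) {
  # advance y by `lag` samples (so that y aligned to reference)
  n <- length(y)
  out <- numeric(n)
  if (lag >= 0) {
    out[seq_len(n - lag)] <- y[seq_len(n - lag) + lag]
  } else {
    out[seq_len(n + lag) - lag] <- y[seq_len(n + lag)]
  }
  out
}

#' Align channels to a reference and sum
#'
#' Corrects inter-channel phase differences by shifting each channel by the
#' integer lag that maximises its cross-correlation with channel 1 (bounded
#' by `max_lag_s`), then sums all channels into one series.
#'
#' @param rec An [ephys_rec()].
#' @param max_lag_s Maximum alignment lag (seconds; default 10 ms).
#' @return A list with `summed` (numeric series), `lags` (samples, one per
#'   channel), `fs`.
#' @export
align_and_sum_channels <- function(rec, max_lag_s = 0.01) {
  ch <- rec$channels
  stopifnot(nrow(ch) >= 1)
  max_lag <- max(1L, round(max_lag_s * rec$fs))
  ref <- ch[1, ]
  lags <- integer(nrow(ch))
  summed <- ref
  if (nrow(ch) > 1) {
    for (k in 2:nrow(ch)) {
      y <- ch[k, ]
      if (all(y == 0) || var(y) == 0) {
        warn(sprintf("align_and_sum_channels: channel %d has zero variance; lag set to 0", k))
        lags[k] <- 0L
      } else {
        lags[k] <- best_lag(ref, y, max_lag)
      }
      summed <- summed + shift_series(y, lags[k])
    }
  }
  list(summed = summed, lags = lags, fs = rec$fs)
}

#' Build per-slice MR-artifact templates
#'
#' Segments the summed trace into half-open windows
#' `[onset, onset + tr/n_slices)` (sample index `floor(onset * fs)`), groups
#' segments by slice index, and averages — the MR interference template per
#' slice. Segments extending past the end of the trace are dropped with a
#' warning.
#'
#' @param summed Numeric voltage series.
#' @param fs Sampling rate (Hz).
#' @param schedule A [slice_schedule()].
#' @param align_pass If `TRUE`, refine each template once by re-averaging
#'   segments after aligning them to the first-pass template by
#'   cross-correlation — robust to small onset jitter.
#' @param max_lag Alignment bound for the refinement pass (samples).
#' @return A list of class `artifact_templates`: `templates` (matrix,
#'   slice x sample), `seg_len`, `n_used` per slice, `fs`.
#' @export
build_templates <- function(summed, fs, schedule, align_pass = TRUE,
                            max_lag = 3) {
  len <- segment_length(schedule, fs)
  n <- length(summed)
  n_slices <- attr(schedule, "n_slices")
  starts <- floor(schedule$onset_s * fs) + 1L
  usable <- starts >= 1L & starts + len - 1L <= n
  if (any(!usable)) {
    warn(sprintf("build_templates: %d segment(s) outside the trace were dropped",
                 sum(!usable)))
  }
  average_segments <- function(lag_fun) {
    tot <- matrix(0, n_slices, len)
    cnt <- integer(n_slices)
    for (i in which(usable)) {
      s <- schedule$slice[i]
      seg <- summed[starts[i]:(starts[i] + len - 1L)]
      lag <- lag_fun(seg, s)
      if (lag != 0L) seg <- shift_series(seg, lag)
      tot[s, ] <- tot[s, ] + seg
      cnt[s] <- cnt[s] + 1L
    }
    if (any(cnt == 0)) abort("build_templates: some slice indices have no complete segments")
    tot / cnt
  }
  templates <- average_segments(function(seg, s) 0L)
  if (align_pass && max_lag > 0) {
    first <- templates
    templates <- average_segments(function(seg, s) {
      # shift the segment so it lines up with the first-pass template
      best_lag(first[s, ], seg, max_lag)
    })
  }
  structure(
    list(templates = templates, seg_len = len, n_used = NULL, fs = fs),
    class = "artifact_templates"
  )
}

#' Regress slice-locked artifact templates out of a trace
#'
#' For each slice acquisition the matching template is aligned by
#' cross-correlation (lag bounded by `max_lag`), scaled by a per-segment
#' least-squares fit, and subtracted. Samples outside every slice window
#' pass through unchanged.
#'
#' @param summed Numeric voltage series.
#' @param templates An `artifact_templates` from [build_templates()].
#' @param schedule The matching [slice_schedule()].
#' @param max_lag Alignment search bound (samples).
#' @return Denoised numeric series.
#' @export
regress_templates <- function(summed, templates, schedule, max_lag = 3) {
  fs <- templates$fs
  len <- templates$seg_len
  n <- length(summed)
  out <- summed
  warned <- FALSE
  for (i in seq_len(nrow(schedule))) {
    start <- floor(schedule$onset_s[i] * fs) + 1L
    if (start < 1L || start + len - 1L > n) next
    seg <- out[start:(start + len - 1L)]
    tmpl <- templates$templates[schedule$slice[i], ]
    tv <- sum((tmpl - mean(tmpl))^2)
    if (tv < .Machine$double.eps * len) {
      if (!warned) {
        warn("regress_templates: zero-variance template; segment(s) left unchanged")
        warned <- TRUE
      }
      next
    }
    lag <- if (max_lag > 0) best_lag(seg, tmpl, max_lag) else 0L
    tal <- shift_series(tmpl, lag)
    beta <- sum(seg * tal) / sum(tal * tal)
    out[start:(start + len - 1L)] <- seg - beta * tal
  }
  out
}

#' End-to-end MR-artifact denoising
#'
#' Channel alignment and summing, template construction, and template
#' regression in one call.
#'
#' @param rec An [ephys_rec()].
#' @param schedule A [slice_schedule()].
#' @param max_lag_s Channel-alignment bound (seconds).
#' @return A list with `denoised`, `summed`, `templates`, `lags`, `fs`.
#' @export
denoise_mr_artifact <- function(rec, schedule, max_lag_s = 0.01) {
  al <- align_and_sum_channels(rec, max_lag_s)
  tmpl <- build_templates(al$summed, al$fs, schedule)
  den <- regress_templates(al$summed, tmpl, schedule)
  list(denoised = den, summed = al$summed, templates = tmpl,
       lags = al$lags, fs = al$fs)
}
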