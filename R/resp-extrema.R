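# Candidate local maxima of x (strict rise, non-strict fall handles plateaus).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Topographic prominence of peaks at indices `pk` (ascending) in x.
peak_prominence <- function(x, pk) {
  vapply(seq_along(pk), function(i) {
    p <- pk[i]
    # walk left until a higher sample, track the minimum on the way
    left <- if (i == 1) 1L else pk[i - 1]
    lmin <- min(x[left:p])
    j <- i - 1
    while (j >= 1 && x[pk[j]] <= x[p]) {
      left <- if (j == 1) 1L else pk[j - 1]
      lmin <- min(lmin, min(x[left:pk[j]]))
      j <- j - 1
    }
    right <- if (i == length(pk)) length(x) else pk[i + 1]
    rmin <- min(x[p:right])
    j <- i + 1
    while (j <= length(pk) && x[pk[j]] <= x[p]) {
      right <- if (j == length(pk)) length(x) else pk[j + 1]
      rmin <- min(rmin, min(x[pk[j]:right]))
      j <- j + 1
    }
    x[p] - max(lmin, rmin)
  }, numeric(1))
}

# Greedy minimum-distance enforcement: keep the larger peak.
enforce_min_distance <- function(idx, height, min_dist) {
  if (length(idx) < 2) return(idx)
  ord <- order(height, decreasing = TRUE)
  keep <- logical(length(idx))
  taken <- integer(0)
  for (i in ord) {
    if (all(abs(idx[i] - taken) >= min_dist)) {
      keep[i] <- TRUE
      taken <- c(taken, idx[i])
    }
  }
  sort(idx[keep])
}

#' Detect respiratory peaks and troughs
#'
#' Finds inspiration maxima and expiration minima with a minimum inter-event
#' distance of one maximum-rate period and a topographic-prominence
#' threshold (default 10% of the waveform's inter-quartile range), then
#' enforces strict peak/trough alternation by dropping the lesser of two
#' consecutive same-type extrema.
#'
#' @param resp A [resp_trace()].
#' @param min_rate_hz,max_rate_hz Plausible respiration-rate bounds (Hz).
#' @param prominence_frac Prominence threshold as a fraction of the
#'   waveform IQR.
#' @return A tibble of class `extrema_series` with columns `time_s`,
#'   `value`, `type` (`"peak"`/`"trough"`), sorted by time and strictly
#'   alternating.
#' @export
#' @examples
#' tr <- resp_trace(sin(2 * pi * seq(0, 10, by = 1 / 225)), fs = 225)
#' table(detect_extrema(tr)$type)
detect_extrema <- function(resp, min_rate_hz = 0.3, max_rate_hz = 3,
                           prominence_frac = 0.1) {
  fs <- resp_fs(resp)
  stopifnot(min_rate_hz > 0, min_rate_hz < max_rate_hz, max_rate_hz < fs / 2)
  x <- resp$value
  thr <- prominence_frac * IQR(x)
  min_dist <- fs / max_rate_hz

  find <- function(v) {
    idx <- local_maxima(v)
    if (length(idx) == 0) return(integer(0))
    idx <- idx[peak_prominence(v, idx) >= thr]
    enforce_min_distance(idx, v[idx], min_dist)
  }
  pk <- find(x)
  tr <- find(-x)
  if (length(pk) == 0 || length(tr) == 0) {
    abort("no respiratory cycles detected")
  }

  ev <- tibble(
    idx = c(pk, tr),
    type = rep(c("peak", "trough"), c(length(pk), length(tr)))
  )
  ev <- ev[order(ev$idx), ]
  # enforce alternation: among runs of the same type keep the most extreme
  keep <- rep(TRUE, nrow(ev))
  i <- 1
  while (i < nrow(ev)) {
    if (ev$type[i] == ev$type[i + 1]) {
      a <- x[ev$idx[i]]; b <- x[ev$idx[i + 1]]
      drop_first <- if (ev$type[i] == "peak") a <= b else a >= b
      if (drop_first) {
        ev <- ev[-i, ]
      } else {
        ev <- ev[-(i + 1), ]
      }
    } else i <- i + 1
  }
  out <- tibble(
    time_s = resp$time_s[ev$idx],
    value = x[ev$idx],
    type = ev$type
  )
  class(out) <- c("extrema_series", class(out))
  out
}

#' Respiration volume per time (RVT)
#'
#' For each inspiration peak *i*, RVT is the peak value minus the following
#' trough value, divided by the interval to the next peak — breath depth per
#' breath period. Event values are linearly interpolated onto the TR grid;
#' edges hold the nearest value.
#'
#' @param extrema An `extrema_series` from [detect_extrema()].
#' @param tr_s Repetition time (seconds) of the output grid.
#' @param n_volumes Length of the output grid.
#' @param t0 Time of the first volume (seconds).
#' @param interval Use `"peaks"` (default) or `"troughs"` as the breath
#'   period markers.
#' @return A tibble of class `rvt_series` with columns `time_s`, `rvt` on
#'   the TR grid; the raw per-breath events are in `attr(, "events")`.
#' @export
compute_rvt <- function(extrema, tr_s = 1, n_volumes = NULL, t0 = 0,
                        interval = c("peaks", "troughs")) {
  interval <- match.arg(interval)
  pk <- extrema[extrema$type == "peak", ]
  tr <- extrema[extrema$type == "trough", ]
  if (nrow(pk) < 2) abort("compute_rvt: need at least 2 inspiration peaks")

  ev_t <- numeric(0); ev_v <- numeric(0)
  marker <- if (interval == "peaks") pk else tr
  for (i in seq_len(nrow(pk) - 1)) {
    # trough following peak i
    j <- which(tr$time_s > pk$time_s[i])
    if (length(j) == 0) next
    depth <- pk$value[i] - tr$value[j[1]]
    # breath period from consecutive markers around this breath
    k <- which(marker$time_s > pk$time_s[i] - 1e-9)
    if (interval == "peaks") {
      period <- pk$time_s[i + 1] - pk$time_s[i]
    } else {
      if (length(j) < 2) next
      period <- tr$time_s[j[2]] - tr$time_s[j[1]]
    }
    if (period <= 0) next
    ev_t <- c(ev_t, pk$time_s[i])
    ev_v <- c(ev_v, depth / period)
  }
  if (length(ev_v) == 0) abort("compute_rvt: no complete breaths found")
  if (length(ev_v) == 1) {
    warn("compute_rvt: single respiratory cycle; RVT is constant")
    ev_t <- c(ev_t, ev_t + 1); ev_v <- rep(ev_v, 2)
  }
  if (is.null(n_volumes)) {
    grid <- ev_t
  } else {
    grid <- t0 + (seq_len(n_volumes) - 1) * tr_s
  }
  vals <- approx(ev_t, ev_v, xout = grid, rule = 2)$y
  out <- tibble(time_s = grid, rvt = vals)
  attr(out, "events") <- tibble(time_s = ev_t, rvt = ev_v)
  attr(out, "tr_s") <- tr_s
  class(out) <- c("rvt_series", class(out))
  out
}

#' Instantaneous respiration rate
#'
#' Rate is the reciprocal inter-peak interval, timestamped at the interval
#' midpoint.
#'
#' @param extrema An `extrema_series` from [detect_extrema()].
#' @return A tibble (`time_s`, `rate_hz`) with attributes `mean_hz`, `sd_hz`.
#' @export
respiration_rate <- function(extrema) {
  pk <- extrema[extrema$type == "peak", ]
  if (nrow(pk) < 2) abort("respiration_rate: need at least 2 peaks")
  iv <- diff(pk$time_s)
  out <- tibble(
    time_s = pk$time_s[-nrow(pk)] + iv / 2,
    rate_hz = 1 / iv
  )
  attr(out, "mean_hz") <- mean(out$rate_hz)
  attr(out, "sd_hz") <- sd(out$rate_hz)
  out
}

#' @export
glance.rvt_series <- function(x, ...) {
  tibble(mean_rvt = mean(x$rvt), sd_rvt = sd(x$rvt),
         n = nrow(x), tr_s = attr(x, "tr_s"))
}
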