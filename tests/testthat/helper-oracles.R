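# Independent brute-force oracles, deliberately naive.

# Benjamini-Hochberg step-up by exhaustive threshold scan: find the largest
# k with p_(k) <= k/m * alpha, reject all p <= p_(k).
bh_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  if (m == 0) return(logical(0))
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * alpha) k <- i
  if (k == 0) return(rep(FALSE, m))
  p <= ps[k]
}

# naive topographic prominence of one extremum: walk each way to the
# nearest strictly higher sample, take the minimum en route, prominence is
# height above the larger of the two minima
prominence_naive <- function(x, p) {
  n <- length(x)
  l <- p
  while (l > 1 && x[l - 1] <= x[p]) l <- l - 1
  lmin <- min(x[max(1, l - 1):p])
  r <- p
  while (r < n && x[r + 1] <= x[p]) r <- r + 1
  rmin <- min(x[p:min(n, r + 1)])
  x[p] - max(lmin, rmin)
}

# exhaustive local-extrema scan with optional naive prominence filtering
# (threshold as a fraction of IQR, matching the documented contract) and
# alternation enforcement
extrema_oracle <- function(x, t, prominence_frac = 0) {
  n <- length(x)
  cand <- data.frame(i = integer(0), type = character(0))
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) {
      cand <- rbind(cand, data.frame(i = i, type = "peak"))
    } else if (x[i] < x[i - 1] && x[i] <= x[i + 1]) {
      cand <- rbind(cand, data.frame(i = i, type = "trough"))
    }
  }
  if (prominence_frac > 0 && nrow(cand) > 0) {
    thr <- prominence_frac * IQR(x)
    ok <- vapply(seq_len(nrow(cand)), function(k) {
      v <- if (cand$type[k] == "peak") x else -x
      prominence_naive(v, cand$i[k]) >= thr
    }, logical(1))
    cand <- cand[ok, ]
  }
  # alternation: keep the most extreme of consecutive same-type events
  repeat {
    same <- which(cand$type[-1] == cand$type[-nrow(cand)])
    if (length(same) == 0) break
    j <- same[1]
    a <- x[cand$i[j]]; b <- x[cand$i[j + 1]]
    drop <- if (cand$type[j] == "peak") {
      if (a <= b) j else j + 1
    } else {
      if (a >= b) j else j + 1
    }
    cand <- cand[-drop, ]
  }
  cand
}

# per-breath RVT by direct loop over detected peak/trough lists
rvt_oracle <- function(peak_t, peak_v, trough_t, trough_v) {
  out_t <- numeric(0); out_v <- numeric(0)
  for (i in seq_len(length(peak_t) - 1)) {
    j <- which(trough_t > peak_t[i])
    if (length(j) == 0) next
    depth <- peak_v[i] - trough_v[j[1]]
    out_t <- c(out_t, peak_t[i])
    out_v <- c(out_v, depth / (peak_t[i + 1] - peak_t[i]))
  }
  list(t = out_t, v = out_v)
}

# pairwise correlation matrix by explicit double loop
rsfc_oracle <- function(ts) {
  k <- nrow(ts)
  out <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) out[i, j] <- suppressWarnings(cor(ts[i, ], ts[j, ]))
  }
  diag(out)[!is.na(diag(out))] <- 1
  out
}

# integer-lag cross-correlation over every admissible lag
lag_oracle <- function(x, y, max_lag) {
  best <- -Inf; arg <- 0L
  for (l in -max_lag:max_lag) {
    if (l >= 0) {
      n <- length(x) - l
      v <- sum(x[seq_len(n)] * y[seq_len(n) + l])
    } else {
      n <- length(x) + l
      v <- sum(x[seq_len(n) - l] * y[seq_len(n)])
    }
    if (v > best) { best <- v; arg <- l }
  }
  arg
}

# per-label mean series by naive loop
roi_oracle <- function(arr4, labels) {
  labs <- sort(unique(labels[labels > 0]))
  nt <- dim(arr4)[4]
  out <- matrix(0, length(labs), nt)
  for (li in seq_along(labs)) {
    idx <- which(labels == labs[li], arr.ind = TRUE)
    for (tt in seq_len(nt)) {
      s <- 0
      for (r in seq_len(nrow(idx))) {
        s <- s + arr4[idx[r, 1], idx[r, 2], idx[r, 3], tt]
      }
      out[li, tt] <- s / nrow(idx)
    }
  }
  out
}

# small standard config for fast tests
quick_cfg <- function(...) {
  args <- list(n_volumes = 120, ephys_fs = 500, grid_shape = c(12L, 12L, 2L),
               seed = 42)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
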