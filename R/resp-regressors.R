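#' Respiratory phase at arbitrary times
#'
#' Phase runs linearly from 0 at one inspiration peak to 2*pi at the next.
#' Times before the first or after the last peak are extrapolated from the
#' adjacent cycle (with a warning when outside the record).
#'
#' @param extrema An `extrema_series` from [detect_extrema()].
#' @param times Numeric vector of query times (seconds).
#' @return Phase values in `[0, 2*pi)`.
#' @export
respiratory_phase <- function(extrema, times) {
  pk <- extrema$time_s[extrema$type == "peak"]
  if (length(pk) < 2) abort("respiratory_phase: need at least 2 peaks")
  if (any(times < pk[1] - mean(diff(pk)) | times > tail(pk, 1) + mean(diff(pk)))) {
    warn("respiratory_phase: some times fall outside the breathing record; phase extrapolated from the nearest cycle")
  }
  # cycle index per time: last peak at or before t (clamped)
  i <- findInterval(times, pk)
  i <- pmin(pmax(i, 1L), length(pk) - 1L)
  frac <- (times - pk[i]) / (pk[i + 1] - pk[i])
  (2 * pi * frac) %% (2 * pi)
}

#' RETROICOR respiratory phase regressors
#'
#' Sinusoids of the respiratory-cycle phase evaluated at the fMRI volume
#' times: columns `sin(k * phi), cos(k * phi)` for `k = 1..order`. Fitting
#' their linear combination per voxel ([retroicor_fit()]) models the fast
#' cyclic respiratory artifact.
#'
#' @param resp A [resp_trace()], or an `extrema_series` already detected.
#' @param volume_times Volume acquisition times (seconds).
#' @param order Highest harmonic (default 2: 4 columns).
#' @return A numeric matrix (`length(volume_times)` x `2 * order`) with
#'   columns `sin1, cos1, sin2, cos2, ...` and the phase in
#'   `attr(, "phase")`.
#' @export
retroicor_regressors <- function(resp, volume_times, order = 2) {
  stopifnot(order >= 1)
  ext <- if (inherits(resp, "extrema_series")) resp else detect_extrema(resp)
  phi <- respiratory_phase(ext, volume_times)
  X <- do.call(cbind, lapply(seq_len(order), function(k) {
    cbind(sin(k * phi), cos(k * phi))
  }))
  colnames(X) <- as.vector(vapply(seq_len(order), function(k)
    c(paste0("sin", k), paste0("cos", k)), character(2)))
  attr(X, "phase") <- phi
  X
}

#' Per-voxel fitted RETROICOR component
#'
#' Least-squares fit of the phase sinusoids to each voxel series; returns the
#' predicted fast-respiration component (the best-fitting linear combination
#' of sinusoids per voxel).
#'
#' @param bold A [bold_data()].
#' @param X Regressor matrix from [retroicor_regressors()].
#' @return A [bold_data()] holding the fitted component (zero outside mask).
#' @export
retroicor_fit <- function(bold, X) {
  stopifnot(nrow(X) == n_volumes(bold))
  Y <- mask_matrix(bold) # time x voxel
  Xi <- cbind(1, X)
  # qr.fitted is robust to rank-deficient designs (e.g. a harmonic that is
  # identically zero at the sampled phases)
  fit <- qr.fitted(qr(Xi), Y)
  d <- dim(bold$data)
  out <- array(0, d)
  m <- matrix(0, prod(d[1:3]), d[4])
  m[as.vector(bold$mask), ] <- t(fit)
  out[] <- m
  bold_data(out, tr_s = bold$tr_s, mask = bold$mask, vox_mm = bold$vox_mm)
}

#' Respiration response function (RRF)
#'
#' The canonical impulse response linking slow RVT changes to the BOLD
#' signal: `RRF(t) = 0.6 t^2.1 exp(-t/1.6) - 0.0023 t^3.54 exp(-t/4.25)`,
#' zero for `t < 0`.
#'
#' @param t Time (seconds), vectorised.
#' @return Kernel values.
#' @export
#' @examples
#' rrf(c(0, 1, 5, 15))
rrf <- function(t) {
  out <- 0.6 * t^2.1 * exp(-t / 1.6) - 0.0023 * t^3.54 * exp(-t / 4.25)
  out[t < 0] <- 0
  out
}

#' Convolve an RVT series with the RRF
#'
#' The kernel is sampled on the TR grid over a 60 s support (both gamma
#' variate terms are negligible beyond that) and convolved causally; output
#' is truncated to the input length.
#'
#' @param rvt Numeric RVT series on the TR grid, or an `rvt_series` tibble.
#' @param tr_s Repetition time (seconds).
#' @param support_s Kernel support (seconds).
#' @return Numeric series of the input length.
#' @export
rrf_convolve <- function(rvt, tr_s = 1, support_s = 60) {
  if (inherits(rvt, "rvt_series")) {
    tr_s <- attr(rvt, "tr_s") %||% tr_s
    rvt <- rvt$rvt
  }
  kern <- rrf(seq(0, support_s, by = tr_s))
  causal_convolve(rvt, kern)
}

# causal discrete convolution truncated to length(x)
causal_convolve <- function(x, kern) {
  n <- length(x)
  out <- stats::convolve(x, rev(kern), type = "open")[seq_len(n)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
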