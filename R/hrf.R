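#' Hemodynamic response function kernel
#'
#' A single gamma probability density, shape `a = 3`, scale `b = 0.8` s,
#' sampled on the TR grid over a 30 s support and peak-normalised (maximum
#' 1), so regression coefficients on HRF-convolved regressors keep the
#' input's amplitude scale. The kernel mode sits at `(a - 1) * b` seconds.
#'
#' @param tr_s Sampling interval (seconds).
#' @param a Shape parameter (dimensionless, `> 1`).
#' @param b Scale parameter (seconds, `> 0`).
#' @param support_s Kernel support (seconds).
#' @return Numeric kernel samples at `0, tr_s, 2 tr_s, ...`.
#' @export
hrf_kernel <- function(tr_s = 1, a = 3, b = 0.8, support_s = 30) {
  stopifnot(a > 1, b > 0)
  t <- seq(0, support_s, by = tr_s)
  k <- dgamma(t, shape = a, scale = b)
  peak <- dgamma((a - 1) * b, shape = a, scale = b)
  k / peak
}

#' Convolve a neural envelope with the HRF
#'
#' Causal discrete convolution of a TR-gridded envelope (e.g. gamma-band
#' power) with [hrf_kernel()], truncated to the input length — the predicted
#' BOLD response to that envelope.
#'
#' @param env Numeric series on the TR grid.
#' @param tr_s Repetition time (seconds).
#' @param a,b,support_s Passed to [hrf_kernel()].
#' @return Numeric series of the input length.
#' @export
#' @examples
#' imp <- c(1, rep(0, 29))
#' plot(hrf_convolve(imp, tr_s = 0.5), type = "l")
hrf_convolve <- function(env, tr_s = 1, a = 3, b = 0.8, support_s = 30) {
  stopifnot(all(is.finite(env)))
  causal_convolve(env, hrf_kernel(tr_s, a, b, support_s))
}
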