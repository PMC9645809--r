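# fast column-wise Pearson correlation of a (time x voxel) matrix with one
# regressor; zero-variance columns get r = 0
cor_with <- function(Y, reg) {
  reg <- reg - mean(reg)
  Yc <- sweep(Y, 2, colMeans(Y))
  num <- as.vector(crossprod(Yc, reg))
  den <- sqrt(colSums(Yc^2) * sum(reg^2))
  r <- ifelse(den > 0, num / den, 0)
  pmin(pmax(r, -1), 1)
}

#' Voxel-wise Pearson correlation map
#'
#' Correlates one regressor (RVT, HRF-convolved gamma power, ...) with every
#' in-mask voxel series. Zero-variance voxels are flagged and given r = 0.
#'
#' @param bold A [bold_data()].
#' @param regressor Numeric series, length = volumes.
#' @return A [stat_map()] with `r_map` (and `n_flagged` attribute).
#' @export
voxelwise_corr <- function(bold, regressor) {
  stopifnot(length(regressor) == n_volumes(bold))
  Y <- mask_matrix(bold)
  flagged <- sum(apply(Y, 2, var) == 0)
  r <- cor_with(Y, regressor)
  rm3 <- array(0, dim(bold$data)[1:3])
  rm3[bold$mask] <- r
  out <- stat_map(bold$mask, r_map = rm3, df = length(regressor) - 2)
  attr(out, "n_flagged") <- flagged
  out
}

#' Regress a confound out of a series
#'
#' OLS residual of `sig` on an intercept plus `confound`. A constant
#' confound returns the demeaned series with a warning.
#'
#' @param sig Numeric series.
#' @param confound Numeric series of equal length.
#' @return Residual series.
#' @export
regress_out <- function(sig, confound) {
  stopifnot(length(sig) == length(confound))
  if (var(confound) == 0) {
    warn("regress_out: constant confound; returning demeaned signal")
    return(sig - mean(sig))
  }
  stats::lsfit(confound, sig)$residuals
}

#' Regress a confound out of every voxel series
#'
#' @param bold A [bold_data()].
#' @param confound Numeric series, length = volumes.
#' @return A [bold_data()] of residuals.
#' @export
regress_out_bold <- function(bold, confound) {
  nuisance_regress(bold, matrix(confound, ncol = 1))
}

#' Gamma-regression mediation analysis
#'
#' The neural-mediation test: correlate RVT with every voxel series, regress
#' the gamma-power regressor out of both RVT and the voxel signals, repeat
#' the correlation on the residuals, and contrast the maps. If the
#' RVT-BOLD correlation is mediated by gamma activity, the post-regression
#' map collapses; a purely vascular (RRF-pathway) correlation is untouched.
#'
#' @param bold A [bold_data()].
#' @param rvt RVT on the (kept-)volume grid: numeric or `rvt_series`.
#' @param gamma Gamma-power regressor on the same grid.
#' @param hrf_convolve_gamma If `TRUE` (default), the regressor removed from
#'   the voxel signals is the HRF-convolved gamma power — BOLD lags neural
#'   activity, so the hemodynamic prediction of the gamma envelope is what a
#'   neurally mediated voxel actually contains; the raw power is always the
#'   regressor removed from RVT, which is not hemodynamically lagged. Set
#'   `FALSE` to remove the raw TR-gridded power from both.
#' @return A list with `pre` and `post` ([stat_map()]s), `diff_map` (pre -
#'   post r), and `reduction(mask)` — a helper returning the fractional
#'   reduction of mean |r| within a voxel mask.
#' @export
mediation_analysis <- function(bold, rvt, gamma, hrf_convolve_gamma = TRUE) {
  if (inherits(rvt, "rvt_series")) rvt <- rvt$rvt
  if (is.data.frame(gamma)) gamma <- gamma$power
  stopifnot(length(rvt) == n_volumes(bold), length(gamma) == length(rvt))
  reg_bold <- if (hrf_convolve_gamma) hrf_convolve(gamma, tr_s = bold$tr_s) else gamma
  pre <- voxelwise_corr(bold, rvt)
  rvt_res <- regress_out(rvt, gamma)
  bold_res <- regress_out_bold(bold, reg_bold)
  post <- voxelwise_corr(bold_res, rvt_res)
  diff_map <- pre$r_map - post$r_map
  reduction <- function(mask) {
    a <- mean(abs(pre$r_map[mask]))
    b <- mean(abs(post$r_map[mask]))
    (a - b) / a
  }
  list(pre = pre, post = post, diff_map = diff_map, reduction = reduction)
}

#' Seed-based correlation map
#'
#' Correlates the mean series of a seed region with every in-mask voxel.
#'
#' @param bold A [bold_data()].
#' @param seed_mask Logical 3-D array; must contain at least one voxel.
#' @return A [stat_map()] with `r_map`.
#' @export
seedmap <- function(bold, seed_mask) {
  if (!any(seed_mask)) abort("seedmap: empty seed")
  seed_ts <- rowMeans(mask_matrix(bold, seed_mask))
  voxelwise_corr(bold, seed_ts)
}

#' ROI x ROI functional-connectivity matrix
#'
#' Pairwise Pearson correlations of ROI-mean time courses: symmetric with a
#' unit diagonal; NaN rows (empty ROIs) propagate.
#'
#' @param roi_ts Numeric matrix, ROI x time.
#' @return Correlation matrix ROI x ROI.
#' @export
rsfc_matrix <- function(roi_ts) {
  stopifnot(nrow(roi_ts) >= 2)
  r <- suppressWarnings(cor(t(roi_ts)))
  diag(r)[!is.na(diag(r))] <- 1
  r
}

#' Voxel-to-voxel spatial correlation of two maps
#'
#' @param mapA,mapB 3-D arrays on the same grid.
#' @param mask Logical 3-D array of voxels to compare.
#' @return Pearson correlation (scalar).
#' @export
spatial_map_corr <- function(mapA, mapB, mask) {
  stopifnot(identical(dim(mapA), dim(mapB)), identical(dim(mapA), dim(mask)))
  if (!any(mask)) abort("spatial_map_corr: empty mask")
  cor(mapA[mask], mapB[mask])
}
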