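#' Framewise displacement
#'
#' Per-volume head-motion summary: the sum of absolute backward differences
#' of the three translations (mm) plus `head_radius_mm` times the sum of
#' absolute rotation differences (radians projected to arc length). The
#' first volume gets FD 0.
#'
#' @param mp Motion parameters: matrix or data frame, volumes x 6
#'   (3 translations mm, 3 rotations rad).
#' @param head_radius_mm Rotation-to-translation radius (mm; rat default 5).
#' @return Tibble (`volume`, `fd_mm`).
#' @export
framewise_displacement <- function(mp, head_radius_mm = 5) {
  mp <- as.matrix(mp)
  stopifnot(ncol(mp) == 6, nrow(mp) >= 2)
  d <- abs(diff(mp))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  tibble(volume = seq_len(nrow(mp)), fd_mm = fd)
}

#' Motion scrubbing mask
#'
#' Flags for removal every volume whose FD exceeds the threshold, together
#' with its immediate predecessor and successor (clamped at the series
#' ends); returns the keep mask.
#'
#' @param fd FD series: numeric vector or the tibble from
#'   [framewise_displacement()].
#' @param threshold_mm Scrub threshold (mm).
#' @return Logical keep-flag vector.
#' @export
#' @examples
#' scrub(c(0, 0.3, 0, 0, 0))
scrub <- function(fd, threshold_mm = 0.25) {
  if (is.data.frame(fd)) fd <- fd$fd_mm
  stopifnot(threshold_mm > 0)
  n <- length(fd)
  bad <- which(fd > threshold_mm)
  drop <- unique(pmin(pmax(c(bad - 1L, bad, bad + 1L), 1L), n))
  keep <- rep(TRUE, n)
  keep[drop] <- FALSE
  if (!any(keep)) abort("scan unusable after scrubbing: every volume removed")
  keep
}

#' Apply a keep mask to a BOLD dataset and paired series
#'
#' Scrubbed volumes must be removed from every series analysed alongside the
#' BOLD data (RVT, band power, regressors) to keep temporal alignment.
#'
#' @param bold A [bold_data()].
#' @param keep Logical keep-flag vector (length `n_volumes`).
#' @return A [bold_data()] with only kept volumes.
#' @export
apply_scrub <- function(bold, keep) {
  stopifnot(length(keep) == n_volumes(bold))
  bold_data(bold$data[, , , keep, drop = FALSE], tr_s = bold$tr_s,
            mask = bold$mask, labels = bold$labels, vox_mm = bold$vox_mm)
}

#' Voxel-wise nuisance regression
#'
#' Ordinary least squares of every in-mask voxel series on an intercept plus
#' the supplied nuisance regressors (motion parameters, white-matter and
#' ventricle mean signals, ...); residuals are returned. Collinear columns
#' are dropped with a warning.
#'
#' @param bold A [bold_data()].
#' @param regressors Numeric matrix, volumes x regressors.
#' @return A [bold_data()] of residuals (zero outside the mask).
#' @export
nuisance_regress <- function(bold, regressors) {
  X <- cbind(intercept = 1, as.matrix(regressors))
  stopifnot(nrow(X) == n_volumes(bold))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep_cols <- qrX$pivot[seq_len(qrX$rank)]
    warn(sprintf("nuisance_regress: dropped %d collinear regressor column(s)",
                 ncol(X) - qrX$rank))
    X <- X[, keep_cols, drop = FALSE]
    qrX <- qr(X)
  }
  Y <- mask_matrix(bold)
  res <- qr.resid(qrX, Y)
  d <- dim(bold$data)
  m <- matrix(0, prod(d[1:3]), d[4])
  m[as.vector(bold$mask), ] <- t(res)
  out <- array(m, d)
  bold_data(out, tr_s = bold$tr_s, mask = bold$mask, labels = bold$labels,
            vox_mm = bold$vox_mm)
}

#' Build a nuisance design from motion parameters and tissue masks
#'
#' @param bold A [bold_data()].
#' @param mp Optional motion-parameter matrix (volumes x 6).
#' @param wm_mask,csf_mask Optional logical arrays; their in-mask mean
#'   series are added as columns.
#' @return Numeric matrix (volumes x regressors).
#' @export
nuisance_design <- function(bold, mp = NULL, wm_mask = NULL, csf_mask = NULL) {
  cols <- list()
  if (!is.null(mp)) cols$mp <- as.matrix(mp)
  mean_series <- function(msk) rowMeans(mask_matrix(bold, msk))
  if (!is.null(wm_mask)) cols$wm <- mean_series(wm_mask)
  if (!is.null(csf_mask)) cols$csf <- mean_series(csf_mask)
  if (length(cols) == 0) abort("nuisance_design: no regressors supplied")
  do.call(cbind, cols)
}

# separable 1-D Gaussian convolution along one array axis (zero padding)
gauss_smooth_axis <- function(arr, sigma_vox, axis) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k <- k / sum(k)
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, da[1], prod(da[-1]))
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
  }
  a[] <- out
  aperm(a, order(perm))
}

#' Mask-normalised spatial smoothing
#'
#' Per-volume Gaussian smoothing restricted to the brain mask: the masked
#' data and the mask are smoothed separately and their ratio taken, which
#' avoids dimming at mask edges; each volume's in-mask mean is then restored
#' exactly.
#'
#' @param bold A [bold_data()].
#' @param fwhm_mm Kernel full width at half maximum (mm); 0 is the identity.
#' @return A smoothed [bold_data()].
#' @export
spatial_smooth <- function(bold, fwhm_mm) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(bold)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / bold$vox_mm
  mask <- bold$mask
  msm <- array(as.numeric(mask), dim(mask))
  for (ax in 1:3) msm <- gauss_smooth_axis(msm, sigma_vox[ax], ax)
  d <- dim(bold$data)
  out <- array(0, d)
  for (tt in seq_len(d[4])) {
    v <- array(bold$data[, , , tt], d[1:3]) * mask
    for (ax in 1:3) v <- gauss_smooth_axis(v, sigma_vox[ax], ax)
    sm <- array(0, d[1:3])
    sm[mask] <- v[mask] / msm[mask]
    sm[mask] <- sm[mask] - mean(sm[mask]) + mean(bold$data[, , , tt][mask])
    out[, , , tt] <- sm
  }
  bold_data(out, tr_s = bold$tr_s, mask = mask, labels = bold$labels,
            vox_mm = bold$vox_mm)
}

#' Extract ROI-mean time series
#'
#' Mean over voxels per label per volume; rows are ordered by ascending
#' label value. Empty labels give NaN rows with a warning.
#'
#' @param bold A [bold_data()].
#' @param labels Integer 3-D array of ROI labels (0/NA = unlabelled);
#'   defaults to `bold$labels`.
#' @return Numeric matrix ROI x time, rownames the label values.
#' @export
extract_roi_timeseries <- function(bold, labels = NULL) {
  labels <- labels %||% bold$labels
  if (is.null(labels)) abort("extract_roi_timeseries: no label volume supplied")
  stopifnot(identical(dim(labels), dim(bold$data)[1:3]))
  labs <- sort(unique(as.vector(labels)))
  labs <- labs[!is.na(labs) & labs > 0]
  d <- dim(bold$data)
  flat <- matrix(bold$data, prod(d[1:3]), d[4])
  out <- matrix(NA_real_, length(labs), d[4])
  rownames(out) <- labs
  lv <- as.vector(labels)
  for (i in seq_along(labs)) {
    sel <- which(lv == labs[i])
    if (length(sel) == 0) {
      warn(sprintf("extract_roi_timeseries: label %s is empty", labs[i]))
      next
    }
    out[i, ] <- colMeans(flat[sel, , drop = FALSE])
  }
  out
}

#' Read a motion-parameter table
#'
#' Whitespace-delimited text, volumes x 6 (3 translations mm, 3 rotations
#' rad).
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_motion_params <- function(path) {
  mp <- as.matrix(read.table(path))
  stopifnot(ncol(mp) == 6)
  unname(mp)
}
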