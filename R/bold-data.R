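#' BOLD dataset container
#'
#' Wraps a 4-D BOLD array with its repetition time, brain mask, and optional
#' ROI labels. Voxel-wise operations ([voxelwise_corr()], [seedmap()],
#' [nuisance_regress()], ...) take and return this class.
#'
#' @param data 4-D numeric array (x, y, z, t).
#' @param tr_s Repetition time (seconds).
#' @param mask Logical 3-D array (brain mask); default all `TRUE`.
#' @param labels Optional integer 3-D array of ROI labels (0 = none).
#' @param vox_mm Voxel size per axis (mm), used by [spatial_smooth()].
#' @return An object of class `bold_data`.
#' @export
bold_data <- function(data, tr_s, mask = NULL, labels = NULL,
                      vox_mm = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 4, tr_s > 0)
  dims <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(identical(dim(mask), dims))
  if (!is.null(labels)) stopifnot(identical(dim(labels), dims))
  structure(
    list(data = data, tr_s = tr_s, mask = mask, labels = labels,
         vox_mm = vox_mm),
    class = "bold_data"
  )
}

#' @export
print.bold_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_data> %dx%dx%d voxels x %d volumes, TR %g s, %d in mask\n",
              d[1], d[2], d[3], d[4], x$tr_s, sum(x$mask)))
  invisible(x)
}

n_volumes <- function(bold) dim(bold$data)[4]

# in-mask voxel series as a (time x voxel) matrix
mask_matrix <- function(bold, mask = bold$mask) {
  d <- dim(bold$data)
  t(matrix(bold$data, prod(d[1:3]), d[4])[as.vector(mask), , drop = FALSE])
}

#' Tidy a BOLD dataset into a long tibble
#'
#' @param x A [bold_data()].
#' @param ... Unused.
#' @return Tibble with columns `x`, `y`, `z`, `volume`, `time_s`, `bold`
#'   (in-mask voxels only).
#' @export
tidy.bold_data <- function(x, ...) {
  d <- dim(x$data)
  idx <- which(x$mask, arr.ind = TRUE)
  nt <- d[4]
  mat <- mask_matrix(x) # time x voxel
  tibble(
    x = rep(idx[, 1], each = nt),
    y = rep(idx[, 2], each = nt),
    z = rep(idx[, 3], each = nt),
    volume = rep(seq_len(nt), nrow(idx)),
    time_s = (rep(seq_len(nt), nrow(idx)) - 1) * x$tr_s,
    bold = as.vector(mat)
  )
}

#' Read / write BOLD volumes as NIfTI-1
#'
#' @param path NIfTI file path.
#' @param tr_s Repetition time; if `NULL`, taken from the NIfTI header.
#' @param mask Optional logical array or path to a 3-D mask NIfTI.
#' @return `read_bold_nifti()` returns a [bold_data()].
#' @export
read_bold_nifti <- function(path, tr_s = NULL, mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (is.null(tr_s)) {
    pd <- RNifti::pixdim(img)
    tr_s <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  }
  if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask)) > 0
  vox <- RNifti::pixdim(img)[1:3]
  bold_data(arr, tr_s = tr_s, mask = mask, vox_mm = vox)
}

#' @param bold A [bold_data()].
#' @rdname read_bold_nifti
#' @export
write_bold_nifti <- function(bold, path) {
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(bold$vox_mm, bold$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a 3-D scalar or mask volume as NIfTI-1
#'
#' @param vol 3-D array (logical masks are written as integer).
#' @param path Output path.
#' @param vox_mm Voxel size (mm).
#' @export
write_volume_nifti <- function(vol, path, vox_mm = c(1, 1, 1)) {
  if (is.logical(vol)) vol <- array(as.integer(vol), dim(vol))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- vox_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
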