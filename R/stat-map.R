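#' Voxel-wise statistic map container
#'
#' Holds r / t / p / significance fields on a brain mask.
#'
#' @param mask Logical 3-D array.
#' @param r_map,t_map,p_map 3-D arrays (or `NULL`).
#' @param sig Logical 3-D array of FDR-significant voxels (or `NULL`).
#' @param df Degrees of freedom of the test.
#' @param alpha FDR level.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(mask, r_map = NULL, t_map = NULL, p_map = NULL,
                     sig = NULL, df = NA_integer_, alpha = NA_real_) {
  structure(
    list(mask = mask, r_map = r_map, t_map = t_map, p_map = p_map,
         sig = sig, df = df, alpha = alpha),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s voxels in mask", sum(x$mask)))
  if (!is.null(x$sig)) cat(sprintf(", %d significant (alpha %g)", sum(x$sig), x$alpha))
  cat("\n")
  invisible(x)
}

#' Tidy a stat map into a voxel tibble
#'
#' @param x A [stat_map()].
#' @param ... Unused.
#' @return Tibble with voxel coordinates and available fields.
#' @export
tidy.stat_map <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  out <- tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3])
  for (f in c("r_map", "t_map", "p_map")) {
    if (!is.null(x[[f]])) out[[sub("_map", "", f)]] <- x[[f]][x$mask]
  }
  if (!is.null(x$sig)) out$sig <- x$sig[x$mask]
  out
}

#' Write a stat-map field as NIfTI-1
#'
#' @param map A [stat_map()].
#' @param field One of `"r_map"`, `"t_map"`, `"p_map"`, `"sig"`.
#' @param path Output path.
#' @param vox_mm Voxel size (mm).
#' @export
write_stat_map_nifti <- function(map, field, path, vox_mm = c(1, 1, 1)) {
  vol <- map[[field]]
  if (is.null(vol)) abort(sprintf("write_stat_map_nifti: field %s is empty", field))
  write_volume_nifti(vol, path, vox_mm)
}
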