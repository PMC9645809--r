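#' Fisher z transform and inverse
#'
#' @param r Correlations in (-1, 1).
#' @return `fisher_z()` returns atanh(r); `fisher_z_inv()` returns tanh(z).
#' @export
fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

#' @param z Fisher z values.
#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up procedure at level `alpha` over `m` tests (via BH-adjusted
#' p-values).
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return Logical vector of the input length (empty input gives empty
#'   output).
#' @export
#' @examples
#' fdr_bh(c(0.001, 0.02, 0.04, 0.9))
fdr_bh <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0) return(logical(0))
  stopifnot(all(pvals >= 0 & pvals <= 1))
  p.adjust(pvals, method = "BH") <= alpha
}

#' Two-sided p-value of a Pearson correlation
#'
#' `t = r sqrt((n - 2) / (1 - r^2))` referred to a Student t distribution
#' with `n - 2` degrees of freedom.
#'
#' @param r Correlation.
#' @param n Sample count (`>= 3`).
#' @return Two-sided p-value.
#' @export
#' @examples
#' round(pearson_pvalue(0.086, 1200), 3)
pearson_pvalue <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) == 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Two-sample t-test (pooled variance)
#'
#' Equal-variance form with `df = n1 + n2 - 2`, as used to compare scalar
#' summaries (SD of respiration rate, SD of RVT) between conditions.
#'
#' @param x,y Numeric samples.
#' @return Tibble (`t`, `df`, `p`, `mean_x`, `mean_y`).
#' @export
two_sample_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    warn("two_sample_t: zero pooled variance")
    t <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
  } else {
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  df <- n1 + n2 - 2
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df),
         mean_x = mean(x), mean_y = mean(y))
}

#' Two-sided p for a given t statistic
#'
#' @param t t statistic.
#' @param df Degrees of freedom.
#' @return Two-sided p-value.
#' @export
#' @examples
#' round(t_pvalue(-1.0, 97), 2)
t_pvalue <- function(t, df) 2 * pt(-abs(t), df)

# vectorised one-sample t across rows of a (scan x voxel) matrix
one_sample_t_rows <- function(Z) {
  n <- nrow(Z)
  m <- colMeans(Z)
  s <- sqrt(colSums(sweep(Z, 2, m)^2) / (n - 1))
  se <- s / sqrt(n)
  t <- numeric(length(m))
  ok <- se > 0
  t[ok] <- m[ok] / se[ok]
  t[!ok & m == 0] <- 0
  t[!ok & m != 0] <- sign(m[!ok & m != 0]) * Inf
  p <- 2 * pt(-abs(t), df = n - 1)
  p[!ok & m == 0] <- 1
  p[!ok & m != 0] <- 0
  list(t = t, p = p, df = n - 1, flagged = sum(!ok))
}

#' Group t-tests on correlation-map stacks
#'
#' One-sample t across scans on Fisher-z-transformed correlation maps, or a
#' paired t on the difference of two stacks (algebraically a one-sample t on
#' the per-scan map differences). Voxels are thresholded at `alpha` after
#' Benjamini-Hochberg FDR correction across in-mask voxels. The group mean
#' map is averaged in z and back-transformed to r.
#'
#' @param maps List of [stat_map()]s (one per scan) sharing a mask.
#' @param maps2 Optional second list for the paired contrast
#'   (`maps` - `maps2`).
#' @param alpha FDR level.
#' @return A [stat_map()] with `r_map` (group mean r), `t_map`, `p_map`,
#'   `sig`.
#' @export
group_ttest_maps <- function(maps, maps2 = NULL, alpha = 0.05) {
  stopifnot(length(maps) >= 2)
  mask <- maps[[1]]$mask
  Z <- do.call(rbind, lapply(maps, function(m) fisher_z(m$r_map[mask])))
  if (!is.null(maps2)) {
    stopifnot(length(maps2) == length(maps))
    Z2 <- do.call(rbind, lapply(maps2, function(m) fisher_z(m$r_map[mask])))
    Z <- Z - Z2
  }
  res <- one_sample_t_rows(Z)
  if (res$flagged > 0) {
    warn(sprintf("group_ttest_maps: %d zero-variance voxel(s) flagged", res$flagged))
  }
  sig <- fdr_bh(res$p, alpha)
  to_vol <- function(v) {
    a <- array(0, dim(mask))
    a[mask] <- v
    a
  }
  sig_vol <- array(FALSE, dim(mask))
  sig_vol[mask] <- sig
  stat_map(mask,
           r_map = to_vol(fisher_z_inv(colMeans(Z))),
           t_map = to_vol(res$t), p_map = to_vol(res$p),
           sig = sig_vol, df = res$df, alpha = alpha)
}

#' FDR-threshold a single correlation map
#'
#' Converts each in-mask r to a two-sided p via [pearson_pvalue()] given the
#' time-series length, applies BH-FDR, and flags significant voxels —
#' single-scan significance, used e.g. for the isoelectric null check.
#'
#' @param map A [stat_map()] with `r_map`.
#' @param n_timepoints Time-series length behind each correlation.
#' @param alpha FDR level.
#' @return The input [stat_map()] with `p_map` and `sig` filled.
#' @export
threshold_map_fdr <- function(map, n_timepoints, alpha = 0.05) {
  r <- map$r_map[map$mask]
  p <- vapply(r, pearson_pvalue, numeric(1), n = n_timepoints)
  sig <- fdr_bh(p, alpha)
  pv <- array(1, dim(map$mask)); pv[map$mask] <- p
  sv <- array(FALSE, dim(map$mask)); sv[map$mask] <- sig
  map$p_map <- pv
  map$sig <- sv
  map$alpha <- alpha
  map$df <- n_timepoints - 2
  map
}

#' Circular mean of phases
#'
#' Mean direction of angles in radians — how per-scan cross-spectral phases
#' are pooled.
#'
#' @param phi Angles (radians).
#' @return Mean angle in (-pi, pi].
#' @export
circular_mean <- function(phi) Arg(mean(exp(1i * phi)))
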