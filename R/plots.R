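#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_col
#'   facet_wrap scale_fill_gradient2 scale_fill_viridis_c labs theme_minimal
#'   coord_equal geom_vline
NULL

#' @export
ggplot2::autoplot

#' Plot a respiration trace
#'
#' @param object A [resp_trace()].
#' @param window_s Optional time window (seconds) to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.resp_trace <- function(object, window_s = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(window_s)) df <- df[df$time_s <= window_s, ]
  ggplot(df, aes(.data$time_s, .data$value)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = "respiration (a.u.)") +
    theme_minimal()
}

#' Plot coherence and phase spectra
#'
#' @param object A `coherence_result` from [msc()].
#' @param f_max Upper frequency limit (Hz).
#' @param ... Unused.
#' @return A ggplot (coherence with the peak frequency marked).
#' @export
autoplot.coherence_result <- function(object, f_max = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(f_max)) df <- df[df$freq_hz <= f_max, ]
  pk <- attr(object, "peak")
  p <- ggplot(df, aes(.data$freq_hz, .data$msc)) +
    geom_line() +
    labs(x = "frequency (Hz)", y = "magnitude-squared coherence") +
    theme_minimal()
  if (!is.null(pk)) p <- p + geom_vline(xintercept = pk$peak_freq_hz,
                                        linetype = "dashed", colour = "red")
  p
}

#' Plot a band-power envelope
#'
#' @param object A `band_power_series` from [band_power()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.band_power_series <- function(object, ...) {
  b <- attr(object, "band")
  ggplot(as_tibble(object), aes(.data$time_s, .data$power)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = "band power",
         title = if (!is.null(b)) sprintf("%g-%g Hz", b[1], b[2]) else NULL) +
    theme_minimal()
}

#' Slice montage of a stat map
#'
#' @param object A [stat_map()].
#' @param field Which field to display.
#' @param ... Unused.
#' @return A ggplot faceted by slice.
#' @export
autoplot.stat_map <- function(object, field = c("r_map", "t_map", "p_map"),
                              ...) {
  field <- match.arg(field)
  vol <- object[[field]]
  if (is.null(vol)) abort(sprintf("autoplot.stat_map: field %s is empty", field))
  df <- tidy(object)
  df$value <- vol[object$mask]
  ggplot(df, aes(.data$x, .data$y, fill = .data$value)) +
    geom_raster() +
    facet_wrap(~z, labeller = ggplot2::label_both) +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    coord_equal() +
    labs(fill = sub("_map", "", field)) +
    theme_minimal()
}

#' Heatmap of an RSFC matrix
#'
#' @param r ROI x ROI correlation matrix from [rsfc_matrix()].
#' @return A ggplot.
#' @export
plot_rsfc <- function(r) {
  df <- as.data.frame(as.table(r))
  names(df) <- c("roi_a", "roi_b", "r")
  ggplot(df, aes(.data$roi_a, .data$roi_b, fill = .data$r)) +
    geom_raster() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         limits = c(-1, 1)) +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "r") +
    theme_minimal()
}
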