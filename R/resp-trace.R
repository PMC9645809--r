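#' Respiration trace container
#'
#' A respiration waveform is stored as a tibble with columns `time_s` and
#' `value` plus `fs` / `t0` attributes, so it pipes straight into dplyr and
#' ggplot2 while keeping the sampling metadata the analysis functions need.
#'
#' @param values Numeric sensor waveform.
#' @param fs Sampling rate (Hz). Must exceed twice the highest plausible
#'   respiration rate (3 Hz).
#' @param t0 Time of the first sample (seconds).
#' @return A tibble of class `resp_trace` with columns `time_s`, `value`.
#' @export
#' @examples
#' tr <- resp_trace(sin(2 * pi * 1.1 * seq(0, 10, by = 1 / 225)), fs = 225)
#' head(tr)
resp_trace <- function(values, fs, t0 = 0) {
  stopifnot(is.numeric(values), length(values) > 1)
  if (fs <= 6) abort("resp_trace: fs must exceed 6 Hz (2 x max plausible respiration rate)")
  out <- tibble(
    time_s = t0 + (seq_along(values) - 1) / fs,
    value = as.numeric(values)
  )
  attr(out, "fs") <- fs
  attr(out, "t0") <- t0
  class(out) <- c("resp_trace", class(out))
  out
}

resp_fs <- function(resp) {
  fs <- attr(resp, "fs")
  if (is.null(fs)) {
    dt <- diff(resp$time_s)
    fs <- 1 / stats::median(dt)
  }
  fs
}

#' Read / write a respiration trace as CSV
#'
#' CSV layout is two headed columns, `time_s` and `value`.
#'
#' @param path File path.
#' @return `read_resp_csv()` returns a [resp_trace()].
#' @export
read_resp_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(df)))
  fs <- 1 / stats::median(diff(df$time_s))
  resp_trace(df$value, fs = fs, t0 = df$time_s[1])
}

#' @param resp A [resp_trace()].
#' @rdname read_resp_csv
#' @export
write_resp_csv <- function(resp, path) {
  write.csv(as.data.frame(resp[, c("time_s", "value")]), path,
            row.names = FALSE)
  invisible(path)
}
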