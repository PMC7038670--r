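#' Uniformly sampled signal trace
#'
#' Light-weight container for a uniformly sampled signal with explicit units,
#' used for every stage of the pipeline: arterial pressure in mmHg, the
#' sensor output in mV, and the amplified front-end output in V. Units are
#' carried through every transform so that stage order errors (e.g. amplifying
#' a pressure trace) are caught immediately.
#'
#' @param values numeric vector of samples; must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param units one of `"mmHg"`, `"mV"`, `"V"`.
#' @param t0 time of the first sample in seconds (default 0). Sample `i`
#'   (0-based) is at `t0 + i/fs`.
#' @return An object of class `signal_trace`.
#' @examples
#' tr <- signal_trace(sin(2 * pi * 1 * (0:999) / 250), fs = 250, units = "mmHg")
#' tr
#' @export
signal_trace <- function(values, fs, units = c("mmHg", "mV", "V"), t0 = 0) {
  units <- match.arg(units)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (!all(is.finite(values))) stop("'values' must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number")
  structure(list(values = values, fs = fs, units = units, t0 = t0),
            class = "signal_trace")
}

#' Sample times of a trace
#'
#' @param trace a [signal_trace()].
#' @return Numeric vector of times in seconds, one per sample.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  trace$t0 + (seq_along(trace$values) - 1) / trace$fs
}

#' Duration of a trace in seconds
#' @param trace a [signal_trace()].
#' @return Duration (n samples / fs) in seconds.
#' @export
trace_duration <- function(trace) length(trace$values) / trace$fs

# internal: replace samples, keep metadata
trace_with_values <- function(trace, values, units = trace$units) {
  signal_trace(values, fs = trace$fs, units = units, t0 = trace$t0)
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples @ %g Hz (%.2f s), units %s\n",
              length(x$values), x$fs, trace_duration(x), x$units))
  cat(sprintf("  range [%.6g, %.6g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$values)

#' @export
as.data.frame.signal_trace <- function(x, ...) {
  data.frame(time_s = trace_times(x), value = x$values)
}

#' @export
plot.signal_trace <- function(x, xlim = NULL, ...) {
  t <- trace_times(x)
  if (!is.null(xlim)) {
    keep <- t >= xlim[1] & t <= xlim[2]
    t <- t[keep]
    y <- x$values[keep]
  } else y <- x$values
  graphics::plot(t, y, type = "l", xlab = "time (s)",
                 ylab = sprintf("amplitude (%s)", x$units), ...)
  invisible(x)
}
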