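#' Feature-detection configuration
#'
#' Threshold-based peak/valley detection parameters. Thresholds are placed
#' at fixed fractions of the local dynamic range (estimated over a rolling
#' window), which makes detection invariant to constant offsets and robust
#' to slow residual drift: the peak search arms when the signal rises above
#' the upper threshold, the valley is the minimum between consecutive
#' peaks, and a refractory period suppresses double-detections within one
#' cycle.
#'
#' @param peak_frac upper (peak) threshold as a fraction of the dynamic
#'   range (default 0.6).
#' @param valley_frac lower (valley) threshold fraction (default 0.4);
#'   must satisfy `0 < valley_frac < peak_frac < 1`.
#' @param refractory minimum peak-to-peak spacing in seconds (default
#'   0.25 s, i.e. a 240 bpm ceiling).
#' @param window rolling window in seconds for local range estimation
#'   (default 5 s).
#' @param range_floor minimum dynamic range (trace units) below which the
#'   trace is declared flat and no features are reported.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(peak_frac = 0.6, valley_frac = 0.4,
                             refractory = 0.25, window = 5,
                             range_floor = 1e-9) {
  if (!(valley_frac > 0 && valley_frac < peak_frac && peak_frac < 1))
    stop("need 0 < valley_frac < peak_frac < 1")
  if (refractory <= 0) stop("'refractory' must be positive")
  if (window <= 0) stop("'window' must be positive")
  structure(list(peak_frac = peak_frac, valley_frac = valley_frac,
                 refractory = refractory, window = window,
                 range_floor = range_floor),
            class = "detection_config")
}

#' Per-beat peak/valley annotations
#'
#' Container for the detected systolic peaks and diastolic valleys of a
#' pulse-wave trace: the `V_max` / `V_min` feature-point sequences the
#' tracker consumes. Peaks and valleys strictly alternate in time and their
#' counts differ by at most one.
#'
#' @param peak_times,peak_values,valley_times,valley_values numeric vectors.
#' @return An object of class `beat_annotations`.
#' @export
beat_annotations <- function(peak_times, peak_values,
                             valley_times, valley_values) {
  stopifnot(length(peak_times) == length(peak_values),
            length(valley_times) == length(valley_values))
  ann <- structure(list(peak_times = peak_times, peak_values = peak_values,
                        valley_times = valley_times,
                        valley_values = valley_values),
                   class = "beat_annotations")
  validate_alternation(ann)
  ann
}

validate_alternation <- function(ann) {
  np <- length(ann$peak_times); nv <- length(ann$valley_times)
  if (abs(np - nv) > 1L)
    stop("peak and valley counts differ by more than 1")
  if (np == 0L || nv == 0L) return(invisible(TRUE))
  ev <- rbind(data.frame(t = ann$peak_times, kind = 1L),
              data.frame(t = ann$valley_times, kind = -1L))
  ev <- ev[order(ev$t), ]
  if (any(diff(ev$kind) == 0))
    stop("peaks and valleys do not strictly alternate in time")
  invisible(TRUE)
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations> %d peaks, %d valleys\n",
              length(x$peak_times), length(x$valley_times)))
  invisible(x)
}

#' @export
as.data.frame.beat_annotations <- function(x, ...) {
  p <- pair_beats(x)
  data.frame(beat_index = seq_len(nrow(p)),
             peak_time_s = x$peak_times[p$peak],
             peak_v = x$peak_values[p$peak],
             valley_time_s = x$valley_times[p$valley],
             valley_v = x$valley_values[p$valley])
}

#' Detect systolic peaks and diastolic valleys by thresholding
#'
#' Implements the threshold detection scheme: an upper and a lower
#' threshold are placed at configurable fractions of the locally estimated
#' dynamic range; each excursion above the upper threshold yields one peak
#' (the maximum sample of the excursion, earliest sample on ties), peaks
#' closer than the refractory period are merged keeping the larger, and
#' each valley is the minimum between consecutive peaks. A leading (or
#' trailing) valley is added when the trace dips below the lower threshold
#' before the first (after the last) peak, so a single clean pulse yields
#' one peak flanked by its two feet.
#'
#' @param trace a `signal_trace` (typically the preprocessed front-end
#'   output in volts).
#' @param cfg a [detection_config()].
#' @return A [beat_annotations()] object. A flat trace (dynamic range below
#'   `cfg$range_floor`) gives empty annotations with a warning; NaN/NA
#'   samples are an error.
#' @export
detect_features <- function(trace, cfg = detection_config()) {
  stopifnot(inherits(trace, "signal_trace"), inherits(cfg, "detection_config"))
  x <- trace$values
  if (anyNA(x) || any(!is.finite(x))) stop("trace contains NA/NaN/Inf samples")
  n <- length(x)
  fs <- trace$fs
  if (n < ceiling(2 * cfg$refractory * fs))
    stop("trace shorter than twice the refractory period")
  if (diff(range(x)) < cfg$range_floor) {
    warning("trace dynamic range below floor; no features detected")
    return(beat_annotations(numeric(0), numeric(0), numeric(0), numeric(0)))
  }
  thr <- local_thresholds(x, fs, cfg)
  peaks <- find_peaks(x, thr$upper, fs, cfg$refractory)
  if (!length(peaks)) {
    warning("no threshold crossings; no features detected")
    return(beat_annotations(numeric(0), numeric(0), numeric(0), numeric(0)))
  }
  valleys <- integer(0)
  if (length(peaks) > 1L) {
    valleys <- vapply(seq_len(length(peaks) - 1L), function(k) {
      seg <- peaks[k]:peaks[k + 1L]
      seg[which.min(x[seg])]
    }, integer(1))
  }
  # leading/trailing feet where the trace dips below the lower threshold
  if (peaks[1] > 1L) {
    seg <- 1L:peaks[1]
    i <- seg[which.min(x[seg])]
    if (x[i] < thr$lower[i]) valleys <- c(i, valleys)
  }
  last <- peaks[length(peaks)]
  if (last < n) {
    seg <- last:n
    i <- seg[which.min(x[seg])]
    if (x[i] < thr$lower[i]) valleys <- c(valleys, i)
  }
  t <- trace_times(trace)
  beat_annotations(t[peaks], x[peaks], t[valleys], x[valleys])
}

# block-wise local min/max, linearly interpolated to per-sample thresholds
local_thresholds <- function(x, fs, cfg) {
  n <- length(x)
  w <- max(1L, round(cfg$window * fs))
  starts <- seq(1L, n, by = w)
  lo <- hi <- numeric(length(starts))
  mid <- numeric(length(starts))
  for (b in seq_along(starts)) {
    seg <- starts[b]:min(starts[b] + w - 1L, n)
    lo[b] <- min(x[seg]); hi[b] <- max(x[seg])
    mid[b] <- (starts[b] + min(starts[b] + w - 1L, n)) / 2
  }
  if (length(starts) > 1L) {
    # widen each block's range with its neighbours so beats straddling a
    # block edge see consistent thresholds
    lo <- pmin(lo, c(lo[-1], lo[length(lo)]), c(lo[1], lo[-length(lo)]))
    hi <- pmax(hi, c(hi[-1], hi[length(hi)]), c(hi[1], hi[-length(hi)]))
    lo_s <- stats::approx(mid, lo, xout = seq_len(n), rule = 2)$y
    hi_s <- stats::approx(mid, hi, xout = seq_len(n), rule = 2)$y
  } else {
    lo_s <- rep(lo, n); hi_s <- rep(hi, n)
  }
  rng <- hi_s - lo_s
  list(upper = lo_s + cfg$peak_frac * rng,
       lower = lo_s + cfg$valley_frac * rng)
}

# one peak per contiguous above-threshold excursion, then refractory merge
find_peaks <- function(x, upper, fs, refractory) {
  above <- x > upper
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- integer(0)
  for (j in which(r$values)) {
    seg <- starts[j]:ends[j]
    cand <- c(cand, seg[which.max(x[seg])])
  }
  min_gap <- refractory * fs
  kept <- cand[1]
  for (i in cand[-1]) {
    lastk <- kept[length(kept)]
    if (i - lastk >= min_gap) kept <- c(kept, i)
    else if (x[i] > x[lastk]) kept[length(kept)] <- i
  }
  kept
}

#' Pair each peak with the valley that follows it
#'
#' Beat `k` is the k-th peak matched with the first valley after it; a
#' trailing peak with no following valley is dropped (with a message).
#'
#' @param ann a [beat_annotations()] object.
#' @return A data.frame with columns `peak` and `valley` (indices into the
#'   annotation vectors), one row per matched beat.
#' @export
pair_beats <- function(ann) {
  stopifnot(inherits(ann, "beat_annotations"))
  validate_alternation(ann)
  np <- length(ann$peak_times)
  if (np == 0L) return(data.frame(peak = integer(0), valley = integer(0)))
  vi <- findInterval(ann$peak_times, ann$valley_times) + 1L
  ok <- vi <= length(ann$valley_times)
  if (any(!ok))
    message(sum(!ok), " trailing peak(s) without a following valley dropped")
  data.frame(peak = which(ok), valley = vi[ok])
}
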