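#' Differences between adjacent feature-point voltages
#'
#' The inter-beat voltage changes `delta_k = v[k+1] - v[k]` for a sequence
#' of per-beat peak (or valley) voltages. Summing the deltas telescopes to
#' last minus first, which is what makes cuff-anchored accumulation exact
#' -- and drift-sensitive.
#'
#' @param values numeric vector of per-beat voltages (length >= 1).
#' @return Numeric vector of length `length(values) - 1`.
#' @examples
#' voltage_deltas(c(1.0, 1.2, 1.1))  # 0.2, -0.1
#' @export
voltage_deltas <- function(values) {
  if (length(values) < 1L) stop("'values' must be non-empty")
  diff(values)
}

#' Convert a voltage change to a pressure change
#'
#' The chain inversion: an amplified output change of `delta_v` volts
#' corresponds to `delta_v * 1000 / gain` millivolts at the sensor, and
#' dividing by the sensor sensitivity (mV per mmHg) gives the pressure
#' change in mmHg. At the design sensitivity of 2 mV/mmHg this is the
#' familiar 0.5 mmHg per sensor-referred millivolt.
#'
#' @param delta_v voltage change; amplifier-output volts by default, or
#'   sensor-referred millivolts with `units = "mV_sensor"`.
#' @param gain dimensionless amplifier gain (used for `units = "V"`).
#' @param sensitivity sensor sensitivity in mV per mmHg.
#' @param units `"V"` (amplified output volts) or `"mV_sensor"`
#'   (sensor-referred millivolts, i.e. before amplification).
#' @return Pressure change in mmHg.
#' @examples
#' delta_to_mmhg(989 / 1000, gain = 989, sensitivity = 2)  # 0.5 mmHg
#' delta_to_mmhg(1, units = "mV_sensor")                    # 0.5 mmHg
#' @export
delta_to_mmhg <- function(delta_v, gain = gain_from_rg(50), sensitivity = 2,
                          units = c("V", "mV_sensor")) {
  units <- match.arg(units)
  if (any(!is.finite(delta_v))) stop("'delta_v' must be finite")
  if (units == "V") delta_v * 1000 / gain / sensitivity
  else delta_v / sensitivity
}

#' Track beat-to-beat blood pressure from feature annotations
#'
#' The core measurement strategy: beat-to-beat pressure is the initial cuff
#' reading plus the accumulated per-beat pressure changes,
#' `SBP[k] = SBP_init + sum_{j<k} delta_mmHg(peak_j)` and likewise for DBP
#' from the valley sequence. Beat 1 is exactly the cuff pair; beat
#' timestamps are the systolic peak times.
#'
#' Because the accumulation telescopes, any residual baseline drift in the
#' feature voltages integrates directly into the tracked pressure; the
#' first-to-last valley voltage drift is therefore reported as a quality
#' metric, and beats where the tracked SBP does not exceed the tracked DBP
#' are flagged (never silently clipped).
#'
#' @param ann a [beat_annotations()] object (non-empty).
#' @param init_sbp,init_dbp initial cuff systolic/diastolic pressure, mmHg.
#' @param gain amplifier gain of the front end that produced the voltages.
#' @param sensitivity sensor sensitivity in mV per mmHg.
#' @param units units of the annotation voltages, as in [delta_to_mmhg()].
#' @return An object of class `bp_series`: `beat_times`, `sbp`, `dbp`,
#'   `delta_sbp`, `delta_dbp` (mmHg per transition), `init`, `gain`,
#'   `sensitivity`, and `quality` (valley drift in volts and the indices of
#'   any SBP <= DBP inversions).
#' @export
track_bp <- function(ann, init_sbp, init_dbp, gain = gain_from_rg(50),
                     sensitivity = 2, units = c("V", "mV_sensor")) {
  stopifnot(inherits(ann, "beat_annotations"))
  units <- match.arg(units)
  if (init_sbp <= init_dbp) stop("'init_sbp' must exceed 'init_dbp'")
  validate_alternation(ann)
  nb <- length(ann$peak_values)
  nv <- length(ann$valley_values)
  if (nb == 0L || nv == 0L) stop("empty annotations: nothing to track")
  # Beat k's diastolic foot is the valley preceding its peak (valley-to-valley
  # beat convention). When the trace opens with a foot, valley k is therefore
  # beat k's own DBP feature; without a leading foot the first observable
  # valley anchors the DBP accumulation instead (one-foot shift, noted).
  if (!(ann$valley_times[1] < ann$peak_times[1]))
    message("no leading diastolic foot; anchoring DBP at the first valley ",
            "after the first peak")
  n <- min(nb, nv)
  v_peak <- ann$peak_values[seq_len(n)]
  v_valley <- ann$valley_values[seq_len(n)]
  d_sbp <- delta_to_mmhg(voltage_deltas(v_peak), gain, sensitivity, units)
  d_dbp <- delta_to_mmhg(voltage_deltas(v_valley), gain, sensitivity, units)
  sbp <- init_sbp + c(0, cumsum(d_sbp))
  dbp <- init_dbp + c(0, cumsum(d_dbp))
  inversions <- which(sbp <= dbp)
  if (length(inversions))
    warning(length(inversions),
            " beat(s) with tracked SBP <= DBP (physiological sanity flag)")
  structure(list(beat_times = ann$peak_times[seq_len(n)],
                 sbp = sbp, dbp = dbp,
                 delta_sbp = d_sbp, delta_dbp = d_dbp,
                 init = c(sbp = init_sbp, dbp = init_dbp),
                 gain = gain, sensitivity = sensitivity,
                 quality = list(
                   valley_drift_v = v_valley[length(v_valley)] - v_valley[1],
                   inversions = inversions)),
            class = "bp_series")
}

#' @export
print.bp_series <- function(x, ...) {
  n <- length(x$sbp)
  cat(sprintf("<bp_series> %d beats, anchored at %g/%g mmHg\n",
              n, x$init["sbp"], x$init["dbp"]))
  cat(sprintf("  SBP %.1f-%.1f, DBP %.1f-%.1f mmHg; valley drift %.3g V\n",
              min(x$sbp), max(x$sbp), min(x$dbp), max(x$dbp),
              x$quality$valley_drift_v))
  if (length(x$quality$inversions))
    cat("  WARNING:", length(x$quality$inversions), "SBP<=DBP inversions\n")
  invisible(x)
}

#' @export
summary.bp_series <- function(object, ...) {
  data.frame(measure = c("SBP", "DBP"),
             mean = c(mean(object$sbp), mean(object$dbp)),
             sd = c(stats::sd(object$sbp), stats::sd(object$dbp)),
             min = c(min(object$sbp), min(object$dbp)),
             max = c(max(object$sbp), max(object$dbp)))
}

#' @export
as.data.frame.bp_series <- function(x, ...) {
  data.frame(beat_index = seq_along(x$sbp), beat_time_s = x$beat_times,
             sbp_mmhg = x$sbp, dbp_mmhg = x$dbp)
}

#' @export
plot.bp_series <- function(x, ...) {
  graphics::plot(x$beat_times, x$sbp, type = "b", pch = 20,
                 ylim = range(c(x$sbp, x$dbp)),
                 xlab = "time (s)", ylab = "pressure (mmHg)", ...)
  graphics::lines(x$beat_times, x$dbp, type = "b", pch = 1)
  graphics::legend("topright", legend = c("SBP", "DBP"), pch = c(20, 1),
                   lty = 1, bty = "n")
  invisible(x)
}
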