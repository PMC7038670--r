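#' Instrumentation-amplifier gain from the external gain resistor
#'
#' The amplifier's gain is set by a single external resistor:
#' `gain = 49.4 kOhm / rg + 1`, tunable from 1 to 10,000. The design value
#' used throughout this package is `rg = 50` ohms, giving a gain of 989.
#'
#' @param rg external gain resistor in ohms (> 0).
#' @return Dimensionless gain.
#' @examples
#' gain_from_rg(50)     # 989
#' gain_from_rg(49400)  # 2
#' @export
gain_from_rg <- function(rg) {
  if (any(rg <= 0)) stop("'rg' must be positive")
  49.4e3 / rg + 1
}

#' First-order RC cutoff frequency
#'
#' `fc = 1 / (2 pi R C)`. With four arguments, returns the cutoff of a
#' two-RC-product (Sallen-Key style) stage via the geometric mean,
#' `fc = 1 / (2 pi sqrt(r1 c1 r2 c2))`.
#'
#' @param r,c resistance in ohms and capacitance in farads (> 0).
#' @param r2,c2 optional second RC product (defaults equal to `r`, `c`).
#' @return Cutoff frequency in Hz.
#' @examples
#' cutoff_from_components(5.3e6, 1e-6)  # ~0.030 Hz AC-coupling design value
#' @export
cutoff_from_components <- function(r, c, r2 = r, c2 = c) {
  if (any(c(r, c, r2, c2) <= 0)) stop("components must be positive")
  1 / (2 * pi * sqrt(r * c * r2 * c2))
}

#' Analog front-end specification
#'
#' The front-end chain applied to the sensor signal, in order: first-order
#' AC-coupling high-pass (DC removal, default 0.03 Hz), Butterworth
#' high-pass (default second order at 0.05 Hz), instrumentation-amplifier
#' gain (default 989 from `rg = 50` ohms), and Butterworth low-pass
#' (default second order at 35 Hz), giving the 0.05-35 Hz pulse-wave
#' bandwidth. Set a cutoff to `NA` to disable that stage (used e.g. for the
#' flat-gain bypass in round-trip tests).
#'
#' @param rg external gain resistor in ohms; `gain` is derived from it via
#'   [gain_from_rg()] unless given explicitly.
#' @param gain dimensionless passband gain (>= 1).
#' @param fc_ac AC-coupling cutoff in Hz, or `NA` to disable.
#' @param fc_hpf,fc_lpf Butterworth high-/low-pass cutoffs in Hz, or `NA`.
#' @param order_hpf,order_lpf Butterworth orders (>= 1).
#' @return A list of class `frontend_spec`.
#' @examples
#' frontend_spec()               # the hardware design values
#' frontend_bypass()             # flat gain, no filtering
#' @export
frontend_spec <- function(rg = 50, gain = gain_from_rg(rg),
                          fc_ac = 0.03, fc_hpf = 0.05, fc_lpf = 35,
                          order_hpf = 2, order_lpf = 2) {
  if (gain < 1) stop("'gain' must be >= 1")
  if (order_hpf < 1 || order_lpf < 1) stop("filter orders must be >= 1")
  fcs <- c(fc_ac, fc_hpf, fc_lpf)
  if (any(!is.na(fcs) & fcs <= 0)) stop("cutoff frequencies must be positive (or NA)")
  on <- fcs[!is.na(fcs)]
  if (length(on) > 1 && any(diff(on) <= 0))
    stop("cutoffs must satisfy fc_ac < fc_hpf < fc_lpf among enabled stages")
  structure(list(rg = rg, gain = gain, fc_ac = fc_ac, fc_hpf = fc_hpf,
                 fc_lpf = fc_lpf, order_hpf = order_hpf, order_lpf = order_lpf),
            class = "frontend_spec")
}

#' @rdname frontend_spec
#' @export
frontend_bypass <- function(gain = gain_from_rg(50)) {
  frontend_spec(gain = gain, fc_ac = NA, fc_hpf = NA, fc_lpf = NA)
}

#' @export
print.frontend_spec <- function(x, ...) {
  stage <- function(fc, lab) if (is.na(fc)) sprintf("%s: off", lab)
    else sprintf("%s: %g Hz", lab, fc)
  cat(sprintf("<frontend_spec> gain %.4g (%.2f dB)\n", x$gain, 20 * log10(x$gain)))
  cat(" ", stage(x$fc_ac, "AC-coupling HP (1st order)"), "|",
      stage(x$fc_hpf, sprintf("Butterworth HP (order %d)", x$order_hpf)), "|",
      stage(x$fc_lpf, sprintf("Butterworth LP (order %d)", x$order_lpf)), "\n")
  invisible(x)
}

#' Magnitude of the front-end transfer function
#'
#' Analytic magnitude of the cascade at frequency `f`:
#' `|H(f)| = gain * |HP1(f)| * |HPn(f)| * |LPn(f)|` with the standard
#' Butterworth magnitudes `1/sqrt(1 + (fc/f)^(2n))` (high-pass) and
#' `1/sqrt(1 + (f/fc)^(2n))` (low-pass); the first-order AC-coupling stage
#' is the `n = 1` high-pass case. Disabled stages contribute 1.
#'
#' @param spec a [frontend_spec()].
#' @param f frequency in Hz (> 0); vectorized.
#' @return Dimensionless magnitude |H(f)|.
#' @export
transfer_magnitude <- function(spec, f) {
  stopifnot(inherits(spec, "frontend_spec"))
  if (any(f <= 0)) stop("'f' must be positive")
  hp <- function(fc, n) if (is.na(fc)) 1 else 1 / sqrt(1 + (fc / f)^(2 * n))
  lp <- function(fc, n) if (is.na(fc)) 1 else 1 / sqrt(1 + (f / fc)^(2 * n))
  spec$gain * hp(spec$fc_ac, 1) * hp(spec$fc_hpf, spec$order_hpf) *
    lp(spec$fc_lpf, spec$order_lpf)
}

#' Simulated frequency response of the front end
#'
#' Sweeps the analytic cascade magnitude over log-spaced frequencies (the
#' hardware characterization sweep is 1e-3 to 1e3 Hz) and locates the
#' midband level and the two -3 dB (half-power) crossings relative to it by
#' bracketing on the sweep and linear interpolation in (log10 f, dB) space
#' on a locally refined grid.
#'
#' @param spec a [frontend_spec()].
#' @param f_min,f_max sweep bounds in Hz (0 < f_min < f_max).
#' @param n_points number of sweep points (>= 100; default 2000).
#' @return An object of class `frequency_response`: `freqs`, `magnitude_db`,
#'   `midband_db`, `f_low_3db`, `f_high_3db` (NA when a crossing does not
#'   occur inside the sweep).
#' @examples
#' fr <- frequency_response(frontend_spec())
#' fr
#' @export
frequency_response <- function(spec, f_min = 1e-3, f_max = 1e3,
                               n_points = 2000) {
  stopifnot(inherits(spec, "frontend_spec"))
  if (f_min <= 0 || f_min >= f_max) stop("need 0 < f_min < f_max")
  if (n_points < 100) stop("'n_points' must be >= 100")
  freqs <- 10^seq(log10(f_min), log10(f_max), length.out = n_points)
  db <- 20 * log10(transfer_magnitude(spec, freqs))
  i_max <- which.max(db)
  midband <- db[i_max]
  target <- midband - 10 * log10(2)  # half-power (-3.01 dB) point
  lf <- log10(freqs)
  # linear interpolation in (log f, dB) on a fine local regrid of the
  # analytic magnitude between the bracketing sweep points
  interp_cross <- function(l1, l2) {
    lg <- seq(l1, l2, length.out = 400)
    dbg <- 20 * log10(transfer_magnitude(spec, 10^lg))
    s <- (dbg - target)
    i <- which(s[-length(s)] * s[-1] <= 0)[1]
    if (is.na(i)) return(10^((l1 + l2) / 2))
    10^(lg[i] + (target - dbg[i]) / (dbg[i + 1] - dbg[i]) * (lg[i + 1] - lg[i]))
  }
  cross_left <- function() {
    below <- which(db[seq_len(i_max)] < target)
    if (!length(below)) return(NA_real_)
    i <- max(below)  # db[i] < target <= db[i+1]
    interp_cross(lf[i], lf[i + 1])
  }
  cross_right <- function() {
    below <- which(db[i_max:length(db)] < target)
    if (!length(below)) return(NA_real_)
    j <- i_max + min(below) - 1L  # db[j] < target <= db[j-1]
    interp_cross(lf[j - 1], lf[j])
  }
  structure(list(freqs = freqs, magnitude_db = db, midband_db = midband,
                 f_low_3db = cross_left(), f_high_3db = cross_right(),
                 spec = spec),
            class = "frequency_response")
}

#' @export
print.frequency_response <- function(x, ...) {
  cat(sprintf("<frequency_response> %d points, %.3g-%.3g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs)))
  cat(sprintf("  midband %.2f dB; -3 dB at %.4g Hz and %.4g Hz\n",
              x$midband_db, x$f_low_3db, x$f_high_3db))
  invisible(x)
}

#' @export
plot.frequency_response <- function(x, ...) {
  graphics::plot(x$freqs, x$magnitude_db, type = "l", log = "x",
                 xlab = "frequency (Hz)", ylab = "magnitude (dB)", ...)
  graphics::abline(h = x$midband_db - 3, lty = 2)
  graphics::abline(v = c(x$f_low_3db, x$f_high_3db), lty = 3)
  invisible(x)
}

#' Apply the front end to a sensor trace in the time domain
#'
#' Digital (bilinear-transform) equivalents of the analog stages are applied
#' in hardware order: AC-coupling high-pass, Butterworth high-pass, gain,
#' Butterworth low-pass; the output is converted from amplified millivolts
#' to volts. Filtering is causal by default, mimicking the analog chain;
#' `zero_phase = TRUE` uses forward-backward filtering instead (no phase
#' distortion, at the cost of non-causality).
#'
#' @param trace a `signal_trace` in mV (sensor output).
#' @param spec a [frontend_spec()]; the sampling rate must exceed
#'   `2 * fc_lpf` when the low-pass stage is enabled.
#' @param zero_phase logical; use forward-backward filtering.
#' @return A `signal_trace` in volts.
#' @export
apply_frontend <- function(trace, spec = frontend_spec(), zero_phase = FALSE) {
  stopifnot(inherits(trace, "signal_trace"), inherits(spec, "frontend_spec"))
  if (trace$units != "mV")
    stop("apply_frontend() expects the sensor trace in mV, got ", trace$units)
  fs <- trace$fs
  if (!is.na(spec$fc_lpf) && fs <= 2 * spec$fc_lpf)
    stop("sampling rate too low for the low-pass cutoff")
  run <- function(x, flt) {
    if (zero_phase) signal::filtfilt(flt, x)
    else as.numeric(signal::filter(flt, x))
  }
  x <- trace$values
  if (!is.na(spec$fc_ac))
    x <- run(x, signal::butter(1, spec$fc_ac / (fs / 2), type = "high"))
  if (!is.na(spec$fc_hpf))
    x <- run(x, signal::butter(spec$order_hpf, spec$fc_hpf / (fs / 2), type = "high"))
  x <- x * spec$gain
  if (!is.na(spec$fc_lpf))
    x <- run(x, signal::butter(spec$order_lpf, spec$fc_lpf / (fs / 2), type = "low"))
  trace_with_values(trace, x / 1000, units = "V")
}
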