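#' Simulate a ground-truth beat-to-beat blood pressure trajectory
#'
#' Generates per-beat true systolic (SBP) and diastolic (DBP) pressures as
#' bounded Gaussian random walks anchored at an initial cuff reading, the
#' way a resting subject's pressure wanders slowly from beat to beat. Beat 1
#' is exactly `(init_sbp, init_dbp)`; each subsequent beat adds an
#' independent Gaussian step and reflects at the physiological bounds
#' (default 70-190 mmHg systolic, 40-100 mmHg diastolic, spanning
#' hypotension through hypertension).
#'
#' @param n_beats number of beats (>= 1).
#' @param init_sbp,init_dbp initial cuff systolic/diastolic pressure, mmHg;
#'   `init_sbp > init_dbp` is required.
#' @param sbp_step_sd,dbp_step_sd per-beat random-walk step standard
#'   deviation in mmHg (>= 0; 0 gives a constant trajectory).
#' @param heart_rate heart rate in beats/min; either a scalar or a vector of
#'   length `n_beats` for beat-varying rate.
#' @param seed integer seed; the trajectory is bit-reproducible for a fixed
#'   seed. `NULL` uses the current RNG state.
#' @param sbp_bounds,dbp_bounds reflecting bounds in mmHg.
#' @return An object of class `bp_trajectory` with fields `beat_times`
#'   (start of each beat, s, valley-to-valley convention), `sbp`, `dbp`
#'   (mmHg per beat), `durations` (s per beat) and `heart_rate`.
#' @examples
#' gt <- simulate_bp_trajectory(12, 109, 61, 0, 0, heart_rate = 72, seed = 1)
#' range(gt$sbp)  # constant 109 for a zero-variance walk
#' @export
simulate_bp_trajectory <- function(n_beats, init_sbp = 109, init_dbp = 61,
                                   sbp_step_sd = 0.5, dbp_step_sd = 0.5,
                                   heart_rate = 72, seed = NULL,
                                   sbp_bounds = c(70, 190),
                                   dbp_bounds = c(40, 100)) {
  n_beats <- as.integer(n_beats)
  if (is.na(n_beats) || n_beats < 1L) stop("'n_beats' must be >= 1")
  if (init_sbp <= init_dbp) stop("'init_sbp' must exceed 'init_dbp'")
  if (sbp_step_sd < 0 || dbp_step_sd < 0) stop("step SDs must be >= 0")
  if (any(heart_rate <= 0)) stop("'heart_rate' must be positive")
  hr <- rep_len(heart_rate, n_beats)
  if (!is.null(seed)) set.seed(seed)
  sbp <- reflecting_walk(n_beats, init_sbp, sbp_step_sd, sbp_bounds)
  dbp <- reflecting_walk(n_beats, init_dbp, dbp_step_sd, dbp_bounds)
  durations <- 60 / hr
  beat_times <- c(0, cumsum(durations[-n_beats]))
  structure(list(beat_times = beat_times, sbp = sbp, dbp = dbp,
                 durations = durations, heart_rate = hr),
            class = "bp_trajectory")
}

# Gaussian random walk reflected at [lo, hi]; reflection preserves the step
# distribution near the interior and keeps every value inside the bounds.
reflecting_walk <- function(n, init, step_sd, bounds) {
  lo <- bounds[1]; hi <- bounds[2]
  if (lo >= hi) stop("invalid bounds")
  if (init < lo || init > hi) stop("initial value outside bounds")
  x <- numeric(n)
  x[1] <- init
  if (n == 1L || step_sd == 0) {
    if (n > 1L) x[] <- init
    return(x)
  }
  steps <- stats::rnorm(n - 1L, 0, step_sd)
  for (k in 2:n) {
    y <- x[k - 1L] + steps[k - 1L]
    while (y < lo || y > hi) {
      if (y < lo) y <- 2 * lo - y else y <- 2 * hi - y
    }
    x[k] <- y
  }
  x
}

#' @export
print.bp_trajectory <- function(x, ...) {
  n <- length(x$sbp)
  cat(sprintf("<bp_trajectory> %d beats over %.1f s\n", n,
              x$beat_times[n] + x$durations[n]))
  cat(sprintf("  SBP %s-%s mmHg, DBP %s-%s mmHg, HR %s bpm\n",
              round(min(x$sbp), 1), round(max(x$sbp), 1),
              round(min(x$dbp), 1), round(max(x$dbp), 1),
              paste(round(range(x$heart_rate)), collapse = "-")))
  invisible(x)
}

#' @export
as.data.frame.bp_trajectory <- function(x, ...) {
  data.frame(beat_index = seq_along(x$sbp), beat_time_s = x$beat_times,
             sbp_mmhg = x$sbp, dbp_mmhg = x$dbp)
}

#' Pulse morphology parameters
#'
#' The per-beat pulse shape is a sum of Gaussian bumps over the normalized
#' cycle phase u in [0, 1): a dominant systolic peak plus a dicrotic
#' shoulder. The shape is only a template; within every beat it is rescaled
#' affinely so the sampled maximum and minimum hit that beat's true
#' SBP and DBP exactly, which makes the extrema contract exact regardless of
#' the template details.
#'
#' In addition to the bumps, a small "foot rise" pedestal
#' `foot_rise * (1 - exp(-u / foot_tau))` keeps the late-diastolic tail a
#' margin above the foot, so every beat's sampled minimum is strictly its
#' first sample (the diastolic foot) and the waveform minimum between two
#' systolic peaks is exactly the intervening beat's foot -- which is what
#' makes valley detection and DBP round-trips exact on clean signals.
#'
#' @param centers,widths,amplitudes numeric vectors (one entry per bump) of
#'   phase centers in (0, 1), Gaussian widths (> 0) and relative amplitudes.
#' @param foot_rise pedestal height relative to the pulse amplitude (>= 0).
#' @param foot_tau pedestal rise scale in cycle-phase units (> 0).
#' @return A list of class `ppw_morphology`.
#' @export
ppw_morphology <- function(centers = c(0.32, 0.62),
                           widths = c(0.09, 0.13),
                           amplitudes = c(1, 0.42),
                           foot_rise = 0.05, foot_tau = 0.02) {
  if (length(centers) != length(widths) ||
      length(centers) != length(amplitudes))
    stop("morphology vectors must have equal length")
  if (any(widths <= 0)) stop("bump widths must be positive")
  if (any(centers <= 0 | centers >= 1)) stop("bump centers must lie in (0,1)")
  if (foot_rise < 0 || foot_tau <= 0) stop("invalid foot pedestal parameters")
  structure(list(centers = centers, widths = widths, amplitudes = amplitudes,
                 foot_rise = foot_rise, foot_tau = foot_tau),
            class = "ppw_morphology")
}

# template shape evaluated at phase u in [0,1)
ppw_shape <- function(u, morph) {
  s <- morph$foot_rise * (1 - exp(-u / morph$foot_tau))
  for (j in seq_along(morph$centers)) {
    s <- s + morph$amplitudes[j] *
      exp(-((u - morph$centers[j]) / morph$widths[j])^2)
  }
  s
}

#' Synthesize a pressure pulse waveform from a BP trajectory
#'
#' Realizes a continuous radial-artery pressure pulse wave whose per-beat
#' sampled maximum equals that beat's true SBP and whose sampled minimum
#' equals its true DBP (exactly, by per-beat affine rescaling of the
#' morphology template). Beats are delimited valley-to-valley; the template
#' is near its minimum at both cycle edges, so the waveform is continuous
#' across beat boundaries up to the (small) beat-to-beat DBP change.
#'
#' @param gt a [simulate_bp_trajectory()] result.
#' @param fs sampling rate in Hz; must be >= 100 so pulse peaks are resolved.
#' @param morphology a [ppw_morphology()].
#' @return A `signal_trace` in mmHg with attribute `beat_index` giving, for
#'   every sample, the (1-based) beat it belongs to.
#' @export
synthesize_ppw <- function(gt, fs = 500, morphology = ppw_morphology()) {
  stopifnot(inherits(gt, "bp_trajectory"))
  if (fs < 100) stop("'fs' must be >= 100 Hz to resolve pulse peaks")
  n_beats <- length(gt$sbp)
  total <- gt$beat_times[n_beats] + gt$durations[n_beats]
  n_samp <- floor(total * fs)
  t <- (seq_len(n_samp) - 1) / fs
  beat_of <- findInterval(t, gt$beat_times)
  u <- (t - gt$beat_times[beat_of]) / gt$durations[beat_of]
  raw <- ppw_shape(u, morphology)
  p <- numeric(n_samp)
  for (k in seq_len(n_beats)) {
    idx <- which(beat_of == k)
    if (length(idx) < 4L)
      stop("fewer than 4 samples in a beat; increase 'fs'")
    r <- raw[idx]
    rng <- range(r)
    if (rng[2] - rng[1] <= 0) stop("degenerate morphology: flat pulse shape")
    p[idx] <- gt$dbp[k] + (gt$sbp[k] - gt$dbp[k]) * (r - rng[1]) / (rng[2] - rng[1])
  }
  out <- signal_trace(p, fs = fs, units = "mmHg")
  attr(out, "beat_index") <- beat_of
  out
}

#' Add respiratory baseline wander
#'
#' Adds a low-frequency sinusoid (plus, optionally, a smoothed random drift)
#' to a trace, emulating the respiration-driven baseline wandering that the
#' preprocessing stage must remove.
#'
#' @param trace a `signal_trace`.
#' @param amplitude sinusoid amplitude in the trace's units (>= 0).
#' @param resp_freq respiration frequency in Hz, in (0, 1); default 0.25 Hz
#'   (15 breaths/min).
#' @param drift_sd standard deviation (trace units) of an additional slow
#'   random drift component; default 0 (none).
#' @param seed integer seed for the drift component.
#' @return A `signal_trace` with the wander added; unchanged units.
#' @export
add_baseline_wander <- function(trace, amplitude, resp_freq = 0.25,
                                drift_sd = 0, seed = NULL) {
  stopifnot(inherits(trace, "signal_trace"))
  if (amplitude < 0) stop("'amplitude' must be >= 0")
  if (resp_freq <= 0 || resp_freq >= 1) stop("'resp_freq' must lie in (0, 1) Hz")
  t <- trace_times(trace)
  w <- amplitude * sin(2 * pi * resp_freq * t)
  if (drift_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    # random walk low-passed to sub-respiratory frequencies, rescaled
    raw <- cumsum(stats::rnorm(length(t)))
    k <- max(3L, 2L * floor(trace$fs / (2 * resp_freq)) + 1L)
    sm <- stats::filter(raw, rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- 0
    sm <- as.numeric(sm)
    if (stats::sd(sm) > 0) sm <- sm / stats::sd(sm) * drift_sd
    w <- w + sm
  }
  trace_with_values(trace, trace$values + w)
}

#' Piezoelectric sensor specification
#'
#' Linear pressure-to-voltage characteristics of the pulse sensor: a PVDF
#' medical pulse sensor with 2 mV/mmHg sensitivity over a -50 to 3000 mmHg
#' rated range (the defaults). Outside the rated range the output clips.
#'
#' @param sensitivity mV per mmHg (> 0).
#' @param pressure_range length-2 numeric, rated range in mmHg (min < max).
#' @return A list of class `sensor_spec`.
#' @export
sensor_spec <- function(sensitivity = 2, pressure_range = c(-50, 3000)) {
  if (sensitivity <= 0) stop("'sensitivity' must be positive")
  if (length(pressure_range) != 2L || pressure_range[1] >= pressure_range[2])
    stop("'pressure_range' must be c(min, max) with min < max")
  structure(list(sensitivity = sensitivity, pressure_range = pressure_range),
            class = "sensor_spec")
}

#' Transduce a pressure trace to sensor voltage
#'
#' Applies the sensor's linear conversion `v = sensitivity * p` (mV) for
#' pressures inside the rated range; values outside are clipped to the
#' boundary and counted.
#'
#' @param trace a `signal_trace` in mmHg.
#' @param sensor a [sensor_spec()].
#' @return A `signal_trace` in mV with attribute `n_clipped` (number of
#'   clipped samples). A warning is raised when clipping occurs.
#' @examples
#' tr <- signal_trace(c(0, 1, 100), fs = 100, units = "mmHg")
#' piezo_transduce(tr)$values  # 0, 2, 200 mV at 2 mV/mmHg
#' @export
piezo_transduce <- function(trace, sensor = sensor_spec()) {
  stopifnot(inherits(trace, "signal_trace"), inherits(sensor, "sensor_spec"))
  if (trace$units != "mmHg")
    stop("piezo_transduce() expects a pressure trace in mmHg, got ", trace$units)
  p <- trace$values
  lo <- sensor$pressure_range[1]; hi <- sensor$pressure_range[2]
  n_clipped <- sum(p < lo | p > hi)
  p <- pmin(pmax(p, lo), hi)
  out <- trace_with_values(trace, sensor$sensitivity * p, units = "mV")
  attr(out, "n_clipped") <- n_clipped
  if (n_clipped > 0)
    warning(sprintf("%d sample(s) outside the sensor's rated range were clipped",
                    n_clipped))
  out
}

#' Add Gaussian measurement noise
#'
#' @param trace a `signal_trace`.
#' @param noise_sd standard deviation of additive zero-mean Gaussian noise,
#'   in the trace's units (>= 0).
#' @param seed integer seed; output is bit-reproducible for a fixed seed.
#' @return A `signal_trace` with noise added; unchanged units.
#' @export
add_noise <- function(trace, noise_sd, seed = NULL) {
  stopifnot(inherits(trace, "signal_trace"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (noise_sd == 0) return(trace)
  if (!is.null(seed)) set.seed(seed)
  trace_with_values(trace,
                    trace$values + stats::rnorm(length(trace$values), 0, noise_sd))
}
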