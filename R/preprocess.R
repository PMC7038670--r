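#' Preprocessing configuration
#'
#' Parameters for the two digital post-processing steps applied before
#' feature detection: baseline-wander (respiration) removal by detrending,
#' then wavelet shrinkage denoising.
#'
#' Detrending estimates the baseline with a cascaded (two-pass) moving
#' average of windows `detrend_window` and `detrend_window / 2`. With the
#' window set to one beat period (the 0.833 s default, one cycle at 72 bpm)
#' the estimator's comb nulls fall exactly on the pulse fundamental and its
#' harmonics, so pulse spans pass through essentially untouched while
#' respiratory-band drift (at and below ~0.3 / `detrend_window` Hz) is
#' attenuated by 90% or more. A robust moving-median variant and a global
#' polynomial fit are available as alternatives; for best span fidelity set
#' `detrend_window` to the actual beat period.
#' Denoising defaults to the standard wavelet-shrinkage recipe: db4 wavelet,
#' decomposition level `floor(log2(fs / 8))`, universal threshold
#' `sigma * sqrt(2 log N)` with `sigma` estimated from the median absolute
#' deviation of the finest detail scale, soft thresholding.
#'
#' @param detrend_method one of `"moving_mean"` (cascaded moving average,
#'   the default), `"moving_median"` (median pass followed by a smoothing
#'   average, more robust to transient artifacts but with weaker
#'   respiratory-band rejection), `"polynomial"`.
#' @param detrend_window baseline-estimation window in seconds (> 0);
#'   ideally the beat period.
#' @param poly_degree polynomial degree for `detrend_method = "polynomial"`.
#' @param wavelet wavelet family: `"db4"`, `"db2"` or `"haar"`.
#' @param wavelet_level decomposition depth (>= 1), or `NULL` to derive
#'   `floor(log2(fs / 8))` from the trace's sampling rate.
#' @param threshold_rule `"universal"` or `"fixed"`.
#' @param threshold_value detail threshold when `threshold_rule = "fixed"`.
#' @param threshold_mode `"soft"` or `"hard"`.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(detrend_method = c("moving_mean", "moving_median",
                                                 "polynomial"),
                              detrend_window = 60 / 72, poly_degree = 5,
                              wavelet = c("db4", "db2", "haar"),
                              wavelet_level = NULL,
                              threshold_rule = c("universal", "fixed"),
                              threshold_value = NULL,
                              threshold_mode = c("soft", "hard")) {
  detrend_method <- match.arg(detrend_method)
  wavelet <- match.arg(wavelet)
  threshold_rule <- match.arg(threshold_rule)
  threshold_mode <- match.arg(threshold_mode)
  if (detrend_window <= 0) stop("'detrend_window' must be positive")
  if (!is.null(wavelet_level) && wavelet_level < 1)
    stop("'wavelet_level' must be >= 1")
  if (threshold_rule == "fixed" &&
      (is.null(threshold_value) || threshold_value < 0))
    stop("'threshold_value' must be a non-negative number for the fixed rule")
  structure(list(detrend_method = detrend_method,
                 detrend_window = detrend_window, poly_degree = poly_degree,
                 wavelet = wavelet, wavelet_level = wavelet_level,
                 threshold_rule = threshold_rule,
                 threshold_value = threshold_value,
                 threshold_mode = threshold_mode),
            class = "preprocess_config")
}

#' Remove baseline wander from a trace
#'
#' Estimates the slow baseline (respiration drift and below) and subtracts
#' it. The moving-window methods use reflection padding at the edges; the
#' polynomial method fits a global polynomial in time by least squares.
#'
#' @param trace a `signal_trace` longer than the detrend window.
#' @param cfg a [preprocess_config()].
#' @return A `signal_trace` with the baseline removed (same length, units);
#'   the estimated baseline is attached as attribute `baseline`.
#' @export
detrend_trace <- function(trace, cfg = preprocess_config()) {
  stopifnot(inherits(trace, "signal_trace"), inherits(cfg, "preprocess_config"))
  x <- trace$values
  n <- length(x)
  w <- round(cfg$detrend_window * trace$fs)
  if (n <= w) stop("trace shorter than the detrend window")
  baseline <- switch(cfg$detrend_method,
    moving_median = running_stat(running_stat(x, w, stats::median),
                                 max(3L, w %/% 2L), mean),
    moving_mean = running_stat(running_stat(x, w, mean),
                               max(3L, w %/% 2L), mean),
    polynomial = {
      t <- trace_times(trace)
      as.numeric(stats::fitted(stats::lm(x ~ stats::poly(t, cfg$poly_degree))))
    })
  out <- trace_with_values(trace, x - baseline)
  attr(out, "baseline") <- baseline
  out
}

# centered running statistic with reflection padding; window forced odd
running_stat <- function(x, w, fun) {
  k <- if (w %% 2 == 1) w else w + 1L
  k <- max(3L, as.integer(k))
  half <- (k - 1L) %/% 2L
  n <- length(x)
  half <- min(half, n - 1L)
  k <- 2L * half + 1L
  xp <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  if (identical(fun, stats::median)) {
    as.numeric(stats::runmed(xp, k, endrule = "keep"))[(half + 1L):(half + n)]
  } else {
    as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(half + 1L):(half + n)]
  }
}

# ---- periodized orthonormal discrete wavelet transform -------------------
# Orthonormal scaling filters; the wavelet filter is the quadrature mirror
# g[n] = (-1)^n h[L-1-n]. Analysis uses periodic wrap-around; synthesis is
# the transpose of the (orthonormal) analysis operator, hence exact.

wavelet_filter <- function(name) {
  switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4 = c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
            -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728),
    stop("unknown wavelet: ", name))
}

dwt_step <- function(x, h) {
  n <- length(x)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  n2 <- n %/% 2L
  a <- numeric(n2); d <- numeric(n2)
  base <- 2L * (seq_len(n2) - 1L)
  for (j in seq_along(h)) {
    idx <- (base + (j - 1L)) %% n + 1L
    a <- a + h[j] * x[idx]
    d <- d + g[j] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, h) {
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  n <- 2L * length(a)
  x <- numeric(n)
  base <- 2L * (seq_along(a) - 1L)
  for (j in seq_along(h)) {
    idx <- (base + (j - 1L)) %% n + 1L
    contrib <- h[j] * a + g[j] * d
    # scatter-add; idx values are unique within one tap shift
    x[idx] <- x[idx] + contrib
  }
  x
}

# full periodized DWT to 'levels'; length must be divisible by 2^levels
dwt_periodic <- function(x, h, levels) {
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- dwt_step(a, h)
    a <- s$a
    details[[l]] <- s$d
  }
  list(approx = a, details = details)
}

idwt_periodic <- function(decomp, h) {
  a <- decomp$approx
  for (l in rev(seq_along(decomp$details)))
    a <- idwt_step(a, decomp$details[[l]], h)
  a
}

#' Wavelet shrinkage denoising
#'
#' Decomposes the trace with a periodized orthonormal discrete wavelet
#' transform (reflection-padded to a dyadic-divisible length), thresholds
#' the detail coefficients, and reconstructs. With the universal rule the
#' threshold is `sigma * sqrt(2 log N)` where `sigma` is the robust noise
#' estimate `MAD(finest details) / 0.6745`.
#'
#' @param trace a `signal_trace` with at least `2^level` samples.
#' @param cfg a [preprocess_config()].
#' @return A denoised `signal_trace` (same length, units).
#' @export
wavelet_denoise <- function(trace, cfg = preprocess_config()) {
  stopifnot(inherits(trace, "signal_trace"), inherits(cfg, "preprocess_config"))
  x <- trace$values
  n <- length(x)
  level <- cfg$wavelet_level
  if (is.null(level)) level <- max(1L, floor(log2(trace$fs / 8)))
  if (n < 2^level) stop("trace too short for wavelet level ", level)
  h <- wavelet_filter(cfg$wavelet)
  # reflection-pad to a multiple of 2^level
  block <- 2^level
  n_pad <- (block - n %% block) %% block
  xp <- if (n_pad > 0) c(x, x[n:(n - n_pad + 1L)]) else x
  dec <- dwt_periodic(xp, h, level)
  thr <- if (cfg$threshold_rule == "fixed") cfg$threshold_value else {
    sigma <- stats::mad(dec$details[[1]], center = 0)
    sigma * sqrt(2 * log(length(xp)))
  }
  dec$details <- lapply(dec$details, function(d) {
    if (cfg$threshold_mode == "soft") sign(d) * pmax(abs(d) - thr, 0)
    else d * (abs(d) > thr)
  })
  y <- idwt_periodic(dec, h)[seq_len(n)]
  trace_with_values(trace, y)
}

#' Run the full preprocessing chain
#'
#' Applies [detrend_trace()] then [wavelet_denoise()] in that fixed order
#' (wander removal first, so the shrinkage threshold is estimated on a
#' drift-free signal).
#'
#' @param trace a `signal_trace`.
#' @param cfg a [preprocess_config()].
#' @return The preprocessed `signal_trace`.
#' @export
preprocess_trace <- function(trace, cfg = preprocess_config()) {
  wavelet_denoise(detrend_trace(trace, cfg), cfg)
}
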