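test_that("periodized DWT reconstructs exactly with no thresholding", {
  set.seed(1)
  for (wv in c("haar", "db2", "db4")) {
    h <- piezobp:::wavelet_filter(wv)
    # orthonormality of the filter
    expect_equal(sum(h^2), 1)
    expect_equal(sum(h), sqrt(2))
    for (n in c(64, 256)) {
      x <- rnorm(n)
      dec <- piezobp:::dwt_periodic(x, h, 4)
      expect_equal(piezobp:::idwt_periodic(dec, h), x, tolerance = 1e-10)
    }
  }
})

test_that("denoising shrinks white noise but leaves clean signals intact", {
  fs <- 250
  cfg <- preprocess_config()
  # clean smooth signal: near-identity
  t <- (0:(20 * fs - 1)) / fs
  clean <- signal_trace(sin(2 * pi * 1.2 * t), fs = fs, units = "V")
  den <- wavelet_denoise(clean, cfg)
  expect_equal(length(den), length(clean))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(den$values - clean$values) / rms(clean$values), 0.01)

  # pure white noise: RMS reduced by at least half (over several seeds)
  for (s in 1:3) {
    set.seed(s)
    noise <- signal_trace(rnorm(5000), fs = fs, units = "V")
    dn <- wavelet_denoise(noise, cfg)
    expect_lt(rms(dn$values), 0.5 * rms(noise$values))
  }
})

test_that("denoising a noisy pulse wave moves peaks by less than 10 ms", {
  sim <- clean_sim(12, fs = 250)
  span <- mean(sim$gt$sbp - sim$gt$dbp)
  noisy <- add_noise(sim$trace, 0.05 * span, seed = 8)
  den <- wavelet_denoise(noisy, preprocess_config())
  t <- trace_times(sim$trace)
  beat_of <- findInterval(t, sim$gt$beat_times)
  for (k in 2:11) {
    idx <- which(beat_of == k)
    t_true <- t[idx[which.max(sim$trace$values[idx])]]
    t_den <- t[idx[which.max(den$values[idx])]]
    expect_lt(abs(t_den - t_true), 0.010 + 1e-9)
  }
})

test_that("denoising never increases the error against the clean signal", {
  sim <- clean_sim(8, fs = 250)
  span <- mean(sim$gt$sbp - sim$gt$dbp)
  rms <- function(x) sqrt(mean(x^2))
  for (s in 1:3) {
    noisy <- add_noise(sim$trace, 0.02 * span, seed = 100 + s)
    den <- wavelet_denoise(noisy, preprocess_config())
    expect_lte(rms(den$values - sim$trace$values),
               rms(noisy$values - sim$trace$values))
  }
})

test_that("detrending removes slow drift and preserves pulse spans", {
  cfg <- preprocess_config()  # cascaded moving mean, beat-period window
  fs <- 250
  # DC trace -> all-zero output
  dc <- signal_trace(rep(7, 10 * fs), fs = fs, units = "V")
  expect_equal(detrend_trace(dc, cfg)$values, rep(0, 10 * fs))

  # zero-mean drift-free trace: output close to input
  t <- (0:(30 * fs - 1)) / fs
  carrier <- signal_trace(sin(2 * pi * 1.2 * t), fs = fs, units = "V")
  out <- detrend_trace(carrier, cfg)
  interior <- (2 * fs):(28 * fs)  # away from the padded record edges
  expect_lt(max(abs((out$values - carrier$values)[interior])) /
              diff(range(carrier$values)), 0.01)

  # clean PPW + 0.25 Hz wander: wander attenuated by >= 90%
  sim <- clean_sim(40, fs = fs)
  span <- mean(sim$gt$sbp - sim$gt$dbp)
  amp <- 0.1 * span
  wandered <- add_baseline_wander(sim$trace, amp, 0.25)
  det <- detrend_trace(wandered, cfg)
  resid <- det$values - detrend_trace(sim$trace, cfg)$values
  interior <- seq(2 * fs, length(resid) - 2 * fs)
  expect_lt(max(abs(resid[interior] - mean(resid[interior]))), 0.1 * amp)

  # per-beat peak-to-valley spans preserved within 2%
  ex <- beat_extrema_oracle(sim$gt, det)
  spans_true <- sim$gt$sbp - sim$gt$dbp
  keep <- 3:38  # away from record edges
  expect_lt(max(abs((ex$max - ex$min)[keep] - spans_true[keep]) /
                spans_true[keep]), 0.02)

  expect_error(detrend_trace(signal_trace(1:10, fs = 250, units = "V"), cfg),
               "shorter")
})

test_that("moving-baseline detrending is idempotent within tolerance", {
  fs <- 250
  sim <- clean_sim(30, fs = fs)
  tr <- add_baseline_wander(sim$trace, 5, 0.2)
  cfg <- preprocess_config()
  once <- detrend_trace(tr, cfg)
  twice <- detrend_trace(once, cfg)
  interior <- (2 * fs):(length(once$values) - 2 * fs)
  expect_lt(max(abs((twice$values - once$values)[interior])) /
              diff(range(once$values)), 0.02)
})

test_that("preprocessing preserves length and units", {
  sim <- clean_sim(10, fs = 250)
  noisy <- add_noise(add_baseline_wander(sim$trace, 3, 0.25), 0.5, seed = 2)
  out <- preprocess_trace(noisy)
  expect_equal(length(out), length(noisy))
  expect_identical(out$units, noisy$units)
})
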