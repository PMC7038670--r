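test_that("gain follows the external-resistor equation", {
  expect_identical(gain_from_rg(50), 989)
  expect_equal(gain_from_rg(49400), 2)
  expect_equal(gain_from_rg(1e12), 1, tolerance = 1e-6)
  expect_error(gain_from_rg(0), "positive")
  # strictly decreasing in rg
  rg <- sort(10^runif(50, 0, 5))
  expect_true(all(diff(gain_from_rg(rg)) < 0))
})

test_that("RC cutoff formula and its two-product form", {
  expect_equal(cutoff_from_components(1 / (2 * pi), 1), 1)
  expect_equal(cutoff_from_components(1, 1), 1 / (2 * pi))
  expect_equal(cutoff_from_components(5.3e6, 1e-6), 0.0300, tolerance = 1e-3)
  # geometric-mean form reduces to the simple form for equal products
  expect_equal(cutoff_from_components(2, 3, 2, 3), cutoff_from_components(2, 3))
  expect_error(cutoff_from_components(-1, 1), "positive")
})

test_that("cascade magnitude matches the Butterworth stage formulas", {
  # isolated LP at its cutoff: the -3 dB definition
  lp_only <- frontend_spec(gain = 1, fc_ac = NA, fc_hpf = NA, fc_lpf = 35)
  expect_equal(transfer_magnitude(lp_only, 35), 1 / sqrt(2))
  # default design at 1 Hz: full amplification, ~59.9 dB
  db1 <- 20 * log10(transfer_magnitude(frontend_spec(), 1))
  expect_equal(db1, 59.9, tolerance = 0.1)
  # |H| never exceeds the gain, for randomized specs
  set.seed(42)
  for (i in 1:20) {
    sp <- frontend_spec(gain = runif(1, 1, 2000),
                        fc_ac = runif(1, 0.01, 0.04),
                        fc_hpf = runif(1, 0.05, 0.5),
                        fc_lpf = runif(1, 10, 60),
                        order_hpf = sample(1:4, 1), order_lpf = sample(1:4, 1))
    f <- 10^runif(40, -3, 3)
    expect_true(all(transfer_magnitude(sp, f) <= sp$gain))
  }
})

test_that("frequency sweep locates midband and the -3 dB crossings", {
  fr <- frequency_response(frontend_spec())
  expect_equal(fr$midband_db, 20 * log10(989), tolerance = 0.05)
  expect_true(fr$f_low_3db > 0.04 && fr$f_low_3db < 0.07)
  expect_equal(fr$f_high_3db, 35, tolerance = 0.01 * 35)
  expect_lt(fr$f_low_3db, fr$f_high_3db)
  expect_equal(fr$midband_db, max(fr$magnitude_db))
  # magnitude at the crossings is midband - 3 dB (interpolation tolerance)
  for (fx in c(fr$f_low_3db, fr$f_high_3db))
    expect_equal(20 * log10(transfer_magnitude(frontend_spec(), fx)),
                 fr$midband_db - 3, tolerance = 0.02)

  # isolated Butterworth LP: upper crossing is the design cutoff exactly
  lp <- frequency_response(frontend_spec(gain = 1, fc_ac = NA, fc_hpf = NA,
                                         fc_lpf = 35))
  expect_equal(lp$f_high_3db, 35, tolerance = 1e-4)

  # doubling the gain shifts midband by +6.02 dB, cutoffs unchanged
  doubled <- frontend_spec(gain = 2 * 989)
  fr2 <- frequency_response(doubled)
  expect_equal(fr2$midband_db - fr$midband_db, 20 * log10(2), tolerance = 1e-6)
  expect_equal(fr2$f_low_3db, fr$f_low_3db, tolerance = 1e-9)
  expect_equal(fr2$f_high_3db, fr$f_high_3db, tolerance = 1e-9)

  expect_error(frequency_response(frontend_spec(), 1, 0.1), "f_min")
})

test_that("-3 dB crossings agree with closed-form root finding", {
  # independent oracle: solve |H(f)| = max|H| / sqrt(2) on the analytic
  # magnitude with uniroot, not with the sweep interpolation
  sp <- frontend_spec()
  fr <- frequency_response(sp)
  mid <- transfer_magnitude(sp, 10^stats::optimize(
    function(lf) -transfer_magnitude(sp, 10^lf), c(-3, 3))$minimum)
  g <- function(f) transfer_magnitude(sp, f) - mid / sqrt(2)
  f_lo <- stats::uniroot(g, c(1e-3, 1), tol = 1e-10)$root
  f_hi <- stats::uniroot(g, c(1, 1e3), tol = 1e-10)$root
  expect_equal(fr$f_low_3db, f_lo, tolerance = 0.002)
  expect_equal(fr$f_high_3db, f_hi, tolerance = 0.002)
})

test_that("time-domain front end matches the analytic magnitude in steady state", {
  fs <- 500
  spec <- frontend_spec()
  t <- (0:(60 * fs - 1)) / fs
  for (f in c(0.5, 1, 5, 20)) {
    tr <- signal_trace(sin(2 * pi * f * t), fs = fs, units = "mV")
    out <- apply_frontend(tr, spec)
    # steady-state amplitude over the last 20% of the record
    tail_idx <- floor(0.8 * length(t)):length(t)
    amp <- (max(out$values[tail_idx]) - min(out$values[tail_idx])) / 2
    expect_equal(amp, transfer_magnitude(spec, f) / 1000, tolerance = 0.01)
  }
})

test_that("front end removes DC, bypass mode is exact scaling", {
  fs <- 250
  dc <- signal_trace(rep(3, 120 * fs), fs = fs, units = "mV")
  out <- apply_frontend(dc, frontend_spec())
  expect_lt(abs(out$values[length(out$values)]), 1e-3)

  tr <- signal_trace(rnorm(1000), fs = fs, units = "mV")
  by <- apply_frontend(tr, frontend_bypass())
  expect_equal(by$values, tr$values * 989 / 1000)
  expect_identical(by$units, "V")

  expect_error(apply_frontend(signal_trace(1:10, fs = 50, units = "mmHg"),
                              frontend_spec()), "mV")
  expect_error(apply_frontend(signal_trace(1:10, fs = 50, units = "mV"),
                              frontend_spec(fc_lpf = 35)), "sampling rate")
})

test_that("spec invariants are validated", {
  expect_error(frontend_spec(gain = 0.5), "gain")
  expect_error(frontend_spec(fc_ac = 0.1, fc_hpf = 0.05), "cutoffs")
  expect_error(frontend_spec(order_hpf = 0), "order")
})
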