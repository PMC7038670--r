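test_that("a single clean pulse yields one peak at systole and its feet", {
  sim <- clean_sim(1, fs = 500, init_sbp = 120, init_dbp = 80)
  ann <- detect_features(sim$trace)
  expect_equal(length(ann$peak_times), 1)
  expect_equal(ann$peak_values, 120)
  expect_true(length(ann$valley_times) %in% 1:2)
  expect_equal(ann$valley_values[1], 80)
})

test_that("clean multi-beat traces give exactly N peaks matching the oracle", {
  for (n in c(2, 5, 17, 35, 50)) {
    sim <- clean_sim(n, fs = 250, sbp_sd = 0.5, dbp_sd = 0.5, seed = n)
    ann <- detect_features(sim$trace)
    ex <- beat_extrema_oracle(sim$gt, sim$trace)
    expect_equal(length(ann$peak_times), n)
    expect_equal(ann$peak_values, ex$max)
    # valleys: the first n are the diastolic feet of beats 1..n
    expect_equal(ann$valley_values[seq_len(n)], ex$min)
    expect_true(abs(length(ann$valley_times) - n) <= 1)
  }
})

test_that("detection is invariant to constant offsets", {
  sim <- clean_sim(10, fs = 250, sbp_sd = 0.5, dbp_sd = 0.5, seed = 3)
  ann0 <- detect_features(sim$trace)
  shifted <- signal_trace(sim$trace$values + 250, fs = 250, units = "mmHg")
  ann1 <- detect_features(shifted)
  expect_equal(ann1$peak_times, ann0$peak_times)
  expect_equal(ann1$peak_values, ann0$peak_values + 250)
  expect_equal(ann1$valley_times, ann0$valley_times)
})

test_that("flat and degenerate traces are handled explicitly", {
  flat <- signal_trace(rep(0, 1000), fs = 250, units = "V")
  expect_warning(ann <- detect_features(flat), "range")
  expect_equal(length(ann$peak_times), 0)
  nan_trace <- signal_trace(rep(1, 1000), fs = 250, units = "V")
  nan_trace$values[5] <- NaN
  expect_error(detect_features(nan_trace), "NaN")
})

test_that("noisy detection keeps median peak-time error under 10 ms", {
  fs <- 250
  sim <- clean_sim(30, fs = fs, sbp_sd = 0.5, dbp_sd = 0.5, seed = 11)
  span <- mean(sim$gt$sbp - sim$gt$dbp)
  noisy <- add_noise(sim$trace, 0.02 * span, seed = 12)
  den <- wavelet_denoise(noisy, preprocess_config())
  ann <- detect_features(den)
  expect_equal(length(ann$peak_times), 30)
  # true peak times from the clean trace via the oracle boundaries
  t <- trace_times(sim$trace)
  beat_of <- findInterval(t, sim$gt$beat_times)
  t_true <- vapply(1:30, function(k) {
    idx <- which(beat_of == k)
    t[idx[which.max(sim$trace$values[idx])]]
  }, numeric(1))
  expect_lt(median(abs(ann$peak_times - t_true)), 0.010)
})

test_that("beat pairing matches each peak with its following valley", {
  ann <- beat_annotations(peak_times = c(1, 2, 3), peak_values = c(5, 6, 7),
                          valley_times = c(1.5, 2.5, 3.5),
                          valley_values = c(1, 2, 3))
  p <- pair_beats(ann)
  expect_equal(nrow(p), 3)
  expect_equal(p$valley, 1:3)

  # trace ends after the last peak: one peak dropped
  ann2 <- beat_annotations(peak_times = c(1, 2, 3), peak_values = c(5, 6, 7),
                           valley_times = c(1.5, 2.5), valley_values = c(1, 2))
  expect_message(p2 <- pair_beats(ann2), "dropped")
  expect_equal(nrow(p2), 2)
})

test_that("alternation violations are rejected", {
  expect_error(beat_annotations(c(1, 1.1), c(5, 6), c(2, 2.2), c(0, 0)),
               "alternate")
  expect_error(beat_annotations(c(1, 2, 3), c(5, 6, 7), numeric(0), numeric(0)),
               "differ")
})

test_that("a long simulated record yields the expected beat count", {
  # 5-minute record at 72 bpm -> ~360 beats
  sim <- clean_sim(360, fs = 250, sbp_sd = 0.5, dbp_sd = 0.5, seed = 21)
  ann <- detect_features(sim$trace)
  expect_true(abs(length(ann$peak_times) - 360) <= 2)
  p <- pair_beats(ann)
  expect_true(abs(nrow(p) - 360) <= 2)
})
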