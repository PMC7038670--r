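fake_bp <- function(times, sbp, dbp) {
  structure(list(beat_times = times, sbp = sbp, dbp = dbp,
                 delta_sbp = diff(sbp), delta_dbp = diff(dbp),
                 init = c(sbp = sbp[1], dbp = dbp[1]),
                 gain = 989, sensitivity = 2,
                 quality = list(valley_drift_v = 0, inversions = integer(0))),
            class = "bp_series")
}

test_that("MAE is the mean absolute difference and is translation-invariant", {
  expect_equal(bp_mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bp_mae(c(2, 0, 3), c(1, 1, 1)), 4 / 3)
  y <- rnorm(20); x <- rnorm(20)
  expect_equal(bp_mae(y + 11, x + 11), bp_mae(y, x))
  expect_error(bp_mae(numeric(0), numeric(0)), "non-empty")
})

test_that("the dispersion statistic follows the printed signed-error formula", {
  # all errors equal: signed variant collapses to zero
  expect_equal(bp_error_sd(c(3, 3, 3), c(1, 1, 1), "signed"), 0)
  # sign-mixed errors expose the divergence between the two variants
  expect_equal(bp_error_sd(c(2, 0), c(1, 1), "signed"), 2)      # errors 1, -1
  expect_equal(bp_error_sd(c(2, 0), c(1, 1), "abs_error"), 0)
  expect_equal(bp_error_sd(c(1, 1), c(1, 1)), 0)
  expect_error(bp_error_sd(1, 1), "2 paired")
  # the signed variant is NOT invariant under flipping error signs
  y <- c(2, 3, 5); x <- c(1, 1, 1)
  flipped <- x - (y - x)
  expect_false(isTRUE(all.equal(bp_error_sd(y, x, "signed"),
                                bp_error_sd(flipped, x, "signed"))))
  expect_equal(bp_error_sd(y, x, "abs_error"),
               bp_error_sd(flipped, x, "abs_error"))
})

test_that("reference pairing matches nearest beats within the gap", {
  bp <- fake_bp(times = seq(0.5, 99.5, 1), sbp = rep(110, 100), dbp = rep(70, 100))
  # references exactly at beat times: all matched with zero gap
  ref <- reference_series(c(10.5, 50.5), c(111, 112), c(71, 72))
  pr <- pair_reference(bp, ref)
  expect_equal(nrow(pr), 2)
  expect_equal(pr$gap, c(0, 0))
  expect_equal(attr(pr, "dropped"), 0)
  # a reference far beyond the record is dropped; all-dropped is an error
  far <- reference_series(500, 120, 80)
  expect_error(pair_reference(bp, far, max_gap = 2), "within")
  mixed <- reference_series(c(20.5, 500), c(111, 120), c(71, 80))
  pr2 <- pair_reference(bp, mixed)
  expect_equal(nrow(pr2), 1)
  expect_equal(attr(pr2, "dropped"), 1)
})

test_that("a 30-min record at 1-min cuff intervals gives 30 evaluation pairs", {
  beat_t <- seq(0, 1800, by = 60 / 72)
  n <- length(beat_t)
  bp <- fake_bp(beat_t, rep(110, n), rep(70, n))
  ref_t <- seq(60, 1800, by = 60)
  ref <- reference_series(ref_t, rep(108, 30), rep(69, 30))
  ev <- evaluate_bp(bp, ref)
  expect_equal(ev$n, 30)
  expect_equal(ev$mae_sbp, 2)
  expect_equal(ev$mae_dbp, 1)
  expect_equal(ev$sd_sbp, 0)
  # with errors of the opposite sign the signed dispersion is nonzero:
  # e - MAE = -2 - 2 = -4 for every pair
  ref2 <- reference_series(ref_t, rep(112, 30), rep(71, 30))
  ev2 <- evaluate_bp(bp, ref2)
  expect_equal(ev2$mae_sbp, 2)
  expect_equal(ev2$sd_sbp, 4 * sqrt(30 / 29))
})

test_that("cohort summary reproduces the packaged table's printed averages", {
  tbl <- cohort_accuracy_table()
  expect_equal(nrow(tbl), 30)
  cs <- summarize_cohort(tbl)
  expect_equal(round(cs$sbp_mae, 2), 1.52)
  expect_equal(round(cs$sbp_sd, 2), 0.30)
  expect_equal(round(cs$dbp_mae, 2), 1.83)
  expect_equal(round(cs$dbp_sd, 2), 0.50)
  # single subject passes through unchanged
  one <- summarize_cohort(tbl[5, ])
  expect_equal(one$sbp_mae, tbl$sbp_mae[5])
  expect_equal(one$n_subjects, 1)
  expect_error(summarize_cohort(tbl[0, ]), "empty")
  expect_error(summarize_cohort(data.frame(a = 1)), "columns")
})
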