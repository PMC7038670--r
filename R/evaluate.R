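#' Reference cuff-reading series
#'
#' Timestamped reference SBP/DBP readings (e.g. oscillometric cuff
#' measurements taken at 1-minute intervals) used to evaluate the tracked
#' beat-to-beat series.
#'
#' @param times reading times in seconds, strictly increasing.
#' @param sbp,dbp reference pressures in mmHg.
#' @return An object of class `reference_series`.
#' @export
reference_series <- function(times, sbp, dbp) {
  if (length(times) == 0L) stop("empty reference series")
  if (length(sbp) != length(times) || length(dbp) != length(times))
    stop("'times', 'sbp', 'dbp' must have equal length")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  structure(list(times = times, sbp = sbp, dbp = dbp),
            class = "reference_series")
}

#' @export
print.reference_series <- function(x, ...) {
  cat(sprintf("<reference_series> %d readings over %.1f s\n",
              length(x$times), diff(range(x$times))))
  invisible(x)
}

#' Pair reference readings with tracked beats
#'
#' Each reference time is matched to the nearest tracked beat within
#' `max_gap` seconds; unmatched references are dropped and counted.
#'
#' @param bp a [track_bp()] result (`bp_series`).
#' @param ref a [reference_series()].
#' @param max_gap maximum |beat time - reference time| in seconds
#'   (default 2).
#' @return A data.frame with one row per matched pair: `time_ref`,
#'   `time_beat`, `gap`, `sbp_est`, `sbp_ref`, `dbp_est`, `dbp_ref`, plus
#'   attribute `dropped` (count of unmatched references). Zero pairs is an
#'   error.
#' @export
pair_reference <- function(bp, ref, max_gap = 2) {
  stopifnot(inherits(bp, "bp_series"), inherits(ref, "reference_series"))
  if (max_gap <= 0) stop("'max_gap' must be positive")
  idx <- vapply(ref$times, function(t) which.min(abs(bp$beat_times - t)),
                integer(1))
  gap <- abs(bp$beat_times[idx] - ref$times)
  keep <- gap <= max_gap
  if (!any(keep)) stop("no reference reading within 'max_gap' of any beat")
  out <- data.frame(time_ref = ref$times[keep],
                    time_beat = bp$beat_times[idx[keep]],
                    gap = gap[keep],
                    sbp_est = bp$sbp[idx[keep]], sbp_ref = ref$sbp[keep],
                    dbp_est = bp$dbp[idx[keep]], dbp_ref = ref$dbp[keep])
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Mean absolute error
#'
#' `MAE = mean(|y - x|)` between device estimates `y` and reference values
#' `x`.
#'
#' @param y,x numeric vectors of equal, positive length.
#' @return MAE in the input units.
#' @export
bp_mae <- function(y, x) {
  if (length(y) == 0L || length(y) != length(x))
    stop("'y' and 'x' must be non-empty and of equal length")
  mean(abs(y - x))
}

#' Error dispersion about the MAE
#'
#' The dispersion statistic `sqrt(sum((e_i - MAE)^2) / (n - 1))`. The
#' default variant (`"signed"`) uses the signed errors `e_i = y_i - x_i`
#' exactly as the device-validation tables print it -- a nonstandard
#' deviation of signed errors about the mean *absolute* error. The
#' `"abs_error"` variant substitutes `|y_i - x_i|`, i.e. the ordinary
#' sample SD of the absolute errors. The two diverge whenever errors
#' change sign: signed errors `c(1, -1)` give 2 under the signed form and
#' 0 under the absolute form.
#'
#' @param y,x numeric vectors, length >= 2.
#' @param variant `"signed"` (the printed formula) or `"abs_error"`.
#' @return Dispersion in the input units.
#' @export
bp_error_sd <- function(y, x, variant = c("signed", "abs_error")) {
  variant <- match.arg(variant)
  n <- length(y)
  if (n < 2L || n != length(x)) stop("need >= 2 paired values")
  m <- bp_mae(y, x)
  e <- if (variant == "signed") y - x else abs(y - x)
  sqrt(sum((e - m)^2) / (n - 1))
}

#' Evaluate a tracked BP series against reference readings
#'
#' Pairs the series with the references ([pair_reference()]) and computes
#' MAE and the dispersion statistic for SBP and DBP.
#'
#' @param bp a `bp_series`.
#' @param ref a [reference_series()].
#' @param max_gap pairing window in seconds.
#' @param sd_variant dispersion variant, see [bp_error_sd()].
#' @return An object of class `bp_eval`: `n`, `mae_sbp`, `sd_sbp`,
#'   `mae_dbp`, `sd_dbp`, `sd_variant`, `dropped`, and the `pairs` table.
#' @export
evaluate_bp <- function(bp, ref, max_gap = 2,
                        sd_variant = c("signed", "abs_error")) {
  sd_variant <- match.arg(sd_variant)
  pairs <- pair_reference(bp, ref, max_gap)
  if (nrow(pairs) < 2L) stop("need at least 2 pairs to evaluate")
  structure(list(n = nrow(pairs),
                 mae_sbp = bp_mae(pairs$sbp_est, pairs$sbp_ref),
                 sd_sbp = bp_error_sd(pairs$sbp_est, pairs$sbp_ref, sd_variant),
                 mae_dbp = bp_mae(pairs$dbp_est, pairs$dbp_ref),
                 sd_dbp = bp_error_sd(pairs$dbp_est, pairs$dbp_ref, sd_variant),
                 sd_variant = sd_variant,
                 dropped = attr(pairs, "dropped"),
                 pairs = pairs),
            class = "bp_eval")
}

#' @export
print.bp_eval <- function(x, ...) {
  cat(sprintf("<bp_eval> n = %d pairs (%d reference(s) dropped), SD variant '%s'\n",
              x$n, x$dropped, x$sd_variant))
  cat(sprintf("  SBP: MAE %.2f +/- SD %.2f mmHg\n", x$mae_sbp, x$sd_sbp))
  cat(sprintf("  DBP: MAE %.2f +/- SD %.2f mmHg\n", x$mae_dbp, x$sd_dbp))
  invisible(x)
}

#' @export
residuals.bp_eval <- function(object, ...) {
  data.frame(time_ref = object$pairs$time_ref,
             sbp = object$pairs$sbp_est - object$pairs$sbp_ref,
             dbp = object$pairs$dbp_est - object$pairs$dbp_ref)
}

#' Cohort summary of per-subject accuracy results
#'
#' Unweighted arithmetic means of the per-subject MAE and SD columns, the
#' way multi-subject validation tables report their bottom "Average" row.
#'
#' @param subjects a data.frame with numeric columns `sbp_mae`, `sbp_sd`,
#'   `dbp_mae`, `dbp_sd` (one row per subject).
#' @return An object of class `cohort_summary` with the four column means
#'   and `n_subjects`.
#' @export
summarize_cohort <- function(subjects) {
  need <- c("sbp_mae", "sbp_sd", "dbp_mae", "dbp_sd")
  if (!is.data.frame(subjects) || !all(need %in% names(subjects)))
    stop("'subjects' must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(subjects) == 0L) stop("empty subject table")
  structure(c(as.list(colMeans(subjects[need])),
              list(n_subjects = nrow(subjects))),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d subjects\n", x$n_subjects))
  cat(sprintf("  SBP: MAE %.2f +/- SD %.2f mmHg\n", x$sbp_mae, x$sbp_sd))
  cat(sprintf("  DBP: MAE %.2f +/- SD %.2f mmHg\n", x$dbp_mae, x$dbp_sd))
  invisible(x)
}

#' Packaged 30-subject cohort accuracy table
#'
#' Loads the packaged per-subject accuracy table of a 30-subject wrist
#' pulse-wave validation study (per-subject MAE and SD of SBP and DBP
#' against 1-minute oscillometric cuff references over 30-minute
#' recordings), used as a fixture for [summarize_cohort()].
#'
#' @return A data.frame with columns `subject`, `sex`, `age`, `height_cm`,
#'   `weight_kg`, `sbp_mae`, `sbp_sd`, `dbp_mae`, `dbp_sd`.
#' @export
cohort_accuracy_table <- function() {
  path <- system.file("extdata", "cohort_accuracy.csv", package = "piezobp",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
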