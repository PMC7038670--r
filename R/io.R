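#' Write / read a signal trace as CSV
#'
#' Two-column CSV `time_s,value` preceded by comment lines carrying the
#' units, sampling rate and start time. Values are written with 17
#' significant digits so a write/read cycle is bit-identical.
#'
#' @param trace a `signal_trace`.
#' @param path file path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   the `signal_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# units: %s", trace$units),
               sprintf("# fs: %.17g", trace$fs),
               sprintf("# t0: %.17g", trace$t0),
               "time_s,value"), con)
  t <- trace_times(trace)
  writeLines(sprintf("%.17g,%.17g", t, trace$values), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  if (is.null(meta$units) || is.null(meta$fs))
    stop("trace file missing '# units:' or '# fs:' metadata header")
  body <- lines[!grepl("^#", lines)]
  if (!length(body) || body[1] != "time_s,value")
    stop("trace file missing 'time_s,value' header line")
  body <- body[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed trace CSV at data line ", bad[1])
  t <- as.numeric(vapply(parts, `[[`, "", 1L))
  v <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(t) || anyNA(v))
    stop("malformed trace CSV at data line ",
         which(is.na(t) | is.na(v))[1])
  if (any(diff(t) <= 0)) stop("time column must be strictly increasing")
  t0 <- if (!is.null(meta$t0)) as.numeric(meta$t0) else t[1]
  signal_trace(v, fs = as.numeric(meta$fs), units = meta$units, t0 = t0)
}

#' Write / read beat-indexed BP tables
#'
#' CSV `beat_index,beat_time_s,sbp_mmhg,dbp_mmhg`, used both for
#' ground-truth trajectories and tracked series.
#'
#' @param x a `bp_trajectory` or `bp_series` (anything with an
#'   `as.data.frame` method yielding those columns).
#' @param path file path.
#' @return `write_bp_table()` returns `path` invisibly; `read_bp_table()`
#'   the data.frame.
#' @export
write_bp_table <- function(x, path) {
  df <- as.data.frame(x)
  need <- c("beat_index", "beat_time_s", "sbp_mmhg", "dbp_mmhg")
  stopifnot(all(need %in% names(df)))
  utils::write.csv(format(df[need], digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bp_table
#' @export
read_bp_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("beat_index", "beat_time_s", "sbp_mmhg", "dbp_mmhg")
  if (!all(need %in% names(df))) stop("missing BP table columns")
  df
}

#' Read / write reference cuff readings
#'
#' CSV `time_s,sbp_mmhg,dbp_mmhg` with strictly increasing times.
#'
#' @param path file path.
#' @param ref a [reference_series()].
#' @return `read_reference()` returns a `reference_series`.
#' @export
read_reference <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "sbp_mmhg", "dbp_mmhg")
  if (!all(need %in% names(df))) stop("missing reference columns")
  reference_series(df$time_s, df$sbp_mmhg, df$dbp_mmhg)
}

#' @rdname read_reference
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "reference_series"))
  utils::write.csv(data.frame(time_s = ref$times, sbp_mmhg = ref$sbp,
                              dbp_mmhg = ref$dbp),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' @param eval_result a `bp_eval`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(eval_result, path) {
  stopifnot(inherits(eval_result, "bp_eval"))
  jsonlite::write_json(list(n = eval_result$n,
                            mae_sbp = eval_result$mae_sbp,
                            sd_sbp = eval_result$sd_sbp,
                            mae_dbp = eval_result$mae_dbp,
                            sd_dbp = eval_result$sd_dbp,
                            sd_variant = eval_result$sd_variant,
                            dropped_refs = eval_result$dropped),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
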