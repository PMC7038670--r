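# Shared fixtures built in code.

# a clean synthetic run: trajectory + pressure waveform
clean_sim <- function(n_beats = 12, fs = 250, sbp_sd = 0, dbp_sd = 0,
                      seed = 1, init_sbp = 109, init_dbp = 61, hr = 72) {
  gt <- simulate_bp_trajectory(n_beats, init_sbp, init_dbp, sbp_sd, dbp_sd,
                               heart_rate = hr, seed = seed)
  list(gt = gt, trace = synthesize_ppw(gt, fs = fs))
}

# brute-force per-beat extrema oracle: scan samples beat by beat using the
# generator's beat boundaries (independent of the detector)
beat_extrema_oracle <- function(gt, trace) {
  t <- trace_times(trace)
  beat_of <- findInterval(t, gt$beat_times)
  n <- length(gt$sbp)
  mx <- mn <- numeric(n)
  for (k in seq_len(n)) {
    v <- trace$values[beat_of == k]
    mx[k] <- max(v); mn[k] <- min(v)
  }
  list(max = mx, min = mn)
}
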