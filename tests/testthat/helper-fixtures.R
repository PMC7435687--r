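# Shared fixture builders. Everything is generated in code; no data files.

# a short deterministic walk (no stochastic variation)
fixed_walk_spec <- function(n_strides = 10, ...) {
  gait_spec(n_strides = n_strides, stride_length_sd = 0, stride_time_sd = 0,
            seed = 99, ...)
}

# simulate one foot end to end and return truth + measured strides
simulate_and_measure <- function(spec, art = no_artifacts(),
                                 config = eskf_config(check_psd = FALSE)) {
  traj <- synth_walk_trajectory(spec)
  rec <- inject_artifacts(trajectory_to_imu(traj), art)
  res <- run_eskf(rec, config)
  events <- detect_gait_events(rec)
  strides <- segment_strides(events, res, foot = spec$foot)
  list(traj = traj, rec = rec, res = res, events = events, strides = strides)
}

# independent matrix-exponential oracle: truncated Taylor series plus
# scaling and squaring (no Rodrigues closed form anywhere)
expm_scaling_squaring <- function(A, k = 30L, squarings = 12L) {
  As <- A / 2^squarings
  E <- diag(nrow(A))
  term <- diag(nrow(A))
  for (i in seq_len(k)) {
    term <- term %*% As / i
    E <- E + term
  }
  for (i in seq_len(squarings)) E <- E %*% E
  E
}

frob <- function(M) sqrt(sum(M^2))
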