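# Shared fixtures: small configs and constructed streams used across tests.

quick_gen <- function(duration_s = 60, seed = 1L, ...) {
  gen_config(duration_s = duration_s, seed = seed, ...)
}

# Cursor stream of uniform random positions held for `dwell` frames each,
# with no immediate repeats (every dwell starts with a cursor onset).
dwell_cursor <- function(n_events, dwell = 10L, frame_rate = 40,
                         n_positions = 8L, seed = 1L) {
  set.seed(seed)
  p <- integer(n_events)
  p[1] <- sample.int(n_positions, 1)
  for (i in seq_len(n_events)[-1]) {
    p[i] <- sample.int(n_positions - 1L, 1)
    if (p[i] >= p[i - 1]) p[i] <- p[i] + 1L
  }
  cursor_stream(rep(p, each = dwell), frame_rate, n_positions)
}

# Decoder with hand-set coefficients: p = f_r1 - f_r2 + 3.
unit_params <- function(b = 3, spont_sd = 1) {
  decoder_params(a1 = 1, a2 = 1, b = b, spont_mean = 0, spont_sd = spont_sd)
}

# Trial-log data frame built directly (for metric tests).
mk_trials <- function(outcomes, trial_frames = 1200L, frame_rate = 40) {
  n <- length(outcomes)
  start <- seq(1L, by = trial_frames, length.out = n)
  end <- start + trial_frames - 1L
  hit <- ifelse(outcomes == "hit", end, NA_integer_)
  data.frame(trial_id = seq_len(n), start_frame = start, end_frame = end,
             outcome = outcomes, hit_frame = hit,
             reward_frame = NA_integer_, condition = "task",
             baseline_wait_frames = 0L)
}

# Event-weighted mean rate for one sweep direction.
pooled_rate <- function(sr, dir) {
  sel <- sr$direction == dir & sr$n_events > 0
  sum(sr$rate_hz[sel] * sr$n_events[sel]) / sum(sr$n_events[sel])
}

# Independent type-7 percentile (sort + linear interpolation), used as the
# brute-force oracle against compute_dff's baseline.
oracle_pctl <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  if (lo >= length(s)) return(s[length(s)])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}
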