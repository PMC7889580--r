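# Online decoder: sliding-percentile dF/F, baseline calibration (range/4),
# the visual position and auditory frequency transforms, and chance-rate
# estimation by replaying spontaneous activity through the trial engine.

#' Convert raw fluorescence to dF/F with a sliding-percentile baseline
#'
#' The per-frame baseline F0 is a low percentile (default the 10th) of the
#' raw values in the preceding `window_s` seconds; the output is
#' `(F - F0) / F0`. Frames with less than one full window of history use all
#' preceding frames, with a floor of `min_window_s` seconds (the first
#' frames therefore share the initial window).
#'
#' @param raw an `fl_trace` with `kind = "raw"`.
#' @param window_s baseline window length, seconds (default 20).
#' @param percentile baseline percentile in (0, 100), default 10.
#' @param min_window_s minimum history used for the earliest frames, seconds.
#' @return An `fl_trace` with `kind = "dff"`.
#' @examples
#' raw <- fl_trace(rep(100, 2000), 40, kind = "raw")
#' dff <- compute_dff(raw)
#' range(dff$values)
#' @export
compute_dff <- function(raw, window_s = 20, percentile = 10,
                        min_window_s = 1) {
  stopifnot(inherits(raw, "fl_trace"))
  if (raw$kind != "raw") stop("compute_dff expects a raw trace")
  fr <- raw$frame_rate
  v <- raw$values
  n <- length(v)
  W <- round(window_s * fr)
  if (n <= W) stop("trace must be longer than one baseline window")
  m <- max(1L, round(min_window_s * fr))
  p <- percentile / 100
  f0 <- numeric(n)
  for (t in seq_len(n)) {
    i0 <- max(1L, t - W)
    i1 <- t - 1L
    if (i1 - i0 + 1L < m) { i0 <- 1L; i1 <- min(n, m) }
    f0[t] <- stats::quantile(v[i0:i1], p, names = FALSE)
  }
  if (any(f0 <= 0)) {
    stop("non-positive baseline value: raw input is unphysical for dF/F")
  }
  fl_trace((v - f0) / f0, fr, roi_id = raw$roi_id, kind = "dff")
}

#' Decoder parameters
#'
#' Coefficients of the activity-to-cursor transform. In visual mode the
#' cursor position is `p = a1*F_R1 - a2*F_R2 + b`, rounded to the nearest
#' integer (half-up) and clipped to `1..n_positions`. In auditory mode the
#' cursor frequency is `f = a1*exp(F_R1) - a2*exp(F_R2) + b`, floored at
#' `min_frequency` and binned in quarter-octave steps around
#' `ref_frequency`.
#'
#' @param a1,a2 region coefficients (>= 0).
#' @param b offset fixing the resting cursor position (or frequency).
#' @param n_positions number of discrete cursor positions (>= 2).
#' @param mode `"visual"` or `"auditory"`.
#' @param start_position resting position the calibration maps the baseline
#'   median to.
#' @param ref_frequency auditory reference frequency, Hz.
#' @param bin_ratio auditory bin ratio (> 1), default one quarter octave.
#' @param min_frequency audible floor, Hz.
#' @param spont_mean,spont_sd mean and SD of the differential activation
#'   `a1*F_R1 - a2*F_R2` over the calibration baseline; used by the trial
#'   engine's return-to-baseline rule.
#' @return A `decoder_params` object.
#' @export
decoder_params <- function(a1, a2, b, n_positions = 8L,
                           mode = c("visual", "auditory"),
                           start_position = 3L, ref_frequency = 5000,
                           bin_ratio = 2^(1 / 4), min_frequency = 1000,
                           spont_mean = 0, spont_sd = 1) {
  mode <- match.arg(mode)
  if (a1 < 0 || a2 < 0) stop("a1 and a2 must be >= 0")
  if (n_positions < 2) stop("n_positions must be >= 2")
  if (bin_ratio <= 1) stop("bin_ratio must be > 1")
  structure(
    list(a1 = a1, a2 = a2, b = b, n_positions = as.integer(n_positions),
         mode = mode, start_position = start_position,
         ref_frequency = ref_frequency, bin_ratio = bin_ratio,
         min_frequency = min_frequency,
         spont_mean = spont_mean, spont_sd = spont_sd),
    class = "decoder_params"
  )
}

#' @export
print.decoder_params <- function(x, ...) {
  cat(sprintf("<decoder_params> mode = %s, a1 = %.4g, a2 = %.4g, b = %.4g\n",
              x$mode, x$a1, x$a2, x$b))
  cat(sprintf("  %d positions, start %g; baseline differential %.4g +/- %.4g\n",
              x$n_positions, x$start_position, x$spont_mean, x$spont_sd))
  invisible(x)
}

#' Calibrate the decoder from a spontaneous baseline
#'
#' Sets each region coefficient to the region's baseline dynamic range
#' divided by half the number of cursor positions
#' (`a = (max(F) - min(F)) / (n_positions / 2)`; with 8 positions, range/4)
#' and the offset `b` so the baseline median of the differential activation
#' `a1*F_R1 - a2*F_R2` maps to `start_position` (visual) or to
#' `ref_frequency` (auditory, on the exponentiated traces). The baseline
#' mean/SD of the differential are stored for the engine's
#' return-to-baseline rule.
#'
#' @param baseline_r1,baseline_r2 dF/F `fl_trace`s of the calibration
#'   baseline (minimum `min_baseline_s` seconds).
#' @param mode `"visual"` or `"auditory"`.
#' @param start_position resting cursor position (default 3).
#' @param n_positions number of cursor positions (default 8).
#' @param min_baseline_s minimum baseline length, seconds (default 10 min).
#' @return A [decoder_params()] object.
#' @examples
#' pr <- generate_region_pair(gen_config(duration_s = 600, seed = 2))
#' calibrate(pr$r1, pr$r2)
#' @export
calibrate <- function(baseline_r1, baseline_r2,
                      mode = c("visual", "auditory"),
                      start_position = 3L, n_positions = 8L,
                      min_baseline_s = 600) {
  mode <- match.arg(mode)
  stopifnot(inherits(baseline_r1, "fl_trace"), inherits(baseline_r2, "fl_trace"))
  fr <- baseline_r1$frame_rate
  if (length(baseline_r1$values) < min_baseline_s * fr) {
    stop(sprintf("baseline must be at least %g s long", min_baseline_s))
  }
  half <- n_positions / 2
  rng1 <- diff(range(baseline_r1$values))
  rng2 <- diff(range(baseline_r2$values))
  if (rng1 <= 0 || rng2 <= 0) {
    stop("zero dynamic range in a baseline trace; cannot calibrate")
  }
  a1 <- rng1 / half
  a2 <- rng2 / half
  if (mode == "visual") {
    d <- a1 * baseline_r1$values - a2 * baseline_r2$values
    b <- start_position - stats::median(d)
  } else {
    d <- a1 * exp(baseline_r1$values) - a2 * exp(baseline_r2$values)
    b <- 5000 - stats::median(d)
  }
  decoder_params(a1 = a1, a2 = a2, b = b, n_positions = n_positions,
                 mode = mode, start_position = start_position,
                 spont_mean = mean(d), spont_sd = stats::sd(d))
}

#' Decode instantaneous activity to a cursor position (visual mode)
#'
#' `p = a1*f_r1 - a2*f_r2 + b`, rounded half-up to the nearest integer and
#' clipped to `[1, n_positions]`. Vectorized over frames.
#'
#' @param f_r1,f_r2 dF/F values (scalars or equal-length vectors).
#' @param params a [decoder_params()] with `mode = "visual"`.
#' @return Integer position(s) in `1..n_positions`.
#' @examples
#' p <- decoder_params(1, 1, 3)
#' decode_position(4.5, 3, p)
#' @export
decode_position <- function(f_r1, f_r2, params) {
  stopifnot(inherits(params, "decoder_params"))
  if (params$mode != "visual") stop("decode_position requires visual mode")
  p <- params$a1 * f_r1 - params$a2 * f_r2 + params$b
  as.integer(pmin(pmax(floor(p + 0.5), 1), params$n_positions))
}

#' Decode instantaneous activity to a cursor frequency (auditory mode)
#'
#' Linear changes in activity map to exponential changes in cursor
#' frequency: `f = a1*exp(f_r1) - a2*exp(f_r2) + b`, floored at the audible
#' minimum; the bin index counts quarter-octave (by default) steps from the
#' reference frequency.
#'
#' @param f_r1,f_r2 dF/F values (scalars or equal-length vectors).
#' @param params a [decoder_params()] with `mode = "auditory"`.
#' @return List with numeric `frequency` (Hz) and integer `bin`.
#' @export
decode_frequency <- function(f_r1, f_r2, params) {
  stopifnot(inherits(params, "decoder_params"))
  if (params$mode != "auditory") stop("decode_frequency requires auditory mode")
  f <- params$a1 * exp(f_r1) - params$a2 * exp(f_r2) + params$b
  f <- pmax(f, params$min_frequency)
  bin <- as.integer(round(log(f / params$ref_frequency) /
                            log(params$bin_ratio)))
  list(frequency = f, bin = bin)
}

#' Estimate the chance hit rate by spontaneous replay
#'
#' Replays a spontaneous baseline through the decoder and the trial engine
#' (30-s trials, hold detection, timeouts) and reports how often the target
#' would have been hit by spontaneous activity alone, in hits per minute of
#' baseline.
#'
#' @param baseline_r1,baseline_r2 dF/F `fl_trace`s of the spontaneous
#'   baseline.
#' @param params a visual-mode [decoder_params()].
#' @param cfg a [session_config()]; must be at least one trial long.
#' @return Hits per minute (numeric scalar); the replayed session is
#'   attached as attribute `"session"`.
#' @export
estimate_chance_rate <- function(baseline_r1, baseline_r2, params,
                                 cfg = session_config()) {
  fr <- baseline_r1$frame_rate
  n <- length(baseline_r1$values)
  if (n < cfg$trial_limit_s * fr) {
    stop("baseline shorter than one trial")
  }
  ses <- run_session(list(r1 = baseline_r1, r2 = baseline_r2), params, cfg)
  hits <- sum(ses$trials$outcome == "hit")
  rate <- hits / (n / fr / 60)
  attr(rate, "session") <- ses
  rate
}
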