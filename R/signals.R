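# Behavioral and signal metrics: sliding-window spectral entropy, hit-rate
# curves, time to criterion, hit-aligned variance, masked pairwise
# correlation.

#' Sliding-window spectral entropy of a trace
#'
#' For each window the one-sided periodogram over `[0, fs/2]` (DC included)
#' is normalized to sum 1 and its Shannon entropy
#' `SE = -sum(PSDn * log2(PSDn))` (with `0*log(0) = 0`) is reported in bits.
#' High entropy indicates a flat, noise-like spectrum (exploration); low
#' entropy indicates power concentrated in few frequencies (stereotyped
#' exploitation). Windows default to 10 s with 5 s overlap.
#'
#' @param trace an `fl_trace` at least one window long.
#' @param window_s window length, seconds.
#' @param step_s window step, seconds (5 s step on a 10 s window gives 50%
#'   overlap).
#' @param method `"periodogram"` (raw, default) or `"welch"` (average of 4
#'   half-overlapping Hann-tapered sub-segments per window).
#' @param normalized if `TRUE`, divide each window's entropy by
#'   `log2(n_freq_bins)` so values lie in `[0, 1]`.
#' @return An `entropy_series` data frame with columns `time_s` (window
#'   center) and `se` (bits); attributes `window_s`, `step_s`,
#'   `n_freq_bins`.
#' @examples
#' tr <- fl_trace(sin(2 * pi * 2 * seq(0, 30, by = 1 / 40))[-1], 40)
#' spectral_entropy(tr)$se[1]  # single spectral line: ~0 bits
#' @export
spectral_entropy <- function(trace, window_s = 10, step_s = 5,
                             method = c("periodogram", "welch"),
                             normalized = FALSE) {
  stopifnot(inherits(trace, "fl_trace"))
  method <- match.arg(method)
  fr <- trace$frame_rate
  v <- trace$values
  W <- round(window_s * fr)
  S <- round(step_s * fr)
  if (length(v) < W) stop("trace shorter than one entropy window")
  nb <- as.integer(floor(W / 2)) + 1L  # one-sided bins, DC through Nyquist
  starts <- seq(1L, length(v) - W + 1L, by = S)
  n_zero <- 0L
  se <- vapply(starts, function(s0) {
    x <- v[s0:(s0 + W - 1L)]
    psd <- .window_psd(x, method)
    tot <- sum(psd)
    if (tot <= 0) {
      n_zero <<- n_zero + 1L
      return(0)
    }
    p <- psd / tot
    p <- p[p > 0]
    -sum(p * log2(p))
  }, 1)
  if (n_zero > 0) {
    warning(n_zero, " all-zero window(s): spectral entropy set to 0")
  }
  if (normalized) se <- se / log2(nb)
  out <- data.frame(time_s = (starts - 1L + W / 2) / fr, se = se)
  attr(out, "window_s") <- window_s
  attr(out, "step_s") <- step_s
  attr(out, "n_freq_bins") <- nb
  class(out) <- c("entropy_series", "data.frame")
  out
}

.window_psd <- function(x, method) {
  one_sided <- function(z) {
    n <- length(z)
    Mod(stats::fft(z))[seq_len(floor(n / 2) + 1L)]^2
  }
  if (method == "periodogram") return(one_sided(x))
  # Welch: 4 half-overlapping Hann-tapered sub-segments, zero-padded to the
  # full window so the bin grid matches the periodogram's.
  n <- length(x)
  seg <- floor(n / 2.5)
  step <- floor(seg / 2)
  taper <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = seg)))
  starts <- seq(1L, n - seg + 1L, by = step)
  acc <- 0
  for (s0 in starts) {
    z <- x[s0:(s0 + seg - 1L)] * taper
    acc <- acc + one_sided(c(z, numeric(n - seg)))
  }
  acc / length(starts)
}

#' Hit-rate time course
#'
#' Counts hit frames from a trial log in consecutive windows and reports
#' hits per minute. With the default step (one window) the bins tile the
#' session, so `sum(rate * duration)` equals the total hit count for any
#' window length.
#'
#' @param trials trial-log data frame (from a `bmi_session`) with columns
#'   `hit_frame`, `outcome`.
#' @param window_min window length, minutes.
#' @param session_frames total session length in frames; defaults to the
#'   last trial's end.
#' @param frame_rate Hz.
#' @param step_min window step, minutes; default `window_min`
#'   (non-overlapping).
#' @return Data frame with `time_min` (window center), `hits_per_min`, and
#'   `window_min` (actual, the last bin may be shorter).
#' @export
hit_rate_curve <- function(trials, window_min = 2,
                           session_frames = max(trials$end_frame),
                           frame_rate = 40, step_min = window_min) {
  if (!nrow(trials)) stop("empty trial log")
  hits <- trials$hit_frame[!is.na(trials$hit_frame)]
  total_min <- session_frames / frame_rate / 60
  starts <- seq(0, total_min, by = step_min)
  starts <- starts[starts < total_min]
  ends <- pmin(starts + window_min, total_min)
  hmin <- hits / frame_rate / 60
  cnt <- vapply(seq_along(starts), function(i)
    sum(hmin >= starts[i] & hmin < ends[i]), 1)
  data.frame(time_min = (starts + ends) / 2,
             hits_per_min = cnt / (ends - starts),
             window_min = ends - starts)
}

#' Time to criterion performance
#'
#' First time the moving average (over `span` trials) of the per-trial hit
#' indicator reaches `criterion`, in minutes from session start; `NA` if the
#' criterion is never reached.
#'
#' @param trials trial-log data frame.
#' @param criterion hit/trial criterion (default 0.5).
#' @param span moving-average span in trials (default 10).
#' @param frame_rate Hz.
#' @return Minutes (numeric) or `NA`.
#' @export
time_to_criterion <- function(trials, criterion = 0.5, span = 10L,
                              frame_rate = 40) {
  if (!nrow(trials)) stop("empty trial log")
  hit <- as.numeric(trials$outcome == "hit")
  if (length(hit) < span) return(NA_real_)
  ma <- stats::filter(hit, rep(1 / span, span), sides = 1)
  idx <- which(!is.na(ma) & ma >= criterion)
  if (!length(idx)) return(NA_real_)
  trials$end_frame[idx[1]] / frame_rate / 60
}

#' Across-hit variance of activity around hit times
#'
#' Aligns the trace on each hit frame and computes, at every lag in
#' `[-half_window_s, +half_window_s]`, the variance across hits. Hits
#' closer to the record edge than the half window are dropped (with a
#' message).
#'
#' @param trace an `fl_trace`.
#' @param hit_frames integer frames of target hits (>= 2 usable).
#' @param half_window_s half window, seconds.
#' @return Data frame with `lag_s` and `variance`; attribute `n_hits` gives
#'   the number of hits used.
#' @export
variance_around_hits <- function(trace, hit_frames, half_window_s = 5) {
  stopifnot(inherits(trace, "fl_trace"))
  fr <- trace$frame_rate
  hw <- round(half_window_s * fr)
  n <- length(trace$values)
  keep <- hit_frames > hw & hit_frames + hw <= n
  if (any(!keep)) {
    message(sum(!keep), " hit(s) dropped: closer to the record edge than the half window")
  }
  hf <- hit_frames[keep]
  if (length(hf) < 2) stop("need at least 2 usable hits")
  lags <- -hw:hw
  snip <- vapply(hf, function(h) trace$values[h + lags], numeric(length(lags)))
  out <- data.frame(lag_s = lags / fr,
                    variance = apply(snip, 1, stats::var))
  attr(out, "n_hits") <- length(hf)
  out
}

#' Masked pairwise Pearson correlation between two traces
#'
#' @param trace_a,trace_b `fl_trace`s of equal length.
#' @param mask logical (or integer index) frame mask selecting the frames to
#'   correlate, e.g. task-only periods; default all frames.
#' @return Pearson correlation coefficient.
#' @export
pairwise_correlation <- function(trace_a, trace_b, mask = NULL) {
  a <- trace_a$values; b <- trace_b$values
  if (length(a) != length(b)) stop("traces must have equal length")
  if (is.null(mask)) mask <- seq_along(a)
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) < 3) stop("fewer than 3 masked frames")
  stats::cor(a[mask], b[mask])
}
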