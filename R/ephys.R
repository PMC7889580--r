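# Single-unit analyses: RS/FS classification by waveform width, cursor
# onset extraction, tuning curves in the 80-200 ms post-onset window, and
# sweep-direction-conditioned firing.

#' Single-unit spike record
#'
#' @param spike_times numeric vector of spike times in seconds, strictly
#'   increasing.
#' @param peak_to_trough_ms waveform peak-to-trough width, ms (> 0).
#' @param unit_id label.
#' @param label `"RS"`, `"FS"` or `"unset"` (assign via [classify_unit()]).
#' @return A `unit_spikes` object.
#' @export
unit_spikes <- function(spike_times, peak_to_trough_ms, unit_id = "u001",
                        label = c("unset", "RS", "FS")) {
  label <- match.arg(label)
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) > 1 && any(diff(spike_times) <= 0)) {
    stop("spike_times must be strictly increasing")
  }
  if (!is.numeric(peak_to_trough_ms) || peak_to_trough_ms <= 0) {
    stop("peak_to_trough_ms must be > 0")
  }
  structure(
    list(spike_times = spike_times, peak_to_trough_ms = peak_to_trough_ms,
         label = label, unit_id = as.character(unit_id)),
    class = "unit_spikes"
  )
}

#' @export
print.unit_spikes <- function(x, ...) {
  cat(sprintf("<unit_spikes %s> %d spikes, width %.2f ms, label %s\n",
              x$unit_id, length(x$spike_times), x$peak_to_trough_ms, x$label))
  invisible(x)
}

#' Classify a unit as regular- or fast-spiking by waveform width
#'
#' Fast-spiking (putative interneuron) if the peak-to-trough width is below
#' the cutoff, regular-spiking otherwise; a width exactly at the cutoff is
#' assigned to the broad (RS) class.
#'
#' @param unit a [unit_spikes()] (or a numeric width in ms).
#' @param cutoff_ms width cutoff, ms (default 0.66).
#' @return `"FS"` or `"RS"`.
#' @examples
#' classify_unit(0.5)
#' classify_unit(0.9)
#' @export
classify_unit <- function(unit, cutoff_ms = 0.66) {
  w <- if (inherits(unit, "unit_spikes")) unit$peak_to_trough_ms else
    as.numeric(unit)
  if (w < cutoff_ms) "FS" else "RS"
}

#' Bin a spike train to imaging frames
#'
#' @param unit a [unit_spikes()].
#' @param n_frames number of frames.
#' @param frame_rate Hz; frame `k` spans `[(k-1)/fr, k/fr)` seconds.
#' @return Integer vector of per-frame spike counts.
#' @export
bin_spike_train <- function(unit, n_frames, frame_rate) {
  idx <- floor(unit$spike_times * frame_rate) + 1L
  idx <- idx[idx >= 1L & idx <= n_frames]
  tabulate(idx, nbins = n_frames)
}

#' Cursor onsets
#'
#' An onset is any frame at which the displayed cursor changes position or
#' (re)appears. Each onset carries the new position, the preceding position
#' (NA if the cursor just appeared) and the sweep direction of the
#' transition: `"toward"` if the change reduced the distance to the target,
#' `"away"` if it increased it, `NA` for appearances.
#'
#' @param cursor a [cursor_stream()].
#' @param target target position (default: highest).
#' @return Data frame with `frame`, `position`, `prev_position`,
#'   `direction`.
#' @export
cursor_onsets <- function(cursor, target = cursor$n_positions) {
  pos <- cursor$position
  prev <- c(NA_integer_, pos[-length(pos)])
  is_onset <- !is.na(pos) & (is.na(prev) | pos != prev)
  f <- which(is_onset)
  p <- pos[f]
  pp <- prev[f]
  dirn <- ifelse(is.na(pp), NA_character_,
                 ifelse(abs(pp - target) > abs(p - target), "toward",
                        ifelse(abs(pp - target) < abs(p - target), "away",
                               NA_character_)))
  data.frame(frame = f, position = p, prev_position = pp,
             direction = dirn, stringsAsFactors = FALSE)
}

# Mean rate of one unit in [w1, w2] seconds after each onset frame.
.onset_rates <- function(unit, onset_frames, frame_rate, window_ms) {
  t0 <- (onset_frames - 1L) / frame_rate
  w <- window_ms / 1000
  dur <- w[2] - w[1]
  st <- unit$spike_times
  vapply(t0, function(tt)
    sum(st >= tt + w[1] & st < tt + w[2]) / dur, 1)
}

#' Cursor-position tuning curve of a unit
#'
#' Mean firing rate per cursor position in a fixed window after cursor
#' onset (default 80-200 ms). Rates are per-event rates averaged across the
#' position's onsets, so positions with unequal event counts are
#' comparable. Positions with no onsets are `NA`. Onsets closer together
#' than the window are both counted.
#'
#' @param unit a [unit_spikes()].
#' @param onsets data frame from [cursor_onsets()] (columns `frame`,
#'   `position`), or a [cursor_stream()] from which onsets are extracted.
#' @param window_ms `c(start, end)` ms relative to onset.
#' @param frame_rate Hz (taken from a `cursor_stream` input if given).
#' @param n_positions number of cursor positions.
#' @param normalize if `TRUE`, divide rates by the unit's maximum rate
#'   (population heat-map convention).
#' @return A `tuning_curve`: data frame with `position`, `rate_hz`,
#'   `n_events`.
#' @export
tuning_curve <- function(unit, onsets, window_ms = c(80, 200),
                         frame_rate = 40, n_positions = 8L,
                         normalize = FALSE) {
  stopifnot(inherits(unit, "unit_spikes"))
  if (inherits(onsets, "cursor_stream")) {
    frame_rate <- onsets$frame_rate
    n_positions <- onsets$n_positions
    onsets <- cursor_onsets(onsets)
  }
  if (!nrow(onsets)) stop("need at least one onset")
  rates <- .onset_rates(unit, onsets$frame, frame_rate, window_ms)
  rate_hz <- n_events <- rep(NA_real_, n_positions)
  for (p in seq_len(n_positions)) {
    sel <- onsets$position == p
    n_events[p] <- sum(sel)
    if (any(sel)) rate_hz[p] <- mean(rates[sel])
  }
  if (normalize && any(is.finite(rate_hz)) && max(rate_hz, na.rm = TRUE) > 0) {
    rate_hz <- rate_hz / max(rate_hz, na.rm = TRUE)
  }
  out <- data.frame(position = seq_len(n_positions), rate_hz = rate_hz,
                    n_events = as.integer(n_events))
  attr(out, "window_ms") <- window_ms
  attr(out, "unit_id") <- unit$unit_id
  class(out) <- c("tuning_curve", "data.frame")
  out
}

#' @export
plot.tuning_curve <- function(x, ...) {
  graphics::plot(x$position, x$rate_hz, type = "b", xlab = "cursor position",
                 ylab = "rate (Hz)", main = attr(x, "unit_id"), ...)
  invisible(x)
}

#' Sweep-direction-conditioned tuning
#'
#' Computes the post-onset tuning curve separately for onsets whose
#' transition swept toward vs away from the target. Onsets with no position
#' change (appearances) are excluded; a (position, direction) cell with no
#' onsets is `NA` (flagged missing).
#'
#' @param unit a [unit_spikes()].
#' @param cursor a [cursor_stream()].
#' @param window_ms `c(start, end)` ms relative to onset.
#' @param target target position.
#' @return Data frame with `position`, `direction`, `rate_hz`, `n_events`.
#' @export
sweep_conditioned_rates <- function(unit, cursor, window_ms = c(80, 200),
                                    target = cursor$n_positions) {
  ons <- cursor_onsets(cursor, target = target)
  ons <- ons[!is.na(ons$direction), , drop = FALSE]
  np <- cursor$n_positions
  out <- expand.grid(position = seq_len(np),
                     direction = c("toward", "away"),
                     stringsAsFactors = FALSE)
  out$rate_hz <- NA_real_
  out$n_events <- 0L
  if (nrow(ons)) {
    rates <- .onset_rates(unit, ons$frame, cursor$frame_rate, window_ms)
    for (i in seq_len(nrow(out))) {
      sel <- ons$position == out$position[i] & ons$direction == out$direction[i]
      out$n_events[i] <- sum(sel)
      if (any(sel)) out$rate_hz[i] <- mean(rates[sel])
    }
  }
  out
}

#' Unit metadata table
#'
#' @param units list of [unit_spikes()].
#' @param cutoff_ms RS/FS width cutoff, ms.
#' @return Data frame with `unit_id`, `width_ms`, `label`, `n_spikes`.
#' @export
unit_table <- function(units, cutoff_ms = 0.66) {
  data.frame(
    unit_id = vapply(units, function(u) u$unit_id, ""),
    width_ms = vapply(units, function(u) u$peak_to_trough_ms, 1),
    label = vapply(units, classify_unit, "", cutoff_ms = cutoff_ms),
    n_spikes = vapply(units, function(u) length(u$spike_times), 1L),
    stringsAsFactors = FALSE
  )
}
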