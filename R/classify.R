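# Population template classifier: correlation-to-class-mean matching with
# contiguous-segment cross-validation, per-unit z-scoring on training
# statistics, repeated splits and shuffle controls; accuracy per time bin.

#' Classifier specification
#'
#' @param bin_ms spike-count bin width, ms (default 50).
#' @param n_splits number of contiguous event segments (default 40); one is
#'   held out per repeat.
#' @param n_repeats number of cross-validation repeats (default 20), each
#'   holding out a different segment.
#' @param shuffle_labels if `TRUE`, training labels are permuted each
#'   repeat (chance control).
#' @param seed integer seed for the repeat/shuffle draws.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(bin_ms = 50, n_splits = 40L, n_repeats = 20L,
                            shuffle_labels = FALSE, seed = 1L) {
  if (n_splits < 2) stop("n_splits must be >= 2")
  if (bin_ms <= 0) stop("bin_ms must be > 0")
  structure(
    list(bin_ms = bin_ms, n_splits = as.integer(n_splits),
         n_repeats = as.integer(n_repeats),
         shuffle_labels = isTRUE(shuffle_labels), seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

#' Bin population responses around events
#'
#' Counts each unit's spikes in `bin_ms` bins over a window around each
#' event (cursor onset). Pre-onset bins are included so pre-presentation
#' decoding is computable.
#'
#' @param units list of [unit_spikes()].
#' @param onset_frames integer event frames.
#' @param frame_rate Hz.
#' @param bin_ms bin width, ms.
#' @param window_ms `c(start, end)` ms relative to each event (default
#'   -250..500).
#' @return Numeric array `events x units x bins` with attribute `time_ms`
#'   (bin centers relative to onset).
#' @export
bin_event_responses <- function(units, onset_frames, frame_rate,
                                bin_ms = 50, window_ms = c(-250, 500)) {
  edges_ms <- seq(window_ms[1], window_ms[2], by = bin_ms)
  n_bins <- length(edges_ms) - 1L
  n_ev <- length(onset_frames)
  n_units <- length(units)
  t0 <- (onset_frames - 1L) / frame_rate
  resp <- array(0, dim = c(n_ev, n_units, n_bins))
  for (u in seq_len(n_units)) {
    st <- units[[u]]$spike_times
    for (e in seq_len(n_ev)) {
      rel <- (st - t0[e]) * 1000
      rel <- rel[rel >= window_ms[1] & rel < window_ms[2]]
      if (length(rel)) {
        b <- pmin(floor((rel - window_ms[1]) / bin_ms) + 1L, n_bins)
        resp[e, u, ] <- tabulate(b, nbins = n_bins)
      }
    }
  }
  attr(resp, "time_ms") <- (edges_ms[-1] + edges_ms[-length(edges_ms)]) / 2
  resp
}

#' Train and evaluate the correlation-template classifier
#'
#' Events are partitioned into `n_splits` contiguous segments by event
#' order. Per repeat: one segment is held out for testing; each unit is
#' z-scored using training-fold mean/SD only (units with zero training SD
#' are dropped for that repeat); per time bin, a mean population vector is
#' computed for every label class on the training events, and each test
#' event is predicted as the class with the maximum Pearson correlation
#' between its population vector and the class means. Ties and undefined
#' (constant-vector) correlations fall to the lowest class index and are
#' counted in `n_flagged`. With `shuffle_labels`, training labels are
#' permuted each repeat. The reported accuracy per time bin is the mean
#' over repeats.
#'
#' @param responses numeric array `events x units x bins` (see
#'   [bin_event_responses()]).
#' @param labels vector of event labels (>= 2 classes; every class must
#'   appear in the training fold of every repeat).
#' @param spec a [classifier_spec()].
#' @return An `accuracy_course`: list with `time_ms`, per-bin `accuracy`
#'   (mean over repeats), `repeats` (repeat x bin matrix), `overall` (grand
#'   mean), `chance_level`, `classes`, `n_events`, `n_flagged`,
#'   `dropped_units`.
#' @export
train_eval <- function(responses, labels, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  d <- dim(responses)
  if (length(d) != 3L) stop("responses must be an events x units x bins array")
  n_ev <- d[1]; n_units <- d[2]; n_bins <- d[3]
  labels <- factor(labels)
  classes <- levels(labels)
  if (length(classes) < 2) stop("need at least 2 label classes")
  if (length(labels) != n_ev) stop("labels must match the event dimension")
  if (n_ev < 2 * spec$n_splits) {
    stop("too few events for the requested number of splits")
  }
  seg <- as.integer(cut(seq_len(n_ev), breaks = spec$n_splits))

  set.seed(spec$seed)
  acc <- matrix(NA_real_, spec$n_repeats, n_bins)
  n_flagged <- 0L
  dropped <- integer(0)
  for (r in seq_len(spec$n_repeats)) {
    test_seg <- ((r - 1L) %% spec$n_splits) + 1L
    test <- which(seg == test_seg)
    train <- which(seg != test_seg)
    lab_tr <- labels[train]
    missing <- setdiff(classes, as.character(unique(lab_tr)))
    if (length(missing)) {
      stop(sprintf("class '%s' absent from the training fold of repeat %d",
                   missing[1], r))
    }
    if (spec$shuffle_labels) lab_tr <- sample(lab_tr)

    # per-unit z-scoring from training statistics (events x bins pooled)
    tr_flat <- matrix(aperm(responses[train, , , drop = FALSE], c(1, 3, 2)),
                      ncol = n_units)
    mu <- colMeans(tr_flat)
    sdv <- apply(tr_flat, 2, stats::sd)
    keep <- which(sdv > 0)
    if (length(keep) < 2) stop("fewer than 2 units with nonzero training SD")
    dropped <- union(dropped, setdiff(seq_len(n_units), keep))

    for (b in seq_len(n_bins)) {
      Xtr <- sweep(sweep(responses[train, keep, b, drop = FALSE][, , 1],
                         2, mu[keep]), 2, sdv[keep], "/")
      Xte <- sweep(sweep(responses[test, keep, b, drop = FALSE][, , 1],
                         2, mu[keep]), 2, sdv[keep], "/")
      M <- t(vapply(classes, function(cl)
        colMeans(Xtr[lab_tr == cl, , drop = FALSE]),
        numeric(length(keep))))
      cc <- suppressWarnings(stats::cor(t(Xte), t(M)))
      bad <- !is.finite(cc)
      if (any(bad)) {
        n_flagged <- n_flagged + sum(rowSums(bad) > 0)
        cc[bad] <- -Inf
      }
      allbad <- rowSums(is.finite(cc)) == 0
      pred <- classes[apply(cc, 1, which.max)]
      pred[allbad] <- classes[1]
      acc[r, b] <- mean(pred == as.character(labels[test]))
    }
  }
  structure(
    list(time_ms = attr(responses, "time_ms"),
         accuracy = colMeans(acc), repeats = acc, overall = mean(acc),
         chance_level = 1 / length(classes), classes = classes,
         n_events = n_ev, n_flagged = n_flagged, dropped_units = dropped,
         spec = spec),
    class = "accuracy_course"
  )
}

#' @export
print.accuracy_course <- function(x, ...) {
  cat(sprintf(
    "<accuracy_course> %d classes, %d events, %d repeats; mean accuracy %.1f%% (chance %.1f%%)\n",
    length(x$classes), x$n_events, nrow(x$repeats),
    100 * x$overall, 100 * x$chance_level))
  invisible(x)
}

#' @export
plot.accuracy_course <- function(x, ...) {
  tm <- if (is.null(x$time_ms)) seq_along(x$accuracy) else x$time_ms
  graphics::plot(tm, x$accuracy, type = "b", ylim = c(0, 1),
                 xlab = "time from cursor onset (ms)", ylab = "accuracy", ...)
  graphics::abline(h = x$chance_level, lty = 2)
  invisible(x)
}

#' Build a classifier dataset from a cursor stream and spiking population
#'
#' Extracts cursor onsets, bins each unit's spikes around them, and labels
#' events by cursor position or by sweep direction (toward/away; events
#' without a defined direction are dropped).
#'
#' @param cursor a [cursor_stream()].
#' @param units list of [unit_spikes()].
#' @param classes `"position"` or `"direction"`.
#' @param bin_ms bin width, ms.
#' @param window_ms event window, ms relative to onset.
#' @return List with `responses` (events x units x bins), `labels`,
#'   `onsets`.
#' @export
classifier_dataset <- function(cursor, units,
                               classes = c("position", "direction"),
                               bin_ms = 50, window_ms = c(-250, 500)) {
  classes <- match.arg(classes)
  ons <- cursor_onsets(cursor)
  if (classes == "direction") ons <- ons[!is.na(ons$direction), , drop = FALSE]
  labels <- if (classes == "position") factor(ons$position) else
    factor(ons$direction)
  resp <- bin_event_responses(units, ons$frame, cursor$frame_rate,
                              bin_ms = bin_ms, window_ms = window_ms)
  list(responses = resp, labels = labels, onsets = ons)
}
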