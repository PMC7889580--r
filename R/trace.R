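#' Fluorescence trace
#'
#' One region-of-interest's fluorescence time series at a fixed frame rate.
#' A trace is either `raw` (camera units, strictly positive in any physical
#' recording) or `dff` (dF/F, dimensionless change relative to a running
#' baseline). The dF/F traces of the two control regions are the decoder's
#' input.
#'
#' @param values numeric vector, one sample per frame; all values finite.
#' @param frame_rate sampling rate in Hz (> 0).
#' @param roi_id label for the region of interest.
#' @param kind `"dff"` or `"raw"`.
#' @return An object of class `fl_trace`.
#' @examples
#' tr <- fl_trace(sin(seq(0, 10, by = 0.025)), frame_rate = 40, roi_id = "R1")
#' n_frames(tr)
#' @export
fl_trace <- function(values, frame_rate, roi_id = "roi", kind = c("dff", "raw")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 1L || !all(is.finite(values))) {
    stop("trace values must be a non-empty, all-finite numeric vector")
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("frame_rate must be a single positive number")
  }
  structure(
    list(values = values, frame_rate = frame_rate,
         roi_id = as.character(roi_id), kind = kind),
    class = "fl_trace"
  )
}

#' @export
print.fl_trace <- function(x, ...) {
  cat(sprintf("<fl_trace '%s'> %d frames @ %g Hz (%.1f s), kind = %s\n",
              x$roi_id, length(x$values), x$frame_rate,
              length(x$values) / x$frame_rate, x$kind))
  cat(sprintf("  range [%.4g, %.4g], sd %.4g\n",
              min(x$values), max(x$values), stats::sd(x$values)))
  invisible(x)
}

#' @export
plot.fl_trace <- function(x, ...) {
  t_s <- seq_along(x$values) / x$frame_rate
  graphics::plot(t_s, x$values, type = "l", xlab = "time (s)",
                 ylab = if (x$kind == "dff") "dF/F" else "F (raw)",
                 main = x$roi_id, ...)
  invisible(x)
}

#' Number of frames in a trace, movie or cursor stream
#' @param x an `fl_trace`, `cursor_stream` or `pixel_movie`.
#' @return integer frame count.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.fl_trace <- function(x) length(x$values)

#' @export
n_frames.cursor_stream <- function(x) length(x$position)

#' @export
n_frames.pixel_movie <- function(x) dim(x$frames)[3]

#' Discrete feedback cursor stream
#'
#' The cursor occupies one of `n_positions` discrete locations per frame
#' (position `n_positions` is the rewarded target) or is absent (`NA`)
#' between trials.
#'
#' @param position integer vector of positions in `1..n_positions`, `NA`
#'   where the cursor is absent.
#' @param frame_rate frames per second.
#' @param n_positions number of discrete cursor locations (default 8).
#' @return An object of class `cursor_stream`.
#' @export
cursor_stream <- function(position, frame_rate, n_positions = 8L) {
  pos <- as.integer(position)
  if (any(!is.na(pos) & (pos < 1L | pos > n_positions))) {
    stop("cursor positions must lie in 1..n_positions (or NA when absent)")
  }
  structure(
    list(position = pos, frame_rate = frame_rate,
         n_positions = as.integer(n_positions)),
    class = "cursor_stream"
  )
}

#' @export
print.cursor_stream <- function(x, ...) {
  pres <- sum(!is.na(x$position))
  cat(sprintf("<cursor_stream> %d frames @ %g Hz, %d positions, %.1f%% present\n",
              length(x$position), x$frame_rate, x$n_positions,
              100 * pres / length(x$position)))
  invisible(x)
}
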