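# Pixel-level map analyses: task-activation maps, seed-pixel correlation
# maps, spike-pixel affiliation maps and region-ratio summaries.

#' Pixel movie
#'
#' Low-resolution dF/F movie of dorsal cortex with named region masks in
#' movie pixel coordinates.
#'
#' @param frames numeric array `rows x cols x frames`, all values finite.
#' @param frame_rate Hz.
#' @param region_masks named list of logical matrices matching the frame
#'   shape (e.g. R1, R2, V1, AM, PM, RL, S1).
#' @return A `pixel_movie` object.
#' @export
pixel_movie <- function(frames, frame_rate, region_masks = list()) {
  if (length(dim(frames)) != 3L) stop("frames must be a rows x cols x frames array")
  if (!all(is.finite(frames))) stop("movie values must be finite")
  shp <- dim(frames)[1:2]
  for (nm in names(region_masks)) {
    if (!all(dim(region_masks[[nm]]) == shp)) {
      stop(sprintf("mask '%s' does not match the movie shape", nm))
    }
  }
  structure(
    list(frames = frames, frame_rate = frame_rate,
         region_masks = region_masks),
    class = "pixel_movie"
  )
}

#' @export
print.pixel_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<pixel_movie> %dx%d px, %d frames @ %g Hz; masks: %s\n",
              d[1], d[2], d[3], x$frame_rate,
              paste(names(x$region_masks), collapse = ", ")))
  invisible(x)
}

# Movie as an (n_pixels x n_frames) matrix.
.pix_mat <- function(movie) {
  d <- dim(movie$frames)
  matrix(movie$frames, nrow = d[1] * d[2], ncol = d[3])
}

#' Cortical map
#'
#' One scalar per pixel: a correlation (`seed_corr`, `affiliation`; bounded
#' in `[-1, 1]`) or a normalized activation. Undefined pixels (constant
#' traces, zero off-period SD) are `NA` and counted in attribute
#' `n_undefined`.
#'
#' @param values numeric matrix (rows x cols).
#' @param kind one of `"seed_corr"`, `"activation"`, `"affiliation"`.
#' @return A `cortical_map` object.
#' @export
cortical_map <- function(values, kind = c("seed_corr", "activation",
                                          "affiliation")) {
  kind <- match.arg(kind)
  if (kind != "activation" &&
      any(values < -1 - 1e-12 | values > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlation-kind map values must lie in [-1, 1]")
  }
  structure(list(values = values, kind = kind),
            class = "cortical_map")
}

#' @export
print.cortical_map <- function(x, ...) {
  cat(sprintf("<cortical_map> %s, %dx%d px, range [%.3g, %.3g], %d undefined\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
plot.cortical_map <- function(x, ...) {
  graphics::image(t(x$values[nrow(x$values):1, ]), axes = FALSE,
                  main = x$kind, ...)
  invisible(x)
}

#' Task-activation map
#'
#' Per pixel, the mean over the "on" frames (task) minus the mean over the
#' "off" frames (not performing), normalized by the off-frame SD
#' (`normalize = "zscore"`, default) or left as a plain mean difference
#' (`normalize = "none"`). Pixels with zero off-frame SD are undefined
#' (`NA`).
#'
#' @param movie a [pixel_movie()].
#' @param on_frames,off_frames disjoint, nonempty logical masks or integer
#'   frame indices.
#' @param normalize `"zscore"` or `"none"`.
#' @return A `cortical_map` of kind `"activation"`.
#' @export
activation_map <- function(movie, on_frames, off_frames,
                           normalize = c("zscore", "none")) {
  normalize <- match.arg(normalize)
  if (is.logical(on_frames)) on_frames <- which(on_frames)
  if (is.logical(off_frames)) off_frames <- which(off_frames)
  if (!length(on_frames) || !length(off_frames)) {
    stop("on/off frame masks must be nonempty")
  }
  if (length(intersect(on_frames, off_frames))) {
    stop("on and off frame masks must be disjoint")
  }
  m <- .pix_mat(movie)
  mu_on <- rowMeans(m[, on_frames, drop = FALSE])
  mu_off <- rowMeans(m[, off_frames, drop = FALSE])
  val <- mu_on - mu_off
  if (normalize == "zscore") {
    sd_off <- apply(m[, off_frames, drop = FALSE], 1, stats::sd)
    val <- ifelse(sd_off > 0, val / sd_off, NA_real_)
  }
  shp <- dim(movie$frames)[1:2]
  cortical_map(matrix(val, shp[1], shp[2]), kind = "activation")
}

# Pearson correlation of one reference trace against every pixel.
.pixel_correlation <- function(movie, ref, frame_mask, kind) {
  if (is.null(frame_mask)) frame_mask <- seq_len(dim(movie$frames)[3])
  if (is.logical(frame_mask)) frame_mask <- which(frame_mask)
  m <- .pix_mat(movie)[, frame_mask, drop = FALSE]
  r <- ref[frame_mask]
  if (stats::sd(r) == 0) stop("reference trace is constant over the masked frames")
  px_sd <- apply(m, 1, stats::sd)
  val <- rep(NA_real_, nrow(m))
  ok <- px_sd > 0
  val[ok] <- as.numeric(stats::cor(r, t(m[ok, , drop = FALSE])))
  val <- pmin(pmax(val, -1), 1)
  shp <- dim(movie$frames)[1:2]
  cortical_map(matrix(val, shp[1], shp[2]), kind = kind)
}

#' Seed-pixel correlation map
#'
#' Per pixel, the Pearson correlation between the pixel's trace and the
#' mean trace of the seed region, over the masked frames. Constant pixels
#' are undefined (`NA`).
#'
#' @param movie a [pixel_movie()].
#' @param seed_mask nonempty logical matrix (or the name of a stored region
#'   mask) selecting the seed pixels.
#' @param frame_mask logical mask or integer frame indices (default: all).
#' @return A `cortical_map` of kind `"seed_corr"`.
#' @export
seed_correlation_map <- function(movie, seed_mask, frame_mask = NULL) {
  if (is.character(seed_mask)) seed_mask <- movie$region_masks[[seed_mask]]
  if (is.null(seed_mask) || !any(seed_mask)) stop("seed mask is empty")
  m <- .pix_mat(movie)
  seed_trace <- colMeans(m[as.vector(seed_mask), , drop = FALSE])
  .pixel_correlation(movie, seed_trace, frame_mask, "seed_corr")
}

#' Spike-pixel affiliation map
#'
#' Bins a unit's spike train to match imaging frames and correlates the
#' binned train with each pixel's dF/F over the masked frames. A silent
#' (constant) unit gives an error.
#'
#' @param unit a [unit_spikes()].
#' @param movie a [pixel_movie()] sharing the unit's time base (frame `k`
#'   spans `[(k-1)/fr, k/fr)` seconds).
#' @param frame_mask logical mask or integer frame indices (default: all).
#' @return A `cortical_map` of kind `"affiliation"`.
#' @export
affiliation_map <- function(unit, movie, frame_mask = NULL) {
  stopifnot(inherits(unit, "unit_spikes"))
  n <- dim(movie$frames)[3]
  binned <- bin_spike_train(unit, n_frames = n, frame_rate = movie$frame_rate)
  if (stats::sd(binned) == 0) {
    stop(sprintf("unit %s is silent (constant binned train): affiliation undefined",
                 unit$unit_id))
  }
  .pixel_correlation(movie, binned, frame_mask, "affiliation")
}

#' Region-ratio summary of a cortical map
#'
#' Mean map value over the union of the numerator masks divided by the mean
#' over the denominator mask (e.g. higher-visual-area activation relative
#' to V1).
#'
#' @param map a [cortical_map()].
#' @param numerator_masks list of logical matrices (or a single matrix).
#' @param denominator_mask logical matrix.
#' @return Numeric ratio.
#' @export
region_ratio <- function(map, numerator_masks, denominator_mask) {
  if (is.matrix(numerator_masks)) numerator_masks <- list(numerator_masks)
  if (!length(numerator_masks) || !any(denominator_mask)) {
    stop("masks must be nonempty")
  }
  num_mask <- Reduce(`|`, numerator_masks)
  if (!any(num_mask)) stop("masks must be nonempty")
  num <- mean(map$values[num_mask], na.rm = TRUE)
  den <- mean(map$values[denominator_mask], na.rm = TRUE)
  if (!is.finite(den) || den <= 0) {
    stop("denominator mean <= 0: ratio undefined on this map")
  }
  num / den
}

#' Balance two frame masks by random subsampling
#'
#' Randomly drops frames from the larger of two masks so both select the
#' same number of frames (used to compare early vs late epochs with
#' comparable numbers of success trials).
#'
#' @param mask_a,mask_b logical frame masks of equal length.
#' @param seed integer seed.
#' @return List with balanced logical masks `a` and `b`.
#' @export
balance_frame_masks <- function(mask_a, mask_b, seed = 1L) {
  stopifnot(length(mask_a) == length(mask_b))
  set.seed(seed)
  na <- sum(mask_a); nb <- sum(mask_b)
  k <- min(na, nb)
  shrink <- function(m, k) {
    idx <- which(m)
    keep <- sort(sample(idx, k))
    out <- logical(length(m)); out[keep] <- TRUE; out
  }
  list(a = shrink(mask_a, k), b = shrink(mask_b, k))
}
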