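# Session container I/O: a directory bundle holding every array and table
# of one session plus provenance sufficient to regenerate it bit-exactly.

.bundle_version <- "1"
.bundle_required <- c("traces", "cursor")

#' Session bundle
#'
#' Container for everything one session produces: region traces, pixel
#' movie, cursor stream, trial log, spiking population, behavioral
#' covariates, and provenance (configs, seeds, package version) sufficient
#' to regenerate the bundle bit-exactly.
#'
#' @param traces named list of `fl_trace` (required).
#' @param cursor a [cursor_stream()] (required).
#' @param movie optional [pixel_movie()].
#' @param trials optional trial-log data frame.
#' @param spikes optional list of [unit_spikes()].
#' @param covariates optional data frame.
#' @param provenance list of configs/seeds/version.
#' @return A `session_bundle` object.
#' @export
session_bundle <- function(traces, cursor, movie = NULL, trials = NULL,
                           spikes = NULL, covariates = NULL,
                           provenance = list()) {
  if (!length(traces)) stop("a bundle requires at least one trace")
  stopifnot(inherits(cursor, "cursor_stream"))
  provenance$package_version <-
    as.character(utils::packageVersion("cortexloop"))
  structure(
    list(traces = traces, cursor = cursor, movie = movie, trials = trials,
         spikes = spikes, covariates = covariates, provenance = provenance),
    class = "session_bundle"
  )
}

#' @export
print.session_bundle <- function(x, ...) {
  have <- names(Filter(Negate(is.null), unclass(x)))
  cat(sprintf("<session_bundle> groups: %s\n", paste(have, collapse = ", ")))
  invisible(x)
}

#' Write a session bundle to disk
#'
#' Writes a directory container: one `.rds` per array group (exact binary
#' round trip), the trial log and unit metadata additionally as CSV for
#' interoperability, provenance as YAML, and a manifest naming the format
#' version and the groups present.
#'
#' @param bundle a [session_bundle()].
#' @param path directory to create (must not already contain a manifest).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  groups <- c("traces", "cursor", "movie", "trials", "spikes", "covariates")
  present <- groups[!vapply(bundle[groups], is.null, TRUE)]
  for (g in present) {
    saveRDS(bundle[[g]], file.path(path, paste0(g, ".rds")))
  }
  if (!is.null(bundle$trials)) {
    utils::write.csv(bundle$trials, file.path(path, "trials.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$spikes)) {
    utils::write.csv(unit_table(bundle$spikes),
                     file.path(path, "units.csv"), row.names = FALSE)
  }
  saveRDS(bundle$provenance, file.path(path, "provenance.rds"))
  yaml::write_yaml(bundle$provenance, file.path(path, "provenance.yaml"))
  yaml::write_yaml(list(format_version = .bundle_version, groups = present),
                   file.path(path, "manifest.yaml"))
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Validates the manifest version and the presence of the required groups
#' (`traces`, `cursor`); a missing required group raises an error naming
#' it. Reading a written bundle reproduces all arrays and metadata exactly.
#'
#' @param path bundle directory.
#' @return A [session_bundle()].
#' @export
read_bundle <- function(path) {
  mf <- file.path(path, "manifest.yaml")
  if (!file.exists(mf)) stop("not a session bundle: no manifest at ", path)
  manifest <- yaml::read_yaml(mf)
  if (!identical(as.character(manifest$format_version), .bundle_version)) {
    stop(sprintf("bundle format version mismatch: found '%s', expected '%s'",
                 manifest$format_version, .bundle_version))
  }
  for (g in .bundle_required) {
    if (!file.exists(file.path(path, paste0(g, ".rds")))) {
      stop(sprintf("missing required group '%s' in bundle %s", g, path))
    }
  }
  comp <- function(g) {
    f <- file.path(path, paste0(g, ".rds"))
    if (file.exists(f)) readRDS(f) else NULL
  }
  prov_rds <- file.path(path, "provenance.rds")
  prov <- if (file.exists(prov_rds)) readRDS(prov_rds) else
    yaml::read_yaml(file.path(path, "provenance.yaml"))
  b <- session_bundle(traces = comp("traces"), cursor = comp("cursor"),
                      movie = comp("movie"), trials = comp("trials"),
                      spikes = comp("spikes"),
                      covariates = comp("covariates"),
                      provenance = prov)
  b$provenance <- prov  # keep the stored version string untouched
  b
}

#' Build a session bundle from preset configurations
#'
#' Runs the synthetic generators and the trial engine for a preset and
#' packs every output into a bundle whose provenance records the arguments,
#' so [regenerate_bundle()] can rebuild it bit-exactly.
#'
#' @param preset `"naive"`, `"expert"` or `"spontaneous"`.
#' @param seed integer seed.
#' @param n_trials agent trials (ignored for spontaneous).
#' @param baseline_s calibration-baseline duration, seconds.
#' @return A [session_bundle()].
#' @export
build_session_bundle <- function(preset = "expert", seed = 1L,
                                 n_trials = 30L, baseline_s = 600) {
  seed <- as.integer(seed)
  n_trials <- as.integer(n_trials)
  pc <- preset_config(preset, seed = seed, duration_s = baseline_s,
                      n_trials = n_trials)
  base <- generate_region_pair(pc$gen)
  params <- calibrate(base$r1, base$r2, min_baseline_s = min(600, baseline_s))
  if (preset == "spontaneous") {
    ses <- run_session(base, params, pc$session)
    traces <- list(r1 = base$r1, r2 = base$r2)
  } else {
    ag <- generate_agent_session(pc$gen, pc$agent, n_trials = n_trials,
                                 seed = seed)
    ses <- run_session(ag, params, pc$session)
    traces <- list(r1 = ag$r1, r2 = ag$r2)
  }
  spikes <- generate_population_spikes(pc$spiking, ses$cursor,
                                       condition = "task", seed = seed)
  cov_cfg <- pc$gen
  cov_cfg$duration_s <- n_frames(ses$cursor) / pc$gen$frame_rate
  cov <- generate_covariates(cov_cfg)
  session_bundle(
    traces = traces, cursor = ses$cursor, trials = ses$trials,
    spikes = spikes, covariates = cov,
    provenance = list(preset = preset, seed = seed, n_trials = n_trials,
                      baseline_s = baseline_s)
  )
}

#' Regenerate a bundle from its provenance
#'
#' @param bundle a [session_bundle()] built by [build_session_bundle()].
#' @return A freshly generated [session_bundle()] with identical arrays.
#' @export
regenerate_bundle <- function(bundle) {
  p <- bundle$provenance
  build_session_bundle(preset = p$preset, seed = p$seed,
                       n_trials = p$n_trials, baseline_s = p$baseline_s)
}
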