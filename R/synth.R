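# Synthetic-data generators: correlated region traces with calcium-indicator
# dynamics, pixel movies, a learning (explore -> exploit) agent, and
# cursor-tuned Poisson spiking populations. All generators are pure functions
# of (config, seed).

#' Generator configuration for synthetic fluorescence signals
#'
#' Controls the statistics of the synthetic two-region traces and pixel
#' movies. The latent dynamics of each region are mean-reverting
#' (Ornstein-Uhlenbeck) processes with autocorrelation time `ou_tau`,
#' convolved with a single-exponential calcium-indicator kernel of decay
#' `calcium_tau`; a shared latent imposes the requested pairwise Pearson
#' correlation in closed form. Traces are emitted in dF/F units with
#' stationary standard deviation `amp_sd` plus white observation noise of
#' standard deviation `noise_sd` (the latent mixing is inflated so the
#' *observed* correlation, noise included, targets `pair_correlation`).
#'
#' Defaults are the package's documented spontaneous ("naive-preset")
#' conditions: 40 Hz frame rate, 20 min duration, `ou_tau` 1 s and
#' `calcium_tau` 1.5 s from the GCaMP6s literature, pair correlation 0.7
#' (control regions are highly spontaneously correlated), and an amplitude
#' `amp_sd` fixed once so that replaying this baseline through range/4
#' calibration and the trial engine yields a chance rate near 0.3 hits/min.
#'
#' @param frame_rate acquisition rate, Hz.
#' @param duration_s trace duration, seconds.
#' @param ou_tau latent autocorrelation time constant, seconds.
#' @param calcium_tau calcium-indicator decay time constant, seconds.
#' @param pair_correlation target Pearson correlation between the two region
#'   traces, in `[-1, 1]`.
#' @param amp_sd stationary standard deviation of each trace, dF/F units.
#' @param noise_sd white observation-noise standard deviation, dF/F units.
#' @param movie_shape integer `c(rows, cols)` of the synthetic pixel movie.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A `gen_config` list.
#' @export
gen_config <- function(frame_rate = 40, duration_s = 1200, ou_tau = 1,
                       calcium_tau = 1.5, pair_correlation = 0.7,
                       amp_sd = 1.23, noise_sd = 0.05,
                       movie_shape = c(32L, 32L), seed = 1L) {
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (ou_tau <= 0 || calcium_tau <= 0) stop("time constants must be > 0")
  if (!is.finite(pair_correlation) ||
      pair_correlation < -1 || pair_correlation > 1) {
    stop("pair_correlation must lie in [-1, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (amp_sd <= 0) stop("amp_sd must be > 0")
  if (length(movie_shape) != 2L || any(movie_shape < 1)) {
    stop("movie_shape must be c(rows, cols)")
  }
  structure(
    list(frame_rate = frame_rate, duration_s = duration_s, ou_tau = ou_tau,
         calcium_tau = calcium_tau, pair_correlation = pair_correlation,
         amp_sd = amp_sd, noise_sd = noise_sd,
         movie_shape = as.integer(movie_shape), seed = as.integer(seed)),
    class = "gen_config"
  )
}

# Exact discretization of a unit-variance OU process.
.ou_sim <- function(n, dt, tau) {
  phi <- exp(-dt / tau)
  innov_sd <- sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  eps <- stats::rnorm(n - 1L, sd = innov_sd)
  for (i in 2:n) x[i] <- phi * x[i - 1L] + eps[i - 1L]
  x
}

# Single-exponential calcium kernel applied as a recursive AR(1) filter.
.calcium_filter <- function(x, dt, tau) {
  as.numeric(stats::filter(x, exp(-dt / tau), method = "recursive"))
}

# Correlated trace pair (does not touch the seed; callers seed first).
# Returns calcium-filtered, amplitude-scaled traces plus the mixed latents.
.gen_pair_values <- function(cfg, n) {
  rho <- cfg$pair_correlation
  rho_lat <- rho
  if (cfg$noise_sd > 0 && rho != 0) {
    rho_lat <- rho * (1 + cfg$noise_sd^2 / cfg$amp_sd^2)
    if (abs(rho_lat) > 1) {
      stop("pair_correlation unattainable at this noise_sd/amp_sd ratio; ",
           "reduce noise_sd or the target correlation")
    }
  }
  dt <- 1 / cfg$frame_rate
  w <- sqrt(abs(rho_lat))
  s <- .ou_sim(n, dt, cfg$ou_tau)
  u1 <- .ou_sim(n, dt, cfg$ou_tau)
  u2 <- .ou_sim(n, dt, cfg$ou_tau)
  x1 <- w * s + sqrt(1 - w^2) * u1
  x2 <- sign(rho_lat + (rho_lat == 0)) * w * s + sqrt(1 - w^2) * u2
  y1 <- .calcium_filter(x1, dt, cfg$calcium_tau)
  y2 <- .calcium_filter(x2, dt, cfg$calcium_tau)
  y1 <- y1 / stats::sd(y1) * cfg$amp_sd
  y2 <- y2 / stats::sd(y2) * cfg$amp_sd
  if (cfg$noise_sd > 0) {
    y1 <- y1 + stats::rnorm(n, sd = cfg$noise_sd)
    y2 <- y2 + stats::rnorm(n, sd = cfg$noise_sd)
  }
  list(y1 = y1, y2 = y2, x1 = x1, x2 = x2)
}

#' Generate a correlated pair of synthetic region traces
#'
#' Builds the dF/F traces of the two control regions as calcium-kernel
#' convolved mixtures of one shared and two private mean-reverting latents,
#' mixed so the expected Pearson correlation of the observed traces equals
#' `cfg$pair_correlation`, plus additive white observation noise.
#'
#' @param cfg a [gen_config()].
#' @return A list with `fl_trace` elements `r1` and `r2`; the mixed
#'   pre-kernel latents are attached as attribute `"latents"` (a two-column
#'   matrix) for diagnostic use.
#' @examples
#' pr <- generate_region_pair(gen_config(duration_s = 60, seed = 7))
#' cor(pr$r1$values, pr$r2$values)
#' @export
generate_region_pair <- function(cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$frame_rate)
  v <- .gen_pair_values(cfg, n)
  out <- list(
    r1 = fl_trace(v$y1, cfg$frame_rate, roi_id = "R1", kind = "dff"),
    r2 = fl_trace(v$y2, cfg$frame_rate, roi_id = "R2", kind = "dff")
  )
  attr(out, "latents") <- cbind(x1 = v$x1, x2 = v$x2)
  out
}

#' Generate a synthetic pixel movie from region traces
#'
#' Each pixel is the mask-weighted sum of the region traces plus independent
#' white noise, emulating a low-resolution dorsal-cortex fluorescence movie.
#'
#' @param cfg a [gen_config()]; `movie_shape` and `noise_sd` are used. Movie
#'   noise draws use a fixed offset of the config seed so they are
#'   independent of the trace draws.
#' @param region_traces named list of `fl_trace` (or plain numeric vectors),
#'   all the same length.
#' @param region_masks named list (same names) of logical or numeric weight
#'   matrices with dimensions `cfg$movie_shape`.
#' @return A [pixel_movie()] with the masks attached.
#' @export
generate_movie <- function(cfg, region_traces, region_masks) {
  stopifnot(inherits(cfg, "gen_config"))
  if (!identical(sort(names(region_traces)), sort(names(region_masks)))) {
    stop("region_traces and region_masks must share names")
  }
  vals <- lapply(region_traces, function(tr) {
    if (inherits(tr, "fl_trace")) tr$values else as.numeric(tr)
  })
  n <- unique(vapply(vals, length, 1L))
  if (length(n) != 1L) stop("all region traces must have equal length")
  shp <- cfg$movie_shape
  for (nm in names(region_masks)) {
    m <- region_masks[[nm]]
    if (!identical(dim(m), as.integer(shp)) &&
        !identical(dim(m), as.numeric(shp))) {
      if (!all(dim(m) == shp)) {
        stop(sprintf("mask '%s' does not match movie_shape %dx%d",
                     nm, shp[1], shp[2]))
      }
    }
  }
  set.seed(cfg$seed + 1000003L)
  frames <- array(stats::rnorm(prod(shp) * n, sd = cfg$noise_sd),
                  dim = c(shp[1], shp[2], n))
  for (nm in names(region_masks)) {
    w <- region_masks[[nm]] * 1.0
    if (any(w != 0)) frames <- frames + outer(w, vals[[nm]])
  }
  pixel_movie(frames, frame_rate = cfg$frame_rate,
              region_masks = lapply(region_masks, function(m) m != 0))
}

#' Default cortical region masks for the synthetic movie
#'
#' Small disk masks, in movie pixel coordinates, for the two control regions
#' (R1, R2), primary visual cortex (V1), the higher visual areas AM, PM and
#' RL, and somatosensory cortex (S1). Positions are schematic; no atlas
#' registration is performed.
#'
#' @param shape integer `c(rows, cols)`.
#' @return Named list of logical matrices.
#' @export
default_region_masks <- function(shape = c(32L, 32L)) {
  centers <- list(
    R1 = c(0.22, 0.30), R2 = c(0.22, 0.62),
    V1 = c(0.80, 0.72), AM = c(0.62, 0.58),
    PM = c(0.68, 0.72), RL = c(0.62, 0.40),
    S1 = c(0.42, 0.30)
  )
  r <- max(1.5, 0.06 * min(shape))
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  lapply(centers, function(ct) {
    (rows - ct[1] * shape[1])^2 + (cols - ct[2] * shape[2])^2 <= r^2
  })
}

#' Agent configuration for the closed-loop learning simulation
#'
#' The synthetic agent starts by emitting stochastic bursts of activity in
#' the two control regions (exploration) and, on each rewarded trial, blends
#' its emission policy toward a stereotyped target waveform
#' (`policy <- (1 - learning_rate) * policy + learning_rate * exploit_pattern`),
#' so late-session trials emit the exploit pattern plus jitter.
#'
#' @param exploration_burst_rate rate of random bursts per region, events/s,
#'   at full exploration; scaled down as the policy converges.
#' @param exploration_amp_sd standard deviation of burst amplitudes, dF/F.
#' @param exploration_noise_sd white-noise amplitude added during
#'   exploration (scaled by the current exploration level), dF/F; models the
#'   broadband, high-spectral-entropy character of stochastic exploration.
#' @param learning_rate convex policy-blend step per rewarded trial (>= 0).
#' @param exploit_pattern 2-row matrix (R1; R2) target dF/F waveform, or
#'   `NULL` to build [default_exploit_pattern()] at session time.
#' @param exploit_jitter_sd per-frame jitter on emitted patterns, dF/F.
#' @param trial_dur_s,gap_s trial and inter-trial durations, seconds.
#' @param reward_threshold peak R1-R2 differential that counts as a rewarded
#'   pattern; `NULL` for 65% of the exploit pattern's peak differential
#'   (rewards a substantial minority of pure-exploration trials).
#' @param init one of `"naive"` (zero policy, full exploration) or
#'   `"expert"` (policy starts at the exploit pattern).
#' @return An `agent_config` list.
#' @export
agent_config <- function(exploration_burst_rate = 0.4,
                         exploration_amp_sd = 1.5,
                         exploration_noise_sd = 0.4,
                         learning_rate = 0.25,
                         exploit_pattern = NULL,
                         exploit_jitter_sd = 0.1,
                         trial_dur_s = 8, gap_s = 2,
                         reward_threshold = NULL,
                         init = c("naive", "expert")) {
  init <- match.arg(init)
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (exploit_jitter_sd < 0) stop("exploit_jitter_sd must be >= 0")
  if (exploration_burst_rate < 0 || exploration_amp_sd < 0 ||
      exploration_noise_sd < 0) {
    stop("exploration parameters must be >= 0")
  }
  structure(
    list(exploration_burst_rate = exploration_burst_rate,
         exploration_amp_sd = exploration_amp_sd,
         exploration_noise_sd = exploration_noise_sd,
         learning_rate = learning_rate,
         exploit_pattern = exploit_pattern,
         exploit_jitter_sd = exploit_jitter_sd,
         trial_dur_s = trial_dur_s, gap_s = gap_s,
         reward_threshold = reward_threshold, init = init),
    class = "agent_config"
  )
}

#' Default exploit pattern: R1 surges while R2 dips
#'
#' A smooth (Hann window) differential activation lasting `dur_s` seconds,
#' peaking at `peak` dF/F in R1 and `-peak` in R2. With the default
#' generator amplitude and range/4 calibration this pattern decodes to the
#' target position.
#'
#' @param frame_rate Hz.
#' @param peak peak dF/F excursion per region.
#' @param dur_s pattern duration, seconds.
#' @return 2-row matrix (R1; R2).
#' @export
default_exploit_pattern <- function(frame_rate = 40, peak = 3.1, dur_s = 2) {
  len <- round(dur_s * frame_rate)
  h <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = len)))
  rbind(R1 = peak * h, R2 = -peak * h)
}

# Half-cosine burst waveform of about 1 s.
.burst_shape <- function(frame_rate, dur_s = 1) {
  len <- round(dur_s * frame_rate)
  sin(pi * seq(0, 1, length.out = len))
}

#' Simulate a closed-loop session of the learning agent
#'
#' Generates the two control-region traces for a session of `n_trials`
#' agent trials. Early trials superimpose random independent bursts on a
#' correlated spontaneous background; each internally rewarded trial (peak
#' R1-R2 differential above threshold) moves the emission policy toward the
#' exploit pattern; late trials emit the exploit pattern plus jitter. The
#' per-frame ground-truth mode (`"background"`, `"explore"`, `"exploit"`)
#' and a per-trial event log are returned.
#'
#' @param gen a [gen_config()] (frame rate, background statistics).
#' @param agent an [agent_config()].
#' @param n_trials number of agent trials (>= 1).
#' @param seed integer seed; defaults to `gen$seed`.
#' @return List with `fl_trace`s `r1`, `r2`, data frame `events`
#'   (trial, start/end frame, rewarded, explore_scale, emit_frame), and
#'   character vector `mode` (one entry per frame).
#' @export
generate_agent_session <- function(gen, agent, n_trials, seed = gen$seed) {
  stopifnot(inherits(gen, "gen_config"), inherits(agent, "agent_config"))
  if (n_trials < 1) stop("n_trials must be >= 1")
  fr <- gen$frame_rate
  set.seed(seed)
  E <- agent$exploit_pattern
  if (is.null(E)) {
    E <- default_exploit_pattern(fr, peak = 2.5 * gen$amp_sd)
  }
  L <- ncol(E)
  thr <- agent$reward_threshold
  if (is.null(thr)) thr <- 0.65 * max(E[1, ] - E[2, ])
  trial_f <- round(agent$trial_dur_s * fr)
  gap_f <- round(agent$gap_s * fr)
  if (trial_f < L + fr) stop("trial_dur_s too short for the exploit pattern")
  n <- n_trials * (trial_f + gap_f)

  bg <- .gen_pair_values(gen, n)
  r1 <- bg$y1; r2 <- bg$y2
  mode <- rep("background", n)
  policy <- if (agent$init == "expert") E else matrix(0, 2, L)
  normE <- sqrt(sum(E^2))
  bshape <- .burst_shape(fr)
  bl <- length(bshape)

  ev <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    t0 <- (k - 1L) * (trial_f + gap_f) + 1L
    t1 <- t0 + trial_f - 1L
    progress <- max(0, min(1, 1 - sqrt(sum((policy - E)^2)) / normE))
    explore_scale <- 1 - progress

    emit_frame <- NA_integer_
    if (any(policy != 0)) {
      e0 <- t0 + round(0.5 * fr) +
        sample.int(max(1L, trial_f - L - fr), 1L) - 1L
      seg <- e0:(e0 + L - 1L)
      r1[seg] <- policy[1, ] + stats::rnorm(L, sd = agent$exploit_jitter_sd)
      r2[seg] <- policy[2, ] + stats::rnorm(L, sd = agent$exploit_jitter_sd)
      mode[seg] <- "exploit"
      emit_frame <- e0
    }
    if (agent$exploration_noise_sd > 0 && explore_scale > 0) {
      nseg <- t0:t1
      keep <- mode[nseg] != "exploit"
      wn_sd <- agent$exploration_noise_sd * explore_scale
      r1[nseg][keep] <- r1[nseg][keep] +
        stats::rnorm(sum(keep), sd = wn_sd)
      r2[nseg][keep] <- r2[nseg][keep] +
        stats::rnorm(sum(keep), sd = wn_sd)
    }
    nb <- stats::rpois(2L, agent$exploration_burst_rate *
                         agent$trial_dur_s * explore_scale)
    for (reg in 1:2) {
      if (nb[reg] > 0) {
        starts <- t0 + sample.int(max(1L, trial_f - bl), nb[reg],
                                  replace = TRUE) - 1L
        amps <- stats::rnorm(nb[reg], sd = agent$exploration_amp_sd)
        for (j in seq_len(nb[reg])) {
          seg <- starts[j]:(starts[j] + bl - 1L)
          keep <- mode[seg] != "exploit"
          if (reg == 1L) {
            r1[seg][keep] <- r1[seg][keep] + amps[j] * bshape[keep]
          } else {
            r2[seg][keep] <- r2[seg][keep] + amps[j] * bshape[keep]
          }
          mode[seg][keep & mode[seg] == "background"] <- "explore"
        }
      }
    }
    rewarded <- max(r1[t0:t1] - r2[t0:t1]) >= thr
    if (rewarded) {
      policy <- (1 - agent$learning_rate) * policy + agent$learning_rate * E
      if (all(policy == 0) && agent$learning_rate > 0) policy <- agent$learning_rate * E
    }
    ev[[k]] <- data.frame(trial = k, start_frame = t0, end_frame = t1,
                          rewarded = rewarded, explore_scale = explore_scale,
                          emit_frame = emit_frame)
  }
  list(
    r1 = fl_trace(r1, fr, roi_id = "R1", kind = "dff"),
    r2 = fl_trace(r2, fr, roi_id = "R2", kind = "dff"),
    events = do.call(rbind, ev),
    mode = mode
  )
}

#' Spiking population configuration
#'
#' Inhomogeneous-Poisson units whose instantaneous rate is
#' `baseline_rate * position_gain[pos] * sweep_gain * task_boost`, with the
#' sweep gain set by whether the cursor's last transition moved toward or
#' away from the target and the task boost applied only in the task (not
#' playback) condition. Waveform peak-to-trough widths are drawn per class
#' (regular- vs fast-spiking).
#'
#' @param n_units number of units.
#' @param baseline_rate Hz.
#' @param position_gain numeric vector of 8 multiplicative gains; the
#'   default rises toward the target position.
#' @param sweep_gain_toward,sweep_gain_away multiplicative gains applied over
#'   the dwell following a transition toward/away from the target.
#' @param task_boost multiplicative gain in the task condition.
#' @param tuning_heterogeneity SD of the per-unit tuning exponent: unit `u`
#'   follows `position_gain^e_u` with `e_u ~ N(1, tuning_heterogeneity)`,
#'   so units share the toward-target tuning shape with varying steepness
#'   (occasionally inverted), giving the population distinct per-position
#'   patterns. The uniform sweep gain carries no such pattern, so it scales
#'   rates without changing the population pattern. Set to 0 for
#'   identically tuned (homogeneous) units.
#' @param fs_fraction proportion of fast-spiking units, in `[0, 1]`.
#' @param width_params list with `rs_mean`, `rs_sd`, `fs_mean`, `fs_sd`
#'   (peak-to-trough widths, ms).
#' @return A `spiking_config` list.
#' @export
spiking_config <- function(n_units = 30L, baseline_rate = 5,
                           position_gain = c(1, 1, 1, 1, 1.1, 1.25, 1.5, 2),
                           sweep_gain_toward = 1.3, sweep_gain_away = 1,
                           task_boost = 1.5, tuning_heterogeneity = 0.5,
                           fs_fraction = 0.2,
                           width_params = list(rs_mean = 0.95, rs_sd = 0.15,
                                               fs_mean = 0.45, fs_sd = 0.08)) {
  if (baseline_rate < 0 || any(position_gain < 0) ||
      sweep_gain_toward < 0 || sweep_gain_away < 0 || task_boost < 0) {
    stop("rates and gains must be >= 0")
  }
  if (tuning_heterogeneity < 0) stop("tuning_heterogeneity must be >= 0")
  if (fs_fraction < 0 || fs_fraction > 1) stop("fs_fraction must lie in [0, 1]")
  structure(
    list(n_units = as.integer(n_units), baseline_rate = baseline_rate,
         position_gain = position_gain,
         sweep_gain_toward = sweep_gain_toward,
         sweep_gain_away = sweep_gain_away, task_boost = task_boost,
         tuning_heterogeneity = tuning_heterogeneity,
         fs_fraction = fs_fraction, width_params = width_params),
    class = "spiking_config"
  )
}

#' Per-frame sweep state of a cursor stream
#'
#' For every frame, +1 if the most recent position change within the current
#' presentation moved the cursor toward the target, -1 if away, 0 if the
#' cursor has not yet changed position (or is absent). The state persists
#' over the dwell that follows a transition.
#'
#' @param cursor a [cursor_stream()].
#' @param target target position (default: the highest position).
#' @return Integer vector, one entry per frame.
#' @export
sweep_state <- function(cursor, target = cursor$n_positions) {
  pos <- cursor$position
  n <- length(pos)
  state <- integer(n)
  cur <- 0L
  prev <- NA_integer_
  for (i in seq_len(n)) {
    p <- pos[i]
    if (is.na(p)) {
      cur <- 0L
      prev <- NA_integer_
    } else {
      if (!is.na(prev) && p != prev) {
        d <- abs(prev - target) - abs(p - target)
        cur <- if (d > 0) 1L else if (d < 0) -1L else 0L
      }
      prev <- p
    }
    state[i] <- cur
  }
  state
}

#' Generate a cursor-tuned spiking population
#'
#' @param cfg a [spiking_config()].
#' @param cursor a [cursor_stream()]; frames with an absent cursor take all
#'   gains equal to 1.
#' @param condition `"task"` (applies `task_boost`) or `"playback"`.
#' @param seed integer seed.
#' @return List of [unit_spikes()] objects.
#' @examples
#' cur <- cursor_stream(rep(c(1L, 8L), each = 200), frame_rate = 40)
#' pop <- generate_population_spikes(spiking_config(n_units = 4), cur,
#'                                   condition = "task", seed = 1)
#' @export
generate_population_spikes <- function(cfg, cursor,
                                       condition = c("task", "playback"),
                                       seed = 1L) {
  stopifnot(inherits(cfg, "spiking_config"), inherits(cursor, "cursor_stream"))
  condition <- match.arg(condition)
  if (length(cfg$position_gain) < cursor$n_positions) {
    stop("position_gain shorter than the number of cursor positions")
  }
  set.seed(seed)
  fr <- cursor$frame_rate
  dt <- 1 / fr
  pos <- cursor$position
  n <- length(pos)
  np <- cursor$n_positions
  sw <- sweep_state(cursor)
  sg <- ifelse(sw > 0, cfg$sweep_gain_toward,
               ifelse(sw < 0, cfg$sweep_gain_away, 1))
  boost <- if (condition == "task") cfg$task_boost else 1

  is_fs <- stats::runif(cfg$n_units) < cfg$fs_fraction
  wp <- cfg$width_params
  widths <- ifelse(is_fs,
                   stats::rnorm(cfg$n_units, wp$fs_mean, wp$fs_sd),
                   stats::rnorm(cfg$n_units, wp$rs_mean, wp$rs_sd))
  widths <- pmax(widths, 0.15)
  # per-unit tuning steepness: gain^e_u with e_u ~ N(1, heterogeneity)
  expo <- stats::rnorm(cfg$n_units, mean = 1, sd = cfg$tuning_heterogeneity)
  unit_gain <- vapply(expo, function(e) {
    cfg$position_gain[seq_len(np)]^e
  }, numeric(np))

  frame_start <- (seq_len(n) - 1L) * dt
  lapply(seq_len(cfg$n_units), function(u) {
    gain <- ifelse(is.na(pos), 1, unit_gain[pos, u])
    rate <- cfg$baseline_rate * gain * sg * boost  # Hz, per frame
    counts <- stats::rpois(n, rate * dt)
    times <- rep(frame_start, counts) + stats::runif(sum(counts)) * dt
    unit_spikes(sort(times), peak_to_trough_ms = widths[u],
                unit_id = sprintf("u%03d", u))
  })
}

#' Generate running-speed and pupil-diameter covariates
#'
#' Slow positive behavioral covariates with no coupling to the task: running
#' speed is a rectified slow mean-reverting process, pupil diameter a slow
#' process around a positive mean.
#'
#' @param cfg a [gen_config()] (frame rate and duration).
#' @param seed integer seed (defaults to `cfg$seed + 2000003`).
#' @return Data frame with columns `frame`, `run_speed`, `pupil`.
#' @export
generate_covariates <- function(cfg, seed = cfg$seed + 2000003L) {
  set.seed(seed)
  n <- round(cfg$duration_s * cfg$frame_rate)
  dt <- 1 / cfg$frame_rate
  run <- pmax(0, 5 * .ou_sim(n, dt, tau = 10))
  pupil <- 2 + 0.4 * .ou_sim(n, dt, tau = 20)
  data.frame(frame = seq_len(n), run_speed = run, pupil = pmax(pupil, 0.2))
}

#' Preset study conditions
#'
#' Bundles the generator, agent, spiking and session configurations for the
#' three canonical conditions: `"spontaneous"` (pre-task baseline only),
#' `"naive"` (agent starts at full exploration) and `"expert"` (agent starts
#' at the exploit policy).
#'
#' @param preset one of `"naive"`, `"expert"`, `"spontaneous"`.
#' @param seed integer seed threaded to every config.
#' @param duration_s baseline duration for the generator (default 20 min).
#' @param n_trials agent trials for the session presets.
#' @return List with elements `gen`, `agent` (NULL for spontaneous),
#'   `spiking`, `session`, `n_trials`, `preset`.
#' @export
preset_config <- function(preset = c("naive", "expert", "spontaneous"),
                          seed = 1L, duration_s = 1200, n_trials = 40L) {
  preset <- match.arg(preset)
  gen <- gen_config(duration_s = duration_s, seed = seed)
  agent <- switch(preset,
    spontaneous = NULL,
    naive = agent_config(init = "naive"),
    expert = agent_config(init = "expert", exploit_jitter_sd = 0.05)
  )
  list(gen = gen, agent = agent, spiking = spiking_config(),
       session = session_config(), n_trials = as.integer(n_trials),
       preset = preset)
}
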