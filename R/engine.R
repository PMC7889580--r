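# Closed-loop trial engine: hold detection, trial structure and reward
# scheduling, the control conditions (random reward, random feedback,
# passive playback) and ghost-decoder evaluation.

#' Session configuration
#'
#' Trial-structure parameters of the closed-loop task. Defaults follow the
#' standard protocol: a 300 ms hold at the target to count as a hit, a 30 s
#' trial limit, reward after a 1 s delay, a 10 s timeout after misses, and
#' a return-to-baseline wait of at most 5 s between trials (triggered when
#' the differential activation is within `baseline_tol_sd` spontaneous SDs
#' of the spontaneous mean).
#'
#' @param hold_ms time at target required for a hit, ms.
#' @param trial_limit_s trial duration limit, s.
#' @param reward_delay_s hit-to-reward delay, s.
#' @param miss_timeout_s post-miss timeout, s.
#' @param inter_trial_max_s cap on the return-to-baseline wait, s.
#' @param condition one of `"task"`, `"random_reward"`, `"random_feedback"`,
#'   `"playback"`.
#' @param random_reward_rate Poisson reward rate of the random-reward
#'   condition, rewards/min.
#' @param frame_rate Hz.
#' @param baseline_tol_sd return-to-baseline tolerance, spontaneous SDs.
#' @param feedback_delay_frames display latency applied to the presented
#'   cursor, frames (analyses use the logged cursor, so the default is 0).
#' @return A `session_config` list.
#' @export
session_config <- function(hold_ms = 300, trial_limit_s = 30,
                           reward_delay_s = 1, miss_timeout_s = 10,
                           inter_trial_max_s = 5,
                           condition = c("task", "random_reward",
                                         "random_feedback", "playback"),
                           random_reward_rate = 1.5, frame_rate = 40,
                           baseline_tol_sd = 0.5,
                           feedback_delay_frames = 0L) {
  condition <- match.arg(condition)
  durs <- c(hold_ms, trial_limit_s, reward_delay_s, miss_timeout_s,
            inter_trial_max_s, frame_rate)
  if (any(durs <= 0)) stop("all durations and the frame rate must be > 0")
  hold_frames <- round(hold_ms * frame_rate / 1000)
  if (hold_frames < 1) stop("hold_ms shorter than one frame")
  structure(
    list(hold_ms = hold_ms, trial_limit_s = trial_limit_s,
         reward_delay_s = reward_delay_s, miss_timeout_s = miss_timeout_s,
         inter_trial_max_s = inter_trial_max_s, condition = condition,
         random_reward_rate = random_reward_rate, frame_rate = frame_rate,
         baseline_tol_sd = baseline_tol_sd,
         feedback_delay_frames = as.integer(feedback_delay_frames),
         hold_frames = as.integer(hold_frames)),
    class = "session_config"
  )
}

# First index at which `x` has been TRUE for k consecutive entries.
.first_hold <- function(x, k) {
  if (k <= length(x)) {
    r <- rle(x)
    starts <- cumsum(r$lengths) - r$lengths + 1L
    ok <- which(r$values & r$lengths >= k)
    if (length(ok)) return(starts[ok[1]] + as.integer(k) - 1L)
  }
  NA_integer_
}

#' Detect a target hold in a cursor stream
#'
#' Returns the first frame at which the cursor has occupied the target
#' position for `hold_frames` consecutive frames (at 40 Hz the standard
#' 300 ms hold is 12 frames), or `NA` if no such hold occurs.
#'
#' @param cursor a [cursor_stream()] (or plain integer vector).
#' @param target_position target position.
#' @param hold_frames required consecutive frames (>= 1).
#' @return Integer frame index or `NA`.
#' @examples
#' detect_hold(cursor_stream(rep(8L, 12), 40), 8, 12)
#' @export
detect_hold <- function(cursor, target_position, hold_frames) {
  if (hold_frames < 1) stop("hold_frames must be >= 1")
  pos <- if (inherits(cursor, "cursor_stream")) cursor$position else
    as.integer(cursor)
  .first_hold(!is.na(pos) & pos == target_position, hold_frames)
}

# Count the hold-completing hits recoverable from a cursor stream alone:
# one per maximal run of >= hold_frames consecutive frames at target.
.hits_from_positions <- function(pos, target, hold_frames) {
  r <- rle(!is.na(pos) & pos == target)
  starts <- cumsum(r$lengths) - r$lengths + 1L
  ok <- r$values & r$lengths >= hold_frames
  starts[ok] + as.integer(hold_frames) - 1L
}

#' Hit frames recomputed from a cursor stream
#'
#' One hit per maximal run of at least `hold_frames` consecutive frames at
#' the target, reported at the frame completing the hold. In the task
#' condition this reproduces the trial log's hit frames exactly (the cursor
#' disappears at a hit, so each hit leaves one such run).
#'
#' @param cursor a [cursor_stream()].
#' @param target target position (default: highest).
#' @param hold_frames consecutive-frame requirement (default: 300 ms).
#' @return Integer vector of hit frames.
#' @export
cursor_hits <- function(cursor, target = cursor$n_positions,
                        hold_frames = round(0.3 * cursor$frame_rate)) {
  .hits_from_positions(cursor$position, target, hold_frames)
}

# Core engine loop shared by the activity-driven conditions.
# pos: decoded (true) positions per frame; d: differential activation;
# displayed: positions shown to the subject (defaults to pos);
# contingent: whether hits schedule rewards.
.run_engine <- function(pos, d, params, cfg, displayed = NULL,
                        contingent = TRUE) {
  n <- length(pos)
  fr <- cfg$frame_rate
  hold_f <- cfg$hold_frames
  limit_f <- as.integer(round(cfg$trial_limit_s * fr))
  delay_f <- as.integer(round(cfg$reward_delay_s * fr))
  timeout_f <- as.integer(round(cfg$miss_timeout_s * fr))
  inter_max_f <- as.integer(round(cfg$inter_trial_max_s * fr))
  target <- params$n_positions
  if (is.null(displayed)) displayed <- pos
  if (cfg$feedback_delay_frames > 0L) {
    k <- cfg$feedback_delay_frames
    displayed <- c(rep(displayed[1], k), displayed)[seq_len(n)]
  }
  ok <- abs(d - params$spont_mean) < cfg$baseline_tol_sd * params$spont_sd

  cursor <- rep(NA_integer_, n)
  rows <- list()
  trial_frames <- 0L; timeout_frames <- 0L; inter_frames <- 0L
  incomplete <- FALSE
  f <- 1L
  trial_id <- 0L
  while (f <= n) {
    # inter-trial: wait for return to baseline, capped
    idx <- which(ok[f:min(f + inter_max_f - 1L, n)])
    start <- if (length(idx)) f + idx[1] - 1L else f + inter_max_f
    if (start > n) { inter_frames <- inter_frames + (n - f + 1L); break }
    wait <- start - f
    inter_frames <- inter_frames + wait

    seg_end_full <- start + limit_f - 1L
    seg_end <- min(seg_end_full, n)
    relhit <- .first_hold(pos[start:seg_end] == target, hold_f)
    trial_id <- trial_id + 1L
    if (!is.na(relhit)) {
      hf <- start + relhit - 1L
      cursor[start:hf] <- displayed[start:hf]
      trial_frames <- trial_frames + (hf - start + 1L)
      reward <- hf + delay_f
      rows[[trial_id]] <- data.frame(
        trial_id = trial_id, start_frame = start, end_frame = hf,
        outcome = "hit", hit_frame = hf,
        reward_frame = if (contingent) reward else NA_integer_,
        condition = cfg$condition, baseline_wait_frames = wait)
      inter_frames <- inter_frames + (min(reward, n) - hf)
      f <- reward + 1L
    } else if (seg_end == seg_end_full) {
      end <- start + limit_f
      cursor[start:(end - 1L)] <- displayed[start:(end - 1L)]
      trial_frames <- trial_frames + limit_f
      rows[[trial_id]] <- data.frame(
        trial_id = trial_id, start_frame = start, end_frame = end,
        outcome = "miss", hit_frame = NA_integer_,
        reward_frame = NA_integer_,
        condition = cfg$condition, baseline_wait_frames = wait)
      if (end <= n) {
        timeout_frames <- timeout_frames +
          (min(end + timeout_f - 1L, n) - end + 1L)
      }
      f <- end + timeout_f
    } else {
      # activity exhausted mid-trial
      cursor[start:seg_end] <- displayed[start:seg_end]
      trial_frames <- trial_frames + (seg_end - start + 1L)
      rows[[trial_id]] <- data.frame(
        trial_id = trial_id, start_frame = start, end_frame = seg_end,
        outcome = "miss", hit_frame = NA_integer_,
        reward_frame = NA_integer_,
        condition = cfg$condition, baseline_wait_frames = wait)
      incomplete <- TRUE
      break
    }
  }
  trials <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial_id = integer(), start_frame = integer(),
               end_frame = integer(), outcome = character(),
               hit_frame = integer(), reward_frame = integer(),
               condition = character(), baseline_wait_frames = integer())
  list(trials = trials, cursor = cursor,
       frames = list(trial = trial_frames, timeout = timeout_frames,
                     intertrial = inter_frames),
       incomplete = incomplete)
}

.new_session <- function(eng, decoded, rewards, cfg, params, n, fr) {
  structure(
    list(trials = eng$trials,
         cursor = cursor_stream(eng$cursor, fr, params$n_positions),
         rewards = rewards, decoded = decoded,
         condition = cfg$condition, frame_rate = fr, n_frames = n,
         frames = eng$frames, incomplete = eng$incomplete,
         params = params, cfg = cfg),
    class = "bmi_session"
  )
}

#' @export
print.bmi_session <- function(x, ...) {
  nh <- sum(x$trials$outcome == "hit")
  cat(sprintf(
    "<bmi_session> %s: %d trials (%d hits, %d misses), %d rewards, %.1f min\n",
    x$condition, nrow(x$trials), nh, sum(x$trials$outcome == "miss"),
    length(x$rewards), x$n_frames / x$frame_rate / 60))
  if (x$incomplete) cat("  [incomplete: activity exhausted mid-trial]\n")
  invisible(x)
}

#' @export
summary.bmi_session <- function(object, ...) {
  mins <- object$n_frames / object$frame_rate / 60
  nh <- sum(object$trials$outcome == "hit")
  out <- list(condition = object$condition, n_trials = nrow(object$trials),
              n_hits = nh, n_rewards = length(object$rewards),
              minutes = mins, hits_per_min = nh / mins,
              hit_fraction = if (nrow(object$trials)) nh / nrow(object$trials)
                             else NA_real_)
  class(out) <- "summary.bmi_session"
  out
}

#' @export
print.summary.bmi_session <- function(x, ...) {
  cat(sprintf("%s session: %.1f min, %d trials, %d hits (%.0f%%), %.2f hits/min, %d rewards\n",
              x$condition, x$minutes, x$n_trials, x$n_hits,
              100 * x$hit_fraction, x$hits_per_min, x$n_rewards))
  invisible(x)
}

#' Run a closed-loop task session
#'
#' Decodes the activity frame by frame and loops trials: wait (capped) until
#' the differential activation returns within tolerance of the spontaneous
#' mean, start a trial, end it on a detected target hold (hit; reward
#' scheduled after the delay) or at the trial limit (miss; followed by the
#' timeout). The cursor is marked absent between trials.
#'
#' @param activity list with dF/F `fl_trace`s `r1` and `r2`.
#' @param params a visual-mode [decoder_params()].
#' @param cfg a [session_config()] with `condition = "task"` (other
#'   conditions go through [run_condition()]).
#' @param seed optional integer seed (the task condition is deterministic;
#'   the seed matters only for stochastic conditions).
#' @return A `bmi_session`: trial log, cursor stream, reward frames, decoded
#'   positions, frame accounting and the configs used.
#' @export
run_session <- function(activity, params, cfg = session_config(),
                        seed = NULL) {
  stopifnot(inherits(params, "decoder_params"))
  if (!is.null(seed)) set.seed(seed)
  r1 <- activity$r1$values; r2 <- activity$r2$values
  if (length(r1) != length(r2)) stop("region traces must have equal length")
  n <- length(r1)
  fr <- activity$r1$frame_rate
  d <- params$a1 * r1 - params$a2 * r2
  pos <- decode_position(r1, r2, params)
  eng <- .run_engine(pos, d, params, cfg)
  rewards <- eng$trials$reward_frame[!is.na(eng$trials$reward_frame) &
                                       eng$trials$reward_frame <= n]
  .new_session(eng, pos, as.integer(rewards), cfg, params, n, fr)
}

#' Run a control condition
#'
#' Implements the three dissociation conditions. `random_reward`: the cursor
#' is still activity-driven and target hits are logged, but rewards come
#' from an independent Poisson schedule at `cfg$random_reward_rate` and hits
#' are unrewarded. `random_feedback`: the displayed cursor is drawn
#' per frame from a Gaussian matched to a reference session's displayed
#' mean/variance (then rounded and clipped like the decoder output), while
#' hit detection still runs on the true decoded activity. `playback`: the
#' cursor and trial timing are replayed frame for frame from the reference
#' session with no decoding.
#'
#' @param activity list with `fl_trace`s `r1`, `r2` (ignored for playback).
#' @param params a [decoder_params()] (ignored for playback).
#' @param cfg a [session_config()] whose `condition` selects the branch.
#' @param reference a prior task `bmi_session`; required for
#'   `random_feedback` (moment matching) and `playback` (replay source).
#' @param seed integer seed for the stochastic conditions.
#' @return A `bmi_session`.
#' @export
run_condition <- function(activity, params, cfg, reference = NULL,
                          seed = 1L) {
  cond <- cfg$condition
  if (cond == "task") return(run_session(activity, params, cfg))
  set.seed(seed)
  if (cond == "playback") {
    if (is.null(reference)) stop("playback requires a reference session")
    trials <- reference$trials
    trials$condition <- "playback"
    eng <- list(trials = trials, cursor = reference$cursor$position,
                frames = reference$frames, incomplete = reference$incomplete)
    return(.new_session(eng, decoded = NULL, rewards = reference$rewards,
                        cfg, reference$params, reference$n_frames,
                        reference$frame_rate))
  }
  r1 <- activity$r1$values; r2 <- activity$r2$values
  n <- length(r1)
  fr <- activity$r1$frame_rate
  d <- params$a1 * r1 - params$a2 * r2
  pos <- decode_position(r1, r2, params)
  if (cond == "random_reward") {
    gaps <- stats::rexp(ceiling(cfg$random_reward_rate * n / fr / 60 * 4) + 20,
                        rate = cfg$random_reward_rate / 60 / fr)
    sched <- cumsum(gaps)
    rewards <- as.integer(ceiling(sched[sched <= n]))
    eng <- .run_engine(pos, d, params, cfg, contingent = FALSE)
    return(.new_session(eng, pos, rewards, cfg, params, n, fr))
  }
  if (cond == "random_feedback") {
    if (is.null(reference)) stop("random_feedback requires a reference session")
    ref_pos <- reference$cursor$position
    ref_pos <- ref_pos[!is.na(ref_pos)]
    if (length(ref_pos) < 2) stop("reference session has no displayed cursor")
    draw <- stats::rnorm(n, mean = mean(ref_pos), sd = stats::sd(ref_pos))
    disp <- as.integer(pmin(pmax(floor(draw + 0.5), 1), params$n_positions))
    eng <- .run_engine(pos, d, params, cfg, displayed = disp)
    rewards <- eng$trials$reward_frame[!is.na(eng$trials$reward_frame) &
                                         eng$trials$reward_frame <= n]
    return(.new_session(eng, pos, as.integer(rewards), cfg, params, n, fr))
  }
  stop("unknown condition: ", cond)
}

#' Ghost-decoder evaluation
#'
#' Replays identical activity through two decoders' hold detection (no trial
#' structure) and returns hits/min for each in sliding windows. Used to
#' track persistence of a strategy after the decoder (control-region
#' assignment) changes: the previous "ghost" decoder's rate decays while the
#' new decoder's rate recovers.
#'
#' @param activity list with dF/F `fl_trace`s `r1`, `r2`.
#' @param old_params,new_params visual-mode [decoder_params()].
#' @param cfg a [session_config()] (hold duration).
#' @param window_min,step_min sliding-window length and step, minutes.
#' @param swap_regions_new if `TRUE`, the new decoder reads the regions in
#'   swapped order (the mid-session R1/R2 swap manipulation: both decoders
#'   see identical cortical activity but assign the control roles
#'   oppositely).
#' @return Data frame with `time_min` (window center), `old_rate`,
#'   `new_rate` (hits/min).
#' @export
ghost_decoder_eval <- function(activity, old_params, new_params,
                               cfg = session_config(), window_min = 2,
                               step_min = 0.5, swap_regions_new = FALSE) {
  r1 <- activity$r1$values; r2 <- activity$r2$values
  fr <- activity$r1$frame_rate
  n <- length(r1)
  hold_f <- cfg$hold_frames
  hit_frames <- function(p, swap = FALSE) {
    pos <- if (swap) decode_position(r2, r1, p) else decode_position(r1, r2, p)
    .hits_from_positions(pos, p$n_positions, hold_f)
  }
  h_old <- hit_frames(old_params)
  h_new <- hit_frames(new_params, swap = swap_regions_new)
  w_f <- window_min * 60 * fr
  centers <- seq(w_f / 2, n - w_f / 2, by = step_min * 60 * fr)
  if (!length(centers)) centers <- n / 2
  rate <- function(h) {
    vapply(centers, function(ct)
      sum(h >= ct - w_f / 2 & h < ct + w_f / 2) / window_min, 1)
  }
  data.frame(time_min = centers / fr / 60,
             old_rate = rate(h_old), new_rate = rate(h_new))
}
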