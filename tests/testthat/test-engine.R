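# Trial engine: hold detection, trial structure, the control conditions and
# ghost-decoder evaluation.

test_that("a hold is exactly the configured consecutive-frame run", {
  # 300 ms at 40 Hz = 12 frames
  expect_identical(detect_hold(cursor_stream(rep(8L, 12), 40), 8, 12), 12L)
  expect_identical(detect_hold(c(rep(3L, 5), rep(8L, 12)), 8, 12), 17L)
  # 11 frames then leaving: no hit
  expect_identical(detect_hold(c(rep(8L, 11), 7L, rep(8L, 11)), 8, 12),
                   NA_integer_)
  # alternating positions never accumulate a hold
  expect_identical(detect_hold(rep(c(8L, 7L), 50), 8, 2), NA_integer_)
  # absence breaks a run
  expect_identical(detect_hold(c(rep(8L, 6), NA, rep(8L, 6)), 8, 12),
                   NA_integer_)
  expect_error(detect_hold(rep(8L, 5), 8, 0), ">= 1")
})

test_that("activity pinned at the target yields a hit every trial", {
  act <- list(r1 = fl_trace(rep(10, 8000), 40), r2 = fl_trace(rep(0, 8000), 40))
  ses <- run_session(act, unit_params())
  expect_true(all(ses$trials$outcome == "hit"))
  # differential never returns to baseline: every wait is capped at 5 s
  expect_true(all(ses$trials$baseline_wait_frames == 200L))
  expect_identical(ses$trials$hit_frame, ses$trials$start_frame + 11L)
  expect_identical(ses$trials$reward_frame, ses$trials$hit_frame + 40L)
})

test_that("activity pinned away from the target misses every trial", {
  n <- 8000L
  act <- list(r1 = fl_trace(rep(0, n), 40), r2 = fl_trace(rep(10, n), 40))
  ses <- run_session(act, unit_params())
  expect_true(all(ses$trials$outcome == "miss"))
  full <- if (ses$incomplete) head(ses$trials, -1) else ses$trials
  expect_true(all(full$end_frame - full$start_frame == 1200L))
  expect_identical(ses$rewards, integer(0))
  expect_identical(ses$frames$trial + ses$frames$timeout +
                     ses$frames$intertrial, n)
})

test_that("a session ending mid-trial is flagged incomplete", {
  act <- list(r1 = fl_trace(rep(0, 1000), 40), r2 = fl_trace(rep(10, 1000), 40))
  ses <- run_session(act, unit_params())
  expect_true(ses$incomplete)
})

test_that("trial log and cursor stream agree on hits and rewards", {
  gen <- quick_gen(seed = 6)
  ag <- generate_agent_session(gen, agent_config(init = "expert"),
                               n_trials = 15, seed = 6)
  base <- generate_region_pair(quick_gen(duration_s = 600, seed = 1))
  params <- calibrate(base$r1, base$r2)
  ses <- run_session(ag, params)
  n_hits <- sum(ses$trials$outcome == "hit")
  expect_gt(n_hits, 0)
  # the cursor record alone reproduces the hit count and frames
  expect_identical(cursor_hits(ses$cursor),
                   ses$trials$hit_frame[!is.na(ses$trials$hit_frame)])
  # one reward per hit, never before it
  expect_identical(length(ses$rewards), sum(!is.na(ses$trials$reward_frame) &
                                              ses$trials$reward_frame <= ses$n_frames))
  with(ses$trials[ses$trials$outcome == "hit", ],
       expect_true(all(reward_frame > hit_frame)))
  # frame accounting tiles the session
  expect_identical(ses$frames$trial + ses$frames$timeout +
                     ses$frames$intertrial, ses$n_frames)
  # cursor absent outside trials
  intrial <- logical(ses$n_frames)
  for (i in seq_len(nrow(ses$trials))) {
    e <- min(ses$trials$end_frame[i], ses$n_frames)
    intrial[ses$trials$start_frame[i]:e] <- TRUE
  }
  expect_true(all(is.na(ses$cursor$position[!intrial])))
})

test_that("identical inputs reproduce an identical trial log", {
  gen <- quick_gen(seed = 9)
  ag <- generate_agent_session(gen, agent_config(init = "expert"),
                               n_trials = 20, seed = 9)
  base <- generate_region_pair(quick_gen(duration_s = 600, seed = 2))
  params <- calibrate(base$r1, base$r2)
  s1 <- run_session(ag, params)
  s2 <- run_session(ag, params)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$cursor$position, s2$cursor$position)
})

test_that("random rewards arrive at the configured Poisson rate, uncoupled", {
  pr <- generate_region_pair(quick_gen(duration_s = 3600, seed = 11))
  params <- calibrate(pr$r1, pr$r2)
  cfg <- session_config(condition = "random_reward")
  ses <- run_condition(pr, params, cfg, seed = 2)
  # 1.5/min for 60 min: Poisson 95% CI around 90
  expect_gte(length(ses$rewards), qpois(0.025, 90))
  expect_lte(length(ses$rewards), qpois(0.975, 90))
  # target hits are logged but never rewarded
  expect_true(all(is.na(ses$trials$reward_frame)))
})

test_that("random feedback matches the reference's displayed moments", {
  set.seed(5)
  refp <- pmin(pmax(round(rnorm(20000, 4.5, 1.5)), 1), 8)
  reference <- list(cursor = cursor_stream(refp, 40))
  # true activity pinned low: all trials run their full 30 s
  n <- 60000
  act <- list(r1 = fl_trace(rep(0, n), 40), r2 = fl_trace(rep(10, n), 40))
  cfg <- session_config(condition = "random_feedback")
  ses <- run_condition(act, unit_params(), cfg, reference = reference,
                       seed = 3)
  disp <- ses$cursor$position[!is.na(ses$cursor$position)]
  expect_gt(length(disp), 10000)
  expect_lt(abs(mean(disp) - mean(refp)) / mean(refp), 0.02)
  expect_lt(abs(sd(disp) - sd(refp)) / sd(refp), 0.02)
  # hit detection ran on the true (decoded) activity: no hits
  expect_true(all(ses$trials$outcome == "miss"))
  expect_error(run_condition(act, unit_params(), cfg), "reference")
})

test_that("playback replays the source cursor and trial timing exactly", {
  act <- list(r1 = fl_trace(rep(10, 6000), 40), r2 = fl_trace(rep(0, 6000), 40))
  src <- run_session(act, unit_params())
  pb <- run_condition(NULL, NULL, session_config(condition = "playback"),
                      reference = src)
  expect_identical(pb$cursor$position, src$cursor$position)
  expect_identical(pb$trials$start_frame, src$trials$start_frame)
  expect_true(all(pb$trials$condition == "playback"))
  # exactly the source's k target-hold epochs, at the source frames
  expect_identical(cursor_hits(pb$cursor), cursor_hits(src$cursor))
  expect_error(run_condition(NULL, NULL,
                             session_config(condition = "playback")),
               "reference")
})

test_that("ghost evaluation separates decoders reading swapped regions", {
  # identical params: identical hit-rate time courses
  pr <- generate_region_pair(quick_gen(duration_s = 300, seed = 4))
  params <- calibrate(pr$r1, pr$r2, min_baseline_s = 300)
  g0 <- ghost_decoder_eval(pr, params, params)
  expect_identical(g0$old_rate, g0$new_rate)

  # activity holding only the old decoder's target: ghost rate > 0, new = 0
  n <- 24000
  r1v <- rep(0, n)
  for (s in seq(1000, 20000, by = 4000)) r1v[s:(s + 30)] <- 5.2
  act <- list(r1 = fl_trace(r1v, 40), r2 = fl_trace(rep(0, n), 40))
  g <- ghost_decoder_eval(act, unit_params(), unit_params(),
                          swap_regions_new = TRUE)
  expect_gt(mean(g$old_rate), 0)
  expect_identical(unique(g$new_rate), 0)
})
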