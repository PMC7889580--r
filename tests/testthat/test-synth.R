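# Synthetic generators: seeded determinism, correlation targeting, latent
# dynamics, movies, the learning agent, and Poisson spiking populations.

test_that("identical config and seed give bit-identical generator output", {
  cfg <- quick_gen(seed = 42)
  a <- generate_region_pair(cfg)
  b <- generate_region_pair(cfg)
  expect_identical(a$r1$values, b$r1$values)
  expect_identical(a$r2$values, b$r2$values)
  c <- generate_region_pair(quick_gen(seed = 43))
  expect_false(identical(a$r1$values, c$r1$values))

  cur <- dwell_cursor(50)
  p1 <- generate_population_spikes(spiking_config(n_units = 3), cur, "task", 7)
  p2 <- generate_population_spikes(spiking_config(n_units = 3), cur, "task", 7)
  expect_identical(p1, p2)
})

test_that("a pure shared latent yields perfectly correlated traces", {
  cfg <- quick_gen(pair_correlation = 1, noise_sd = 0)
  pr <- generate_region_pair(cfg)
  expect_equal(cor(pr$r1$values, pr$r2$values), 1)
  expect_equal(pr$r1$values, pr$r2$values)
})

test_that("pair_correlation = 0 gives near-zero empirical correlation", {
  pr <- generate_region_pair(quick_gen(duration_s = 600, pair_correlation = 0,
                                       seed = 5))
  expect_lt(abs(cor(pr$r1$values, pr$r2$values)), 0.1)
})

test_that("correlation targeting is unbiased at the default rho", {
  rs <- vapply(1:15, function(s) {
    pr <- generate_region_pair(quick_gen(duration_s = 600, seed = s))
    cor(pr$r1$values, pr$r2$values)
  }, 1)
  expect_lt(abs(mean(rs) - 0.7), 0.05)
})

test_that("pair_correlation outside [-1, 1] is rejected", {
  expect_error(gen_config(pair_correlation = 1.2), "pair_correlation")
  expect_error(gen_config(pair_correlation = -1.01), "pair_correlation")
})

test_that("latent autocorrelation follows the mean-reversion time constant", {
  acs <- vapply(1:4, function(s) {
    cfg <- quick_gen(duration_s = 600, ou_tau = 1, seed = s)
    lat <- attr(generate_region_pair(cfg), "latents")
    stats::acf(lat[, "x1"], lag.max = 40, plot = FALSE)$acf[41]
  }, 1)
  expect_lt(abs(mean(acs) - exp(-1)), 0.05)
})

test_that("movie pixels carry mask-weighted region signals plus noise", {
  cfg <- quick_gen(duration_s = 5, noise_sd = 0, movie_shape = c(8L, 8L))
  tr <- generate_region_pair(cfg)
  mask <- matrix(FALSE, 8, 8); mask[2:3, 2:3] <- TRUE
  mv <- generate_movie(cfg, list(R1 = tr$r1), list(R1 = mask))
  # noiseless, weight-1 mask: pixel trace equals the region trace exactly
  expect_equal(mv$frames[2, 2, ], tr$r1$values)
  # outside all masks (noiseless): identically zero
  expect_true(all(mv$frames[6, 6, ] == 0))

  # 0.5-weight pixel with unit-variance noise: analytic correlation
  cfg2 <- quick_gen(duration_s = 120, noise_sd = 1, pair_correlation = 0,
                    movie_shape = c(4L, 4L), seed = 9)
  tr2 <- generate_region_pair(cfg2)
  w <- matrix(0, 4, 4); w[1, 1] <- 0.5
  mv2 <- generate_movie(cfg2, list(R1 = tr2$r1), list(R1 = w))
  s <- sd(tr2$r1$values)
  r_theory <- 0.5 * s / sqrt(0.25 * s^2 + 1)
  r_emp <- cor(mv2$frames[1, 1, ], tr2$r1$values)
  expect_lt(abs(r_emp - r_theory), 0.05)
})

test_that("movie masks must match the configured shape", {
  cfg <- quick_gen(duration_s = 2, movie_shape = c(8L, 8L))
  tr <- generate_region_pair(cfg)
  expect_error(
    generate_movie(cfg, list(R1 = tr$r1), list(R1 = matrix(TRUE, 4, 4))),
    "movie_shape"
  )
})

test_that("a non-learning agent is stationary across the session", {
  gen <- quick_gen()
  ag <- generate_agent_session(gen, agent_config(learning_rate = 0),
                               n_trials = 40, seed = 3)
  expect_true(all(ag$events$explore_scale == 1))
  n <- length(ag$r1$values)
  q <- floor(n / 4)
  ratio <- var(ag$r1$values[1:q]) / var(ag$r1$values[(n - q + 1):n])
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("zero exploit jitter makes late emissions exactly stereotyped", {
  gen <- quick_gen()
  ag <- generate_agent_session(gen,
                               agent_config(init = "expert",
                                            exploit_jitter_sd = 0),
                               n_trials = 6, seed = 4)
  E <- default_exploit_pattern(gen$frame_rate, peak = 2.5 * gen$amp_sd)
  L <- ncol(E)
  snips <- lapply(ag$events$emit_frame, function(e0) {
    ag$r1$values[e0:(e0 + L - 1)]
  })
  for (s in snips) expect_equal(s, snips[[1]])
  expect_equal(snips[[1]], unname(E[1, ]))
})

test_that("learning concentrates the rewarded activity pattern", {
  # across seeds, align the R1-R2 differential at each rewarded trial's peak:
  # late-session across-trial variance drops below early-session variance
  lower <- vapply(1:8, function(s) {
    gen <- quick_gen(seed = s)
    ag <- generate_agent_session(gen, agent_config(learning_rate = 0.4),
                                 n_trials = 40, seed = s)
    d <- ag$r1$values - ag$r2$values
    ev <- ag$events[ag$events$rewarded, ]
    peaks <- vapply(seq_len(nrow(ev)), function(i) {
      seg <- ev$start_frame[i]:ev$end_frame[i]
      seg[which.max(d[seg])]
    }, 1L)
    lags <- -20:20
    half <- nrow(ag$events) / 2
    early <- peaks[ev$trial <= half]
    late <- peaks[ev$trial > half]
    if (length(early) < 2 || length(late) < 2) return(NA)
    v <- function(p) mean(apply(vapply(p, function(h) d[h + lags],
                                       numeric(length(lags))), 1, var))
    v(late) < v(early)
  }, TRUE)
  expect_gte(mean(lower, na.rm = TRUE), 0.7)
})

test_that("spike counts follow the configured Poisson rates", {
  # flat gains, 5 Hz, 100 s: count near 500
  cur <- cursor_stream(rep(1L, 4000), 40)
  cfg <- spiking_config(n_units = 1, baseline_rate = 5,
                        position_gain = rep(1, 8), sweep_gain_toward = 1,
                        task_boost = 1, tuning_heterogeneity = 0)
  u <- generate_population_spikes(cfg, cur, "task", seed = 1)[[1]]
  expect_gte(length(u$spike_times), 400)
  expect_lte(length(u$spike_times), 600)
  expect_true(all(diff(u$spike_times) > 0))

  # zero baseline: no spikes
  cfg0 <- spiking_config(n_units = 1, baseline_rate = 0,
                         tuning_heterogeneity = 0)
  u0 <- generate_population_spikes(cfg0, cur, "task", seed = 1)[[1]]
  expect_length(u0$spike_times, 0)

  expect_error(spiking_config(baseline_rate = -1), ">= 0")
})

test_that("constant-rate per-frame counts pass a dispersion test", {
  cur <- cursor_stream(rep(1L, 1e5), 40)
  cfg <- spiking_config(n_units = 1, baseline_rate = 10,
                        position_gain = rep(1, 8), sweep_gain_toward = 1,
                        task_boost = 1, tuning_heterogeneity = 0)
  u <- generate_population_spikes(cfg, cur, "task", seed = 2)[[1]]
  counts <- bin_spike_train(u, 1e5, 40)
  disp <- var(counts) / mean(counts)
  expect_gt(disp, 0.9)
  expect_lt(disp, 1.1)
})

test_that("position gains are recovered from generated spikes", {
  cur <- dwell_cursor(4000, seed = 6)
  cfg <- spiking_config(n_units = 1, baseline_rate = 8,
                        position_gain = c(1, 1, 1, 1, 1, 1, 1, 2),
                        sweep_gain_toward = 1, task_boost = 1,
                        tuning_heterogeneity = 0)
  u <- generate_population_spikes(cfg, cur, "task", seed = 6)[[1]]
  tc <- tuning_curve(u, cur)
  expect_gt(tc$rate_hz[8] / tc$rate_hz[1], 1.7)
  expect_lt(tc$rate_hz[8] / tc$rate_hz[1], 2.3)
})

test_that("sweep state persists over the dwell after a transition", {
  cur <- cursor_stream(c(NA, 5L, 5L, 6L, 6L, 6L, 4L, 4L, NA, 7L), 40)
  st <- sweep_state(cur, target = 8)
  expect_identical(st, c(0L, 0L, 0L, 1L, 1L, 1L, -1L, -1L, 0L, 0L))
})

test_that("behavioral covariates are nonnegative and seeded", {
  cfg <- quick_gen(duration_s = 30)
  cv1 <- generate_covariates(cfg)
  cv2 <- generate_covariates(cfg)
  expect_identical(cv1, cv2)
  expect_true(all(cv1$run_speed >= 0))
  expect_true(all(cv1$pupil > 0))
})
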