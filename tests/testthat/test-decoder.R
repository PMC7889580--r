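# Decoder: sliding-percentile dF/F, range/4 calibration, position and
# frequency transforms, chance-rate estimation.

test_that("dF/F of a constant raw trace is identically zero", {
  raw <- fl_trace(rep(100, 2000), 40, kind = "raw")
  dff <- compute_dff(raw)
  expect_true(all(dff$values == 0))
  expect_identical(dff$kind, "dff")
})

test_that("a step above a stable baseline reads as (F - F0)/F0", {
  raw <- fl_trace(c(rep(100, 801), rep(120, 800)), 40, kind = "raw")
  dff <- compute_dff(raw)
  # while the preceding window's 10th percentile remains 100 the step reads 0.2
  expect_true(all(abs(dff$values[805:1480] - 0.2) < 1e-12))
  expect_true(all(dff$values[1:801] == 0))
})

test_that("the sliding baseline matches a brute-force percentile oracle", {
  set.seed(11)
  fr <- 40; W <- 20 * fr; m <- 1 * fr
  raw_v <- 100 + cumsum(rnorm(1600, sd = 0.5))
  raw <- fl_trace(raw_v, fr, kind = "raw")
  dff <- compute_dff(raw)
  oracle <- vapply(seq_along(raw_v), function(t) {
    i0 <- max(1, t - W); i1 <- t - 1
    if (i1 - i0 + 1 < m) { i0 <- 1; i1 <- min(length(raw_v), m) }
    f0 <- oracle_pctl(raw_v[i0:i1], 0.1)
    (raw_v[t] - f0) / f0
  }, 1)
  expect_equal(dff$values, oracle, tolerance = 1e-12)

  ramp <- fl_trace(seq(100, 140, length.out = 1200), fr, kind = "raw")
  dr <- compute_dff(ramp)
  oracle_r <- vapply(seq_len(1200), function(t) {
    i0 <- max(1, t - W); i1 <- t - 1
    if (i1 - i0 + 1 < m) { i0 <- 1; i1 <- min(1200, m) }
    f0 <- oracle_pctl(ramp$values[i0:i1], 0.1)
    (ramp$values[t] - f0) / f0
  }, 1)
  expect_equal(dr$values, oracle_r, tolerance = 1e-12)
})

test_that("unphysical raw input and wrong trace kinds are rejected", {
  neg <- fl_trace(c(rep(-1, 900), rep(100, 100)), 40, kind = "raw")
  expect_error(compute_dff(neg), "non-positive baseline")
  dff <- fl_trace(rnorm(2000), 40, kind = "dff")
  expect_error(compute_dff(dff), "raw")
  short <- fl_trace(rep(100, 100), 40, kind = "raw")
  expect_error(compute_dff(short), "longer")
})

test_that("calibration divides each baseline range by half the positions", {
  n <- 24000
  r1 <- fl_trace(seq(0, 1, length.out = n), 40)
  r2 <- fl_trace(seq(0.2, 1.0, length.out = n), 40)
  p <- calibrate(r1, r2)
  expect_equal(p$a1, 0.25)
  expect_equal(p$a2, 0.2)

  # symmetric, identically distributed baselines: median decoded position
  # equals the configured start position
  set.seed(3)
  s1 <- fl_trace(rnorm(24001), 40)
  s2 <- fl_trace(rnorm(24001), 40)
  ps <- calibrate(s1, s2, start_position = 3)
  dec <- decode_position(s1$values, s2$values, ps)
  expect_equal(median(dec), 3)
  expect_true(all(dec >= 1 & dec <= 8))
})

test_that("degenerate or short baselines fail calibration", {
  flat <- fl_trace(rep(0.5, 24000), 40)
  ok <- fl_trace(rnorm(24000), 40)
  expect_error(calibrate(flat, ok), "zero dynamic range")
  expect_error(calibrate(fl_trace(rnorm(100), 40), ok), "at least")
})

test_that("position decoding rounds half-up and clips to the range", {
  p0 <- decoder_params(1, 1, 0)
  expect_identical(decode_position(4.5, 0, p0), 5L)
  expect_identical(decode_position(8.7, 0, p0), 8L)
  expect_identical(decode_position(-2, 0, p0), 1L)
  expect_error(decode_position(0, 0, decoder_params(1, 1, 0, mode = "auditory")),
               "visual")
})

test_that("position decoding matches a brute-force oracle on random draws", {
  set.seed(7)
  for (i in 1:5) {
    a1 <- runif(1, 0, 3); a2 <- runif(1, 0, 3); b <- runif(1, -2, 6)
    p <- decoder_params(a1, a2, b)
    x <- rnorm(2000, sd = 2); y <- rnorm(2000, sd = 2)
    oracle <- pmin(pmax(floor(a1 * x - a2 * y + b + 0.5), 1), 8)
    expect_identical(decode_position(x, y, p), as.integer(oracle))
  }
})

test_that("position decoding is monotone in each region's activity", {
  p <- decoder_params(1.3, 0.8, 2.5)
  x <- seq(-4, 8, by = 0.05)
  expect_true(all(diff(decode_position(x, 1.2, p)) >= 0))
  expect_true(all(diff(decode_position(0.7, x, p)) <= 0))
})

test_that("frequency decoding is exponential with quarter-octave bins", {
  p <- decoder_params(5000, 0, 0, mode = "auditory")
  expect_equal(decode_frequency(0, 0, p)$frequency, 5000)
  expect_identical(decode_frequency(0, 0, p)$bin, 0L)
  expect_identical(decode_frequency(log(2^0.25), 0, p)$bin, 1L)

  p2 <- decoder_params(3000, 1000, 500, mode = "auditory")
  expect_equal(decode_frequency(0, 0, p2)$frequency, 3000 - 1000 + 500)

  # monotone: raising f_r1 never lowers the frequency
  x <- seq(-2, 2, by = 0.01)
  f <- decode_frequency(x, 0.3, p2)$frequency
  expect_true(all(diff(f) >= 0))
  # audible floor
  pf <- decoder_params(0, 5000, 0, mode = "auditory", min_frequency = 1000)
  expect_equal(decode_frequency(0, 3, pf)$frequency, 1000)
})

test_that("chance rate counts hand-placed target holds", {
  # positions decode to 3 except three 12-frame epochs at 8, placed inside
  # the 1st, 3rd and 5th trials of the deterministic miss/timeout cycle
  n <- 24000  # 10 min at 40 Hz
  r1v <- rep(0, n)
  for (s in c(101, 1853, 3605)) r1v[s:(s + 11)] <- 5.2
  r1 <- fl_trace(r1v, 40)
  r2 <- fl_trace(rep(0, n), 40)
  rate <- estimate_chance_rate(r1, r2, unit_params())
  expect_equal(as.numeric(rate), 0.3)
  ses <- attr(rate, "session")
  expect_identical(ses$trials$hit_frame[!is.na(ses$trials$hit_frame)],
                   c(112L, 1864L, 3616L))

  # never reaching the target: zero
  quiet <- fl_trace(rep(0, n), 40)
  expect_equal(as.numeric(estimate_chance_rate(quiet, quiet, unit_params())), 0)

  short <- fl_trace(rep(0, 100), 40)
  expect_error(estimate_chance_rate(short, short, unit_params()), "shorter")
})

test_that("chance rate is invariant to rescaling the raw fluorescence", {
  # (kF - kF0) / (kF0) = (F - F0) / F0: the whole replay chain is unchanged
  pr <- generate_region_pair(quick_gen(duration_s = 300, seed = 8))
  raw1 <- fl_trace(100 + 5 * pr$r1$values, 40, kind = "raw")
  raw2 <- fl_trace(100 + 5 * pr$r2$values, 40, kind = "raw")
  scale_k <- 3.7
  d1a <- compute_dff(raw1); d2a <- compute_dff(raw2)
  d1b <- compute_dff(fl_trace(scale_k * raw1$values, 40, kind = "raw"))
  d2b <- compute_dff(fl_trace(scale_k * raw2$values, 40, kind = "raw"))
  expect_equal(d1a$values, d1b$values, tolerance = 1e-12)
  pa <- calibrate(d1a, d2a, min_baseline_s = 300)
  pb <- calibrate(d1b, d2b, min_baseline_s = 300)
  ra <- estimate_chance_rate(d1a, d2a, pa)
  rb <- estimate_chance_rate(d1b, d2b, pb)
  expect_equal(as.numeric(ra), as.numeric(rb))
})
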