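test_that("smoothing is zero-phase, mean-removing, and low-pass", {
  rate <- 500
  # constants vanish entirely
  const <- resp_trace(rep(3.7, 5 * rate), rate)
  expect_true(all(abs(smooth_and_center(const)$samples) < 1e-9))

  # passband sinusoid: unchanged shape, unshifted peaks
  tr <- sin_trace(0.2, 40)
  sm <- smooth_and_center(tr)
  expect_equal(length(sm$samples), length(tr$samples))
  expect_lt(abs(mean(sm$samples)), 1e-9)
  expect_gt(cor(sm$samples, tr$samples), 0.999)
  # first analytic peak at t = 1.25 s
  win <- 400:900
  expect_lt(abs(which.max(sm$samples[win]) - which.max(tr$samples[win])), 1.5)

  # 10 Hz ripple attenuated below 10% in amplitude (projection oracle)
  t <- seq(0, 40 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * 0.2 * t) + 0.5 * sin(2 * pi * 10 * t)
  sm2 <- smooth_and_center(resp_trace(x, rate))
  amp_in <- sqrt(power_at(x, rate, 10))
  amp_out <- sqrt(power_at(sm2$samples, rate, 10))
  expect_lt(amp_out / amp_in, 0.10)

  expect_error(smooth_and_center(resp_trace(rnorm(100), rate)), "shorter")
})

test_that("z-scoring normalizes, is idempotent and affine-invariant", {
  set.seed(11)
  tr <- resp_trace(rnorm(5000, 5, 3), 500)
  z <- zscore(tr)
  expect_equal(mean(z$samples), 0, tolerance = 1e-12)
  expect_equal(sd(z$samples), 1, tolerance = 1e-12)
  expect_equal(zscore(z)$samples, z$samples, tolerance = 1e-10)
  aff <- resp_trace(2.5 * tr$samples - 7, 500)
  expect_equal(zscore(aff)$samples, z$samples, tolerance = 1e-10)
  expect_error(zscore(resp_trace(rep(1, 1000), 500)), "zero variance")
})

test_that("extrema detection finds sinusoid peaks/troughs and rejects ripples", {
  tr <- zscore(sin_trace(0.2, 30))
  ex <- detect_extrema(tr)
  expect_length(ex$peaks, 6)
  expect_length(ex$troughs, 6)
  # analytic peak times 1.25 + 5k s, troughs 3.75 + 5k s (+-1 sample)
  expect_equal((ex$peaks - 1) / 500, 1.25 + 5 * (0:5), tolerance = 2 / 500)
  expect_equal((ex$troughs - 1) / 500, 3.75 + 5 * (0:5), tolerance = 2 / 500)
  # alternation
  idx <- c(ex$peaks, ex$troughs)
  typ <- c(rep(1, length(ex$peaks)), rep(-1, length(ex$troughs)))
  expect_true(all(diff(typ[order(idx)]) != 0))

  # small ripples below the 0.5 SD prominence rule do not add extrema
  t <- seq(0, 30 - 1 / 500, by = 1 / 500)
  ripply <- zscore(resp_trace(sin(2 * pi * 0.2 * t) +
                              0.07 * sin(2 * pi * 1.3 * t), 500))
  ex2 <- detect_extrema(ripply)
  expect_length(ex2$peaks, 6)
  expect_length(ex2$troughs, 6)
})

test_that("detected breath count matches generator ground truth on drifting traces", {
  p <- breathing_profile(frequency_drift_sd = 0.01, noise_sd = 0.03,
                         amplitude_drift_sd = 0.01)
  g <- generate_respiration(p, duration = 120, seed = 31)
  z <- zscore(smooth_and_center(g$trace))
  ex <- detect_extrema(z)
  expect_lte(abs(length(ex$peaks) - g$truth$n_breaths), 1)
})

test_that("trial-level FFT frequency estimation is accurate and flags noise", {
  f <- as.numeric(estimate_frequency_trial(sin_trace(0.25, 40)))
  expect_equal(f, 0.25, tolerance = 0.01)

  # two-tone signal: dominant component wins (checked against projection oracle)
  t <- seq(0, 60 - 1 / 500, by = 1 / 500)
  x <- sin(2 * pi * 0.2 * t) + 0.3 * sin(2 * pi * 0.4 * t)
  expect_gt(power_at(x, 500, 0.2), power_at(x, 500, 0.4))
  f2 <- estimate_frequency_trial(resp_trace(x, 500))
  expect_equal(as.numeric(f2), 0.20, tolerance = 0.01)
  expect_false(attr(f2, "low_confidence"))

  set.seed(5)
  fn <- estimate_frequency_trial(resp_trace(rnorm(30 * 500), 500))
  expect_gte(as.numeric(fn), 0.05)
  expect_lte(as.numeric(fn), 1.0)
  expect_true(attr(fn, "low_confidence"))

  expect_error(estimate_frequency_trial(sin_trace(0.25, 5)), "too short")
})

test_that("parameter recovery across the physiological band", {
  for (f0 in c(0.1, 0.2, 0.3)) {
    est <- as.numeric(estimate_frequency_trial(sin_trace(f0, 60)))
    expect_equal(est, f0, tolerance = 0.01)
  }
})

test_that("sliding-window frequency gives one value per volume", {
  tr <- sin_trace(0.2, 120)
  fs <- estimate_frequency_sliding(tr, tr_s = 2)
  expect_length(fs$values, 60)
  expect_true(all(abs(fs$values - 0.2) <= 0.01))
  # stationary signal: sliding mean agrees with the trial estimate
  expect_equal(mean(fs$values), as.numeric(estimate_frequency_trial(tr)),
               tolerance = 0.01)

  # frequency step: estimates transition within one window of the step
  t1 <- seq(0, 60 - 1 / 500, by = 1 / 500)
  t2 <- seq(0, 60 - 1 / 500, by = 1 / 500)
  x <- c(sin(2 * pi * 0.15 * t1), sin(2 * pi * 0.30 * t2))
  fs2 <- estimate_frequency_sliding(resp_trace(x, 500), tr_s = 2)
  expect_true(all(abs(fs2$values[fs2$grid < 54] - 0.15) < 0.02))
  expect_true(all(abs(fs2$values[fs2$grid > 66] - 0.30) < 0.02))

  expect_error(estimate_frequency_sliding(tr, grid = numeric(0)), "empty")
})

test_that("RVT equals the analytic envelope difference", {
  # unit sinusoid z-scores to amplitude sqrt(2): constant envelope 2*sqrt(2)
  z <- zscore(sin_trace(0.2, 60))
  rvt <- compute_rvt(z, detect_extrema(z))
  interior <- 5000:25000
  expect_equal(mean(rvt$values[interior]), 2 * sqrt(2), tolerance = 0.02)
  expect_lt(sd(rvt$values[interior]), 0.1)

  # envelopes pass exactly through their extrema
  ex <- detect_extrema(z)
  expect_equal(rvt$upper[ex$peaks], z$samples[ex$peaks])
  expect_equal(rvt$lower[ex$troughs], z$samples[ex$troughs])

  # amplitude ramp 1 -> 2: midpoint RVT matches the z-scaled mid-amplitude
  rate <- 500; dur <- 120
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  a <- 1 + t / dur
  x <- a * sin(2 * pi * 0.2 * t)
  zr <- zscore(resp_trace(x, rate))
  rvtr <- compute_rvt(zr, detect_extrema(zr))
  mid <- round(length(t) / 2)
  expected_mid <- 2 * 1.5 / sd(x)
  expect_equal(mean(rvtr$values[(mid - 500):(mid + 500)]), expected_mid,
               tolerance = 0.05 * expected_mid)

  # non-negativity on a messy trace
  g <- generate_respiration(breathing_profile(noise_sd = 0.1), 90, seed = 8)
  zg <- zscore(smooth_and_center(g$trace))
  rg <- compute_rvt(zg, detect_extrema(zg))
  expect_true(all(rg$values >= -1e-9))

  expect_error(compute_rvt(z, detect_extrema(zscore(sin_trace(0.2, 60)),
                                             min_separation_s = 100)),
               "degenerate|at least 2")
})
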