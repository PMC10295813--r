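test_that("respiration generator honours phase arithmetic and determinism", {
  p <- quiet_profile(base = 0.25)
  g <- generate_respiration(p, duration = 40, rate = 500, seed = 1)
  expect_length(g$trace$samples, 20000)
  expect_equal(g$truth$n_breaths, 10)
  expect_length(g$truth$trough_times, 10)
  # exact phase: trace is sin starting at a trough
  t <- time_axis(g$trace)
  expect_equal(g$trace$samples, sin(2 * pi * 0.25 * t - pi / 2),
               tolerance = 1e-9)

  g2 <- generate_respiration(p, duration = 40, rate = 500, seed = 1)
  expect_identical(g$trace$samples, g2$trace$samples)
  g3 <- generate_respiration(breathing_profile(noise_sd = 0.1), 40, seed = 7)
  g4 <- generate_respiration(breathing_profile(noise_sd = 0.1), 40, seed = 8)
  expect_false(identical(g3$trace$samples, g4$trace$samples))

  expect_error(generate_respiration(p, duration = 5, rate = 500), "3 breath")
  expect_error(generate_respiration(p, duration = 60, rate = 10), ">= 50")
})

test_that("breath count conserves integrated instantaneous frequency", {
  p <- breathing_profile(frequency_drift_sd = 0.01, noise_sd = 0)
  g <- generate_respiration(p, duration = 150, seed = 21)
  integrated <- sum(g$truth$instantaneous_frequency) / g$trace$rate
  expect_lte(abs(g$truth$n_breaths - floor(integrated)), 1)
  expect_true(all(diff(g$truth$breath_starts) > 0))
  expect_true(all(g$truth$instantaneous_frequency > 0))
})

test_that("session generator builds a coherent five-condition run", {
  s <- generate_session(quiet_profile(), agent_profile(jitter_sd_ms = 0,
                                                       miss_rate = 0),
                        seed = 4, blocks_per_condition = 2,
                        circle_pauses = FALSE)
  expect_s3_class(s, "session_log")
  expect_equal(nrow(s$trials), 10)
  expect_equal(sort(unique(s$trials$condition)), sort(ieat_conditions()))

  # passive conditions never produce keypresses
  for (cond in c("PasExt", "PasInt")) {
    for (i in which(s$trials$condition == cond)) {
      tr <- s$trials[i, ]
      n_ev <- sum(s$events$time_s >= tr$onset_s &
                  s$events$time_s < tr$onset_s + tr$duration_s)
      expect_equal(n_ev, 0)
    }
  }

  # PasInt circle stationary; pulsing conditions share the estimated period
  expect_true(all(is.na(s$trials$circle_period_s[s$trials$condition %in%
                                                 c("PasInt", "ActInt")])))
  per <- s$trials$circle_period_s[s$trials$condition == "ActExt"]
  expect_true(all(per == s$circle_period_s))
  expect_equal(1 / s$circle_period_s, 0.21, tolerance = 0.02)

  # perfect agent: exactly one keypress per stimulus inflection, at the lag
  lag_s <- s$true_lag_ms / 1000
  i <- which(s$trials$condition == "ActExt")[1]
  tr <- s$trials[i, ]
  sched <- circle_inflections(tr$circle_period_s, tr$duration_s, pauses = FALSE)
  expected <- sched$time_s + tr$onset_s + lag_s
  expected <- expected[expected < tr$onset_s + tr$duration_s]
  got <- s$events$time_s[s$events$time_s >= tr$onset_s &
                         s$events$time_s < tr$onset_s + tr$duration_s]
  expect_equal(sort(got), sort(expected), tolerance = 1e-9)

  expect_error(
    generate_session(quiet_profile(), agent_profile(), seed = 1,
                     design = data.frame(condition = c(ieat_conditions(), "Bogus"),
                                         onset_s = (0:5) * 30,
                                         duration_s = 30)),
    "unknown condition")
})

test_that("cohort substreams are deterministic and carry group/time labels", {
  co <- generate_cohort(n_participants = 2, n_sessions = 1,
                        breathing = quiet_profile(),
                        agent = agent_profile(miss_rate = 0),
                        seed = 9, blocks_per_condition = 1,
                        block_duration_s = 20)
  expect_length(co, 2)
  expect_equal(unique(co[[1]]$trials$group), "MABT")
  expect_equal(unique(co[[2]]$trials$group), "CTL")
  co2 <- generate_cohort(n_participants = 2, n_sessions = 1,
                         breathing = quiet_profile(),
                         agent = agent_profile(miss_rate = 0),
                         seed = 9, blocks_per_condition = 1,
                         block_duration_s = 20)
  expect_identical(co[[2]]$trace$samples, co2[[2]]$trace$samples)
  expect_identical(co[[1]]$events, co2[[1]]$events)
})

test_that("block-level summary simulator produces the full factorial table", {
  d <- simulate_condition_summary(seed = 3)
  expect_equal(nrow(d), 22 * 2 * 5 * 4)
  expect_false(anyDuplicated(d[, c("participant", "session", "block",
                                   "condition")]) > 0)
  expect_equal(sort(unique(d$condition)), sort(ieat_conditions()))
  expect_equal(length(unique(d$participant)), 22)
  # injected interoceptive slowing is present in raw means
  agg <- tapply(d$frequency_hz, d$condition, mean)
  expect_lt(agg[["ActInt"]], agg[["ActExt"]])
})

test_that("session logs and physio traces round-trip through TSV", {
  s <- generate_session(quiet_profile(), agent_profile(), seed = 2,
                        blocks_per_condition = 1, block_duration_s = 15)
  dir <- withr::local_tempdir()
  write_session_log(s, dir)
  rt <- read_session_log(dir)
  expect_equal(rt$trials$condition, s$trials$condition)
  expect_equal(rt$events$time_s, s$events$time_s, tolerance = 1e-6)

  f <- file.path(dir, "physio.tsv")
  short <- resp_trace(s$trace$samples[1:5000], s$trace$rate)
  write_respiration_tsv(short, f)
  rt2 <- read_respiration_tsv(f)
  expect_equal(rt2$rate, 500, tolerance = 1e-6)
  expect_equal(rt2$samples, short$samples, tolerance = 1e-6)

  fb <- file.path(dir, "physio_bids.tsv")
  write_respiration_tsv(short, fb, bids = TRUE)
  rt3 <- read_respiration_tsv(fb, bids = TRUE)
  expect_equal(rt3$rate, 500)
  expect_equal(rt3$samples, short$samples, tolerance = 1e-6)
})
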