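test_that("EMMs equal raw condition means on balanced noiseless data", {
  d <- expand.grid(participant = sprintf("P%02d", 1:4), session = 1:2,
                   condition = ieat_conditions(), block = 1:2,
                   stringsAsFactors = FALSE)
  mu <- c(PasExt = 0.212, PasInt = 0.197, ActExt = 0.212, ActInt = 0.188,
          ActMatch = 0.209)
  d$frequency_hz <- mu[d$condition]
  d$group <- ifelse(d$participant %in% c("P01", "P02"), "MABT", "CTL")
  d$time <- d$session
  # tiny jitter so the fit is non-degenerate but means are preserved
  set.seed(1)
  d$frequency_hz <- d$frequency_hz + rnorm(nrow(d), 0, 1e-6)
  m <- suppressWarnings(suppressMessages(
    fit_condition_model(d, "frequency_hz")))
  e <- suppressWarnings(emm_and_tukey(m))
  raw <- tapply(d$frequency_hz, d$condition, mean)
  expect_equal(e$emmeans$mean, as.numeric(raw[e$emmeans$condition]),
               tolerance = 1e-5)
})

test_that("pairwise machinery: 10 contrasts, EMM consistency, Tukey monotone", {
  d <- simulate_condition_summary(n_participants = 10, seed = 5)
  m <- fit_condition_model(d, "frequency_hz")
  e <- emm_and_tukey(m)
  expect_equal(nrow(e$contrasts), choose(5, 2))
  # each contrast estimate is exactly the difference of its EMMs
  for (i in seq_len(nrow(e$contrasts))) {
    pair <- strsplit(e$contrasts$contrast[i], " - ")[[1]]
    diff_emm <- e$emmeans$mean[e$emmeans$condition == pair[1]] -
      e$emmeans$mean[e$emmeans$condition == pair[2]]
    expect_equal(e$contrasts$estimate[i], diff_emm, tolerance = 1e-8)
  }
  expect_true(all(e$contrasts$p_tukey >= e$contrasts$p_unadjusted - 1e-12))
  expect_true(all(e$emmeans$lower <= e$emmeans$mean &
                  e$emmeans$mean <= e$emmeans$upper))
})

test_that("injected condition effects are recovered with correct ordering", {
  d <- simulate_condition_summary(seed = 23)
  mf <- fit_condition_model(d, "frequency_hz")
  ef <- emm_and_tukey(mf)
  ctr <- ef$contrasts[ef$contrasts$contrast == "ActExt - ActInt", ]
  expect_gt(ctr$estimate, 0)
  expect_true(ctr$lower <= 0.024 && 0.024 <= ctr$upper)

  mr <- fit_condition_model(d, "rvt_au")
  er <- emm_and_tukey(mr)
  emm_r <- er$emmeans$mean
  names(emm_r) <- er$emmeans$condition
  # depth ordering: exteroception ~ shallowest ... active interoception deepest
  expect_lt(max(emm_r[c("ActExt", "PasExt")]), emm_r[["PasInt"]])
  expect_lt(emm_r[["PasInt"]], emm_r[["ActMatch"]])
  expect_lt(emm_r[["ActMatch"]], emm_r[["ActInt"]])
})

test_that("model fitting validates its inputs", {
  d <- simulate_condition_summary(n_participants = 4, seed = 2)
  expect_error(fit_condition_model(d[d$participant == "P01", ], "frequency_hz"),
               "2 participants")
  d1 <- d[d$condition == "ActInt", ]
  expect_error(fit_condition_model(d1, "frequency_hz"), "condition")
  d2 <- d; d2$frequency_hz <- 1
  expect_error(fit_condition_model(d2, "frequency_hz"), "constant")
})

test_that("within-participant correlation behaves at its analytic anchors", {
  # exact construction: rvt = -frequency + participant offset
  d <- simulate_condition_summary(n_participants = 8, coupling_r = 0, seed = 7)
  set.seed(7)
  off <- rnorm(8)
  names(off) <- sprintf("P%02d", 1:8)
  d$rvt_au <- -d$frequency_hz + off[d$participant]
  r1 <- within_participant_correlation(d)
  expect_equal(r1$r, -1, tolerance = 1e-10)

  # independence: near-zero at 880 paired observations
  d0 <- simulate_condition_summary(coupling_r = 0, seed = 19)
  flat <- c(PasExt = 0.21, PasInt = 0.21, ActExt = 0.21, ActInt = 0.21,
            ActMatch = 0.21)
  d0f <- simulate_condition_summary(coupling_r = 0, seed = 19,
                                    freq_means = flat,
                                    rvt_means = flat * 0 + 2.8)
  r0 <- within_participant_correlation(d0f)
  expect_lt(abs(r0$r), 0.1)
  expect_equal(r0$df, 880 - 2)

  # tuned coupling recovered at cohort scale (flat condition means)
  dc <- simulate_condition_summary(n_participants = 22, n_sessions = 2,
                                   blocks_per_condition = 4,
                                   coupling_r = -0.45, seed = 29,
                                   freq_means = flat,
                                   rvt_means = flat * 0 + 2.8)
  rc <- within_participant_correlation(dc)
  expect_equal(rc$r, -0.45, tolerance = 0.06)
  expect_true(rc$ci[1] < rc$r && rc$r < rc$ci[2])

  # repeated-measures df variant
  rrm <- within_participant_correlation(dc, method = "rm")
  expect_equal(rrm$df, 880 - 22 - 1)
  expect_equal(rrm$r, rc$r)
})

test_that("condition Wald F detects injected effects and not their absence", {
  d <- simulate_condition_summary(seed = 41)
  m <- fit_condition_model(d, "frequency_hz")
  a <- condition_anova(m)
  expect_equal(a$df1, 4)
  expect_lt(a$p, 0.01)

  # null world: p-values should look uniform, so their median sits well
  # above small values
  flat <- c(PasExt = 0.21, PasInt = 0.21, ActExt = 0.21, ActInt = 0.21,
            ActMatch = 0.21)
  p0 <- vapply(1:15, function(s) {
    d0 <- simulate_condition_summary(n_participants = 12, seed = 400 + s,
                                     freq_means = flat)
    condition_anova(fit_condition_model(d0, "frequency_hz"))$p
  }, numeric(1))
  expect_gt(median(p0), 0.15)
})
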