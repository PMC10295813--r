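#' The five task conditions
#'
#' Condition labels for the interoceptive/exteroceptive attention paradigm:
#' passive viewing of a pulsing circle (PasExt), passive attention to the
#' breath with a stationary circle (PasInt), button-press tracking of the
#' circle (ActExt) or of the breath (ActInt), and paced breathing matched to
#' the circle (ActMatch).
#'
#' @export
ieat_conditions <- function()
  c("PasExt", "PasInt", "ActExt", "ActInt", "ActMatch")

.active_conditions <- c("ActExt", "ActInt", "ActMatch")

#' Breathing profile for the synthetic-belt generator
#'
#' Describes a participant's breathing as a quasi-periodic oscillation:
#' a base frequency near the adult resting rate of ~0.21 Hz, a per-breath
#' random walk on frequency and amplitude, additive white measurement noise,
#' and condition-dependent shifts in rate and depth. The default offsets
#' encode the qualitative pattern seen in interoceptive-attention tasks:
#' breathing slows by roughly 0.02 Hz and deepens during active
#' interoception, deepens moderately during paced matching, and is
#' essentially unchanged when attending the visual circle.
#'
#' @param base_frequency Base breathing rate in Hz, in (0.05, 1).
#' @param frequency_drift_sd SD of the per-breath random-walk innovation on
#'   frequency (Hz).
#' @param amplitude Base belt amplitude (arbitrary units).
#' @param amplitude_drift_sd SD of the per-breath amplitude random walk (a.u.).
#' @param noise_sd SD of additive white measurement noise (a.u.).
#' @param condition_frequency_offsets Named numeric vector, Hz added to the
#'   base frequency per condition.
#' @param condition_amplitude_offsets Named numeric vector, a.u. added to
#'   the base amplitude per condition.
#' @param couple_amplitude If TRUE, amplitude is scaled by
#'   `(base_frequency / f)^coupling_exponent`, emulating the negative
#'   within-participant frequency-depth trade-off (off by default).
#' @param coupling_exponent Exponent of the frequency-amplitude coupling.
#' @return An object of class `breathing_profile`.
#' @export
breathing_profile <- function(base_frequency = 0.21,
                              frequency_drift_sd = 0.005,
                              amplitude = 1,
                              amplitude_drift_sd = 0.02,
                              noise_sd = 0.05,
                              condition_frequency_offsets = c(
                                PasExt = 0.002, PasInt = -0.013,
                                ActExt = 0.002, ActInt = -0.022,
                                ActMatch = -0.001),
                              condition_amplitude_offsets = c(
                                PasExt = -0.12, PasInt = -0.05,
                                ActExt = -0.15, ActInt = 0.20,
                                ActMatch = 0.10),
                              couple_amplitude = FALSE,
                              coupling_exponent = 1) {
  if (base_frequency <= 0.05 || base_frequency >= 1.0)
    stop("`base_frequency` must lie in (0.05, 1) Hz", call. = FALSE)
  if (noise_sd < 0 || frequency_drift_sd < 0 || amplitude_drift_sd < 0)
    stop("noise and drift SDs must be non-negative", call. = FALSE)
  if (any(base_frequency + condition_frequency_offsets <= 0))
    stop("condition offsets drive frequency non-positive", call. = FALSE)
  structure(list(base_frequency = base_frequency,
                 frequency_drift_sd = frequency_drift_sd,
                 amplitude = amplitude,
                 amplitude_drift_sd = amplitude_drift_sd,
                 noise_sd = noise_sd,
                 condition_frequency_offsets = condition_frequency_offsets,
                 condition_amplitude_offsets = condition_amplitude_offsets,
                 couple_amplitude = couple_amplitude,
                 coupling_exponent = coupling_exponent),
            class = "breathing_profile")
}

#' Behavioral agent profile
#'
#' Generative stand-in for a tracking participant: keypresses follow the
#' stimulus inflection points with a constant sensorimotor transduction lag,
#' Gaussian timing jitter, and occasional misses.
#'
#' @param transduction_lag_ms Constant keypress lag in ms.
#' @param jitter_sd_ms SD of Gaussian timing jitter in ms (>= 0).
#' @param miss_rate Probability of missing an inflection, in [0, 1).
#' @return An object of class `agent_profile`.
#' @export
agent_profile <- function(transduction_lag_ms = 240, jitter_sd_ms = 60,
                          miss_rate = 0.05) {
  if (miss_rate < 0 || miss_rate >= 1)
    stop("`miss_rate` must be in [0, 1)", call. = FALSE)
  if (jitter_sd_ms < 0) stop("`jitter_sd_ms` must be >= 0", call. = FALSE)
  structure(list(transduction_lag_ms = transduction_lag_ms,
                 jitter_sd_ms = jitter_sd_ms, miss_rate = miss_rate),
            class = "agent_profile")
}

#' Generate a synthetic respiration-belt trace with ground truth
#'
#' Simulates belt amplitude as `a(t) * sin(phase(t)) + noise`, where the
#' phase integrates a piecewise-constant instantaneous frequency that
#' performs a random walk from breath to breath (plus any condition offset
#' active at the breath's onset), and the envelope amplitude performs its
#' own per-breath random walk. Each breath starts at a trough (inhalation
#' onset). The returned ground truth records the exact generating process,
#' so downstream estimators can be validated sample for sample.
#'
#' @param profile A [breathing_profile()].
#' @param duration Trace duration in seconds (> 3 breath periods).
#' @param rate Sampling rate in Hz (>= 50; default 500).
#' @param seed Optional integer seed (same seed, bit-identical trace).
#' @param condition_timeline Optional data frame (`condition`, `onset_s`,
#'   `duration_s`): condition offsets are applied to breaths starting inside
#'   each block.
#' @param frequency_override Optional named vector of absolute frequencies
#'   (Hz) that replace the drifting frequency for breaths starting inside
#'   blocks of the named conditions (used for paced breathing).
#' @param reset_onsets Optional times (s) at which a breath boundary
#'   (trough) is forced: the breath straddling each onset is stretched or
#'   compressed to end exactly there, emulating a participant synchronizing
#'   their inhalation onset to a pacing stimulus.
#' @return List with `trace` (a [resp_trace()]) and `truth` (class
#'   `ground_truth`): `trough_times`, `peak_times`, `breath_starts`,
#'   `breath_frequencies`, `instantaneous_frequency` and `envelope_amplitude`
#'   per sample, and `n_breaths` completed within the trace.
#' @export
generate_respiration <- function(profile, duration, rate = 500, seed = NULL,
                                 condition_timeline = NULL,
                                 frequency_override = NULL,
                                 reset_onsets = NULL) {
  stopifnot(inherits(profile, "breathing_profile"))
  if (!is.numeric(duration) || duration <= 0 || !is.numeric(rate) || rate <= 0)
    stop("duration and rate must be positive", call. = FALSE)
  if (duration <= 3 / profile$base_frequency)
    stop("duration must exceed 3 breath periods", call. = FALSE)
  if (rate < 50) stop("rate must be >= 50 Hz", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  cond_at <- function(t) {
    if (is.null(condition_timeline)) return(NA_character_)
    i <- which(t >= condition_timeline$onset_s &
               t < condition_timeline$onset_s + condition_timeline$duration_s)
    if (length(i) == 0L) NA_character_ else condition_timeline$condition[i[1]]
  }

  f_floor <- 0.05
  starts <- numeric(0); freqs <- numeric(0); amps <- numeric(0)
  durs <- numeric(0)
  rw_f <- 0; rw_a <- 0; t_cur <- 0; clipped <- FALSE
  while (t_cur < duration) {
    cond <- cond_at(t_cur)
    f <- profile$base_frequency + rw_f
    if (!is.na(cond) &&
        cond %in% names(profile$condition_frequency_offsets))
      f <- f + profile$condition_frequency_offsets[[cond]]
    if (!is.na(cond) && !is.null(frequency_override) &&
        cond %in% names(frequency_override))
      f <- frequency_override[[cond]]
    if (f <= f_floor) { f <- f_floor; clipped <- TRUE }
    a <- profile$amplitude + rw_a
    if (!is.na(cond) &&
        cond %in% names(profile$condition_amplitude_offsets))
      a <- a + profile$condition_amplitude_offsets[[cond]]
    a <- max(a, 0.05 * profile$amplitude)
    if (profile$couple_amplitude)
      a <- a * (profile$base_frequency / f)^profile$coupling_exponent
    # force a trough onto the next pacing-reset onset if this breath would
    # straddle it (stretch/compress the straddling breath)
    d_breath <- 1 / f
    if (!is.null(reset_onsets)) {
      nxt <- reset_onsets[reset_onsets > t_cur + 1e-9]
      if (length(nxt) > 0L && min(nxt) - t_cur <= 1.5 * d_breath) {
        d_breath <- min(nxt) - t_cur
        f <- 1 / d_breath
      }
    }
    starts <- c(starts, t_cur); freqs <- c(freqs, f); amps <- c(amps, a)
    durs <- c(durs, d_breath)
    t_cur <- t_cur + d_breath
    rw_f <- rw_f + stats::rnorm(1, 0, profile$frequency_drift_sd)
    rw_a <- rw_a + stats::rnorm(1, 0, profile$amplitude_drift_sd)
  }
  if (clipped)
    warning("drift drove instantaneous frequency to the 0.05 Hz floor; clipped")

  n <- as.integer(round(duration * rate))
  t <- (seq_len(n) - 1L) / rate
  bi <- findInterval(t, starts)
  inst_f <- freqs[bi]
  # depth varies smoothly: envelope interpolated across breath midpoints
  # (a hard per-breath amplitude step would shift signal extrema away from
  # the phase extrema once smoothed)
  env_a <- if (length(amps) > 1L)
    stats::approx(starts + durs / 2, amps, xout = t, rule = 2)$y
  else rep(amps, length(t))
  phase <- -pi / 2 + 2 * pi * ((bi - 1L) + (t - starts[bi]) * inst_f)
  x <- env_a * sin(phase)
  if (profile$noise_sd > 0) x <- x + stats::rnorm(n, 0, profile$noise_sd)

  trough_times <- starts[starts < duration]
  peak_times <- starts + 0.5 / freqs
  peak_times <- peak_times[peak_times < duration]
  ends <- starts + 1 / freqs
  truth <- structure(
    list(trough_times = trough_times, peak_times = peak_times,
         breath_starts = starts, breath_frequencies = freqs,
         breath_amplitudes = amps,
         instantaneous_frequency = inst_f, envelope_amplitude = env_a,
         n_breaths = sum(ends <= duration + 1e-9)),
    class = "ground_truth")
  list(trace = resp_trace(x, rate, run_id = "synthetic"), truth = truth)
}

#' Generate a full synthetic task session
#'
#' Builds one scanner run of the five-condition paradigm: a block design
#' (by default 4 blocks per condition, 30 s each, in seeded random order), a
#' respiration trace whose rate and depth shift with the condition of each
#' block, a pacing-circle period matched to the participant's calibration
#' breathing frequency (as done when the circle is set from a belt recording
#' taken during the structural scan), and keypress events for the active
#' conditions. In ActInt, keypresses anchor to the true breath inflections;
#' in ActExt and ActMatch, to the circle's expansion/contraction onsets;
#' button 1 marks inhalation/expansion onset, button 2 exhalation/
#' contraction onset. During ActMatch blocks breathing is paced: its period
#' locks to the circle's full cycle. Passive blocks have no keypresses, and
#' the PasInt circle is stationary (`circle_period_s = NA`).
#'
#' @param breathing A [breathing_profile()].
#' @param agent An [agent_profile()].
#' @param seed Integer seed for the session.
#' @param design Optional trial table (`condition`, `onset_s`, `duration_s`);
#'   built from `blocks_per_condition` and `block_duration_s` if omitted.
#' @param blocks_per_condition Blocks per condition (default 4).
#' @param block_duration_s Block length in seconds (> 10; default 30).
#' @param inter_block_gap_s Fixation gap between blocks in seconds (default
#'   5); keeps lagged keypresses from one block from spilling into the next.
#' @param rate Sampling rate in Hz (default 500).
#' @param circle_pauses Circle cycle includes the 0.2 x half-period holds
#'   (default TRUE; cycle length 1.2 x period).
#' @param participant,session Labels stored in the trial table.
#' @return An object of class `session_log`: list with `trials`, `events`,
#'   `trace`, `truth`, `circle_period_s`.
#' @export
generate_session <- function(breathing, agent, seed = 1L, design = NULL,
                             blocks_per_condition = 4, block_duration_s = 30,
                             inter_block_gap_s = 5, rate = 500,
                             circle_pauses = TRUE,
                             participant = "P01", session = 1L) {
  stopifnot(inherits(breathing, "breathing_profile"),
            inherits(agent, "agent_profile"))
  set.seed(seed)

  if (is.null(design)) {
    if (block_duration_s <= 10)
      stop("block_duration_s must exceed 10 s", call. = FALSE)
    conds <- sample(rep(ieat_conditions(), blocks_per_condition))
    design <- data.frame(
      condition = conds,
      onset_s = (seq_along(conds) - 1L) * (block_duration_s + inter_block_gap_s),
      duration_s = block_duration_s)
  }
  if (!all(design$condition %in% ieat_conditions()))
    stop("unknown condition label: ",
         paste(setdiff(unique(design$condition), ieat_conditions()),
               collapse = ", "), call. = FALSE)
  if (!all(ieat_conditions() %in% design$condition))
    stop("design must cover all five conditions", call. = FALSE)

  # calibration recording (no condition offsets) sets the circle period
  cal <- generate_respiration(breathing, duration = 60, rate = rate)
  f_cal <- as.numeric(estimate_frequency_trial(smooth_and_center(cal$trace)))
  period <- 1 / f_cal
  cycle_len <- if (circle_pauses) 1.2 * period else period

  run_dur <- max(design$onset_s + design$duration_s) + inter_block_gap_s
  gen <- generate_respiration(
    breathing, duration = run_dur, rate = rate,
    condition_timeline = design,
    frequency_override = c(ActMatch = 1 / cycle_len),
    reset_onsets = design$onset_s[design$condition == "ActMatch"])

  trials <- data.frame(participant = participant, session = session,
                       block = seq_len(nrow(design)),
                       condition = design$condition,
                       onset_s = design$onset_s,
                       duration_s = design$duration_s,
                       circle_period_s = ifelse(
                         design$condition %in% c("PasExt", "ActExt", "ActMatch"),
                         period, NA_real_))

  events <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (!tr$condition %in% .active_conditions) next
    if (tr$condition == "ActInt") {
      anchors <- data.frame(
        time_s = c(gen$truth$trough_times, gen$truth$peak_times),
        button = c(rep(1L, length(gen$truth$trough_times)),
                   rep(2L, length(gen$truth$peak_times))))
      anchors <- anchors[anchors$time_s >= tr$onset_s &
                         anchors$time_s < tr$onset_s + tr$duration_s, ]
    } else {
      sched <- circle_inflections(period, tr$duration_s, pauses = circle_pauses)
      anchors <- data.frame(time_s = sched$time_s + tr$onset_s,
                            button = sched$button)
    }
    if (nrow(anchors) == 0L) next
    keep <- stats::runif(nrow(anchors)) >= agent$miss_rate
    anchors <- anchors[keep, , drop = FALSE]
    anchors$time_s <- anchors$time_s + agent$transduction_lag_ms / 1000 +
      stats::rnorm(nrow(anchors), 0, agent$jitter_sd_ms / 1000)
    anchors <- anchors[anchors$time_s >= tr$onset_s &
                       anchors$time_s < tr$onset_s + tr$duration_s, ,
                       drop = FALSE]
    anchors$block <- tr$block
    events[[length(events) + 1L]] <- anchors
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(time_s = numeric(), button = integer(), block = integer())
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL

  structure(list(trials = trials, events = events, trace = gen$trace,
                 truth = gen$truth, circle_period_s = period,
                 true_lag_ms = agent$transduction_lag_ms),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %d blocks (%s), %d keypresses, %.0f s run\n",
              nrow(x$trials),
              paste(sort(unique(x$trials$condition)), collapse = "/"),
              nrow(x$events), duration(x$trace)))
  invisible(x)
}

#' Summarize a session into per-block physiological/behavioral outcomes
#'
#' Runs the full estimation pipeline on one session: smooths and z-scores
#' the belt trace, detects extrema (RVT preset) and builds the RVT envelope,
#' then for every block computes the trial-level FFT breathing frequency,
#' the block-mean RVT, and (for active blocks, if `tracking = TRUE`) the
#' mean tracking error across applicable targets.
#'
#' @param session A `session_log`.
#' @param tracking Also score tracking accuracy (default TRUE).
#' @return Data frame with one row per block: `participant`, `session`,
#'   `block`, `condition`, `frequency_hz`, `rvt_au`, `tracking_error_ms`.
#' @export
summarize_session <- function(session, tracking = TRUE) {
  stopifnot(inherits(session, "session_log"))
  sm <- smooth_and_center(session$trace)
  z <- zscore(sm)
  ex <- detect_extrema(z)
  rvt <- compute_rvt(z, ex)
  rate <- z$rate
  trials <- session$trials

  track <- NULL
  if (tracking && any(trials$condition %in% .active_conditions))
    track <- score_session(session, session$trace)

  rows <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    i0 <- as.integer(round(tr$onset_s * rate)) + 1L
    i1 <- min(i0 + as.integer(round(tr$duration_s * rate)) - 1L,
              length(z$samples))
    seg <- resp_trace(sm$samples[i0:i1], rate)
    f <- as.numeric(estimate_frequency_trial(seg))
    r <- mean(rvt$values[i0:i1])
    terr <- NA_real_
    if (!is.null(track)) {
      tri <- track[track$condition == tr$condition &
                   track$trial_id == paste0(tr$condition, "_b", tr$block) &
                   track$scorable, , drop = FALSE]
      if (nrow(tri) > 0L) terr <- mean(tri$mean_abs_error_ms)
    }
    data.frame(participant = tr$participant, session = tr$session,
               block = tr$block, condition = tr$condition,
               frequency_hz = f, rvt_au = r, tracking_error_ms = terr)
  })
  do.call(rbind, rows)
}

#' Generate a cohort of synthetic sessions
#'
#' Generates `n_participants x n_sessions` sessions with deterministic
#' per-session substream seeds derived from one master seed, so any subset
#' of the cohort is reproducible in isolation. Participants in the first
#' half of the roster are labelled group "MABT", the rest "CTL"; session
#' number doubles as the time factor (1 = baseline, 2 = post).
#'
#' @param n_participants,n_sessions Cohort dimensions (defaults 22 and 2).
#' @param breathing,agent Profiles passed to [generate_session()].
#' @param seed Master seed.
#' @param ... Further arguments to [generate_session()].
#' @return List of `session_log` objects with `participant`, `session`,
#'   `group`, `time` fields attached to each trial table.
#' @export
generate_cohort <- function(n_participants = 22, n_sessions = 2,
                            breathing = breathing_profile(),
                            agent = agent_profile(), seed = 1L, ...) {
  out <- list()
  for (p in seq_len(n_participants)) {
    for (s in seq_len(n_sessions)) {
      sub_seed <- (as.integer(seed) + 7919L * p + 104729L * s) %% 2147483647L
      ses <- generate_session(breathing, agent, seed = sub_seed,
                              participant = sprintf("P%02d", p),
                              session = s, ...)
      ses$trials$group <- if (p <= n_participants / 2) "MABT" else "CTL"
      ses$trials$time <- s
      out[[length(out) + 1L]] <- ses
    }
  }
  out
}

#' Directly simulate a block-level condition summary table
#'
#' Draws the per-block outcomes (breathing frequency, RVT) of a full cohort
#' at the summary level, bypassing signal generation: each block outcome is
#' condition mean + participant random intercept + residual noise, with an
#' optional within-participant correlation between the frequency and RVT
#' residuals (negative by default, emulating the rate/depth trade-off).
#' Default condition means and noise scales restate the generator's world:
#' frequencies centred on 0.21 Hz with interoception ~0.02 Hz slower, RVT
#' deepest for active interoception, residual SDs chosen so a 22 x 2 x 5 x 4
#' design yields contrast standard errors near 0.005 Hz and 0.057 z-units.
#'
#' @param n_participants,n_sessions,blocks_per_condition Design dimensions
#'   (defaults 22, 2, 4: 880 condition-block rows).
#' @param freq_means Named per-condition mean frequencies (Hz).
#' @param rvt_means Named per-condition mean RVT (z-units).
#' @param sd_participant_freq,sd_resid_freq Participant-intercept and
#'   residual SDs for frequency (Hz).
#' @param sd_participant_rvt,sd_resid_rvt Same for RVT (z-units).
#' @param coupling_r Correlation between frequency and RVT residuals
#'   (default -0.45; 0 for independence).
#' @param seed Integer seed.
#' @return Data frame with columns `participant`, `session`, `block`,
#'   `condition`, `group`, `time`, `frequency_hz`, `rvt_au`.
#' @export
simulate_condition_summary <- function(n_participants = 22, n_sessions = 2,
                                       blocks_per_condition = 4,
                                       freq_means = c(
                                         PasExt = 0.212, PasInt = 0.197,
                                         ActExt = 0.212, ActInt = 0.188,
                                         ActMatch = 0.209),
                                       rvt_means = c(
                                         PasExt = 2.51, PasInt = 2.72,
                                         ActExt = 2.43, ActInt = 3.42,
                                         ActMatch = 3.15),
                                       sd_participant_freq = 0.05,
                                       sd_resid_freq = 0.048,
                                       sd_participant_rvt = 0.25,
                                       sd_resid_rvt = 0.54,
                                       coupling_r = -0.45,
                                       seed = 1L) {
  stopifnot(all(sort(names(freq_means)) == sort(ieat_conditions())),
            all(sort(names(rvt_means)) == sort(ieat_conditions())),
            abs(coupling_r) <= 1)
  set.seed(seed)
  d <- expand.grid(block = seq_len(blocks_per_condition),
                   condition = ieat_conditions(),
                   session = seq_len(n_sessions),
                   participant = sprintf("P%02d", seq_len(n_participants)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("participant", "session", "block", "condition")]
  p_idx <- match(d$participant, sprintf("P%02d", seq_len(n_participants)))
  d$group <- ifelse(p_idx <= n_participants / 2, "MABT", "CTL")
  d$time <- d$session
  b_f <- stats::rnorm(n_participants, 0, sd_participant_freq)
  b_r <- stats::rnorm(n_participants, 0, sd_participant_rvt)
  n <- nrow(d)
  e_f <- stats::rnorm(n, 0, sd_resid_freq)
  e_r <- coupling_r * (e_f / sd_resid_freq) * sd_resid_rvt +
    sqrt(1 - coupling_r^2) * stats::rnorm(n, 0, sd_resid_rvt)
  d$frequency_hz <- freq_means[d$condition] + b_f[p_idx] + e_f
  d$rvt_au <- rvt_means[d$condition] + b_r[p_idx] + e_r
  rownames(d) <- NULL
  d
}
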