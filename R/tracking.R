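#' Phase-align two waveforms by normalized cross-correlation
#'
#' Finds the integer-sample lag (within `max_lag_samples`, i.e. up to one
#' second at 500 Hz by default) that maximizes the Pearson correlation
#' between the overlapping segments of a stimulus waveform and a keypress
#' waveform. A positive lag means the keypress signal trails the stimulus,
#' as expected from perceptual and motor transduction delays; shifting the
#' stimulus forward by the lag compensates for them. Ties are broken toward
#' the smallest absolute lag. Correlations are normalized per lag (the
#' overlap is re-standardized at every candidate shift).
#'
#' If the keypress waveform carries an `anchor_range` (the span between its
#' first and last press, as set by [keypress_to_waveform()]), only samples
#' inside that span enter the correlation: the clamped extrapolation beyond
#' the anchors contains no behavior and would otherwise bias the lag
#' estimate by tens of milliseconds.
#'
#' @param stimulus,keypress Equal-length `waveform` objects (or numeric
#'   vectors) at the same rate.
#' @param max_lag_samples Maximum |lag| searched, in samples (default 500).
#' @return An object of class `phase_alignment`: list with `lag_samples`,
#'   `lag_s`, `lag_ms`, `ncc_max`, `n_overlap`, `rate`.
#' @export
phase_align <- function(stimulus, keypress, max_lag_samples = 500) {
  rate <- NA_real_
  if (inherits(stimulus, "waveform") || inherits(stimulus, "resp_trace"))
    rate <- stimulus$rate
  if (inherits(keypress, "waveform") || inherits(keypress, "resp_trace")) {
    if (!is.na(rate) && !isTRUE(all.equal(rate, keypress$rate)))
      stop("waveforms must share a sampling rate", call. = FALSE)
    rate <- keypress$rate
  }
  s <- .wf_values(stimulus)
  k <- .wf_values(keypress)
  if (length(s) != length(k))
    stop("waveforms must have equal length", call. = FALSE)
  n <- length(s)
  if (n <= 2L * max_lag_samples)
    stop("waveforms too short for the requested lag range", call. = FALSE)
  if (stats::sd(s) == 0 || stats::sd(k) == 0)
    stop("degenerate signal: zero-variance waveform cannot be phase-aligned",
         call. = FALSE)

  span <- if (inherits(keypress, "waveform") &&
              !is.null(keypress$anchor_range))
    seq.int(keypress$anchor_range[1], keypress$anchor_range[2])
  else seq_len(n)

  lags <- seq.int(-max_lag_samples, max_lag_samples)
  lags <- lags[order(abs(lags), lags)]   # visit small |lag| first: tie-break
  best_lag <- 0L; best_r <- -Inf
  for (lag in lags) {
    src <- span - lag
    ok <- src >= 1L & src <= n
    if (sum(ok) < 3L) next
    r <- suppressWarnings(stats::cor(s[src[ok]], k[span[ok]]))
    if (is.finite(r) && r > best_r + 1e-12) {
      best_r <- r; best_lag <- lag
    }
  }
  structure(list(lag_samples = as.integer(best_lag),
                 lag_s = if (is.na(rate)) NA_real_ else best_lag / rate,
                 lag_ms = if (is.na(rate)) NA_real_ else 1000 * best_lag / rate,
                 ncc_max = best_r,
                 n_overlap = n - abs(best_lag),
                 rate = rate),
            class = "phase_alignment")
}

.wf_values <- function(x) {
  if (inherits(x, "waveform")) x$values
  else if (inherits(x, "resp_trace")) x$samples
  else as.numeric(x)
}

#' @export
print.phase_alignment <- function(x, ...) {
  cat(sprintf("<phase_alignment> lag %d samples (%.0f ms), NCC %.3f\n",
              x$lag_samples, x$lag_ms, x$ncc_max))
  invisible(x)
}

#' Mean absolute tracking error
#'
#' For each stimulus inflection point (peak/trough or expansion/contraction
#' onset, already phase-corrected), finds the temporal distance to the
#' nearest keypress of any button and returns the mean absolute deviation in
#' milliseconds -- the per-trial tracking-accuracy statistic (lower is more
#' accurate). Inflections with no nearby keypress still contribute their
#' distance to the nearest available keypress; there is no cap.
#'
#' @param inflections Numeric vector of inflection times (s), sorted.
#' @param keypresses Numeric vector of keypress times (s), sorted.
#' @return Mean absolute deviation in ms, or `NA` (with a warning) if either
#'   input is empty -- an unscorable trial, distinct from zero error.
#' @export
tracking_error <- function(inflections, keypresses) {
  if (length(keypresses) == 0L || length(inflections) == 0L) {
    warning("no keypresses or no inflections: trial is unscorable")
    return(NA_real_)
  }
  keypresses <- sort(keypresses)
  j <- findInterval(inflections, keypresses)
  lo <- pmax(j, 1L); hi <- pmin(j + 1L, length(keypresses))
  d <- pmin(abs(inflections - keypresses[lo]),
            abs(inflections - keypresses[hi]))
  1000 * mean(d)
}

#' Score tracking accuracy for every active trial of a session
#'
#' For each trial of the three active conditions, reconstructs the keypress
#' waveform and the appropriate stimulus waveform (the z-scored respiration
#' segment for Active Interoception, the circle-radius schedule for Active
#' Exteroception; Active Matching is scored against both targets),
#' phase-corrects the stimulus by normalized cross-correlation, and computes
#' the mean absolute deviation from stimulus inflection points to the
#' nearest keypress. Respiration inflections come from the trial segment's
#' extrema using the behavior-tracking detector preset (no prominence
#' threshold, 1 s minimum separation); circle inflections come from the
#' analytic schedule.
#'
#' @param session A `session_log` (see [generate_session()]) or a list with
#'   data frames `trials` (participant, session, block, condition, onset_s,
#'   duration_s, circle_period_s) and `events` (time_s, button).
#' @param trace The run's [resp_trace()] (raw; smoothed and z-scored
#'   internally).
#' @param max_lag_samples NCC search range in samples (default 500).
#' @param circle_pauses Does the circle cycle include holds (default TRUE).
#' @return A data frame with one row per active trial per applicable target:
#'   `trial_id`, `condition`, `target`, `lag_samples`, `lag_ms`, `ncc_max`,
#'   `mean_abs_error_ms`, `n_inflections`, `n_keypresses`, `scorable`.
#' @export
score_session <- function(session, trace, max_lag_samples = 500,
                          circle_pauses = TRUE) {
  trials <- session$trials
  events <- session$events
  stopifnot(is.data.frame(trials), is.data.frame(events))
  active <- trials[trials$condition %in% c("ActInt", "ActExt", "ActMatch"), ,
                   drop = FALSE]
  if (nrow(active) == 0L)
    stop("session contains no active trials", call. = FALSE)

  z <- zscore(smooth_and_center(trace))
  rate <- trace$rate
  rows <- list()
  for (i in seq_len(nrow(active))) {
    tr <- active[i, ]
    targets <- switch(tr$condition,
                      ActInt = "breath", ActExt = "circle",
                      ActMatch = c("breath", "circle"))
    on <- tr$onset_s; dur <- tr$duration_s
    ev <- events[events$time_s >= on & events$time_s < on + dur, , drop = FALSE]
    ev$time_s <- ev$time_s - on
    kp_wf <- if (nrow(ev) > 0L)
      suppressWarnings(keypress_to_waveform(ev[order(ev$time_s), ], dur, rate))
    else NULL

    i0 <- as.integer(round(on * rate)) + 1L
    n <- as.integer(round(dur * rate))
    seg <- resp_trace(z$samples[i0:min(i0 + n - 1L, length(z$samples))],
                      rate, t0 = 0)

    for (target in targets) {
      if (target == "breath") {
        stim_vals <- seg$samples
        ex <- suppressWarnings(
          detect_extrema(seg, prominence_sd = 0, min_separation_s = 1))
        infl <- extrema_times(ex)
      } else {
        if (is.na(tr$circle_period_s)) {
          rows[[length(rows) + 1L]] <- .score_row(tr, target, NA, NA, NA, NA, 0L,
                                                  nrow(ev), FALSE)
          next
        }
        stim_vals <- circle_waveform(tr$circle_period_s, dur, rate,
                                     pauses = circle_pauses)$values
        sched <- circle_inflections(tr$circle_period_s, dur,
                                    pauses = circle_pauses)
        infl <- sched$time_s
      }
      scorable <- nrow(ev) > 0L && length(infl) >= 1L &&
        stats::sd(stim_vals) > 0
      if (!scorable) {
        rows[[length(rows) + 1L]] <- .score_row(tr, target, NA, NA, NA, NA,
                                                length(infl), nrow(ev), FALSE)
        next
      }
      al <- phase_align(.waveform(stim_vals, rate, target),
                        kp_wf, max_lag_samples = max_lag_samples)
      shifted <- infl + al$lag_s
      shifted <- shifted[shifted >= 0 & shifted <= dur]
      err <- if (length(shifted) >= 1L)
        tracking_error(shifted, ev$time_s) else NA_real_
      rows[[length(rows) + 1L]] <- .score_row(tr, target, al$lag_samples,
                                              al$lag_ms, al$ncc_max, err,
                                              length(shifted), nrow(ev),
                                              is.finite(err))
    }
  }
  do.call(rbind, rows)
}

.score_row <- function(tr, target, lag_samples, lag_ms, ncc, err,
                       n_infl, n_kp, scorable) {
  data.frame(trial_id = if ("block" %in% names(tr))
               paste0(tr$condition, "_b", tr$block) else tr$condition,
             condition = tr$condition, target = target,
             lag_samples = as.numeric(lag_samples), lag_ms = as.numeric(lag_ms),
             ncc_max = as.numeric(ncc),
             mean_abs_error_ms = as.numeric(err),
             n_inflections = n_infl, n_keypresses = n_kp,
             scorable = scorable)
}
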