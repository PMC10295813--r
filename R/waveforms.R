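#' Keypress events to a continuous waveform
#'
#' Converts discrete button-press events into a continuous tracking waveform
#' on a uniform grid: button 1 (inhalation onset / circle-expansion onset)
#' is coded -1, marking the trough of the period, and button 2 (exhalation /
#' contraction onset) is coded +1, marking the peak. Values between anchors
#' are linearly interpolated; before the first and after the last anchor the
#' waveform is held constant (clamping avoids spurious inflections at trial
#' edges).
#'
#' @param events Data frame with columns `time_s` and `button` (1 or 2),
#'   times within `[0, duration]`.
#' @param duration Waveform duration in seconds.
#' @param rate Sampling rate in Hz (default 500, matching the belt).
#' @return An object of class `waveform` with `round(duration * rate)`
#'   samples in `[-1, 1]`.
#' @export
keypress_to_waveform <- function(events, duration, rate = 500) {
  stopifnot(is.data.frame(events))
  if (!all(c("time_s", "button") %in% names(events)))
    stop("`events` needs columns time_s and button", call. = FALSE)
  n <- as.integer(round(duration * rate))
  grid <- (seq_len(n) - 1L) / rate
  if (nrow(events) == 0L) {
    warning("no keypress events; returning an all-zero waveform")
    return(.waveform(numeric(n), rate, "keypress"))
  }
  if (!all(events$button %in% c(1, 2)))
    stop("buttons must be 1 or 2", call. = FALSE)
  if (is.unsorted(events$time_s))
    stop("events must be time-sorted", call. = FALSE)
  if (any(events$time_s < 0 | events$time_s > duration))
    stop("event times must lie within [0, duration]", call. = FALSE)
  if (anyDuplicated(events$time_s)) {
    warning("duplicate keypress timestamps; keeping the last of each")
    events <- events[!duplicated(events$time_s, fromLast = TRUE), , drop = FALSE]
  }
  y <- ifelse(events$button == 1, -1, 1)
  vals <- if (nrow(events) == 1L) rep(y, n) else
    stats::approx(events$time_s, y, xout = grid, rule = 2)$y
  wf <- .waveform(vals, rate, "keypress")
  # span actually covered by behavior; the clamped extrapolation outside it
  # is excluded from NCC alignment
  wf$anchor_range <- c(max(1L, floor(min(events$time_s) * rate) + 1L),
                       min(n, ceiling(max(events$time_s) * rate) + 1L))
  wf
}

.waveform <- function(values, rate, origin, t0 = 0) {
  structure(list(values = as.numeric(values), rate = rate,
                 origin = origin, t0 = t0),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform:%s> %d samples @ %g Hz (%.1f s)\n",
              x$origin, length(x$values), x$rate, duration(x)))
  invisible(x)
}

#' @export
duration.waveform <- function(x) length(x$values) / x$rate

#' @export
time_axis.waveform <- function(x)
  x$t0 + seq(0, length.out = length(x$values)) / x$rate

#' Pulsing-circle stimulus waveform
#'
#' Reconstructs the radius waveform of the visual pacing circle. The circle
#' expands linearly from -1 to +1 over half the participant's respiratory
#' period, pauses at +1 for 0.2 x the expansion period, contracts back to -1
#' at the same rate, and pauses at -1 for 0.2 x the contraction period, so
#' one full cycle lasts 1.2 x `period_s`. The waveform starts at -1
#' (expansion onset) so that the first button-1 anchor of a perfect tracker
#' coincides with the start of the trial; with `pauses = FALSE` the holds
#' are dropped and the cycle length equals `period_s` exactly.
#'
#' @param period_s Respiratory period in seconds (> 0); expansion =
#'   contraction = `period_s / 2`.
#' @param duration Waveform duration in seconds.
#' @param rate Sampling rate in Hz (default 500).
#' @param pauses Include the 0.2 x half-period holds (default TRUE).
#' @return A `waveform` with values in `[-1, 1]`.
#' @export
circle_waveform <- function(period_s, duration, rate = 500, pauses = TRUE) {
  if (!is.numeric(period_s) || length(period_s) != 1L || !is.finite(period_s) ||
      period_s <= 0)
    stop("`period_s` must be a single positive number", call. = FALSE)
  half <- period_s / 2
  pause <- if (pauses) 0.2 * half else 0
  cycle <- 2 * half + 2 * pause
  n <- as.integer(round(duration * rate))
  t <- (seq_len(n) - 1L) / rate
  tau <- t %% cycle
  v <- numeric(n)
  ris <- tau < half
  hold_hi <- !ris & tau < half + pause
  fal <- !ris & !hold_hi & tau < 2 * half + pause
  v[ris] <- -1 + 2 * tau[ris] / half
  v[hold_hi] <- 1
  v[fal] <- 1 - 2 * (tau[fal] - half - pause) / half
  v[!ris & !hold_hi & !fal] <- -1
  .waveform(v, rate, "circle")
}

#' Analytic inflection schedule of the circle stimulus
#'
#' Returns the times at which the circle switches from expansion to hold/
#' contraction and vice versa -- the cues a tracking participant responds
#' to. Expansion onsets map to button 1, contraction onsets to button 2.
#'
#' @inheritParams circle_waveform
#' @return Data frame with columns `time_s`, `type`
#'   (`"expansion"`/`"contraction"`) and `button` (1/2), time-sorted.
#' @export
circle_inflections <- function(period_s, duration, pauses = TRUE) {
  half <- period_s / 2
  pause <- if (pauses) 0.2 * half else 0
  cycle <- 2 * half + 2 * pause
  starts <- seq(0, duration, by = cycle)
  exp_on <- starts[starts < duration]
  con_on <- starts + half + pause
  con_on <- con_on[con_on < duration]
  out <- data.frame(
    time_s = c(exp_on, con_on),
    type = c(rep("expansion", length(exp_on)), rep("contraction", length(con_on))),
    button = c(rep(1L, length(exp_on)), rep(2L, length(con_on)))
  )
  out[order(out$time_s), , drop = FALSE]
}

#' Segment a run into task trials
#'
#' Slices a full-run trace or waveform into per-trial segments using the
#' trial table's onset/duration timestamps.
#'
#' @param run A [resp_trace()] or `waveform` covering the whole run.
#' @param trials Data frame with columns `condition`, `onset_s`,
#'   `duration_s` (and any extra columns, carried through).
#' @return A list of `trial_segment` objects, each holding the trial row and
#'   the sliced object (same class as `run`).
#' @export
segment_trials <- function(run, trials) {
  stopifnot(inherits(run, "resp_trace") || inherits(run, "waveform"))
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0L) return(list())
  if (!all(c("condition", "onset_s", "duration_s") %in% names(trials)))
    stop("`trials` needs columns condition, onset_s, duration_s", call. = FALSE)
  dur <- duration(run)
  rate <- run$rate
  ord <- order(trials$onset_s)
  ends <- trials$onset_s + trials$duration_s
  if (any(trials$onset_s[ord][-1] < ends[ord][-nrow(trials)] - 1e-9))
    stop("trial windows overlap", call. = FALSE)
  lapply(seq_len(nrow(trials)), function(i) {
    on <- trials$onset_s[i]; d <- trials$duration_s[i]
    if (on < -1e-9 || on + d > dur + 1e-9)
      stop(sprintf("trial %d (%s) window [%.2f, %.2f] outside run extent [0, %.2f]",
                   i, trials$condition[i], on, on + d, dur), call. = FALSE)
    i0 <- as.integer(round(on * rate)) + 1L
    n <- as.integer(round(d * rate))
    i1 <- min(i0 + n - 1L, length(if (inherits(run, "resp_trace")) run$samples else run$values))
    obj <- if (inherits(run, "resp_trace")) {
      resp_trace(run$samples[i0:i1], rate, t0 = on, run_id = run$run_id)
    } else {
      .waveform(run$values[i0:i1], rate, run$origin, t0 = on)
    }
    structure(list(condition = trials$condition[i], onset_s = on,
                   duration_s = d, row = trials[i, , drop = FALSE],
                   data = obj),
              class = "trial_segment")
  })
}
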