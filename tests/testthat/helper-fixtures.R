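# shared fixtures, all generated in code

# pure (optionally noisy) sinusoidal belt trace
sin_trace <- function(freq, duration, rate = 500, amp = 1, noise_sd = 0,
                      phase0 = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  x <- amp * sin(2 * pi * freq * t + phase0)
  if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
  resp_trace(x, rate)
}

# deterministic breathing: no drift, no noise, uniform depth
quiet_profile <- function(base = 0.21, ...) {
  breathing_profile(base_frequency = base, frequency_drift_sd = 0,
                    amplitude_drift_sd = 0, noise_sd = 0,
                    condition_amplitude_offsets = c(
                      PasExt = 0, PasInt = 0, ActExt = 0, ActInt = 0,
                      ActMatch = 0), ...)
}

# keypress events tracking a hold-free circle, with lag/jitter in ms
circle_tracking_events <- function(period_s, duration, lag_ms = 0,
                                   jitter_ms = 0, pauses = FALSE,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sched <- circle_inflections(period_s, duration, pauses = pauses)
  ev <- data.frame(
    time_s = sched$time_s + lag_ms / 1000 +
      rnorm(nrow(sched), 0, jitter_ms / 1000),
    button = sched$button)
  ev <- ev[ev$time_s >= 0 & ev$time_s <= duration, , drop = FALSE]
  ev[order(ev$time_s), , drop = FALSE]
}

# periodogram power of `x` at frequency f (independent spectral oracle)
power_at <- function(x, rate, f) {
  n <- length(x)
  t <- (seq_len(n) - 1) / rate
  # direct Fourier projection at f, no FFT gridding
  (2 / n)^2 * (sum(x * cos(2 * pi * f * t))^2 + sum(x * sin(2 * pi * f * t))^2)
}
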