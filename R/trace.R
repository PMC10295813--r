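#' Respiration-belt trace
#'
#' Container for a uniformly sampled respiration-belt amplitude series, the
#' raw material for all frequency and RVT estimation. Belt amplitude is in
#' arbitrary units (proportional to chest expansion); typical scanner belts
#' sample at 500 Hz.
#'
#' @param samples Numeric vector of belt amplitudes (arbitrary units).
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Start time in seconds (default 0).
#' @param run_id Optional run label.
#' @return An object of class `resp_trace`.
#' @export
resp_trace <- function(samples, rate, t0 = 0, run_id = NA_character_) {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop("`samples` must be a numeric vector of length >= 2", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         t0 = as.numeric(t0), run_id = run_id),
    class = "resp_trace"
  )
}

#' @export
print.resp_trace <- function(x, ...) {
  cat(sprintf("<resp_trace> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$samples), x$rate, duration(x),
              if (is.na(x$run_id)) "" else paste0(" run=", x$run_id)))
  invisible(x)
}

#' @export
length.resp_trace <- function(x) length(x$samples)

#' Run duration in seconds
#' @param x A `resp_trace` or `waveform`.
#' @return Duration in seconds.
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.resp_trace <- function(x) length(x$samples) / x$rate

#' Sample time axis
#' @param x A `resp_trace` or `waveform`.
#' @return Numeric vector of sample times in seconds.
#' @export
time_axis <- function(x) UseMethod("time_axis")

#' @export
time_axis.resp_trace <- function(x)
  x$t0 + seq(0, length.out = length(x$samples)) / x$rate

#' Zero-phase smoothing and mean correction
#'
#' Applies a moving-average low-pass filter of the given window length
#' forward and then backward over the trace (so the net filter has zero
#' phase: features of slow oscillations are not shifted in time), then
#' subtracts the mean. The 1 s default passes breathing-band oscillations
#' (~0.05-1 Hz) essentially intact while suppressing pump/cardiac ripple.
#'
#' @param trace A [resp_trace()].
#' @param window_s Smoothing window length in seconds (default 1).
#' @return A smoothed, mean-centred `resp_trace` of the same length.
#' @export
smooth_and_center <- function(trace, window_s = 1.0) {
  stopifnot(inherits(trace, "resp_trace"))
  w <- as.integer(round(window_s * trace$rate))
  if (w < 3L)
    stop("smoothing window must span at least 3 samples", call. = FALSE)
  if (length(trace$samples) < w)
    stop("trace shorter than smoothing window", call. = FALSE)
  x <- trace$samples
  n <- length(x)
  # antisymmetric reflect-padding continues the signal's slope beyond the
  # run edges, so edge breaths are smoothed without flattening
  pad <- min(w, n - 1L)
  xp <- c(rev(2 * x[1] - x[seq_len(pad) + 1L]), x,
          rev(2 * x[n] - x[n - seq_len(pad)]))
  y <- .ma_causal(xp, w)
  y <- rev(.ma_causal(rev(y), w))
  y <- y[pad + seq_len(n)]
  y <- y - mean(y)
  resp_trace(y, trace$rate, trace$t0, trace$run_id)
}

# causal moving average (partial windows at the very start of the padded
# signal; the backward pass mirrors them so the cascade is symmetric)
.ma_causal <- function(x, w) {
  n <- length(x)
  cs <- cumsum(x)
  full <- (cs - c(rep(0, w), cs[seq_len(n - w)])) / w
  head_n <- seq_len(min(w - 1L, n))
  full[head_n] <- cs[head_n] / head_n
  full
}

#' Z-score a trace
#'
#' Normalizes a belt trace to mean 0 and standard deviation 1 over the whole
#' run, so that amplitude thresholds (e.g. the 0.5 SD peak-trough prominence
#' rule) and RVT values are in comparable z-units across runs.
#'
#' @param trace A [resp_trace()].
#' @return A z-scored `resp_trace`.
#' @export
zscore <- function(trace) {
  stopifnot(inherits(trace, "resp_trace"))
  s <- stats::sd(trace$samples)
  if (!is.finite(s) || s <= .Machine$double.eps * max(1, abs(mean(trace$samples))))
    stop("degenerate signal: zero variance, cannot z-score", call. = FALSE)
  resp_trace((trace$samples - mean(trace$samples)) / s,
             trace$rate, trace$t0, trace$run_id)
}
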