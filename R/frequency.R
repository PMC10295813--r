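#' Trial-level breathing frequency by FFT
#'
#' Estimates the dominant breathing frequency of a trace segment as the
#' argmax of the zero-padded FFT periodogram within the physiological band
#' (0.05-1 Hz by default). Zero-padding guarantees a spectral resolution of
#' at most `resolution` Hz regardless of segment length. If the spectral
#' peak does not dominate the in-band power (e.g. on pure noise), the
#' estimate is flagged low-confidence.
#'
#' @param trace A [resp_trace()] (typically smoothed and mean-centred); the
#'   segment must span at least `min_duration_s` seconds.
#' @param band Frequency search band in Hz (default `c(0.05, 1)`).
#' @param resolution Maximum spectral grid spacing in Hz (default 0.005).
#' @param min_duration_s Minimum segment length in seconds (default 10).
#' @return A single frequency in Hz, with attributes `low_confidence`
#'   (logical) and `peak_ratio` (fraction of in-band power within one
#'   natural resolution width of the peak).
#' @export
estimate_frequency_trial <- function(trace, band = c(0.05, 1.0),
                                     resolution = 0.005,
                                     min_duration_s = 10) {
  stopifnot(inherits(trace, "resp_trace"))
  if (duration(trace) < min_duration_s)
    stop(sprintf("segment too short for frequency estimation (%.2f s < %g s)",
                 duration(trace), min_duration_s), call. = FALSE)
  .fft_peak_frequency(trace$samples, trace$rate, band, resolution)
}

.fft_peak_frequency <- function(x, rate, band = c(0.05, 1.0),
                                resolution = 0.005, conf_threshold = 0.5) {
  x <- x - mean(x)
  n <- length(x)
  nfft <- 2L^ceiling(log2(max(n, rate / resolution)))
  p <- Mod(stats::fft(c(x, numeric(nfft - n))))^2
  freqs <- (seq_len(nfft) - 1L) * rate / nfft
  half <- seq_len(nfft %/% 2L)
  p <- p[half]; freqs <- freqs[half]
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (!any(in_band)) stop("no spectral bins inside the search band", call. = FALSE)
  pb <- p[in_band]; fb <- freqs[in_band]
  k <- which.max(pb)
  f_hat <- fb[k]
  # peak dominance: power within one natural resolution width (1/T Hz) of
  # the peak, relative to total in-band power
  lobe <- abs(fb - f_hat) <= rate / n
  peak_ratio <- sum(pb[lobe]) / sum(pb)
  structure(f_hat,
            low_confidence = peak_ratio < conf_threshold,
            peak_ratio = peak_ratio)
}

#' Sliding-window breathing frequency, one value per fMRI volume
#'
#' Estimates breathing frequency in a sliding window (10 s by default)
#' centred on each point of a time grid -- by default the fMRI volume onsets
#' at the given TR -- producing one frequency value per volume for use as a
#' per-volume nuisance regressor. At the run edges the window slides inward
#' so it always spans the full `window_s` of recorded data (a centred window
#' truncated to one or two breathing cycles has a phase-dependent spectral
#' argmax that can be tens of millihertz off); no value is imputed.
#' Estimates are clipped to the physiological band with a warning.
#'
#' @param trace A [resp_trace()].
#' @param window_s Sliding window length in seconds (default 10).
#' @param tr_s Volume repetition time in seconds (default 2); used to build
#'   the default grid.
#' @param grid Optional explicit vector of grid times in seconds (relative
#'   to the trace start); overrides `tr_s`.
#' @param band Physiological frequency band in Hz.
#' @return An object of class `freq_series`: list with `values` (Hz),
#'   `grid` (s), `window_s`.
#' @export
estimate_frequency_sliding <- function(trace, window_s = 10, tr_s = 2,
                                       grid = NULL, band = c(0.05, 1.0)) {
  stopifnot(inherits(trace, "resp_trace"))
  dur <- duration(trace)
  if (dur < window_s)
    stop("trace shorter than the sliding window", call. = FALSE)
  if (is.null(grid)) {
    n_vol <- floor(dur / tr_s)
    grid <- (seq_len(n_vol) - 1L) * tr_s
  }
  if (length(grid) == 0L) stop("empty volume grid", call. = FALSE)
  half <- window_s / 2
  vals <- vapply(grid, function(g) {
    lo <- min(max(0, g - half), dur - window_s)
    hi <- lo + window_s
    i0 <- floor(lo * trace$rate) + 1L
    i1 <- min(length(trace$samples), ceiling(hi * trace$rate))
    as.numeric(.fft_peak_frequency(trace$samples[i0:i1], trace$rate, band))
  }, numeric(1))
  out_of_band <- vals < band[1] | vals > band[2]
  if (any(out_of_band)) {
    warning(sprintf("%d sliding frequency estimates outside [%g, %g] Hz were clipped",
                    sum(out_of_band), band[1], band[2]))
    vals <- pmin(pmax(vals, band[1]), band[2])
  }
  structure(list(values = vals, grid = as.numeric(grid), window_s = window_s),
            class = "freq_series")
}

#' @export
print.freq_series <- function(x, ...) {
  cat(sprintf("<freq_series> %d values, window %g s, mean %.3f Hz\n",
              length(x$values), x$window_s, mean(x$values)))
  invisible(x)
}

#' Respiratory volume per time (RVT) from peak/trough envelopes
#'
#' Linearly interpolates peak values at peak times (upper envelope) and
#' trough values at trough times (lower envelope) across the z-scored belt
#' trace; the per-sample difference upper - lower is the RVT series, a proxy
#' for breathing depth. Samples before the first and after the last extremum
#' of each envelope are held at the nearest envelope value.
#'
#' @param trace The z-scored [resp_trace()] the extrema were detected on.
#' @param extrema An [detect_extrema()] result with at least 2 peaks and 2
#'   troughs.
#' @return An object of class `rvt_series`: list with per-sample `values`
#'   (z-units), `upper`, `lower`, plus `rate` and `t0`.
#' @export
compute_rvt <- function(trace, extrema) {
  stopifnot(inherits(trace, "resp_trace"), inherits(extrema, "extrema_set"))
  if (length(extrema$peaks) < 2L || length(extrema$troughs) < 2L)
    stop("degenerate signal: need at least 2 peaks and 2 troughs for an RVT envelope",
         call. = FALSE)
  x <- trace$samples
  idx <- seq_along(x)
  upper <- stats::approx(extrema$peaks, x[extrema$peaks], xout = idx, rule = 2)$y
  lower <- stats::approx(extrema$troughs, x[extrema$troughs], xout = idx, rule = 2)$y
  structure(list(values = upper - lower, upper = upper, lower = lower,
                 rate = trace$rate, t0 = trace$t0),
            class = "rvt_series")
}

#' @export
print.rvt_series <- function(x, ...) {
  cat(sprintf("<rvt_series> %d samples @ %g Hz, mean RVT %.3f z-units\n",
              length(x$values), x$rate, mean(x$values)))
  invisible(x)
}
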