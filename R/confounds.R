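#' Per-volume nuisance regressor table
#'
#' Assembles the per-volume physiological confound regressors used in
#' first-level fMRI models: the sliding-window breathing frequency and the
#' TR-interval mean of the sample-level RVT series, one row per acquired
#' volume. Imaging-derived confounds (motion, DVARS, framewise displacement)
#' may be supplied as pass-through columns but are never computed here.
#'
#' @param freq A `freq_series` from [estimate_frequency_sliding()], ideally
#'   on the volume grid.
#' @param rvt An `rvt_series` from [compute_rvt()].
#' @param n_volumes Number of acquired volumes.
#' @param tr_s Repetition time in seconds (default 2).
#' @param extra Optional data frame of pass-through confound columns with
#'   `n_volumes` rows.
#' @return A data frame with columns `volume_index`, `onset_s`,
#'   `resp_frequency_hz`, `rvt_au` (plus pass-through columns); attribute
#'   `edge_filled` lists volumes whose estimate used a nearest-neighbour
#'   fill.
#' @export
build_confound_table <- function(freq, rvt, n_volumes, tr_s = 2.0,
                                 extra = NULL) {
  stopifnot(inherits(freq, "freq_series"), inherits(rvt, "rvt_series"))
  if (n_volumes < 1L) stop("n_volumes must be >= 1", call. = FALSE)
  onsets <- (seq_len(n_volumes) - 1L) * tr_s
  physio_dur <- length(rvt$values) / rvt$rate
  uncovered <- which(onsets > physio_dur + freq$window_s / 2)
  if (length(uncovered) > 0L)
    stop("physio recording shorter than the scan; uncovered volumes: ",
         paste(uncovered, collapse = ", "), call. = FALSE)

  # frequency: exact grid match if available, else nearest-neighbour
  edge_filled <- integer(0)
  if (length(freq$grid) == n_volumes &&
      isTRUE(all.equal(freq$grid, onsets, tolerance = 1e-6))) {
    f_vol <- freq$values
  } else {
    f_vol <- stats::approx(freq$grid, freq$values, xout = onsets,
                           method = "constant", rule = 2, f = 0.5)$y
    edge_filled <- which(onsets < min(freq$grid) | onsets > max(freq$grid))
  }

  r_vol <- vapply(onsets, function(on) {
    i0 <- floor(on * rvt$rate) + 1L
    i1 <- min(length(rvt$values), ceiling((on + tr_s) * rvt$rate))
    if (i0 > length(rvt$values)) NA_real_ else mean(rvt$values[i0:i1])
  }, numeric(1))
  if (anyNA(r_vol)) {
    na_i <- which(is.na(r_vol))
    r_vol[na_i] <- r_vol[max(which(!is.na(r_vol)))]
    edge_filled <- sort(unique(c(edge_filled, na_i)))
  }

  out <- data.frame(volume_index = seq_len(n_volumes) - 1L,
                    onset_s = onsets,
                    resp_frequency_hz = f_vol,
                    rvt_au = r_vol)
  if (!is.null(extra)) {
    stopifnot(is.data.frame(extra), nrow(extra) == n_volumes)
    out <- cbind(out, extra)
  }
  attr(out, "edge_filled") <- edge_filled
  out
}

#' Write a confound table as a GLM-ready TSV
#'
#' One row per volume, tab-separated, named header -- the convention used by
#' standard fMRI preprocessing confound outputs, so the table drops into any
#' GLM tool.
#'
#' @param table A data frame from [build_confound_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_confounds_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-trial physiological covariates
#'
#' Computes trial-averaged covariates for second (group) level models. For a
#' raw belt trace, the trial frequency is a whole-segment FFT estimate (not
#' the mean of sliding values); for an RVT or frequency series, the trial
#' value is the mean over the trial window.
#'
#' @param series A [resp_trace()] (smoothed/centred), `rvt_series`, or
#'   `freq_series`.
#' @param trials Trial table with `condition`, `onset_s`, `duration_s`.
#' @return Data frame with one row per trial: `condition`, `onset_s`,
#'   `duration_s`, `value` (Hz for traces/frequency series, z-units for RVT).
#' @export
trial_average <- function(series, trials) UseMethod("trial_average")

#' @export
trial_average.resp_trace <- function(series, trials) {
  .check_trial_windows(trials, duration(series))
  vals <- vapply(seq_len(nrow(trials)), function(i) {
    i0 <- as.integer(round(trials$onset_s[i] * series$rate)) + 1L
    i1 <- min(i0 + as.integer(round(trials$duration_s[i] * series$rate)) - 1L,
              length(series$samples))
    as.numeric(estimate_frequency_trial(resp_trace(series$samples[i0:i1],
                                                   series$rate)))
  }, numeric(1))
  .trial_cov(trials, vals)
}

#' @export
trial_average.rvt_series <- function(series, trials) {
  .check_trial_windows(trials, length(series$values) / series$rate)
  vals <- vapply(seq_len(nrow(trials)), function(i) {
    i0 <- as.integer(round(trials$onset_s[i] * series$rate)) + 1L
    i1 <- min(i0 + as.integer(round(trials$duration_s[i] * series$rate)) - 1L,
              length(series$values))
    mean(series$values[i0:i1])
  }, numeric(1))
  .trial_cov(trials, vals)
}

#' @export
trial_average.freq_series <- function(series, trials) {
  step <- if (length(series$grid) > 1L) mean(diff(series$grid)) else
    series$window_s
  .check_trial_windows(trials, max(series$grid) + step)
  vals <- vapply(seq_len(nrow(trials)), function(i) {
    sel <- series$grid >= trials$onset_s[i] &
      series$grid < trials$onset_s[i] + trials$duration_s[i]
    mean(series$values[sel])
  }, numeric(1))
  .trial_cov(trials, vals)
}

.check_trial_windows <- function(trials, extent) {
  if (nrow(trials) == 0L) return(invisible())
  bad <- which(trials$onset_s < -1e-9 |
               trials$onset_s + trials$duration_s > extent + 1e-6)
  if (length(bad) > 0L)
    stop("trial window(s) outside series extent: ",
         paste(bad, collapse = ", "), call. = FALSE)
}

.trial_cov <- function(trials, vals) {
  if (nrow(trials) == 0L)
    return(data.frame(condition = character(), onset_s = numeric(),
                      duration_s = numeric(), value = numeric()))
  data.frame(condition = trials$condition, onset_s = trials$onset_s,
             duration_s = trials$duration_s, value = vals)
}
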