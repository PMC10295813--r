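#' Read and write respiration traces
#'
#' Plain-TSV format: two named columns `time_s`, `amplitude`, uniform
#' sampling. BIDS-style physio format: a headerless columns file plus a JSON
#' sidecar with `SamplingFrequency`, `StartTime` and `Columns`.
#'
#' @param trace A [resp_trace()].
#' @param path Output `.tsv` path (for BIDS, the sidecar uses the same stem
#'   with `.json`).
#' @param bids Write BIDS-style physio instead of plain TSV (default FALSE).
#' @return `path`, invisibly (writers) or a `resp_trace` (readers).
#' @export
write_respiration_tsv <- function(trace, path, bids = FALSE) {
  stopifnot(inherits(trace, "resp_trace"))
  if (bids) {
    utils::write.table(data.frame(respiratory = trace$samples), path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    sidecar <- sub("\\.tsv$", ".json", path)
    jsonlite::write_json(list(SamplingFrequency = trace$rate,
                              StartTime = trace$t0,
                              Columns = list("respiratory")),
                         sidecar, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(data.frame(time_s = time_axis(trace),
                                  amplitude = trace$samples),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_respiration_tsv
#' @export
read_respiration_tsv <- function(path, bids = FALSE) {
  if (bids) {
    sidecar <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                                   simplifyVector = TRUE)
    x <- utils::read.table(path, sep = "\t", header = FALSE)
    resp_trace(x[[1]], rate = sidecar$SamplingFrequency,
               t0 = if (is.null(sidecar$StartTime)) 0 else sidecar$StartTime)
  } else {
    x <- utils::read.delim(path)
    dt <- diff(x$time_s)
    if (max(abs(dt - dt[1])) > 1e-6)
      stop("non-uniform sampling in ", path, call. = FALSE)
    resp_trace(x$amplitude, rate = 1 / dt[1], t0 = x$time_s[1])
  }
}

#' Write/read a session log as trial and event TSVs
#'
#' Two tab-separated files under `dir`: `trials.tsv` (participant, session,
#' block, condition, onset_s, duration_s, circle_period_s) and `events.tsv`
#' (time_s, button).
#'
#' @param session A `session_log` (or list with `trials`/`events`).
#' @param dir Output directory (created if missing).
#' @return `dir` invisibly (writer); a list with `trials` and `events`
#'   (reader).
#' @export
write_session_log <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(session$trials, file.path(dir, "trials.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(session$events, file.path(dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(dir) {
  list(trials = utils::read.delim(file.path(dir, "trials.tsv")),
       events = utils::read.delim(file.path(dir, "events.tsv")))
}
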