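#' Detect respiratory peaks and troughs
#'
#' Finds local maxima (peaks) and minima (troughs) of a z-scored belt trace
#' under two constraints: consecutive same-type extrema must be at least
#' `min_separation_s` apart in time, and each adjacent peak-trough pair must
#' differ in amplitude by at least `prominence_sd` (in z-units; a vertical
#' prominence rule that rejects small ripples riding on a breath). After
#' pruning, strict peak/trough alternation is enforced by keeping the
#' maximal peak (minimal trough) within any same-type run, which is required
#' for a well-defined RVT envelope.
#'
#' Two presets are conventional: the RVT preset (`prominence_sd = 0.5`,
#' `min_separation_s = 2`) and the behavior-tracking preset
#' (`prominence_sd = 0`, `min_separation_s = 1`, individual breaths being
#' unlikely to be shorter than 1 s).
#'
#' @param trace A z-scored [resp_trace()].
#' @param prominence_sd Minimum amplitude difference between adjacent peak
#'   and trough, in z-units (default 0.5).
#' @param min_separation_s Minimum time between consecutive same-type
#'   extrema, in seconds (default 2).
#' @return An object of class `extrema_set` with integer sample indices
#'   `peaks` and `troughs` (1-based, strictly increasing, alternating).
#' @export
detect_extrema <- function(trace, prominence_sd = 0.5, min_separation_s = 2.0) {
  stopifnot(inherits(trace, "resp_trace"))
  x <- trace$samples
  n <- length(x)
  min_gap <- as.integer(round(min_separation_s * trace$rate))

  cand <- .local_extrema(x)
  pk <- .enforce_separation(cand$peaks, x, min_gap, keep = "max")
  tr <- .enforce_separation(cand$troughs, x, min_gap, keep = "min")

  if (length(pk) == 0L && length(tr) == 0L) {
    warning("no extrema found; RVT undefined for this trace")
    return(.extrema_set(integer(), integer(), prominence_sd, min_separation_s,
                        trace$rate))
  }

  merged <- .alternate(pk, tr, x)
  merged <- .prune_prominence(merged, x, prominence_sd)
  # pruning can merge same-type neighbours closer than min_gap; re-check
  pk <- .enforce_separation(merged$idx[merged$type == 1L], x, min_gap, "max")
  tr <- .enforce_separation(merged$idx[merged$type == -1L], x, min_gap, "min")
  merged <- .alternate(pk, tr, x)

  .extrema_set(merged$idx[merged$type == 1L], merged$idx[merged$type == -1L],
               prominence_sd, min_separation_s, trace$rate)
}

.extrema_set <- function(peaks, troughs, prominence_sd, min_separation_s, rate) {
  structure(
    list(peaks = as.integer(peaks), troughs = as.integer(troughs),
         prominence_sd = prominence_sd, min_separation_s = min_separation_s,
         rate = rate),
    class = "extrema_set"
  )
}

#' @export
print.extrema_set <- function(x, ...) {
  cat(sprintf("<extrema_set> %d peaks, %d troughs (prominence %.2g SD, min sep %.2g s)\n",
              length(x$peaks), length(x$troughs),
              x$prominence_sd, x$min_separation_s))
  invisible(x)
}

#' Times of all inflection points (peaks and troughs), sorted
#' @param extrema An `extrema_set`.
#' @param t0 Time of the first sample (s).
#' @return Numeric vector of times in seconds.
#' @export
extrema_times <- function(extrema, t0 = 0) {
  stopifnot(inherits(extrema, "extrema_set"))
  sort(t0 + (c(extrema$peaks, extrema$troughs) - 1L) / extrema$rate)
}

# sign-change local extrema; plateaus resolved to their first sample
.local_extrema <- function(x) {
  dx <- diff(x)
  s <- sign(dx)
  nz <- s != 0
  if (!any(nz)) return(list(peaks = integer(), troughs = integer()))
  # carry last non-zero slope sign through flat runs
  idx <- which(nz)
  f <- cumsum(nz)
  s_filled <- numeric(length(s))
  s_filled[f > 0] <- s[idx][f[f > 0]]
  s_filled[f == 0] <- s[idx[1]]
  turns <- diff(s_filled)
  list(peaks   = which(turns == -2) + 1L,
       troughs = which(turns ==  2) + 1L)
}

# greedy left-to-right: within min_gap of the last kept extremum, keep only
# the more extreme of the two
.enforce_separation <- function(idx, x, min_gap, keep = c("max", "min")) {
  keep <- match.arg(keep)
  if (length(idx) <= 1L) return(idx)
  better <- if (keep == "max") `>` else `<`
  out <- idx[1]
  for (i in idx[-1]) {
    last <- out[length(out)]
    if (i - last < min_gap) {
      if (better(x[i], x[last])) out[length(out)] <- i
    } else {
      out <- c(out, i)
    }
  }
  out
}

# merge peak (+1) and trough (-1) indices in time order, collapsing runs of
# the same type to their most extreme member
.alternate <- function(pk, tr, x) {
  idx <- c(pk, tr)
  type <- c(rep(1L, length(pk)), rep(-1L, length(tr)))
  o <- order(idx)
  idx <- idx[o]; type <- type[o]
  if (length(idx) == 0L) return(list(idx = integer(), type = integer()))
  run <- cumsum(c(1L, diff(type) != 0L))
  keep <- vapply(split(seq_along(idx), run), function(g) {
    v <- x[idx[g]]
    g[if (type[g[1]] == 1L) which.max(v) else which.min(v)]
  }, integer(1))
  keep <- sort(unname(keep))
  list(idx = idx[keep], type = type[keep])
}

# iteratively remove the weakest adjacent peak-trough pair whose amplitude
# difference falls below the prominence threshold, keeping the more extreme
# member, until all adjacent pairs pass
.prune_prominence <- function(m, x, prominence_sd) {
  if (prominence_sd <= 0) return(m)
  repeat {
    if (length(m$idx) < 2L) return(m)
    v <- x[m$idx]
    d <- abs(diff(v))
    bad <- which(d < prominence_sd)
    if (length(bad) == 0L) return(m)
    j <- bad[which.min(d[bad])]        # weakest violating pair (j, j+1)
    drop <- if (abs(v[j]) >= abs(v[j + 1])) j + 1L else j
    m$idx <- m$idx[-drop]; m$type <- m$type[-drop]
    m <- .alternate(m$idx[m$type == 1L], m$idx[m$type == -1L], x)
  }
}
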