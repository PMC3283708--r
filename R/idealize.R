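#' Half-amplitude (50% threshold) idealization
#'
#' Converts a noisy two-level current recording into an alternating
#' open/closed event list. The threshold is the midpoint of the closed and
#' open current levels; each sample is classed by which side of the
#' threshold it falls on and runs of equal class become events. When
#' \code{levels} is not supplied, the two levels are estimated from the
#' amplitude histogram by a two-class k-means split; estimation fails (with
#' an error) when the histogram is effectively unimodal, i.e. the fitted
#' levels are not separated by at least \code{minSeparation} pooled
#' within-class standard deviations.
#'
#' @param trace a \linkS4class{CurrentTrace}.
#' @param levels optional \code{c(closed, open)} current levels (pA); by
#'   default estimated from the data.
#' @param minSeparation required level separation in pooled within-class
#'   SDs when estimating levels.
#' @return An \linkS4class{IdealizedRecord}.
#' @examples
#' p <- simulatePath(defaultParameters(), constantProtocol(), 5, seed = 1)
#' tr <- synthesizeTrace(p, AcquisitionSpec(), seed = 2)
#' idealizeThreshold50(tr, levels = c(0, 30))
#' @export
idealizeThreshold50 <- function(trace, levels = NULL, minSeparation = 3.5) {
  stopifnot(is(trace, "CurrentTrace"))
  x <- trace@samples
  if (length(x) < 2L) stop("trace too short to idealize")
  if (is.null(levels)) {
    if (diff(range(x)) < 1e-12)
      stop("level estimation failed: amplitude histogram is unimodal ",
        "(supply `levels` explicitly)")
    km <- stats::kmeans(x, centers = range(x), iter.max = 50)
    ctr <- sort(as.numeric(km$centers))
    pooled_sd <- sqrt(km$tot.withinss / length(x))
    if (diff(ctr) < minSeparation * pooled_sd)
      stop("level estimation failed: amplitude histogram is unimodal ",
        "(supply `levels` explicitly)")
    levels <- ctr
  }
  if (length(levels) != 2L || levels[1] == levels[2])
    stop("levels must be two distinct values c(closed, open)")
  thr <- mean(levels)
  open_is_high <- levels[2] > levels[1]
  cls <- if (open_is_high) x > thr else x < thr
  r <- rle(cls)
  fs <- trace@spec@sampleRate
  new("IdealizedRecord",
    states = ifelse(r$values, "O", "C"),
    durations = r$lengths / fs,
    threshold = thr, totalDuration = length(x) / fs)
}

#' Open probability of an idealized record
#'
#' Open time divided by total time, over the whole record or per fixed
#' window. A whole-record Po from fewer than 180 s of recording is flagged
#' with a warning (single-channel Po is conventionally measured over at
#' least 3 min); pass \code{warnShort = FALSE} to silence it for synthetic
#' material of known length. A window containing no transition simply
#' inherits the spanning state's Po (0 or 1).
#'
#' @param record an \linkS4class{IdealizedRecord}.
#' @param window window width (s), or NULL for whole-record Po.
#' @param warnShort warn when a whole-record Po spans < 180 s.
#' @return scalar Po, or a \linkS4class{PoTimeSeries} when windowed.
#' @export
computePo <- function(record, window = NULL, warnShort = TRUE) {
  stopifnot(is(record, "IdealizedRecord"))
  if (is.null(window)) {
    if (warnShort && record@totalDuration < 180)
      warning("whole-record Po from only ", signif(record@totalDuration, 3),
        " s of recording (< 180 s)")
    return(sum(record@durations[record@states == "O"]) /
      record@totalDuration)
  }
  if (window <= 0) stop("window must be > 0")
  ends <- cumsum(record@durations)
  t0 <- c(0, ends[-length(ends)])
  open <- record@states == "O"
  starts <- .window_starts(record@totalDuration, window)
  wends <- pmin(starts + window, record@totalDuration)
  po <- vapply(seq_along(starts), function(w) {
    lo <- pmax(t0, starts[w]); hi <- pmin(ends, wends[w])
    sum(pmax(hi - lo, 0)[open]) / (wends[w] - starts[w])
  }, numeric(1))
  new("PoTimeSeries", window = window, windowStart = starts, po = po,
    se = rep(NA_real_, length(po)), nTrials = 1L,
    trialPo = matrix(po, nrow = 1))
}

#' Extract dwell times of one conductance class
#'
#' Returns the durations (in milliseconds) of the requested state's events.
#' Events shorter than \code{minDuration} are unresolved at typical filter
#' bandwidths and are excluded. By default excluded events are simply
#' dropped; with \code{merge = TRUE}, sub-threshold events of either class
#' are removed first and flanking same-class events coalesced (durations
#' summed across the removed gap) before extraction.
#'
#' @param record an \linkS4class{IdealizedRecord}.
#' @param state "O" or "C".
#' @param minDuration exclusion threshold (ms); default 1 ms; 0 disables.
#' @param merge coalesce across removed short events instead of dropping.
#' @return dwell durations (ms); empty (with a warning) if nothing
#'   survives the exclusion.
#' @export
extractDwells <- function(record, state = c("O", "C"), minDuration = 1,
    merge = FALSE) {
  state <- match.arg(state)
  states <- record@states
  dur_ms <- record@durations * 1000
  if (merge && minDuration > 0) {
    out_state <- character(0); out_dur <- numeric(0); gap <- 0
    for (i in seq_along(states)) {
      if (dur_ms[i] < minDuration) {
        gap <- gap + dur_ms[i]
      } else if (length(out_state) &&
                 out_state[length(out_state)] == states[i]) {
        # same class on both flanks: the removed gap is absorbed
        out_dur[length(out_dur)] <- out_dur[length(out_dur)] + gap +
          dur_ms[i]
        gap <- 0
      } else {
        out_state <- c(out_state, states[i])
        out_dur <- c(out_dur, dur_ms[i])
        gap <- 0
      }
    }
    states <- out_state
    dur_ms <- out_dur
  }
  d <- dur_ms[states == state]
  d <- d[d >= minDuration]
  if (!length(d))
    warning("no ", state, " events of at least ", minDuration, " ms")
  d
}

setMethod("show", "IdealizedRecord", function(object) {
  n_open <- sum(object@states == "O")
  cat(sprintf(
    "IdealizedRecord: %d events (%d open) over %g s, threshold %.3g pA, Po = %.4g\n",
    length(object@states), n_open, object@totalDuration, object@threshold,
    sum(object@durations[object@states == "O"]) / object@totalDuration))
})

#' Write an idealized event list as CSV
#' @param record an \linkS4class{IdealizedRecord}.
#' @param path CSV path; columns \code{state, duration_s}.
#' @export
writeEvents <- function(record, path) {
  write.csv(data.frame(state = record@states,
    duration_s = record@durations), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  x <- read.csv(path)
  new("IdealizedRecord", states = as.character(x$state),
    durations = x$duration_s, threshold = NA_real_,
    totalDuration = sum(x$duration_s))
}
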