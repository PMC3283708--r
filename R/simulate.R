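# window start times matching the simulator's accumulation grid
.window_starts <- function(total, window) {
  window * (seq_len(ceiling(total / window - 1e-9)) - 1L)
}

.OCC_INIT <- c(free = 0L, "12" = 1L, "12*" = 2L, "12.6" = 3L, "12.6*" = 4L)

# resolve an init spec to 0-based (occ, gate) codes, sampling the
# stationary occupancy/gate when requested (consumes RNG)
.resolve_init <- function(params, protocol, init, form) {
  if (is.list(init)) {
    occ <- .OCC_INIT[[match.arg(init$occupancy, names(.OCC_INIT))]]
    gate <- if (identical(init$gate, "O")) 1L else 0L
    return(c(occ, gate))
  }
  init <- match.arg(init, c("equilibrium", "free"))
  if (init == "free") return(c(0L, 0L))
  conc0 <- concentrationsAt(protocol, 0)
  occd <- equilibriumOccupancy(params, conc0)
  occ <- sample.int(5L, 1L, prob = occd@probs) - 1L
  kO <- .branch_kO(params, form)[occ + 1L]
  po <- kO / (kO + params@kC)
  gate <- as.integer(runif(1) < po)
  c(occ, gate)
}

.run_core <- function(params, protocol, duration, window, init, form,
    record_path) {
  seg <- protocol@segments
  rates <- parameterVector(params)[c("k1", "k_m1", "k2", "k_m2", "k3",
    "k_m3", "k4", "k_m4", "kC")]
  kO_occ <- .branch_kO(params, form)
  st <- .resolve_init(params, protocol, init, form)
  gillespie_core(unname(rates), kO_occ, seg$start, seg$fkbp12, seg$fkbp12_6,
    duration, window, st[1], st[2], record_path)
}

#' Simulate one stochastic trajectory of the joint occupancy/gating process
#'
#' Exact (Gillespie direct method) sample of the 10-state continuous-time
#' Markov chain: five FKBP-occupancy states crossed with closed/open gating.
#' Opening rates are branch-conditional (see the package vignette): zero-,
#' FKBP12- and FKBP12.6-bound branches open at the rate implied by
#' \code{alpha}, \code{alpha + k2/(k2+k_m2)} and \code{alpha + k4/(k4+k_m4)}
#' respectively, which reproduces the ensemble equilibrium Po exactly.
#' Concentration changes at protocol boundaries are applied by truncating
#' the pending waiting time and re-drawing (exact by memorylessness).
#'
#' @param params a \linkS4class{KineticParameters} object.
#' @param protocol a \linkS4class{ConcentrationProtocol}.
#' @param duration simulated time (s), > 0.
#' @param seed integer RNG seed, or NULL to use the current RNG state.
#' @param init initial state: "equilibrium" (occupancy and gate sampled from
#'   the stationary law at the protocol's first segment -- the appropriate
#'   choice for steady-state estimates, since FKBP unbinding takes hours),
#'   "free" (FKBP-free, closed), or \code{list(occupancy =, gate =)}.
#' @param form opening-rate form, see \code{\link{openingRate}}.
#' @return A \linkS4class{StatePath}.
#' @examples
#' p <- simulatePath(defaultParameters(), constantProtocol(), 10, seed = 1)
#' pathOpenFraction(p)
#' @export
simulatePath <- function(params, protocol, duration, seed = NULL,
    init = "equilibrium", form = c("saturating", "linear")) {
  form <- match.arg(form)
  stopifnot(is(params, "KineticParameters"),
    is(protocol, "ConcentrationProtocol"))
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (nrow(protocol@segments) == 0L) stop("empty protocol")
  if (!is.null(seed)) set.seed(seed)
  res <- .run_core(params, protocol, duration, window = duration, init,
    form, record_path = TRUE)
  new("StatePath", times = res$times, occupancy = res$occupancy + 1L,
    gate = res$gate, duration = duration,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    metadata = list())
}

#' Summaries of a simulated trajectory
#'
#' \code{pathOpenFraction} is the fraction of total time spent with the gate
#' open; \code{pathWindowPo} bins it into fixed windows;
#' \code{occupancyFractions} is the fraction of time per occupancy state;
#' \code{pathDwells} extracts gate dwell durations (ms).
#'
#' @param path a \linkS4class{StatePath}.
#' @return \code{pathOpenFraction}: scalar in [0, 1].
#' @export
pathOpenFraction <- function(path) {
  holds <- diff(c(path@times, path@duration))
  sum(holds[path@gate == 1L]) / path@duration
}

#' @rdname pathOpenFraction
#' @param window window width (s).
#' @export
pathWindowPo <- function(path, window) {
  if (window <= 0) stop("window must be > 0")
  if (window > path@duration) stop("window exceeds path duration")
  starts <- .window_starts(path@duration, window)
  ends <- pmin(starts + window, path@duration)
  t0 <- path@times
  t1 <- c(path@times[-1], path@duration)
  open <- path@gate == 1L
  po <- vapply(seq_along(starts), function(w) {
    lo <- pmax(t0, starts[w]); hi <- pmin(t1, ends[w])
    sum(pmax(hi - lo, 0)[open]) / (ends[w] - starts[w])
  }, numeric(1))
  new("PoTimeSeries", window = window, windowStart = starts, po = po,
    se = rep(NA_real_, length(po)), nTrials = 1L,
    trialPo = matrix(po, nrow = 1))
}

#' @rdname pathOpenFraction
#' @export
occupancyFractions <- function(path) {
  holds <- diff(c(path@times, path@duration))
  f <- vapply(1:5, function(s) sum(holds[path@occupancy == s]), numeric(1))
  setNames(f / path@duration, .OCC_LEVELS)
}

#' @rdname pathOpenFraction
#' @param state "O" or "C": which gate class to extract.
#' @export
pathDwells <- function(path, state = c("O", "C")) {
  state <- match.arg(state)
  g <- if (state == "O") 1L else 0L
  holds <- diff(c(path@times, path@duration))
  r <- rle(path@gate)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  runs <- which(r$values == g)
  1000 * vapply(runs, function(i)
    sum(holds[idx_start[i]:idx_end[i]]), numeric(1))
}

#' Trial-averaged windowed open probability
#'
#' Runs \code{nTrials} independent trajectories (child seeds spawned
#' deterministically from \code{seed}) and averages the windowed open
#' fraction across trials, the standard way single-channel steady-state Po
#' is estimated from repeated simulations of one channel.
#'
#' @inheritParams simulatePath
#' @param nTrials number of independent trials (>= 1).
#' @param window window width (s); must not exceed duration.
#' @return A \linkS4class{PoTimeSeries} carrying the per-trial matrix.
#' @export
trialAveragePo <- function(params, protocol, duration, nTrials = 100,
    window = 10, seed = NULL, init = "equilibrium",
    form = c("saturating", "linear")) {
  form <- match.arg(form)
  if (nTrials < 1) stop("nTrials must be >= 1")
  if (window > duration) stop("window exceeds duration")
  if (nrow(protocol@segments) == 0L) stop("empty protocol")
  if (!is.null(seed)) set.seed(seed)
  child <- sample.int(2147483646L, nTrials)
  starts <- .window_starts(duration, window)
  widths <- pmin(starts + window, duration) - starts
  trial <- matrix(NA_real_, nTrials, length(starts))
  for (i in seq_len(nTrials)) {
    set.seed(child[i])
    res <- .run_core(params, protocol, duration, window, init, form,
      record_path = FALSE)
    trial[i, ] <- res$open_time / widths
  }
  po <- colMeans(trial)
  se <- if (nTrials > 1) apply(trial, 2, sd) / sqrt(nTrials)
        else rep(NA_real_, length(po))
  new("PoTimeSeries", window = window, windowStart = starts, po = po,
    se = se, nTrials = as.integer(nTrials), trialPo = trial)
}

#' Steady-state Po from a windowed time series
#'
#' Averages the final equilibrated portion of the record (by default the
#' last half of the windows) and reports the standard error across trials.
#'
#' @param pts a \linkS4class{PoTimeSeries}.
#' @param fraction fraction of the record (from the end) to harvest.
#' @return list with elements \code{po} and \code{se} (SE of the trial
#'   means; NA for a single trial).
#' @export
steadyStatePo <- function(pts, fraction = 0.5) {
  nw <- length(pts@windowStart)
  keep <- seq.int(max(1L, nw - ceiling(fraction * nw) + 1L), nw)
  trial_means <- rowMeans(pts@trialPo[, keep, drop = FALSE])
  list(po = mean(trial_means),
    se = if (pts@nTrials > 1) sd(trial_means) / sqrt(pts@nTrials)
         else NA_real_)
}

#' Sequential-addition antagonism protocols
#'
#' Two canonical single-channel protocols probing the competition between
#' FKBP12 and FKBP12.6 on the ~20 min timescale of a bilayer experiment.
#' \code{"antagonist_first"}: control recording, then 200 nM FKBP12.6, then
#' incremental FKBP12 additions up to 1 uM -- FKBP12.6 occupies the shared
#' site quickly and its slow dissociation prevents activation by FKBP12.
#' \code{"agonist_first"}: control, then 200 nM FKBP12, then 200 nM
#' FKBP12.6 -- activation persists because bound FKBP12 dissociates over
#' hours.
#'
#' @inheritParams trialAveragePo
#' @param order which ligand is applied first.
#' @param duration total simulated time (s); default 1200 (20 min).
#' @return A \linkS4class{PoTimeSeries}. The protocol used is attached as
#'   attribute \code{"protocol"}.
#' @export
simulateAntagonismProtocol <- function(params,
    order = c("antagonist_first", "agonist_first"), seed = NULL,
    duration = 1200, window = 10, nTrials = 1,
    form = c("saturating", "linear")) {
  order <- match.arg(order)
  form <- match.arg(form)
  protocol <- if (order == "antagonist_first") {
    # control; +200 nM FKBP12.6; FKBP12 raised stepwise to 1 uM
    ConcentrationProtocol(
      start = c(0, 0.1, 0.35, 0.55, 0.75) * duration,
      fkbp12 = c(0, 0, 0.02, 0.2, 1),
      fkbp12_6 = c(0, 0.2, 0.2, 0.2, 0.2),
      description = "pre-treatment with FKBP12.6, then incremental FKBP12")
  } else {
    ConcentrationProtocol(
      start = c(0, 0.1, 0.55) * duration,
      fkbp12 = c(0, 0.2, 0.2),
      fkbp12_6 = c(0, 0, 0.2),
      description = "FKBP12 first, then FKBP12.6")
  }
  out <- trialAveragePo(params, protocol, duration, nTrials, window, seed,
    init = "equilibrium", form = form)
  attr(out, "protocol") <- protocol
  out
}

#' Bind-and-washout protocol
#'
#' Exposes the channel to FKBP12 for \code{bindTime} seconds, then perfuses
#' both ligands to zero for \code{washoutTime} seconds. With the reference
#' rates, bound FKBP12 dissociates over hours, so Po stays elevated
#' throughout a 9-minute washout.
#'
#' @inheritParams trialAveragePo
#' @param fkbp12 FKBP12 concentration during the binding phase (uM).
#' @param bindTime,washoutTime phase durations (s).
#' @return A \linkS4class{PoTimeSeries} spanning both phases; the protocol
#'   is attached as attribute \code{"protocol"}.
#' @export
simulateWashout <- function(params, fkbp12 = 1, bindTime = 300,
    washoutTime = 540, seed = NULL, window = 10, nTrials = 1,
    form = c("saturating", "linear")) {
  form <- match.arg(form)
  protocol <- if (bindTime > 0) {
    ConcentrationProtocol(c(0, bindTime), fkbp12 = c(fkbp12, 0),
      fkbp12_6 = 0, description = "bind / washout")
  } else {
    constantProtocol(0, 0, description = "washout only")
  }
  out <- trialAveragePo(params, protocol, bindTime + washoutTime, nTrials,
    window, seed, init = "equilibrium", form = form)
  attr(out, "protocol") <- protocol
  out
}

setMethod("show", "StatePath", function(object) {
  cat(sprintf(
    "StatePath: %d events over %g s (open fraction %.4g)\n",
    length(object@times) - 1L, object@duration, pathOpenFraction(object)))
  occ <- occupancyFractions(object)
  cat("  occupancy time fractions:\n")
  print(signif(occ, 4))
})

setMethod("show", "PoTimeSeries", function(object) {
  cat(sprintf(
    "PoTimeSeries: %d windows of %g s, %d trial(s); mean Po = %.4g\n",
    length(object@po), object@window, object@nTrials, mean(object@po)))
})

#' Export a windowed Po series or state path as a data.frame
#'
#' @param x a \linkS4class{PoTimeSeries} or \linkS4class{StatePath}.
#' @return data.frame ready for CSV export: \code{(window_start, po, se)}
#'   or \code{(time, occupancy, gate)}.
#' @export
asDataFrame <- function(x) {
  if (is(x, "PoTimeSeries")) {
    data.frame(window_start = x@windowStart, po = x@po, se = x@se)
  } else if (is(x, "StatePath")) {
    data.frame(time = x@times, occupancy = .OCC_LEVELS[x@occupancy],
      gate = ifelse(x@gate == 1L, "O", "C"))
  } else stop("unsupported class: ", class(x))
}
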