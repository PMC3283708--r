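#' @import methods
#' @importFrom stats rexp rnorm runif optimize quantile sd qchisq pchisq
#'   dnorm approx setNames
#' @importFrom utils head tail write.csv read.csv packageVersion modifyList
#' @useDynLib RyRgate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# occupancy state labels, in simulator coding order (0-based in C++)
.OCC_LEVELS <- c("free", "12", "12*", "12.6", "12.6*")

#' Rate constants of the RyR2 FKBP-regulation model
#'
#' Holds the ten rate constants of the five-state FKBP-occupancy scheme
#' (association/dissociation of FKBP12 and FKBP12.6 and the two
#' conformational steps), the channel closing rate \code{kC}, and the
#' dimensionless spontaneous-background-activity constant \code{alpha}.
#' Concentration-dependent association rates are in per-micromolar per-second;
#' all other rates in per-second.
#'
#' @slot k1 FKBP12 association rate (uM^-1 s^-1).
#' @slot k_m1 FKBP12 dissociation rate (s^-1).
#' @slot k2 FKBP12-bound conformational activation rate (s^-1).
#' @slot k_m2 reverse conformational rate (s^-1).
#' @slot k3 FKBP12.6 association rate (uM^-1 s^-1).
#' @slot k_m3 FKBP12.6 dissociation rate (s^-1).
#' @slot k4 FKBP12.6-bound conformational activation rate (s^-1).
#' @slot k_m4 reverse conformational rate (s^-1).
#' @slot kC channel closing rate (s^-1).
#' @slot alpha spontaneous background open probability, in (0, 1).
#' @export
setClass("KineticParameters",
  representation(k1 = "numeric", k_m1 = "numeric", k2 = "numeric",
    k_m2 = "numeric", k3 = "numeric", k_m3 = "numeric", k4 = "numeric",
    k_m4 = "numeric", kC = "numeric", alpha = "numeric"),
  validity = function(object) {
    v <- c(k1 = object@k1, k_m1 = object@k_m1, k2 = object@k2,
      k_m2 = object@k_m2, k3 = object@k3, k_m3 = object@k_m3,
      k4 = object@k4, k_m4 = object@k_m4, kC = object@kC)
    if (any(lengths(list(object@k1, object@k_m1, object@k2, object@k_m2,
      object@k3, object@k_m3, object@k4, object@k_m4, object@kC,
      object@alpha)) != 1L))
      return("all rate slots must be length-1 numerics")
    if (any(!is.finite(v)))
      return("all rates must be finite")
    if (any(v < 0))
      return("all rates must be non-negative")
    bad <- names(v)[v <= 0 & !names(v) %in% c("k4", "k_m1")]
    # k4 = 0 is the pure-antagonist limit; k_m1 = 0 freezes FKBP12 binding;
    # both are legitimate modelling limits, every other rate must be > 0
    if (length(bad))
      return(paste("rates must be strictly positive:",
        paste(bad, collapse = ", ")))
    if (!is.finite(object@alpha) || object@alpha <= 0 || object@alpha >= 1)
      return("alpha must lie in (0, 1)")
    TRUE
  })

#' Cytosolic FK-binding protein concentrations
#'
#' Both concentrations are in micromolar.
#'
#' @slot fkbp12 FKBP12 concentration (uM).
#' @slot fkbp12_6 FKBP12.6 concentration (uM).
#' @export
setClass("LigandConcentrations",
  representation(fkbp12 = "numeric", fkbp12_6 = "numeric"),
  validity = function(object) {
    if (length(object@fkbp12) != 1L || length(object@fkbp12_6) != 1L)
      return("concentrations must be length-1")
    if (!is.finite(object@fkbp12) || !is.finite(object@fkbp12_6))
      return("concentrations must be finite")
    if (object@fkbp12 < 0 || object@fkbp12_6 < 0)
      return("concentrations must be >= 0")
    TRUE
  })

#' Equilibrium distribution over the five FKBP-occupancy states
#'
#' @slot probs named probability vector over the states
#'   \code{free, 12, 12*, 12.6, 12.6*}; sums to 1.
#' @slot nu the open-driving fraction, identically
#'   \code{probs["12*"] + probs["12.6*"]}.
#' @export
setClass("OccupancyDistribution",
  representation(probs = "numeric", nu = "numeric"),
  validity = function(object) {
    p <- object@probs
    if (length(p) != 5L || !identical(names(p), .OCC_LEVELS))
      return("probs must be a named length-5 vector over the occupancy states")
    if (any(p < 0) || any(p > 1))
      return("probabilities must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-12)
      return("probabilities must sum to 1 (tolerance 1e-12)")
    if (object@nu != unname(p["12*"] + p["12.6*"]))
      return("nu must equal probs['12*'] + probs['12.6*'] exactly")
    TRUE
  })

#' Two-state gating rates and the equilibrium open probability they imply
#'
#' @slot kO opening rate (s^-1).
#' @slot kC closing rate (s^-1).
#' @slot poEq equilibrium open probability \code{kO / (kO + kC)}.
#' @export
setClass("GatingRates",
  representation(kO = "numeric", kC = "numeric", poEq = "numeric"),
  validity = function(object) {
    if (object@kO < 0) return("kO must be >= 0")
    if (object@kC <= 0) return("kC must be > 0")
    if (object@poEq < 0 || object@poEq >= 1)
      return("poEq must lie in [0, 1)")
    if (abs(object@poEq - object@kO / (object@kO + object@kC)) > 1e-12)
      return("poEq must equal kO / (kO + kC)")
    TRUE
  })

#' Piecewise-constant ligand concentration schedule
#'
#' Encodes addition/washout timelines as an ordered set of segments, each
#' holding from its start time to the start of the next (the last segment
#' holds to the end of the simulation).
#'
#' @slot segments data.frame with columns \code{start} (s), \code{fkbp12}
#'   (uM), \code{fkbp12_6} (uM); first start must be 0, starts strictly
#'   increasing.
#' @slot description free-text label.
#' @export
setClass("ConcentrationProtocol",
  representation(segments = "data.frame", description = "character"),
  validity = function(object) {
    s <- object@segments
    if (!all(c("start", "fkbp12", "fkbp12_6") %in% names(s)))
      return("segments needs columns start, fkbp12, fkbp12_6")
    if (nrow(s) < 1L) return("protocol must have at least one segment")
    if (s$start[1] != 0) return("first segment must start at time 0")
    if (nrow(s) > 1 && any(diff(s$start) <= 0))
      return("segment start times must be strictly increasing")
    if (any(!is.finite(unlist(s))) || any(s$fkbp12 < 0) || any(s$fkbp12_6 < 0))
      return("concentrations must be finite and >= 0")
    TRUE
  })

#' Continuous-time trajectory of the joint (occupancy, gate) process
#'
#' Native output of the Gillespie simulator: the state after each transition
#' together with the transition time. The state at time 0 is the first entry.
#'
#' @slot times event times in seconds, starting at 0, strictly increasing.
#' @slot occupancy integer occupancy codes (1..5 indexing
#'   \code{free, 12, 12*, 12.6, 12.6*}).
#' @slot gate integer gate codes (0 closed, 1 open).
#' @slot duration total simulated time (s).
#' @slot seed RNG seed used (NA when the caller managed the RNG).
#' @slot metadata free-form list (e.g. modal-segment annotation).
#' @export
setClass("StatePath",
  representation(times = "numeric", occupancy = "integer", gate = "integer",
    duration = "numeric", seed = "integer", metadata = "list"),
  validity = function(object) {
    n <- length(object@times)
    if (length(object@occupancy) != n || length(object@gate) != n)
      return("times, occupancy and gate must have equal length")
    if (n < 1L) return("path must contain at least the initial state")
    if (object@times[1] != 0) return("path must start at time 0")
    if (n > 1 && any(diff(object@times) <= 0))
      return("event times must be strictly increasing")
    if (object@times[n] > object@duration + 1e-12)
      return("event times must not exceed duration")
    if (any(object@occupancy < 1L) || any(object@occupancy > 5L))
      return("occupancy codes must be in 1..5")
    if (any(!object@gate %in% c(0L, 1L)))
      return("gate codes must be 0 or 1")
    if (n > 1) {
      d_occ <- diff(object@occupancy) != 0L
      d_gate <- diff(object@gate) != 0L
      if (any(d_occ & d_gate))
        return("consecutive states must differ in exactly one coordinate")
      if (any(!d_occ & !d_gate))
        return("consecutive states must differ")
    }
    TRUE
  })

#' Windowed open-probability time series
#'
#' @slot window window width (s).
#' @slot windowStart start time of each window (s).
#' @slot po mean open probability per window (across trials).
#' @slot se standard error per window across trials (NA for single trial).
#' @slot nTrials number of trials averaged.
#' @slot trialPo trials-by-windows matrix of per-trial window Po.
#' @export
setClass("PoTimeSeries",
  representation(window = "numeric", windowStart = "numeric", po = "numeric",
    se = "numeric", nTrials = "integer", trialPo = "matrix"),
  validity = function(object) {
    if (object@window <= 0) return("window must be > 0")
    if (any(object@po < -1e-12 | object@po > 1 + 1e-12))
      return("po values must lie in [0, 1]")
    if (length(object@po) != length(object@windowStart))
      return("po and windowStart lengths differ")
    if (object@nTrials < 1L) return("nTrials must be >= 1")
    TRUE
  })

#' Acquisition chain description for synthetic recordings
#'
#' Defaults mirror a standard planar-bilayer acquisition chain: 20 kHz
#' digitisation with an 800 Hz (-3 dB) low-pass filter. Set
#' \code{filterCutoff = NA} to disable filtering.
#'
#' @slot sampleRate sampling rate (Hz).
#' @slot filterCutoff -3 dB low-pass cutoff (Hz), NA disables the filter.
#' @slot openCurrent open-level current (pA).
#' @slot closedCurrent closed-level current (pA).
#' @slot noiseSd additive Gaussian baseline noise SD (pA).
#' @export
setClass("AcquisitionSpec",
  representation(sampleRate = "numeric", filterCutoff = "numeric",
    openCurrent = "numeric", closedCurrent = "numeric", noiseSd = "numeric"),
  validity = function(object) {
    if (object@sampleRate <= 0) return("sampleRate must be > 0")
    if (!is.na(object@filterCutoff)) {
      if (object@filterCutoff <= 0) return("filterCutoff must be > 0 or NA")
      if (object@sampleRate <= 2 * object@filterCutoff)
        return("sampleRate must exceed 2 * filterCutoff")
    }
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@openCurrent == object@closedCurrent)
      return("open and closed current levels must differ")
    TRUE
  })

#' Synthetic single-channel current recording
#'
#' @slot samples current samples (pA), uniformly spaced at the spec's rate.
#' @slot spec the \linkS4class{AcquisitionSpec} used.
#' @slot truth the generating \linkS4class{StatePath}, or NULL.
#' @export
setClass("CurrentTrace",
  representation(samples = "numeric", spec = "AcquisitionSpec", truth = "ANY"))

#' Idealized (threshold-crossed) event list
#'
#' @slot states event conductance classes, alternating "O"/"C".
#' @slot durations event durations (s), summing to totalDuration.
#' @slot threshold current threshold used (pA).
#' @slot totalDuration record length (s).
#' @export
setClass("IdealizedRecord",
  representation(states = "character", durations = "numeric",
    threshold = "numeric", totalDuration = "numeric"),
  validity = function(object) {
    n <- length(object@states)
    if (length(object@durations) != n)
      return("states and durations lengths differ")
    if (n == 0L) return("record must contain at least one event")
    if (any(!object@states %in% c("O", "C")))
      return("states must be 'O' or 'C'")
    if (any(object@durations <= 0)) return("durations must be > 0")
    if (n > 1 && any(object@states[-1] == object@states[-n]))
      return("states must alternate")
    if (abs(sum(object@durations) - object@totalDuration) >
        1e-6 * max(1, object@totalDuration))
      return("durations must sum to totalDuration")
    TRUE
  })

#' Exponential-mixture dwell-time fit
#'
#' Maximum-likelihood fit of a left-truncated exponential mixture to a dwell
#' sample. Areas are fractions of the observed (truncated) events; each
#' component density is renormalized over \code{[cutoff, Inf)}.
#'
#' @slot taus component time constants (ms), strictly increasing.
#' @slot areas component fractions, summing to 1.
#' @slot nComponents number of components.
#' @slot loglik maximized log-likelihood.
#' @slot nEvents number of dwells fitted.
#' @slot cutoff left-truncation point (ms).
#' @slot selection model-comparison table (filled by
#'   \code{selectNComponents}), else empty.
#' @export
setClass("DwellFit",
  representation(taus = "numeric", areas = "numeric", nComponents = "integer",
    loglik = "numeric", nEvents = "integer", cutoff = "numeric",
    selection = "data.frame"),
  validity = function(object) {
    if (length(object@taus) != object@nComponents ||
        length(object@areas) != object@nComponents)
      return("taus/areas length must equal nComponents")
    if (any(object@taus <= 0)) return("taus must be > 0")
    if (object@nComponents > 1 && any(diff(object@taus) <= 0))
      return("taus must be strictly increasing")
    if (any(object@areas < 0)) return("areas must be >= 0")
    if (abs(sum(object@areas) - 1) > 1e-9)
      return("areas must sum to 1")
    TRUE
  })

#' Concentration-response curve
#'
#' @slot concentrations ligand grid (uM), strictly increasing.
#' @slot po open probability at each concentration.
#' @slot se Monte Carlo standard errors (NA for analytic curves).
#' @slot mode "analytic" or "monte_carlo".
#' @slot ligand which ligand was varied ("fkbp12" or "fkbp12_6").
#' @slot fixedOther fixed concentration of the other ligand (uM).
#' @export
setClass("DoseResponseCurve",
  representation(concentrations = "numeric", po = "numeric", se = "numeric",
    mode = "character", ligand = "character", fixedOther = "numeric"),
  validity = function(object) {
    if (length(object@po) != length(object@concentrations))
      return("po and concentrations lengths differ")
    if (length(object@concentrations) > 1 &&
        any(diff(object@concentrations) <= 0))
      return("concentration grid must be strictly increasing")
    if (any(object@po < -1e-12 | object@po > 1 + 1e-12))
      return("po must lie in [0, 1]")
    if (!object@mode %in% c("analytic", "monte_carlo"))
      return("mode must be 'analytic' or 'monte_carlo'")
    TRUE
  })

#' Four-parameter log-logistic (Hill) fit of a concentration-response curve
#'
#' @slot ec50 half-maximal concentration, in the grid's units (uM).
#' @slot hill Hill slope.
#' @slot floor lower Po asymptote.
#' @slot ceiling upper Po asymptote.
#' @slot rss residual sum of squares.
#' @export
setClass("Ec50Fit",
  representation(ec50 = "numeric", hill = "numeric", floor = "numeric",
    ceiling = "numeric", rss = "numeric"),
  validity = function(object) {
    if (object@ec50 <= 0) return("ec50 must be > 0")
    if (object@floor > object@ceiling)
      return("floor must not exceed ceiling")
    TRUE
  })

#' Slow modal-gating modulation
#'
#' A hidden Markov modulation of the gating opening rate: the channel
#' switches among modes with exponential dwell times; within mode m the
#' opening rate is multiplied by \code{multiplier[m]}.
#'
#' @slot dwellMean mean mode dwell time per mode (s).
#' @slot multiplier opening-rate multiplier per mode.
#' @export
setClass("ModalSpec",
  representation(dwellMean = "numeric", multiplier = "numeric"),
  validity = function(object) {
    if (length(object@dwellMean) != length(object@multiplier))
      return("dwellMean and multiplier lengths differ")
    if (length(object@dwellMean) < 1L) return("at least one mode required")
    if (any(object@dwellMean <= 0)) return("dwellMean must be > 0")
    if (any(object@multiplier < 0)) return("multiplier must be >= 0")
    TRUE
  })
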