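#' Construct an acquisition spec
#'
#' @param sampleRate digitisation rate (Hz); default 20 kHz.
#' @param filterCutoff low-pass -3 dB cutoff (Hz); default 800 Hz; NA
#'   disables filtering.
#' @param openCurrent,closedCurrent conductance levels (pA). The absolute
#'   scale is arbitrary for all analyses here; 30/0 pA gives a realistic
#'   contrast.
#' @param noiseSd additive Gaussian baseline noise SD (pA); default 3 pA
#'   (SNR 10 against the default amplitude).
#' @return An \linkS4class{AcquisitionSpec}.
#' @export
AcquisitionSpec <- function(sampleRate = 20000, filterCutoff = 800,
    openCurrent = 30, closedCurrent = 0, noiseSd = 3) {
  new("AcquisitionSpec", sampleRate = sampleRate,
    filterCutoff = as.numeric(filterCutoff), openCurrent = openCurrent,
    closedCurrent = closedCurrent, noiseSd = noiseSd)
}

# Gaussian low-pass FIR kernel for a -3 dB cutoff fc at sampling rate fs.
# The time-domain SD giving |H(fc)|^2 = 1/2 is sigma_t = 0.1325/fc
# (sigma_t = sqrt(ln 2) / (2 pi fc)).
.gauss_kernel <- function(fs, fc) {
  sigma <- 0.13257 * fs / fc
  half <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k / sum(k)
}

.gauss_filter <- function(x, fs, fc) {
  k <- .gauss_kernel(fs, fc)
  half <- (length(k) - 1L) / 2L
  # replicate-pad edges so the filter is DC-preserving at the boundaries
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(half + 1L):(half + length(x))])
}

#' Peak amplitude of a filtered rectangular pulse
#'
#' For a Gaussian low-pass filter with -3 dB cutoff \code{fc}, a
#' rectangular pulse of duration \code{width} reaches a peak fraction
#' \code{erf(width / (2 sqrt(2) sigma_t))} of its full amplitude. Pulses
#' shorter than about \code{0.179 / fc} stay below the 50% threshold and
#' are lost to idealization -- the classical dead time of half-amplitude
#' analysis.
#'
#' @param width pulse duration (s).
#' @param fc filter -3 dB cutoff (Hz).
#' @return peak amplitude as a fraction of the step amplitude.
#' @export
pulsePeakAmplitude <- function(width, fc) {
  sigma_t <- 0.13257 / fc
  z <- width / (2 * sqrt(2) * sigma_t)
  2 * stats::pnorm(z * sqrt(2)) - 1  # erf(z)
}

#' Render a state path as a realistic current recording
#'
#' Converts the gate coordinate of a \linkS4class{StatePath} into a
#' two-level current, applies a Gaussian low-pass filter at the spec's
#' -3 dB cutoff, and adds Gaussian baseline noise. The generating path is
#' carried along unmodified as ground truth.
#'
#' @param path a \linkS4class{StatePath}.
#' @param spec an \linkS4class{AcquisitionSpec}.
#' @param seed RNG seed for the noise, or NULL.
#' @return A \linkS4class{CurrentTrace}.
#' @examples
#' p <- simulatePath(defaultParameters(), constantProtocol(), 5, seed = 1)
#' tr <- synthesizeTrace(p, AcquisitionSpec(), seed = 2)
#' @export
synthesizeTrace <- function(path, spec = AcquisitionSpec(), seed = NULL) {
  stopifnot(is(path, "StatePath"), is(spec, "AcquisitionSpec"))
  if (!is.na(spec@filterCutoff) && path@duration < 2 / spec@filterCutoff)
    stop("path duration must be at least 2 / filterCutoff")
  if (!is.null(seed)) set.seed(seed)
  n <- round(path@duration * spec@sampleRate)
  tt <- (seq_len(n) - 1) / spec@sampleRate
  gate <- path@gate[findInterval(tt, path@times)]
  x <- spec@closedCurrent +
    (spec@openCurrent - spec@closedCurrent) * gate
  if (!is.na(spec@filterCutoff))
    x <- .gauss_filter(x, spec@sampleRate, spec@filterCutoff)
  if (spec@noiseSd > 0) x <- x + rnorm(n, 0, spec@noiseSd)
  new("CurrentTrace", samples = x, spec = spec, truth = path)
}

#' Draw dwell times from a (left-truncated) exponential mixture
#'
#' Samples \code{n} dwells from the mixture with time constants \code{taus}
#' and mixing fractions \code{areas}, optionally left-truncated at
#' \code{cutoff} (mimicking the exclusion of unresolved short events).
#' Truncation is exact: the component is drawn with probability
#' proportional to \code{areas * exp(-cutoff / taus)} and the dwell is
#' \code{cutoff} plus a fresh exponential (memorylessness).
#'
#' @param taus component time constants (ms).
#' @param areas mixing fractions (pre-truncation), summing to 1.
#' @param n number of draws.
#' @param cutoff left-truncation point (ms); 0 for none.
#' @param seed RNG seed, or NULL.
#' @return numeric vector of dwell times (ms).
#' @examples
#' d <- generateDwellSample(c(1, 10), c(0.5, 0.5), 1000, seed = 1)
#' @export
generateDwellSample <- function(taus, areas, n, cutoff = 0, seed = NULL) {
  if (length(taus) != length(areas) || !length(taus))
    stop("taus and areas must be non-empty and of equal length")
  if (any(taus <= 0)) stop("taus must be > 0")
  if (any(areas < 0) || abs(sum(areas) - 1) > 1e-9)
    stop("areas must be non-negative and sum to 1")
  if (n <= 0) stop("n must be > 0")
  if (cutoff < 0) stop("cutoff must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  w <- areas * exp(-cutoff / taus)
  comp <- sample.int(length(taus), n, replace = TRUE, prob = w / sum(w))
  cutoff + rexp(n, rate = 1 / taus[comp])
}

#' Modal-gating specification
#' @param dwellMean mean dwell time in each mode (s).
#' @param multiplier per-mode opening-rate multipliers.
#' @return A \linkS4class{ModalSpec}.
#' @export
ModalSpec <- function(dwellMean, multiplier) {
  new("ModalSpec", dwellMean = as.numeric(dwellMean),
    multiplier = as.numeric(multiplier))
}

#' Opening-rate multiplier that yields a target in-mode Po
#'
#' Convenience inverse of the two-state relation
#' \code{Po = m kO / (m kO + kC)} for the zero-ligand opening rate.
#'
#' @param params a \linkS4class{KineticParameters} object.
#' @param po target open probability within the mode.
#' @return multiplier to put in a \linkS4class{ModalSpec}.
#' @export
modalMultiplierForPo <- function(params, po) {
  kO0 <- openingRate(params, 0)@kO
  (po / (1 - po)) * params@kC / kO0
}

#' Simulate a path with slow modal gating
#'
#' Superimposes a slow hidden Markov modulation on the gating process: the
#' channel switches among modes (exponential dwells, uniform jumps to the
#' other modes) and within mode m all opening rates are multiplied by
#' \code{modal@multiplier[m]}. Produces the characteristic 10-second-scale
#' wandering of windowed Po seen in long single-channel records. With a
#' single mode of multiplier 1 this reduces to \code{\link{simulatePath}}.
#'
#' @inheritParams simulatePath
#' @param modal a \linkS4class{ModalSpec} (>= 1 mode).
#' @param conc constant ligand concentrations for the whole path.
#' @return A \linkS4class{StatePath}; the mode timeline is stored in
#'   \code{metadata$modes} as a data.frame \code{(start, mode)}.
#' @export
generateModalPath <- function(params, modal, duration, seed = NULL,
    conc = LigandConcentrations(0, 0), form = c("saturating", "linear")) {
  form <- match.arg(form)
  stopifnot(is(modal, "ModalSpec"))
  if (duration <= 0) stop("duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  nmodes <- length(modal@dwellMean)

  # mode timeline
  mode_start <- 0; mode_id <- sample.int(nmodes, 1)
  t <- rexp(1, 1 / modal@dwellMean[mode_id[1]])
  while (t < duration && nmodes > 1) {
    others <- setdiff(seq_len(nmodes), tail(mode_id, 1))
    nxt <- if (length(others) == 1L) others else sample(others, 1)
    mode_start <- c(mode_start, t)
    mode_id <- c(mode_id, nxt)
    t <- t + rexp(1, 1 / modal@dwellMean[nxt])
  }

  protocol <- constantProtocol(conc@fkbp12, conc@fkbp12_6)
  rates <- unname(parameterVector(params)[c("k1", "k_m1", "k2", "k_m2",
    "k3", "k_m3", "k4", "k_m4", "kC")])
  kO_occ <- .branch_kO(params, form)
  st <- .resolve_init(params, protocol, "equilibrium", form)

  times <- 0; occ <- st[1]; gate <- st[2]
  seg_end <- c(mode_start[-1], duration)
  for (i in seq_along(mode_id)) {
    seg_dur <- seg_end[i] - mode_start[i]
    if (seg_dur <= 0) next
    res <- gillespie_core(rates, kO_occ * modal@multiplier[mode_id[i]],
      0, conc@fkbp12, conc@fkbp12_6, seg_dur, seg_dur,
      tail(occ, 1), tail(gate, 1), TRUE)
    if (length(res$times) > 1L) {
      times <- c(times, res$times[-1] + mode_start[i])
      occ <- c(occ, res$occupancy[-1])
      gate <- c(gate, res$gate[-1])
    }
  }
  new("StatePath", times = times, occupancy = as.integer(occ) + 1L,
    gate = as.integer(gate), duration = duration,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    metadata = list(modes = data.frame(start = mode_start, mode = mode_id)))
}

setMethod("show", "AcquisitionSpec", function(object) {
  cat(sprintf(
    "AcquisitionSpec: %g Hz sampling, %s Hz low-pass, levels %g/%g pA, noise SD %g pA\n",
    object@sampleRate,
    if (is.na(object@filterCutoff)) "no" else format(object@filterCutoff),
    object@closedCurrent, object@openCurrent, object@noiseSd))
})

setMethod("show", "CurrentTrace", function(object) {
  dur <- length(object@samples) / object@spec@sampleRate
  cat(sprintf("CurrentTrace: %d samples (%g s at %g Hz)%s\n",
    length(object@samples), dur, object@spec@sampleRate,
    if (is.null(object@truth)) "" else ", truth attached"))
})

#' Write / read a current trace as CSV with a JSON sidecar
#'
#' The CSV holds a single \code{current_pA} column; the sidecar
#' (\code{<path>.json}) records the acquisition metadata. The ground-truth
#' path, if any, is not serialized.
#'
#' @param trace a \linkS4class{CurrentTrace}.
#' @param path CSV file path.
#' @export
writeTrace <- function(trace, path) {
  write.csv(data.frame(current_pA = trace@samples), path, row.names = FALSE)
  meta <- list(sample_rate_hz = trace@spec@sampleRate,
    filter_cutoff_hz = trace@spec@filterCutoff,
    open_current_pa = trace@spec@openCurrent,
    closed_current_pa = trace@spec@closedCurrent,
    noise_sd_pa = trace@spec@noiseSd)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  x <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- AcquisitionSpec(sampleRate = meta$sample_rate_hz,
    filterCutoff = if (is.null(meta$filter_cutoff_hz)) NA
                   else meta$filter_cutoff_hz,
    openCurrent = meta$open_current_pa,
    closedCurrent = meta$closed_current_pa, noiseSd = meta$noise_sd_pa)
  new("CurrentTrace", samples = x$current_pA, spec = spec, truth = NULL)
}
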