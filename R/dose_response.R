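#' Concentration-response curve of equilibrium open probability
#'
#' Sweeps one ligand over a concentration grid with the other held fixed.
#' Analytic mode evaluates the closed-form equilibrium Po; Monte Carlo mode
#' averages the steady-state Po over \code{nTrials} Gillespie trials per
#' concentration (each trial initialized from the stationary occupancy law,
#' see \code{\link{simulatePath}}), reporting the SE across trials.
#'
#' @param params a \linkS4class{KineticParameters} object.
#' @param ligand which ligand to vary: "fkbp12" or "fkbp12_6".
#' @param grid concentration grid (uM), strictly increasing.
#' @param fixedOther fixed concentration of the other ligand (uM).
#' @param mode "analytic" or "monte_carlo".
#' @param nTrials Monte Carlo trials per concentration.
#' @param duration simulated time per trial (s).
#' @param window Po window (s) within each trial.
#' @param seed master seed (per-concentration/trial seeds derived from it).
#' @param form opening-rate form, see \code{\link{openingRate}}.
#' @return A \linkS4class{DoseResponseCurve}.
#' @examples
#' grid <- 10^seq(-9, -3, length.out = 13)  # 1e-3 .. 1e3 pM, in uM
#' doseResponseCurve(defaultParameters(), "fkbp12", grid)
#' @export
doseResponseCurve <- function(params, ligand = c("fkbp12", "fkbp12_6"),
    grid, fixedOther = 0, mode = c("analytic", "monte_carlo"),
    nTrials = 100, duration = 60, window = 10, seed = NULL,
    form = c("saturating", "linear")) {
  ligand <- match.arg(ligand)
  mode <- match.arg(mode)
  form <- match.arg(form)
  if (!length(grid)) stop("grid must be non-empty")
  conc_of <- function(g) {
    if (ligand == "fkbp12") LigandConcentrations(g, fixedOther)
    else LigandConcentrations(fixedOther, g)
  }
  if (mode == "analytic") {
    po <- vapply(grid, function(g) equilibriumPo(params, conc_of(g), form),
      numeric(1))
    se <- rep(NA_real_, length(grid))
  } else {
    if (!is.null(seed)) set.seed(seed)
    point_seed <- sample.int(2147483646L, length(grid))
    po <- se <- numeric(length(grid))
    for (i in seq_along(grid)) {
      cc <- conc_of(grid[i])
      pts <- trialAveragePo(params,
        constantProtocol(cc@fkbp12, cc@fkbp12_6), duration, nTrials,
        window, seed = point_seed[i], init = "equilibrium", form = form)
      ss <- steadyStatePo(pts, fraction = 1)
      po[i] <- ss$po; se[i] <- ss$se
    }
  }
  new("DoseResponseCurve", concentrations = as.numeric(grid), po = po,
    se = se, mode = mode, ligand = ligand, fixedOther = fixedOther)
}

#' Competition curve: Po versus antagonist at fixed agonist
#'
#' Equilibrium (or Monte Carlo) Po as FKBP12.6 is varied while FKBP12 is
#' held at a fixed (typically physiological, 3 uM) level. Because the
#' FKBP12.6-bound branch has near-zero efficacy, Po falls monotonically as
#' FKBP12.6 displaces FKBP12 from the shared site.
#'
#' @inheritParams doseResponseCurve
#' @param fkbp12Fixed fixed FKBP12 concentration (uM).
#' @param grid FKBP12.6 concentration grid (uM).
#' @return A \linkS4class{DoseResponseCurve} (ligand = "fkbp12_6").
#' @export
competitionCurve <- function(params, fkbp12Fixed = 3, grid,
    mode = c("analytic", "monte_carlo"), nTrials = 100, duration = 60,
    window = 10, seed = NULL, form = c("saturating", "linear")) {
  if (fkbp12Fixed < 0) stop("fkbp12Fixed must be >= 0")
  doseResponseCurve(params, "fkbp12_6", grid, fixedOther = fkbp12Fixed,
    mode = match.arg(mode), nTrials = nTrials, duration = duration,
    window = window, seed = seed, form = match.arg(form))
}

#' Four-parameter log-logistic (Hill) fit and EC50
#'
#' Fits \deqn{Po(c) = floor + (ceiling - floor) /
#'   (1 + 10^{hill (\log_{10} EC_{50} - \log_{10} c)})}
#' to a concentration-response curve by least squares on log10
#' concentration (floor bounded below at 0, Hill slope free). The EC50 is
#' the concentration at half of the fitted span (ceiling - floor), i.e.
#' half of the response rise above its fitted baseline. Zero
#' concentrations cannot be placed on the log axis and are dropped with a
#' message; a flat or non-sigmoid curve raises an error rather than
#' extrapolating.
#'
#' @param curve a \linkS4class{DoseResponseCurve}.
#' @param minSpan smallest fitted-data span (max - min Po) accepted as a
#'   genuine sigmoid.
#' @return An \linkS4class{Ec50Fit}; \code{ec50} is in the grid's units
#'   (uM).
#' @examples
#' grid <- 10^seq(-9, -3, length.out = 13)
#' cur <- doseResponseCurve(defaultParameters(), "fkbp12", grid)
#' estimateEc50(cur)
#' @export
estimateEc50 <- function(curve, minSpan = 1e-3) {
  stopifnot(is(curve, "DoseResponseCurve"))
  keep <- curve@concentrations > 0
  if (!all(keep))
    message("dropping ", sum(!keep), " zero-concentration point(s)")
  conc <- curve@concentrations[keep]
  po <- curve@po[keep]
  if (length(conc) < 5L)
    stop("need at least 5 positive-concentration points for a 4-parameter fit")
  span <- max(po) - min(po)
  if (span < minSpan)
    stop("curve is flat (span ", signif(span, 3),
      "); cannot estimate an EC50")
  lc <- log10(conc)
  if (max(lc) - min(lc) < 1)
    stop("grid must span at least one decade around the half-rise")
  mid <- min(po) + span / 2
  l50 <- approx(po, lc, xout = mid, ties = mean)$y
  if (!is.finite(l50)) l50 <- mean(range(lc))
  df <- data.frame(lc = lc, po = po)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      po ~ fl + (ce - fl) / (1 + 10^(h * (l50f - lc))),
      data = df,
      start = list(fl = max(min(po), 1e-6), ce = max(po), h = 1,
        l50f = l50),
      lower = c(fl = 0, ce = 0, h = 1e-3, l50f = min(lc) - 3),
      upper = c(fl = 1, ce = 1, h = 20, l50f = max(lc) + 3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("log-logistic fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf[["l50f"]] < min(lc) - 1 || cf[["l50f"]] > max(lc) + 1)
    stop("fitted EC50 lies outside the sampled concentration range; ",
      "the curve does not resolve its half-rise")
  new("Ec50Fit", ec50 = 10^cf[["l50f"]], hill = cf[["h"]],
    floor = cf[["fl"]], ceiling = cf[["ce"]],
    rss = sum(stats::resid(fit)^2))
}

setMethod("show", "DoseResponseCurve", function(object) {
  cat(sprintf(
    "DoseResponseCurve (%s): %s varied over %d points, other ligand fixed at %g uM\n",
    object@mode, object@ligand, length(object@concentrations),
    object@fixedOther))
  cat(sprintf("  Po range %.4g .. %.4g\n", min(object@po), max(object@po)))
})

setMethod("show", "Ec50Fit", function(object) {
  cat(sprintf(
    "Ec50Fit: EC50 = %.4g uM (%.4g pM), Hill = %.3g, span %.4g -> %.4g, rss = %.3g\n",
    object@ec50, object@ec50 * 1e6, object@hill, object@floor,
    object@ceiling, object@rss))
})

#' @rdname asDataFrame
#' @export
curveAsDataFrame <- function(x) {
  stopifnot(is(x, "DoseResponseCurve"))
  out <- data.frame(concentration_uM = x@concentrations, po = x@po,
    se = x@se)
  names(out)[1] <- if (x@ligand == "fkbp12") "fkbp12_uM" else "fkbp12_6_uM"
  out
}

#' Serialize an EC50 fit to JSON
#' @param fit an \linkS4class{Ec50Fit}.
#' @param path output path.
#' @export
writeEc50Fit <- function(fit, path) {
  jsonlite::write_json(list(ec50_uM = fit@ec50, ec50_pM = fit@ec50 * 1e6,
    hill = fit@hill, floor = fit@floor, ceiling = fit@ceiling,
    rss = fit@rss), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
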