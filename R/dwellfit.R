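# Negative log-likelihood machinery for left-truncated exponential mixtures.
#
# Each component density is renormalized over [cutoff, Inf):
#   f_i(t) = (1/tau_i) exp(-(t - cutoff)/tau_i),   t >= cutoff,
# so on the shifted scale s = t - cutoff the model is a plain exponential
# mixture and the EM updates are exact:
#   resp_ij  = a_j f_j(s_i) / sum_k a_k f_k(s_i)
#   a_j      = mean_i resp_ij
#   tau_j    = sum_i resp_ij s_i / sum_i resp_ij
# This renormalization is what makes tau estimates unbiased in the presence
# of the short-event exclusion.

.mix_loglik <- function(s, taus, areas) {
  dens <- vapply(seq_along(taus), function(j)
    areas[j] * exp(-s / taus[j]) / taus[j], numeric(length(s)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(s))
  sum(log(pmax(rowSums(dens), 1e-300)))
}

.em_run <- function(s, taus, areas, maxIter, tol) {
  n <- length(s)
  k <- length(taus)
  ll_old <- -Inf
  for (iter in seq_len(maxIter)) {
    dens <- vapply(seq_len(k), function(j)
      areas[j] * exp(-s / taus[j]) / taus[j], numeric(n))
    if (is.null(dim(dens))) dens <- matrix(dens, nrow = n)
    rs <- pmax(rowSums(dens), 1e-300)
    ll <- sum(log(rs))
    if (is.finite(ll_old) && ll - ll_old < tol * (abs(ll) + 1))
      return(list(taus = taus, areas = areas, loglik = ll,
        converged = TRUE, iter = iter))
    ll_old <- ll
    resp <- dens / rs
    wsum <- colSums(resp)
    areas <- pmax(wsum / n, 1e-12)
    areas <- areas / sum(areas)
    taus <- pmax(colSums(resp * s) / pmax(wsum, 1e-300), 1e-9)
  }
  list(taus = taus, areas = areas, loglik = ll_old, converged = FALSE,
    iter = maxIter)
}

# deterministic multi-start grid: geometric tau ladders spanning the sample
# quantile range, shifted by a spread of scale factors
.em_starts <- function(s, k, nStarts) {
  qlo <- max(quantile(s, 0.05), max(min(s[s > 0], na.rm = TRUE), 1e-6))
  qhi <- max(quantile(s, 0.95), qlo * 1.01)
  fac <- c(1, 0.5, 2, 0.25, 4, 0.75, 1.5, 3, 0.1, 10)[seq_len(nStarts)]
  lapply(fac, function(f) {
    taus <- if (k == 1) mean(s) * f
            else exp(seq(log(qlo * f), log(qhi * f), length.out = k))
    list(taus = taus, areas = rep(1 / k, k))
  })
}

#' Maximum-likelihood exponential-mixture fit of dwell times
#'
#' Fits a k-component exponential mixture to a sample of dwell durations by
#' maximum likelihood, correcting for left truncation at \code{cutoff} by
#' renormalizing each component density over \code{[cutoff, Inf)}. The
#' optimum is found by expectation-maximization from multiple deterministic
#' starts (short runs followed by polishing the best), which is monotone in
#' likelihood; areas live on the probability simplex by construction.
#' Components are returned sorted by time constant.
#'
#' @param dwells dwell durations (ms), all \code{>= cutoff}.
#' @param nComponents number of exponential components.
#' @param cutoff left-truncation point (ms); use the same value as the
#'   short-event exclusion applied to the sample.
#' @param nStarts number of starting points (>= 1, <= 10).
#' @param maxIter EM iteration cap per run.
#' @param tol relative log-likelihood convergence tolerance per EM step.
#' @return A \linkS4class{DwellFit}.
#' @examples
#' d <- generateDwellSample(c(1, 10), c(0.5, 0.5), 5000, seed = 1)
#' fitDwellMixture(d, 2)
#' @export
fitDwellMixture <- function(dwells, nComponents, cutoff = 0, nStarts = 8,
    maxIter = 2000, tol = 1e-8) {
  k <- as.integer(nComponents)
  if (k < 1L) stop("nComponents must be >= 1")
  if (any(!is.finite(dwells))) stop("dwells must be finite")
  if (any(dwells < cutoff))
    stop("all dwells must be >= cutoff (", cutoff, " ms)")
  n <- length(dwells)
  if (n < 10L * (2L * k - 1L))
    stop("too few dwells (", n, ") for ", k, " components; need >= ",
      10L * (2L * k - 1L))
  s <- dwells - cutoff
  # Durations measured at finite time resolution (e.g. whole samples of a
  # digitised trace) can tie exactly at the cutoff; a shifted value of 0
  # makes the mixture likelihood unbounded (a component's tau can collapse
  # onto the tie). Flooring at half the data's time quantum bounds the
  # likelihood without moving any resolvable dwell.
  su <- sort(unique(s))
  quantum <- if (length(su) > 1L) min(diff(su)) else 1e-9
  s <- pmax(s, min(quantum, stats::median(s)) / 2)

  starts <- .em_starts(s, k, min(max(nStarts, 1L), 10L))
  short <- lapply(starts, function(st)
    .em_run(s, st$taus, st$areas, maxIter = 40L, tol = tol))
  best <- short[[which.max(vapply(short, `[[`, numeric(1), "loglik"))]]
  fit <- .em_run(s, best$taus, best$areas, maxIter = maxIter, tol = tol)
  if (!fit$converged)
    stop("dwell-mixture fit failed to converge (k = ", k, ", n = ", n,
      ", loglik = ", signif(fit$loglik, 8), "); try fewer components")
  o <- order(fit$taus)
  new("DwellFit", taus = fit$taus[o], areas = fit$areas[o],
    nComponents = k, loglik = fit$loglik, nEvents = as.integer(n),
    cutoff = cutoff,
    selection = data.frame())
}

#' Mixture density of a dwell fit
#'
#' Evaluates the fitted (truncation-renormalized) probability density over
#' \code{[cutoff, Inf)}; zero below the cutoff.
#'
#' @param fit a \linkS4class{DwellFit}.
#' @param t evaluation points (ms).
#' @return density values (per ms).
#' @export
dwellDensity <- function(fit, t) {
  d <- numeric(length(t))
  ok <- t >= fit@cutoff
  for (j in seq_len(fit@nComponents))
    d[ok] <- d[ok] + fit@areas[j] *
      exp(-(t[ok] - fit@cutoff) / fit@taus[j]) / fit@taus[j]
  d
}

#' Choose the number of exponential components
#'
#' Fits 1..\code{maxComponents} mixtures and selects the component count by
#' a forward likelihood-ratio test: k+1 replaces k when twice the
#' log-likelihood gain exceeds the chi-squared critical value with 2
#' degrees of freedom (one extra time constant plus one extra area) at
#' level \code{alpha}; the search stops at the first non-significant gain.
#' BIC selection is available as an alternative. The full comparison table
#' is attached to the returned fit.
#'
#' @inheritParams fitDwellMixture
#' @param maxComponents largest component count to consider.
#' @param criterion "lrt" (default) or "bic".
#' @param alpha significance level for the likelihood-ratio test.
#' @return The selected \linkS4class{DwellFit}, with slot \code{selection}
#'   holding the comparison table (k, loglik, deviance gain, p-value, BIC).
#' @export
selectNComponents <- function(dwells, maxComponents = 4, cutoff = 0,
    criterion = c("lrt", "bic"), alpha = 0.05, nStarts = 8) {
  criterion <- match.arg(criterion)
  n <- length(dwells)
  kmax <- maxComponents
  # cap k so the events-per-parameter precondition holds
  while (kmax > 1L && n < 10L * (2L * kmax - 1L)) kmax <- kmax - 1L
  fits <- lapply(seq_len(kmax), function(k)
    fitDwellMixture(dwells, k, cutoff, nStarts = nStarts))
  ll <- vapply(fits, slot, numeric(1), "loglik")
  npar <- 2 * seq_len(kmax) - 1
  dev <- c(NA, 2 * diff(ll))
  pval <- c(NA, pchisq(pmax(dev[-1], 0), df = 2, lower.tail = FALSE))
  bic <- -2 * ll + npar * log(n)
  tab <- data.frame(nComponents = seq_len(kmax), loglik = ll,
    devianceGain = dev, pValue = pval, bic = bic)
  if (criterion == "lrt") {
    chosen <- 1L
    while (chosen < kmax && isTRUE(pval[chosen + 1L] < alpha))
      chosen <- chosen + 1L
  } else {
    chosen <- which.min(bic)
  }
  fit <- fits[[chosen]]
  fit@selection <- tab
  fit
}

setMethod("show", "DwellFit", function(object) {
  cat(sprintf(
    "DwellFit: %d exponential component(s), %d events, cutoff %g ms, loglik %.2f\n",
    object@nComponents, object@nEvents, object@cutoff, object@loglik))
  print(data.frame(tau_ms = signif(object@taus, 4),
    area = signif(object@areas, 4)), row.names = FALSE)
  if (nrow(object@selection))
    cat("  (selected from", max(object@selection$nComponents),
      "candidate counts)\n")
})

#' Serialize a dwell fit to JSON
#' @param fit a \linkS4class{DwellFit}.
#' @param path output path.
#' @export
writeDwellFit <- function(fit, path) {
  out <- list(taus_ms = fit@taus, areas = fit@areas,
    n_components = fit@nComponents, loglik = fit@loglik,
    n_events = fit@nEvents, cutoff_ms = fit@cutoff)
  if (nrow(fit@selection)) out$selection <- fit@selection
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(path)
}
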