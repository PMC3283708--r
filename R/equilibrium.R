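#' Closed-form equilibrium of the five-state FKBP-occupancy scheme
#'
#' Solves the mass-action stationary distribution of the binding scheme
#' free <-> 12 <-> 12* and free <-> 12.6 <-> 12.6* in closed form. With
#' \code{c12 = [FKBP12] k1 / k_m1}, \code{r12 = k2 / k_m2},
#' \code{c126 = [FKBP12.6] k3 / k_m3}, \code{r126 = k4 / k_m4}:
#' \deqn{x_{free} = 1 / (1 + c12 (1 + r12) + c126 (1 + r126))}
#' and the remaining states scale as \code{c12 x_free}, \code{c12 r12 x_free},
#' \code{c126 x_free}, \code{c126 r126 x_free}. The scheme is a tree, so this
#' stationary point satisfies detailed balance edge by edge. The derived
#' open-driving fraction is \code{nu = x_12* + x_12.6*}.
#'
#' @param params a \linkS4class{KineticParameters} object.
#' @param conc a \linkS4class{LigandConcentrations} object.
#' @return An \linkS4class{OccupancyDistribution}.
#' @examples
#' equilibriumOccupancy(defaultParameters(), LigandConcentrations(1, 0))
#' @export
equilibriumOccupancy <- function(params, conc) {
  stopifnot(is(params, "KineticParameters"),
    is(conc, "LigandConcentrations"))
  validObject(params); validObject(conc)
  c12 <- conc@fkbp12 * params@k1 / params@k_m1
  r12 <- params@k2 / params@k_m2
  c126 <- conc@fkbp12_6 * params@k3 / params@k_m3
  r126 <- params@k4 / params@k_m4
  xf <- 1 / (1 + c12 * (1 + r12) + c126 * (1 + r126))
  p <- c(xf, c12 * xf, c12 * r12 * xf, c126 * xf, c126 * r126 * xf)
  names(p) <- .OCC_LEVELS
  # guard against rounding drift so the class invariant holds exactly
  p <- p / sum(p)
  new("OccupancyDistribution", probs = p,
    nu = unname(p["12*"] + p["12.6*"]))
}

#' Occupancy-dependent opening rate
#'
#' Maps the open-driving fraction nu onto the opening rate of the two-state
#' C <-> O gating scheme. The default ("saturating") form,
#' \deqn{k_O = k_C (\alpha + \nu) / (1 - (\alpha + \nu)),}
#' is the unique choice for which the equilibrium open probability of the
#' gating scheme equals \code{alpha + nu}: the background activity plus the
#' probability of dwelling in an activated (open-driving) conformation. The
#' alternative "linear" form \code{k_O = k_C (alpha + nu)} (so
#' \code{Po = (alpha + nu) / (1 + alpha + nu)}) is provided for sensitivity
#' checks.
#'
#' @param params a \linkS4class{KineticParameters} object.
#' @param occ an \linkS4class{OccupancyDistribution}, or a bare numeric nu.
#' @param form "saturating" (default) or "linear".
#' @return A \linkS4class{GatingRates} object.
#' @examples
#' occ <- equilibriumOccupancy(defaultParameters(), LigandConcentrations())
#' openingRate(defaultParameters(), occ)  # Po(eq) = alpha = 0.005
#' @export
openingRate <- function(params, occ, form = c("saturating", "linear")) {
  form <- match.arg(form)
  nu <- if (is(occ, "OccupancyDistribution")) occ@nu else as.numeric(occ)
  if (!is.finite(nu) || nu < 0) stop("nu must be finite and >= 0")
  p <- params@alpha + nu
  if (form == "saturating") {
    if (p >= 1)
      stop("occupancy-driven Po saturation exceeded: alpha + nu = ", p,
        " >= 1")
    kO <- params@kC * p / (1 - p)
  } else {
    kO <- params@kC * p
  }
  new("GatingRates", kO = kO, kC = params@kC, poEq = kO / (kO + params@kC))
}

#' Equilibrium open probability at given ligand concentrations
#'
#' Convenience composition of \code{\link{equilibriumOccupancy}} and
#' \code{\link{openingRate}}: under the default opening-rate form this is
#' exactly \code{alpha + nu}.
#'
#' @inheritParams equilibriumOccupancy
#' @inheritParams openingRate
#' @return equilibrium open probability (scalar).
#' @examples
#' equilibriumPo(defaultParameters(), LigandConcentrations(0, 0))  # 0.005
#' @export
equilibriumPo <- function(params, conc, form = c("saturating", "linear")) {
  openingRate(params, equilibriumOccupancy(params, conc), form)@poEq
}

# Per-occupancy opening rates for the stochastic single channel.
#
# The analytic nu is an ensemble probability and cannot be attached to a
# single channel sample-path directly. Conditioning instead on the (slow)
# binding coordinate: while FKBP12 is bound the channel flickers between 12
# and 12* with stationary activated fraction nu12 = k2 / (k2 + k_m2), and
# correspondingly nu126 = k4 / (k4 + k_m4) for FKBP12.6; while free, 0.
# Using k_O(branch) = kO(alpha + nu_branch) makes the conditional Po of each
# branch equal alpha + nu_branch (saturating form), and since
# P(branch 12) * nu12 = x_12* etc., the occupancy-averaged Po is exactly
# alpha + nu -- the ensemble law -- while gating stays on the millisecond
# scale.
.branch_kO <- function(params, form = c("saturating", "linear")) {
  form <- match.arg(form)
  nu12 <- params@k2 / (params@k2 + params@k_m2)
  nu126 <- params@k4 / (params@k4 + params@k_m4)
  nu_occ <- c(0, nu12, nu12, nu126, nu126)
  vapply(nu_occ, function(nu) openingRate(params, nu, form)@kO, numeric(1))
}

#' Tabulate equilibrium quantities over a concentration grid
#'
#' @param params a \linkS4class{KineticParameters} object.
#' @param fkbp12,fkbp12_6 concentration vectors (uM), recycled to a common
#'   length (not crossed).
#' @param form opening-rate form, see \code{\link{openingRate}}.
#' @return data.frame with columns \code{fkbp12_uM, fkbp12_6_uM, x_free,
#'   x_12, x_12s, x_126, x_126s, nu, k_O, po} (one row per concentration
#'   pair), suitable for CSV export.
#' @export
equilibriumTable <- function(params, fkbp12, fkbp12_6 = 0,
    form = c("saturating", "linear")) {
  form <- match.arg(form)
  n <- max(length(fkbp12), length(fkbp12_6))
  fkbp12 <- rep_len(fkbp12, n)
  fkbp12_6 <- rep_len(fkbp12_6, n)
  rows <- lapply(seq_len(n), function(i) {
    occ <- equilibriumOccupancy(params,
      LigandConcentrations(fkbp12[i], fkbp12_6[i]))
    g <- openingRate(params, occ, form)
    data.frame(fkbp12_uM = fkbp12[i], fkbp12_6_uM = fkbp12_6[i],
      x_free = occ@probs[["free"]], x_12 = occ@probs[["12"]],
      x_12s = occ@probs[["12*"]], x_126 = occ@probs[["12.6"]],
      x_126s = occ@probs[["12.6*"]], nu = occ@nu, k_O = g@kO, po = g@poEq)
  })
  do.call(rbind, rows)
}
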