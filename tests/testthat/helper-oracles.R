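# Independent oracles, deliberately implemented without touching the
# package's own closed-form code paths.

# Steady state of the five-state mass-action occupancy scheme by long-time
# numerical integration of the rate equations (deSolve), started from all
# mass in the free state.
ode_stationary <- function(params, f12, f126, t_end = NULL,
    rtol = 1e-12, atol = 1e-14) {
  v <- parameterVector(params)
  deriv <- function(t, x, parms) {
    xf <- x[1]; x12 <- x[2]; x12s <- x[3]; x126 <- x[4]; x126s <- x[5]
    list(c(
      -(v["k1"] * f12 + v["k3"] * f126) * xf + v["k_m1"] * x12 +
        v["k_m3"] * x126,
      v["k1"] * f12 * xf - (v["k_m1"] + v["k2"]) * x12 + v["k_m2"] * x12s,
      v["k2"] * x12 - v["k_m2"] * x12s,
      v["k3"] * f126 * xf - (v["k_m3"] + v["k4"]) * x126 +
        v["k_m4"] * x126s,
      v["k4"] * x126 - v["k_m4"] * x126s))
  }
  if (is.null(t_end)) {
    # start from ~100 relaxation times of the slowest first-order step and
    # keep doubling until the flow has genuinely stalled
    active <- c(v["k_m2"], v["k_m4"], v["k2"], v["k_m1"], v["k4"],
      v["k_m3"], v["k1"] * f12, v["k3"] * f126)
    t_end <- 100 / min(active[active > 0])
  }
  x <- c(1, 0, 0, 0, 0)
  for (i in 1:60) {
    sol <- deSolve::lsoda(x, c(0, t_end), deriv, parms = NULL,
      rtol = rtol, atol = atol)
    x <- as.numeric(sol[nrow(sol), -1])
    if (max(abs(unlist(deriv(0, x, NULL)))) < 1e-13) break
    t_end <- t_end * 4
  }
  names(x) <- c("free", "12", "12*", "12.6", "12.6*")
  x
}

ode_nu <- function(params, f12, f126, ...) {
  x <- ode_stationary(params, f12, f126, ...)
  unname(x["12*"] + x["12.6*"])
}

# Closed-form half-max of the equilibrium binding curve for the varied
# agonist (other ligand absent): nu(c) = nu_max * c / (c + K) with
# K = (k_m1/k1) / (1 + k2/k_m2); derived by hand from the binding algebra.
algebra_half_max_uM <- function(params) {
  v <- parameterVector(params)
  (v[["k_m1"]] / v[["k1"]]) / (1 + v[["k2"]] / v[["k_m2"]])
}

# Random moderate-rate parameter/concentration draws for property tests:
# all first-order rates O(0.01..100) so ODE integration and CTMC mixing
# stay fast.
rand_params <- function() {
  r <- function(lo, hi) 10^runif(1, log10(lo), log10(hi))
  KineticParameters(
    k1 = r(0.1, 100), k_m1 = r(0.01, 10),
    k2 = r(0.01, 10), k_m2 = r(0.01, 10),
    k3 = r(0.1, 100), k_m3 = r(0.01, 10),
    k4 = r(0.01, 10), k_m4 = r(0.01, 10),
    kC = r(50, 1000), alpha = runif(1, 0.002, 0.05))
}

# as rand_params, but with conformational equilibria bounded so the
# branch-conditional Po drive alpha + nu_branch stays well below 1 (the
# saturating opening-rate law requires it)
rand_sim_params <- function() {
  repeat {
    p <- rand_params()
    nu12 <- p@k2 / (p@k2 + p@k_m2)
    nu126 <- p@k4 / (p@k4 + p@k_m4)
    if (p@alpha + max(nu12, nu126) < 0.85) return(p)
  }
}

rand_conc <- function() {
  LigandConcentrations(10^runif(1, -3, 1), 10^runif(1, -3, 1))
}

# log-likelihood of a left-truncated exponential mixture, written
# independently of the package's fitting code
mixture_loglik <- function(d, taus, areas, cutoff = 0) {
  s <- d - cutoff
  dens <- sapply(seq_along(taus), function(j)
    areas[j] * exp(-s / taus[j]) / taus[j])
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(s))
  sum(log(rowSums(dens)))
}
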