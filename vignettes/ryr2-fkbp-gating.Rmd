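---
title: "Modelling RyR2 gating under FKBP12/FKBP12.6 regulation"
author: "RyRgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling RyR2 gating under FKBP12/FKBP12.6 regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RyRgate)
```

## The model

The cardiac ryanodine receptor (RyR2) releases Ca²⁺ from the sarcoplasmic
reticulum, and its open probability (Po) is modulated by the FK-binding
proteins FKBP12 and FKBP12.6, which compete for a shared binding site.
RyRgate implements a minimal kinetic description of this regulation as a
continuous-time Markov chain with two coupled coordinates:

1. **Occupancy** — five states: FKBP-free, FKBP12-bound (`12`), the
   activated FKBP12-bound conformation (`12*`), FKBP12.6-bound (`12.6`),
   and its (nearly silent) activated conformation (`12.6*`). Binding obeys
   mass action at the cytosolic ligand concentrations; each binding step is
   followed by a reversible conformational step that changes the channel's
   Ca²⁺ sensitivity.
2. **Gating** — the usual two-state C ⇌ O scheme with opening rate
   \(k_O\) and closing rate \(k_C\).

The tunable parameters (all strictly positive) are:

| parameter | meaning | unit | default |
|---|---|---|---|
| `k1`, `k_m1` | FKBP12 association / dissociation | µM⁻¹s⁻¹, s⁻¹ | 29, 6.11×10⁻⁶ |
| `k2`, `k_m2` | conformational step, FKBP12 branch | s⁻¹ | 0.03, 0.18 |
| `k3`, `k_m3` | FKBP12.6 association / dissociation | µM⁻¹s⁻¹, s⁻¹ | 3.3×10⁵, 4.2×10⁻⁴ |
| `k4`, `k_m4` | conformational step, FKBP12.6 branch | s⁻¹ | 0.001, 0.25 |
| `kC` | channel closing rate | s⁻¹ | 480 |
| `alpha` | spontaneous background activity | – | 0.005 |

The defaults (shipped in `inst/extdata/default_params.yaml`) make FKBP12 a
high-affinity **partial agonist** — binding is essentially irreversible on
the hour scale (Kd ≈ 0.21 pM) and the activated fraction of the bound
branch is \(k_2/(k_2+k_{-2}) = 1/7\) — and FKBP12.6 a high-affinity,
near-zero-efficacy **competitor** (\(k_4/(k_4+k_{-4}) \approx 0.004\)).
Cytosolic Ca²⁺ (and every other modulator) is held fixed; its influence is
folded into `alpha` and the conformational rates. Concentrations are
micromolar throughout; `asMicromolar()` converts from pM/nM.

### Equilibrium occupancy

Because the occupancy scheme is a tree, its stationary distribution is a
closed form. With \(c_{12} = [\mathrm{FKBP12}] k_1/k_{-1}\),
\(r_{12} = k_2/k_{-2}\), and similarly \(c_{126}, r_{126}\),

\[
x_\mathrm{free} = \frac{1}{1 + c_{12}(1+r_{12}) + c_{126}(1+r_{126})},
\qquad
x_{12} = c_{12}\,x_\mathrm{free},\; x_{12^*} = c_{12} r_{12}\,x_\mathrm{free},\;\ldots
\]

and the stationary point satisfies detailed balance on every edge
(`equilibriumOccupancy()`; tested against long-time integration of the
mass-action rate equations). The **open-driving fraction** is
\(\nu = x_{12^*} + x_{12.6^*}\).

### The opening-rate law

The model stipulates that equilibrium Po equals the background activity
plus the probability of dwelling in an activated conformation,
\(P_o = \alpha + \nu\). For the two-state gating scheme this fixes the
opening rate uniquely:

\[
k_O = k_C\,\frac{\alpha+\nu}{1-(\alpha+\nu)} .
\]

This "saturating" form is the package default. A "linear" alternative,
\(k_O = k_C(\alpha+\nu)\) (giving \(P_o = (\alpha+\nu)/(1+\alpha+\nu)\)),
is selectable everywhere via `form = "linear"` for sensitivity analysis.
Since \(\nu \le \max(r_{12},r_{126})/(1+\max(r_{12},r_{126}))\) is small
for the default rates, \(\alpha + \nu\) stays far from 1 and the law is
well defined; `openingRate()` raises a domain error if a parameter set
drives \(\alpha+\nu \ge 1\).

### Attaching the ensemble law to a single stochastic channel

\(\nu\) is an ensemble probability; a single channel is, at any instant,
in one definite occupancy state. A naive per-state rule ("\(\nu = 1\) in
the starred states") is infeasible: no conditional two-level Po can exceed
1, yet \(\alpha + 1 > 1\). RyRgate instead conditions on the **binding
branch**, which is the genuinely slow coordinate (unbinding takes hours,
conformational flicker tens of seconds, gating milliseconds): while
FKBP12 is bound the channel opens at the rate implied by
\(\alpha + k_2/(k_2+k_{-2})\), while FKBP12.6 is bound at
\(\alpha + k_4/(k_4+k_{-4})\), and while free at \(\alpha\). Because
\(P(\text{12 branch})\cdot r_{12}/(1+r_{12}) = x_{12^*}\) (and likewise
for 12.6), the occupancy-averaged Po of this construction equals
\(\alpha+\nu\) **exactly** at equilibrium, while open dwell times keep
their millisecond scale (mean \(1/k_C\)). Both properties are tested.

### Stochastic simulation and steady-state protocol

`simulatePath()` draws exact trajectories of the joint 10-state chain with
the Gillespie direct method; piecewise-constant concentration protocols
(`ConcentrationProtocol`) are handled by truncating the pending waiting
time at each segment boundary and re-drawing, which is exact by
memorylessness. `trialAveragePo()` averages windowed Po over independent
trials whose seeds are spawned deterministically from one master seed.

Occupancy equilibrates over \(\sim 1/k_{-1} \approx 1.6\times10^5\) s, far
beyond any reasonable simulated record, so steady-state estimates
initialize each trial from the analytic stationary occupancy (and the
corresponding stationary gate). Each trial is then an unbiased draw of the
stationary process and a trial average over 100 channels estimates the
equilibrium Po without burn-in. One consequence worth knowing: a 60 s
trial never leaves its initial binding branch, so near the half-maximal
concentration the trial-to-trial spread is dominated by the binomial
branch draw, not by gating noise — the Monte Carlo error model in the
package's tests accounts for this.

Default problem sizes — 100 trials of 60 s per concentration for
dose–response work, 600 s runs (last 50% harvested, configurable via
`steadyStatePo(fraction=)`) for background-activity estimates, 1200 s
(20 min, the span of a typical bilayer experiment) for sequential-addition
protocols — resolve the quantities of interest to within a few percent
while keeping a full analysis in the order of seconds.

## Concentration–response and EC50

`doseResponseCurve()` sweeps one ligand (analytically or by Monte Carlo);
`estimateEc50()` fits a four-parameter log-logistic (Hill) curve on log₁₀
concentration by least squares (floor bounded at 0, slope free), and
reports the concentration at half of the fitted span — i.e. half of the
Po **increase** above the fitted baseline, matching how single-channel
potency is conventionally plotted. Flat or half-rise-unresolved curves
raise errors rather than extrapolating. For the default parameters the
analytic curve is exactly Hill-slope-1 with half-max at

\[
\mathrm{EC}_{50} = \frac{k_{-1}/k_1}{1+k_2/k_{-2}} \approx 0.18\ \mathrm{pM},
\]

and the stochastic pipeline (100 trials per point, 13-point decade grid)
recovers a sub-picomolar value scattered around it. `competitionCurve()`
produces the mirror-image prediction: at a fixed physiological 3 µM
FKBP12, equilibrium Po falls monotonically as FKBP12.6 rises, because the
near-silent competitor displaces the partial agonist from the shared site.

Kinetics, not equilibrium, dominate experiment-length records: whichever
protein binds first rules a 20-minute observation window
(`simulateAntagonismProtocol()`, `simulateWashout()`), since both
dissociation rates are of the order of minutes to hours. The package
reproduces both signatures: pre-applied 200 nM FKBP12.6 keeps Po below
0.05 despite 1 µM FKBP12, and FKBP12-activated channels stay active
through a 9-minute washout and after FKBP12.6 addition.

## The synthetic recording generator

`synthesizeTrace()` emulates the acquisition chain of a planar-bilayer
experiment: the gate coordinate becomes a two-level current (defaults
0/30 pA — the absolute scale is arbitrary for every analysis here), passed
through a Gaussian low-pass filter parameterized by its −3 dB cutoff
(default 800 Hz; time-domain SD \(\sigma_t = \sqrt{\ln 2}/(2\pi f_c)
\approx 0.1325/f_c\)), sampled at 20 kHz, with additive white Gaussian
baseline noise (default SD 3 pA, SNR 10). The Gaussian family matches the
−3 dB characterization of typical analog chains and has a clean
step-response theory: a rectangular pulse of width \(w\) peaks at
\(\operatorname{erf}(w/(2\sqrt2\,\sigma_t))\) of full amplitude
(`pulsePeakAmplitude()`), so events shorter than \(\approx 0.179/f_c\)
(≈ 0.22 ms at 800 Hz) never reach the 50% threshold — the classical dead
time of half-amplitude idealization, reproduced numerically in the tests.

`generateModalPath()` adds the slow modal gating conspicuous in long RyR2
records: a hidden Markov modulation that multiplies the opening rate
mode-by-mode (exponential mode dwells, default tens of seconds), producing
10-second-window Po that wanders between mode levels.
`generateDwellSample()` draws from exponential mixtures with exact left
truncation for testing the fitting chain in isolation.

What the generator deliberately does **not** emulate: baseline drift,
capacitance transients, 50/60 Hz pickup, subconductance levels, or
multi-channel superposition. Tests passing on this synthetic material
therefore validate the analysis algorithms under the model's own
assumptions — idealization robustness to correlated noise or drifting
baselines in real recordings is out of scope.

## Single-channel analysis chain

* `idealizeThreshold50()` — half-amplitude idealization. Levels are taken
  from the caller or estimated by a two-class k-means split of the
  amplitude histogram; estimation refuses (rather than guessing) when the
  fitted levels are separated by less than 3.5 pooled within-class SDs — a
  pure-Gaussian histogram splits at ≈ 2.65, so unimodal traces fail
  loudly. Assumes at most one channel in the record.
* `computePo()` — whole-record or windowed Po; whole-record estimates
  from under 3 min of data carry a warning. Windows without transitions
  inherit the spanning state.
* `extractDwells()` — dwell durations (ms) of one conductance class with
  the sub-millisecond exclusion (default 1 ms). Excluded events are
  *dropped*, not merged; `merge = TRUE` optionally coalesces across
  removed gaps for users who prefer that convention.
* `fitDwellMixture()` — maximum-likelihood exponential-mixture fitting
  with truncation correction: each component density is renormalized over
  \([\text{cutoff}, \infty)\), which on the shifted scale
  \(s = t - \text{cutoff}\) is again a plain exponential mixture. The
  areas therefore refer to the *observed* (truncated) event population.
  The optimum is found by EM — with this parameterization the M-steps are
  exact and every step increases the likelihood — from eight deterministic
  starts (geometric τ ladders spanning the sample quantiles, short runs,
  then the best start polished to convergence at relative tolerance 1e-8).
  Two numerical guards matter in practice: τ estimates are floored at
  1e-9 ms, and shifted dwells are floored at half the smallest distinct
  spacing in the sample, because durations quantized by the sampling
  interval can tie exactly at the cutoff and would otherwise make the
  likelihood unbounded (a component collapsing onto the tie).
* `selectNComponents()` — forward likelihood-ratio selection: k+1 beats k
  when twice the log-likelihood gain exceeds \(\chi^2_{2,0.95}\) (two
  parameters per added component); the scan stops at the first
  non-significant gain. BIC is available as an alternative
  (`criterion = "bic"`); the full comparison table rides along in the
  returned fit. On synthetic control-like material (three closed
  components spanning 1–100 ms, two open components of order 1 ms,
  5×10⁴ events, 1 ms cutoff) the procedure recovers the 3-closed/2-open
  structure in ≥ 80% of seeded replicates.

No missed-event (dead-time) correction beyond the left truncation is
applied, and no burst or amplitude analysis is attempted.

## Design choices made where the design was open

* **Opening-rate functional form.** Two candidate laws are consistent
  with "equilibrium Po = background + activated-state probability"
  composed with two-state gating; the saturating form satisfies it
  exactly and is the default, the linear form is retained as an option.
* **Per-channel ν.** Branch-conditional rather than starred-state
  indicator, for the reasons above (the indicator form is infeasible and
  cannot reproduce the ensemble law).
* **Steady-state initialization** from the analytic occupancy rather than
  hours of simulated burn-in.
* **EC50 definition** as half of the fitted span, not half of absolute
  Po.
* **Exclusion convention**: sub-cutoff events dropped without merging
  (merging available but off by default); the fitting side compensates by
  truncation renormalization.
* **Protocol boundaries** are instantaneous perfusion steps; no mixing
  kinetics.
* **Tetramer stoichiometry** is collapsed to single-site effective
  binding — four FKBP sites per channel are not modelled separately.

## Limitations

The model holds Ca²⁺ and all other modulators fixed; it has no
luminal-regulation, flux, or multi-channel coupling terms, so it speaks
to isolated-channel pharmacology, not to cell-scale Ca²⁺ release. All
validation is against synthetic data generated under the model's own
assumptions plus the acquisition-chain emulation described above. The
dwell-fitting chain assumes a stationary gating mechanism within the
fitted stretch; modal gating violates this over long records, which is
precisely why windowed Po — not a single pooled dwell fit — is the right
summary for modal data.

## A worked session

```{r example, eval = FALSE}
params <- defaultParameters()

# equilibrium prediction at physiological FKBP12 and 200 nM FKBP12.6
equilibriumPo(params, LigandConcentrations(3, 0.2))

# stochastic dose-response + Hill fit (the EC50 pipeline)
grid <- 10^seq(-9, -3, length.out = 13)           # 1e-3..1e3 pM in uM
cur <- doseResponseCurve(params, "fkbp12", grid, mode = "monte_carlo",
  nTrials = 100, duration = 60, window = 10, seed = 1)
estimateEc50(cur)

# synthetic recording -> idealization -> dwell fit
path <- simulatePath(params, constantProtocol(), 60, seed = 2,
  init = list(occupancy = "12", gate = "C"))
trace <- synthesizeTrace(path, AcquisitionSpec(), seed = 3)
rec <- idealizeThreshold50(trace)
computePo(rec, warnShort = FALSE)
fit <- selectNComponents(extractDwells(rec, "C"), 4, cutoff = 1)
fit
```
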