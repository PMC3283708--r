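p_ref <- defaultParameters()

mk_record <- function(states, durations) {
  new("IdealizedRecord", states = states, durations = durations,
    threshold = 15, totalDuration = sum(durations))
}

test_that("whole-record Po is open time over total time", {
  rec <- mk_record(rep(c("O", "C"), 5), rep(c(1, 4), 5))
  expect_equal(computePo(rec, warnShort = FALSE), 0.2)
  expect_warning(computePo(rec), "180 s")
})

test_that("windows with no transition inherit the spanning state", {
  rec <- mk_record("O", 30)
  pts <- computePo(rec, window = 10)
  expect_equal(pts@po, c(1, 1, 1))
  rec2 <- mk_record(c("C", "O", "C"), c(15, 5, 10))
  pts2 <- computePo(rec2, window = 10)
  expect_equal(pts2@po, c(0, 0.5, 0))
  expect_error(computePo(rec2, window = -1), "window")
})

test_that("windowed Po of a modal record reproduces the mode structure", {
  m <- ModalSpec(dwellMean = c(60, 60),
    multiplier = c(modalMultiplierForPo(p_ref, 0.01),
      modalMultiplierForPo(p_ref, 0.2)))
  path <- generateModalPath(p_ref, m, 600, seed = 21)
  rec <- mk_record(ifelse(path@gate == 1L, "O", "C"),
    diff(c(path@times, path@duration)))
  po_rec <- computePo(rec, window = 10)@po
  expect_length(po_rec, 60)
  expect_equal(po_rec, pathWindowPo(path, 10)@po, tolerance = 1e-9)
  # windows segregate around the two mode Po levels
  expect_gt(sum(po_rec < 0.05), 10)
  expect_gt(sum(po_rec > 0.1), 10)
})

test_that("short events are excluded from the dwell sample", {
  rec <- mk_record(c("O", "C", "O", "C", "O"),
    c(0.0005, 0.01, 0.002, 0.01, 0.003))
  expect_equal(extractDwells(rec, "O"), c(2, 3))
  expect_equal(extractDwells(rec, "O", minDuration = 0), c(0.5, 2, 3))
  expect_warning(d <- extractDwells(rec, "O", minDuration = 10), "10 ms")
  expect_length(d, 0)
})

test_that("merge mode coalesces across removed short gaps", {
  rec <- mk_record(c("O", "C", "O"), c(0.002, 0.0005, 0.003))
  expect_equal(extractDwells(rec, "O", merge = TRUE), 5.5)
  expect_equal(extractDwells(rec, "O"), c(2, 3))
})

test_that("single-exponential MLE equals the (shifted) sample mean", {
  d <- generateDwellSample(5, 1, 3000, seed = 31)
  fit <- fitDwellMixture(d, 1)
  expect_equal(fit@taus, mean(d), tolerance = 1e-7)
  dt <- generateDwellSample(5, 1, 3000, cutoff = 2, seed = 32)
  fit_t <- fitDwellMixture(dt, 1, cutoff = 2)
  expect_equal(fit_t@taus, mean(dt - 2), tolerance = 1e-7)
})

test_that("two-component mixture parameters are recovered across seeds", {
  for (s in 1:20) {
    d <- generateDwellSample(c(1, 10), c(0.5, 0.5), 2e4, seed = 100 + s)
    fit <- fitDwellMixture(d, 2)
    expect_lt(max(abs(fit@taus - c(1, 10)) / c(1, 10)), 0.10)
    expect_lt(max(abs(fit@areas - c(0.5, 0.5))), 0.05)
  }
})

test_that("the fitted optimum dominates the generating parameters", {
  for (s in 1:5) {
    d <- generateDwellSample(c(1, 10), c(0.4, 0.6), 1e4, seed = 200 + s)
    fit <- fitDwellMixture(d, 2)
    expect_gte(fit@loglik + 1e-6,
      mixture_loglik(d, c(1, 10), c(0.4, 0.6)))
    # and matches an independent likelihood evaluation at the optimum
    expect_equal(fit@loglik, mixture_loglik(d, fit@taus, fit@areas),
      tolerance = 1e-8)
  }
})

test_that("the fitted density integrates to one above the cutoff", {
  d <- generateDwellSample(c(1, 10, 100), c(0.5, 0.35, 0.15), 2e4,
    cutoff = 1, seed = 41)
  fit <- fitDwellMixture(d, 3, cutoff = 1)
  z <- stats::integrate(function(t) dwellDensity(fit, t), 1, Inf,
    rel.tol = 1e-11)$value
  expect_lt(abs(z - 1), 1e-9)
  expect_equal(dwellDensity(fit, 0.5), 0)
})

test_that("log-binned histogram agrees with the fitted pdf (chi-square)", {
  d <- generateDwellSample(c(1, 10), c(0.5, 0.5), 5e4, seed = 43)
  fit <- fitDwellMixture(d, 2)
  # 10 bins per decade over the sample's range
  edges <- 10^seq(log10(min(d)), log10(max(d)), by = 0.1)
  edges[1] <- 0; edges[length(edges)] <- Inf
  obs <- table(cut(d, edges))
  Fmix <- function(t) sum(fit@areas * (1 - exp(-t / fit@taus)))
  pr <- diff(vapply(edges, Fmix, numeric(1)))
  keep <- pr * length(d) >= 5
  stat <- sum((obs[keep] - length(d) * pr[keep])^2 /
    (length(d) * pr[keep]))
  df <- sum(keep) - 1 - 3
  expect_gt(pchisq(stat, df, lower.tail = FALSE), 0.01)
})

test_that("component counts are selected correctly across structures", {
  # 1 component: no spurious extras
  d1 <- generateDwellSample(5, 1, 1e4, seed = 51)
  expect_equal(selectNComponents(d1, 3)@nComponents, 1L)
  # 2-component open-like mixture with the 1 ms exclusion
  d2 <- generateDwellSample(c(0.9, 5), c(0.7, 0.3), 2e4, cutoff = 1,
    seed = 52)
  expect_equal(selectNComponents(d2, 4, cutoff = 1)@nComponents, 2L)
  # 3-component closed-like mixture
  d3 <- generateDwellSample(c(1.2, 12, 150), c(0.5, 0.35, 0.15), 5e4,
    cutoff = 1, seed = 53)
  sel3 <- selectNComponents(d3, 4, cutoff = 1)
  expect_equal(sel3@nComponents, 3L)
  expect_equal(nrow(sel3@selection), 4L)
  # BIC alternative agrees on the clear-cut case
  expect_equal(selectNComponents(d3, 4, cutoff = 1,
    criterion = "bic")@nComponents, 3L)
})

test_that("idealization recovers events from a synthetic recording", {
  path <- simulatePath(p_ref, constantProtocol(), 20, seed = 61,
    init = list(occupancy = "12", gate = "C"))
  # noiseless, unfiltered: exact recovery of the gate sequence
  tr0 <- synthesizeTrace(path, AcquisitionSpec(filterCutoff = NA,
    noiseSd = 0))
  rec0 <- idealizeThreshold50(tr0, levels = c(0, 30))
  r <- rle(path@gate[findInterval(
    (seq_along(tr0@samples) - 1) / 20000, path@times)])
  expect_equal(as.vector(rec0@states), ifelse(r$values == 1L, "O", "C"))
  expect_equal(rec0@durations, r$lengths / 20000)
  # default noise and filter: Po within 0.02 of the carried truth
  tr <- synthesizeTrace(path, AcquisitionSpec(), seed = 62)
  rec <- idealizeThreshold50(tr)  # levels estimated from the histogram
  expect_lt(abs(computePo(rec, warnShort = FALSE) -
    pathOpenFraction(path)), 0.02)
})

test_that("degenerate traces fail level estimation loudly", {
  quiet <- new("CurrentTrace",
    samples = rnorm(20000, 0, 3), spec = AcquisitionSpec(), truth = NULL)
  expect_error(idealizeThreshold50(quiet), "unimodal")
  allc <- new("CurrentTrace", samples = rep(0, 1000),
    spec = AcquisitionSpec(), truth = NULL)
  expect_error(idealizeThreshold50(allc), "unimodal")
  # with known levels an all-closed trace is a single C event
  rec <- idealizeThreshold50(allc, levels = c(0, 30))
  expect_equal(as.vector(rec@states), "C")
  expect_equal(computePo(rec, warnShort = FALSE), 0)
})

test_that("event lists round-trip through CSV", {
  rec <- mk_record(c("C", "O", "C"), c(0.5, 0.001, 0.25))
  f <- tempfile(fileext = ".csv")
  writeEvents(rec, f)
  back <- readEvents(f)
  expect_equal(as.vector(back@states), as.vector(rec@states))
  expect_equal(back@durations, rec@durations)
})
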