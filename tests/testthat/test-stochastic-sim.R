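p_ref <- defaultParameters()

test_that("the same seed reproduces a bit-identical trajectory", {
  a <- simulatePath(p_ref, constantProtocol(1, 0.2), 30, seed = 7)
  b <- simulatePath(p_ref, constantProtocol(1, 0.2), 30, seed = 7)
  expect_identical(a@times, b@times)
  expect_identical(a@occupancy, b@occupancy)
  expect_identical(a@gate, b@gate)
  c <- simulatePath(p_ref, constantProtocol(1, 0.2), 30, seed = 8)
  expect_false(identical(a@times, c@times))
})

test_that("paths satisfy the one-coordinate-per-event contract", {
  # validity enforces it; exercise on a busy mixed-ligand path
  path <- simulatePath(p_ref, constantProtocol(1e-6, 1e-6), 120, seed = 3)
  expect_true(validObject(path))
  expect_gt(length(path@times), 10)
  expect_true(all(diff(path@times) > 0))
})

test_that("zero-ligand open fraction converges to the background activity", {
  pts <- trialAveragePo(p_ref, constantProtocol(), 300, nTrials = 40,
    window = 10, seed = 11)
  ss <- steadyStatePo(pts, fraction = 1)
  expect_lt(abs(ss$po - 0.005), 3 * ss$se)
})

test_that("a branch-frozen channel gates at the branch-conditional Po", {
  # freeze the FKBP12-bound branch: no unbinding, start bound
  p <- updateParameters(p_ref, k_m1 = 0)
  path <- simulatePath(p, constantProtocol(0, 0), 400, seed = 5,
    init = list(occupancy = "12", gate = "C"))
  expect_true(all(path@occupancy %in% c(2L, 3L)))  # stays on the 12 branch
  target <- p@alpha + p@k2 / (p@k2 + p@k_m2)
  expect_equal(pathOpenFraction(path), target, tolerance = 0.05)
})

test_that("mean open dwell equals 1/kC", {
  p <- updateParameters(p_ref, k_m1 = 0)
  path <- simulatePath(p, constantProtocol(0, 0), 300, seed = 9,
    init = list(occupancy = "12", gate = "C"))
  d <- pathDwells(path, "O") / 1000  # s
  expect_gt(length(d), 3000)
  expect_lt(abs(mean(d) - 1 / p@kC), 3 * sd(d) / sqrt(length(d)))
})

test_that("long-run occupancy frequencies match the analytic equilibrium", {
  set.seed(13)
  for (i in 1:5) {
    p <- rand_sim_params()
    cc <- rand_conc()
    eq <- equilibriumOccupancy(p, cc)@probs
    path <- simulatePath(p, constantProtocol(cc@fkbp12, cc@fkbp12_6),
      1500, init = "equilibrium")
    emp <- occupancyFractions(path)
    # occupancy switches give roughly independent sojourns; 3 MC SEs with
    # an effective sample of half the occupancy transitions
    n_eff <- max(sum(diff(path@occupancy) != 0L) / 2, 10)
    tol <- 3 * sqrt(pmax(eq * (1 - eq), 0.01) / n_eff)
    expect_true(all(abs(emp - eq) < tol),
      info = sprintf("draw %d: max dev %.3g", i, max(abs(emp - eq))))
  }
})

test_that("trial-averaged Po converges to the analytic equilibrium Po", {
  cc <- LigandConcentrations(3, 0.2)
  target <- equilibriumPo(p_ref, cc)
  pts <- trialAveragePo(p_ref, constantProtocol(3, 0.2), 60, nTrials = 60,
    window = 10, seed = 17)
  ss <- steadyStatePo(pts, fraction = 1)
  expect_lt(abs(ss$po - target), 3 * ss$se)
})

test_that("a single trial equals the post-processed path for its child seed", {
  prot <- constantProtocol(1, 0)
  pts <- trialAveragePo(p_ref, prot, 40, nTrials = 1, window = 10,
    seed = 23)
  set.seed(23)
  child <- sample.int(2147483646L, 1)
  path <- simulatePath(p_ref, prot, 40, seed = child)
  expect_equal(pts@po, pathWindowPo(path, 10)@po, tolerance = 1e-12)
})

test_that("standard error of the trial mean shrinks like 1/sqrt(n)", {
  prot <- constantProtocol(asMicromolar(0.2, "pM"), 0)  # near half-max
  s25 <- trialAveragePo(p_ref, prot, 30, nTrials = 25, window = 10,
    seed = 31)
  s100 <- trialAveragePo(p_ref, prot, 30, nTrials = 100, window = 10,
    seed = 31)
  r <- steadyStatePo(s25, 1)$se / steadyStatePo(s100, 1)$se
  expect_gt(r, 1.3)  # expected 2
  expect_lt(r, 3.1)
})

test_that("event counts scale linearly with duration", {
  n1 <- length(simulatePath(p_ref, constantProtocol(), 100, seed = 2,
    init = "free")@times)
  n4 <- length(simulatePath(p_ref, constantProtocol(), 400, seed = 2,
    init = "free")@times)
  expect_gt(n4 / n1, 2.5)
  expect_lt(n4 / n1, 6)
})

test_that("fast artificial unbinding lets washout relax to background", {
  p <- updateParameters(p_ref, k_m1 = 10)
  pts <- simulateWashout(p, fkbp12 = 1, bindTime = 60, washoutTime = 60,
    seed = 19, nTrials = 20)
  wash_tail <- steadyStatePo(pts, fraction = 0.25)  # last 30 s
  expect_lt(wash_tail$po, 0.02)
})

test_that("washout with no binding phase stays at background", {
  pts <- simulateWashout(p_ref, fkbp12 = 1, bindTime = 0,
    washoutTime = 120, seed = 29, nTrials = 20)
  ss <- steadyStatePo(pts, fraction = 1)
  expect_lt(abs(ss$po - 0.005), max(3 * ss$se, 0.003))
})

test_that("protocol plumbing: segments, lookup, file round-trip", {
  prot <- ConcentrationProtocol(c(0, 120, 600), fkbp12 = c(0, 0, 1),
    fkbp12_6 = c(0, 0.2, 0.2))
  expect_equal(concentrationsAt(prot, 130)@fkbp12_6, 0.2)
  expect_equal(concentrationsAt(prot, 700)@fkbp12, 1)
  f <- tempfile(fileext = ".yaml")
  writeProtocol(prot, f)
  expect_equal(readProtocol(f)@segments, prot@segments)
  expect_error(ConcentrationProtocol(c(5, 10)), "start at time 0")
  expect_error(ConcentrationProtocol(c(0, 10, 10)), "increasing")
  expect_error(trialAveragePo(p_ref, prot, 10, window = 60), "window")
})
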