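test_that("zero ligand puts all occupancy mass in the free state", {
  p <- defaultParameters()
  occ <- equilibriumOccupancy(p, LigandConcentrations(0, 0))
  expect_equal(unname(occ@probs[["free"]]), 1)
  expect_equal(occ@nu, 0)
  expect_equal(equilibriumPo(p, LigandConcentrations(0, 0)), 0.005,
    tolerance = 1e-12)
})

test_that("saturating FKBP12 drives nu to the conformational equilibrium", {
  p <- defaultParameters()
  occ <- equilibriumOccupancy(p, LigandConcentrations(1, 0))
  nu_lim <- p@k2 / (p@k2 + p@k_m2)  # = 0.03 / 0.21
  expect_equal(occ@nu, nu_lim, tolerance = 1e-5)
  # independent check: long-time integration of the mass-action ODEs
  expect_equal(occ@nu, ode_nu(p, 1, 0), tolerance = 1e-6)
})

test_that("mixed agonist/antagonist occupancy matches the ODE oracle", {
  p <- defaultParameters()
  occ <- equilibriumOccupancy(p, LigandConcentrations(3, 0.2))
  x_ode <- ode_stationary(p, 3, 0.2)
  expect_equal(unname(occ@probs), unname(x_ode), tolerance = 1e-6)
  # FKBP12.6-bound branch dominates and suppresses nu
  expect_gt(occ@probs[["12.6"]] + occ@probs[["12.6*"]], 0.9)
  expect_equal(occ@nu, 0.0172, tolerance = 0.01)
})

test_that("closed-form equilibrium equals ODE steady state across random draws", {
  set.seed(41)
  for (i in 1:100) {
    p <- rand_params()
    cc <- rand_conc()
    occ <- equilibriumOccupancy(p, cc)
    x_ode <- ode_stationary(p, cc@fkbp12, cc@fkbp12_6)
    expect_lt(max(abs(occ@probs - x_ode)), 1e-8)
  }
})

test_that("occupancy distribution is normalized and detailed-balanced", {
  set.seed(42)
  for (i in 1:100) {
    p <- rand_params()
    cc <- rand_conc()
    occ <- equilibriumOccupancy(p, cc)
    x <- occ@probs
    expect_lt(abs(sum(x) - 1), 1e-12)
    expect_true(all(x >= 0 & x <= 1))
    expect_equal(occ@nu, unname(x[["12*"]] + x[["12.6*"]]))
    # zero net flux on every edge of the (tree-shaped) scheme
    rel <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-300)
    expect_lt(rel(p@k1 * cc@fkbp12 * x[["free"]], p@k_m1 * x[["12"]]), 1e-9)
    expect_lt(rel(p@k2 * x[["12"]], p@k_m2 * x[["12*"]]), 1e-9)
    expect_lt(rel(p@k3 * cc@fkbp12_6 * x[["free"]], p@k_m3 * x[["12.6"]]),
      1e-9)
    expect_lt(rel(p@k4 * x[["12.6"]], p@k_m4 * x[["12.6*"]]), 1e-9)
  }
})

test_that("opening rate reproduces the background-activity anchor", {
  p <- defaultParameters()
  g0 <- openingRate(p, 0)
  expect_equal(g0@poEq, 0.005, tolerance = 1e-12)
  expect_equal(g0@kO, 480 * 0.005 / 0.995, tolerance = 1e-12)  # ~2.4121
  g <- openingRate(p, 0.1429)
  expect_equal(g@poEq, 0.005 + 0.1429, tolerance = 1e-12)
  # alternative linear law for sensitivity checks
  gl <- openingRate(p, 0.1, form = "linear")
  expect_equal(gl@kO, 480 * 0.105, tolerance = 1e-12)
  expect_equal(gl@poEq, 0.105 / 1.105, tolerance = 1e-12)
})

test_that("opening rate rejects saturated occupancy drive", {
  p <- defaultParameters()
  expect_error(openingRate(p, 0.999), "saturation")
  expect_error(openingRate(p, -0.1), "nu")
})

test_that("nu rises monotonically with FKBP12 when FKBP12.6 is absent", {
  p <- defaultParameters()
  grid <- 10^seq(-9, 0, length.out = 40)
  nus <- vapply(grid, function(f)
    equilibriumOccupancy(p, LigandConcentrations(f, 0))@nu, numeric(1))
  expect_true(all(diff(nus) >= 0))
})

test_that("with k4 = 0 FKBP12.6 is a pure antagonist", {
  p <- updateParameters(defaultParameters(), k4 = 0)
  for (f12 in c(1e-6, 1e-3, 1)) {
    grid126 <- 10^seq(-6, 0, length.out = 25)
    po <- vapply(grid126, function(f)
      equilibriumPo(p, LigandConcentrations(f12, f)), numeric(1))
    expect_true(all(diff(po) <= 1e-15))
  }
})

test_that("FKBP12.6 lowers Po against a fixed FKBP12 background", {
  p <- defaultParameters()
  expect_gte(equilibriumPo(p, LigandConcentrations(3, 0)),
    equilibriumPo(p, LigandConcentrations(3, 0.2)))
})

test_that("invalid parameters and concentrations are rejected", {
  expect_error(KineticParameters(kC = -1), "positive|non-negative")
  expect_error(KineticParameters(alpha = 0), "alpha")
  expect_error(KineticParameters(alpha = 1), "alpha")
  expect_error(LigandConcentrations(-1, 0), "concentrations")
  expect_error(LigandConcentrations(Inf, 0), "finite")
  expect_error(updateParameters(defaultParameters(), bogus = 1), "bogus")
})

test_that("equilibrium table carries the CSV export columns", {
  tab <- equilibriumTable(defaultParameters(),
    fkbp12 = c(0, 1e-6, 1), fkbp12_6 = 0)
  expect_named(tab, c("fkbp12_uM", "fkbp12_6_uM", "x_free", "x_12",
    "x_12s", "x_126", "x_126s", "nu", "k_O", "po"))
  expect_equal(tab$po[1], 0.005, tolerance = 1e-12)
  expect_true(all(abs(rowSums(tab[, 3:7]) - 1) < 1e-12))
})

test_that("parameter files round-trip and reject unknown keys", {
  p <- defaultParameters()
  f <- tempfile(fileext = ".yaml")
  writeKineticParameters(p, f)
  expect_equal(parameterVector(readKineticParameters(f)),
    parameterVector(p))
  packaged <- system.file("extdata", "default_params.yaml",
    package = "RyRgate")
  expect_equal(parameterVector(readKineticParameters(packaged)),
    parameterVector(p))
  writeLines(c("k1: 1", "bogus: 2"), f)
  expect_error(readKineticParameters(f), "bogus")
})

test_that("unit conversion reaches micromolar from pM/nM", {
  expect_equal(asMicromolar(120, "pM"), 1.2e-4)
  expect_equal(asMicromolar(200, "nM"), 0.2)
  expect_equal(asMicromolar(3, "uM"), 3)
})
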