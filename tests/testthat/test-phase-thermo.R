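test_that("interaction ramp has the printed limits and strict monotonicity", {
  s <- interactionSchedule()
  expect_equal(interactionParameter(0, s), 7300)
  # 7300 + 10000*(1 - 10^-1)
  expect_equal(interactionParameter(200, s), 16300)
  expect_equal(interactionParameter(1e9, s), 17300, tolerance = 1e-8)
  tt <- seq(0, 1500, by = 7)   # before double-precision saturation
  L <- interactionParameter(tt, s)
  expect_true(all(diff(L) > 0))
  expect_true(all(interactionParameter(seq(0, 1e5, by = 997), s) <= 17300))
  expect_error(interactionParameter(-1, s), "t must be")
})

test_that("bulk free energy matches the closed form and its symmetry", {
  p <- thermoParams()
  expect_equal(bulkFreeEnergyDensity(0.5, 0, p), RT_REF * log(0.5))
  expect_equal(bulkFreeEnergyDensity(0.5, 7300, p),
               RT_REF * log(0.5) + 7300 * 0.25)
  eta <- runif(50, 1e-5, 1 - 1e-5)
  for (L in c(0, 7300, 17300))
    expect_equal(bulkFreeEnergyDensity(eta, L, p),
                 bulkFreeEnergyDensity(1 - eta, L, p))
  expect_error(bulkFreeEnergyDensity(1e-8, 0, p), "guarded interval")
})

test_that("spinodal curvature marks the critical point and the quench", {
  p <- thermoParams()
  expect_equal(spinodalCurvature(0.5, 2 * RT_REF, p), 0)
  # the study composition is inside the spinodal already at L0
  f <- spinodalCurvature(0.38, 7300, p)
  expect_equal(f, RT_REF * (1 / 0.38 + 1 / 0.62) - 14600)
  expect_lt(f, 0)
  expect_equal(f, -4194, tolerance = 5e-4)
  expect_gt(spinodalCurvature(0.38, 2000, p), 0)
})

test_that("chemical potential of a uniform field is uniform and exact", {
  p <- thermoParams()
  g <- gridSpec()
  f <- matrix(0.38, g@nx, g@nz)
  for (L in c(0, 7300)) {
    mu <- chemicalPotentialField(f, L, p, g)
    muExp <- RT_REF * log(0.38 / 0.62) + L * (1 - 2 * 0.38)
    expect_equal(mu, matrix(muExp, g@nx, g@nz))
  }
  expect_equal(chemicalPotentialField(matrix(0.5, g@nx, g@nz), 9999, p, g),
               matrix(0, g@nx, g@nz))
})

test_that("chemical potential of a single mode matches the linearisation", {
  p <- thermoParams()
  g <- gridSpec()
  eps <- 1e-6
  for (k in c(4L, 8L, 16L)) {
    q <- 2 * pi * k / (g@nx * g@dx * 1e-6)    # 1/m
    expect_lte(q * g@dx * 1e-6, 0.5)
    x <- seq_len(g@nx) - 1L
    pert <- eps * cos(2 * pi * k * x / g@nx)
    f <- matrix(0.38 + pert, g@nx, g@nz)
    mu <- chemicalPotentialField(f, 7300, p, g)
    # mu ~ const + (f''(0.38) + alpha q_eff^2) * pert; use the continuum q
    fpp <- RT_REF * (1 / 0.38 + 1 / 0.62) - 2 * 7300
    predicted <- (fpp + p@alpha * q^2) * pert
    measured <- mu[, 1] - mean(mu[, 1])
    expect_equal(measured, predicted, tolerance = 0.01)
  }
})

test_that("binodal classifies the two printed compositions and pure water", {
  m <- binodalModel()
  expect_identical(classifyComposition(composition(4, 4), m)$label,
                   "homogeneous")
  expect_identical(classifyComposition(composition(5, 5), m)$label,
                   "two_phase")
  cw <- classifyComposition(composition(0, 0), m)
  expect_identical(cw$label, "homogeneous")
  expect_true(cw$extrapolated)
  # monotone decreasing, positive over the fitted range
  pp <- seq(1, 10, by = 0.05)
  g <- binodalCurve(m, pp)
  expect_true(all(g > 0))
  expect_true(all(diff(g) < 0))
})

test_that("classification is dilution-consistent above the binodal", {
  m <- binodalModel()
  set.seed(42)
  for (i in 1:20) {
    cp <- runif(1, 1, 6); cd <- binodalCurve(m, cp) * runif(1, 1.01, 1.5)
    for (f in c(1, 1.1, 1.6))
      expect_identical(
        classifyComposition(composition(f * cp, f * cd), m)$label,
        "two_phase")
  }
})

test_that("dilution trajectory preserves the ratio and hits (5,5) at 20%", {
  tr <- dilutionTrajectory(composition(4, 4), c(0, 0.2))
  expect_equal(tr$cPeg, c(4, 5))
  expect_equal(tr$cDex, c(4, 5))
  tr2 <- dilutionTrajectory(composition(3, 1.5), seq(0, 0.9, by = 0.1))
  expect_equal(tr2$cPeg / tr2$cDex, rep(2, 10))
  expect_error(dilutionTrajectory(composition(4, 4), 1), "\\[0, 1\\)")
})

test_that("binodal crossing factor agrees with a brute-force scan", {
  m <- binodalModel()
  expect_equal(binodalCrossingFactor(composition(5, 5), m), 1)
  f44 <- binodalCrossingFactor(composition(4, 4), m)
  expect_gt(f44, 1)
  expect_lte(f44, 1.25)
  set.seed(7)
  for (i in 1:20) {
    c0 <- composition(runif(1, 0.3, 6), runif(1, 0.3, 6))
    fBis <- binodalCrossingFactor(c0, m)
    fScan <- scanCrossingFactor(c0, m)
    if (is.na(fScan)) expect_true(is.na(fBis))
    else expect_equal(fBis, fScan, tolerance = 2e-4)
  }
  # larger c0 at the same ratio needs a smaller factor
  fs <- vapply(seq(1, 4.5, by = 0.5),
               function(c) binodalCrossingFactor(composition(c, c), m),
               numeric(1))
  expect_true(all(diff(fs) < 0))
})

test_that("binodal model round-trips through JSON and exports a grid", {
  m <- binodalModel()
  path <- withr::local_tempfile(fileext = ".json")
  writeBinodalModel(m, path)
  m2 <- readBinodalModel(path)
  expect_equal(m2@coefA, m@coefA)
  expect_equal(m2@coefB, m@coefB)
  expect_equal(m2@coefC, m@coefC)
  expect_equal(m2@range, m@range)
  csv <- withr::local_tempfile(fileext = ".csv")
  g <- exportPhaseDiagram(m, csv)
  expect_true(file.exists(csv))
  expect_setequal(unique(g$label), c("homogeneous", "two_phase"))
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(g))
})
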