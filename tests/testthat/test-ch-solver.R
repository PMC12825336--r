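test_that("snapshot minutes map onto the printed step indices", {
  expect_identical(snapshotStepsForMinutes(c(2, 5, 15, 30)),
                   c(920L, 1100L, 1700L, 2600L))
  expect_identical(snapshotStepsForMinutes(0), 800L)
  expect_error(snapshotStepsForMinutes(0.001), "integer number of steps")
})

test_that("field initialisation is exact in the mean and reproducible", {
  g <- gridSpec()
  f0 <- initializeField(g, solverConfig(noiseAmp = 0))
  expect_equal(f0@eta, matrix(0.38, g@nx, g@nz))
  for (seed in c(1L, 99L)) {
    f <- initializeField(g, solverConfig(seed = seed))
    expect_equal(mean(f@eta), 0.38, tolerance = 1e-14)
    f2 <- initializeField(g, solverConfig(seed = seed))
    expect_identical(f@eta, f2@eta)
  }
  expect_error(solverConfig(noiseAmp = 0.5), "noiseAmp")
})

test_that("a uniform field is a fixed point of the CH step", {
  g <- gridSpec()
  cfg <- solverConfig(noiseAmp = 0)
  st <- initializeField(g, cfg)
  st1 <- chStep(st, g, cfg)
  expect_equal(st1@eta, st@eta)
  expect_equal(st1@t, 1)
  expect_identical(st1@step, 1L)
})

test_that("the conservative stencil conserves mass to round-off", {
  g <- gridSpec()
  cfg <- solverConfig(seed = 3L)
  st <- initializeField(g, cfg)
  m0 <- totalMass(st)
  expect_equal(m0, 0.38 * 256 * 20, tolerance = 1e-12)  # 1945.6
  for (i in 1:20) st <- chStep(st, g, cfg)
  expect_lt(abs(totalMass(st) - m0) / m0, 1e-12)
})

test_that("wall relaxation follows the compensated two-layer update", {
  g <- gridSpec()
  cfg <- solverConfig(noiseAmp = 0)
  st <- initializeField(g, cfg)  # uniform 0.38
  st1 <- applyWallRelaxation(st, cfg)
  # k dt (eta0 - eta) = 1e-5 * 1 * 0.02 = 2e-7 into the wall layers,
  # the identical amount out of the adjacent layers
  expect_equal(st1@eta[, 1], rep(0.38 + 2e-7, g@nx))
  expect_equal(st1@eta[, 2], rep(0.38 - 2e-7, g@nx))
  expect_equal(st1@eta[, g@nz], rep(0.38 + 2e-7, g@nx))
  expect_equal(st1@eta[, g@nz - 1], rep(0.38 - 2e-7, g@nx))
  expect_equal(st1@eta[, 3:(g@nz - 2)], st@eta[, 3:(g@nz - 2)])
  # already at the preferred value: no change anywhere
  cfgW <- solverConfig(noiseAmp = 0, etaInit = 0.4)
  stW <- initializeField(g, cfgW)
  expect_equal(applyWallRelaxation(stW, cfgW)@eta, stW@eta)
})

test_that("wall relaxation conserves each cross-channel column exactly", {
  g <- gridSpec()
  cfg <- solverConfig(seed = 11L, noiseAmp = 0.05)
  st <- initializeField(g, cfg)
  st1 <- applyWallRelaxation(st, cfg)
  expect_equal(rowSums(st1@eta), rowSums(st@eta), tolerance = 1e-15)
})

test_that("single-mode growth matches the dispersion relation", {
  g <- gridSpec()
  p <- thermoParams(a = 0)          # freeze L at L0 = 7300
  sched <- interactionSchedule(p)
  cfg <- solverConfig(noiseAmp = 0, kWall = 0)
  nsteps <- 50L
  for (k in c(4L, 6L, 8L)) {
    q <- 2 * pi * k / (g@nx * g@dx * 1e-6)
    x <- seq_len(g@nx) - 1L
    eta <- matrix(0.38 + 1e-6 * cos(2 * pi * k * x / g@nx), g@nx, g@nz)
    st <- new("FieldState", eta = eta, t = 0, step = 0L)
    a0 <- modeAmplitude(st@eta[, 10], k)
    for (i in seq_len(nsteps)) st <- chStep(st, g, cfg, sched)
    a1 <- modeAmplitude(st@eta[, 10], k)
    measured <- log(a1 / a0) / (nsteps * cfg@dt)
    predicted <- dispersionSigma(q, 0.38, 7300)
    expect_gt(predicted, 0)  # inside the spinodal: the mode grows
    expect_equal(measured, predicted, tolerance = 0.05)
  }
})

test_that("a noiseless start stays x-uniform under the full update", {
  g <- gridSpec()
  cfg <- solverConfig(noiseAmp = 0, nSteps = 120L,
                      snapshotSteps = c(60L, 120L))
  traj <- runSimulation(g, cfg)
  for (s in snapshots(traj)) {
    colSpread <- max(apply(s@eta, 2, function(col) diff(range(col))))
    expect_lt(colSpread, 1e-12)
  }
})

test_that("the trajectory records snapshots, times and the mass ledger", {
  g <- gridSpec()
  cfg <- solverConfig(seed = 5L, nSteps = 120L, snapshotSteps = c(50L, 120L))
  traj <- runSimulation(g, cfg)
  expect_length(massLedger(traj), 120L)
  expect_identical(vapply(snapshots(traj), function(s) s@step, integer(1)),
                   c(50L, 120L))
  # observation clock: dt*(step - lagSteps)
  expect_equal(observationTimes(traj), c(50, 120) - 800)
  drift <- abs(massLedger(traj) - 0.38 * 256 * 20) / (0.38 * 256 * 20)
  expect_lt(max(drift), 1e-12)
  # determinism
  traj2 <- runSimulation(g, cfg)
  expect_identical(snapshots(traj2)[[2]]@eta, snapshots(traj)[[2]]@eta)
})

test_that("stability report bounds scale as dx^4 and flag absurd steps", {
  g <- gridSpec()
  sched <- interactionSchedule()
  rep1 <- stabilityCheck(g, solverConfig(), sched)
  expect_true(rep1$fourthOrderBound > 0.01 && rep1$fourthOrderBound < 10)
  expect_true(rep1$antiDiffusionBound > rep1$fourthOrderBound)
  expect_false(stabilityCheck(g, solverConfig(dt = 1e6, kWall = 0),
                              sched)$pass)
  gHalf <- gridSpec(nx = 256L, nz = 20L, dx = 0.5)
  rep2 <- stabilityCheck(gHalf, solverConfig(), sched)
  expect_equal(rep1$fourthOrderBound / rep2$fourthOrderBound, 16,
               tolerance = 1e-12)
  expect_gte(rep1$substepFactor, 1L)
})

test_that("guard violations abort with a stability error naming the step", {
  g <- gridSpec()
  # absurdly large dt defeats even sub-stepping safety at fixed count:
  # force by calling the kernel path with an unstable configuration
  cfg <- solverConfig(seed = 2L, dt = 1)
  st <- initializeField(g, cfg)
  # corrupt the sub-step logic by driving dt through a huge kWall-free step
  expect_error(
    atpsDroplets:::ch_substeps_cpp(st@eta + 0, 10L, 1e8, 4e-18, RT_REF,
                                   17300, 3.5e-8, 1e-6, 1e-6),
    NA)  # kernel itself returns the abort flag rather than throwing
  res <- atpsDroplets:::ch_substeps_cpp(st@eta + 0, 10L, 1e8, 4e-18, RT_REF,
                                        17300, 3.5e-8, 1e-6, 1e-6)
  expect_gt(res$abort_sub, 0)
})
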