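# Shared fixtures and oracles for the test suite.

RT_REF <- 8.31 * 295  # J/mol at the study temperature

# The full channel-study run is expensive (~half a minute), so tests that
# probe different properties of the same trajectory share one cached run.
.paper_run <- new.env(parent = emptyenv())

paperTrajectory <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.paper_run[[key]])) {
    cfg <- solverConfig(seed = seed,
                        snapshotSteps = snapshotStepsForMinutes())
    .paper_run[[key]] <- runSimulation(gridSpec(), cfg)
  }
  .paper_run[[key]]
}

snapshotAt <- function(traj, step) {
  steps <- vapply(snapshots(traj), function(s) s@step, integer(1))
  snapshots(traj)[[match(step, steps)]]
}

# Independent brute-force oracle: smallest concentration factor crossing the
# binodal, by linear scan.
scanCrossingFactor <- function(c0, m, fStep = 1e-4, fMax = 10) {
  f <- seq(1, fMax, by = fStep)
  above <- c0@cDex * f > binodalCurve(m, c0@cPeg * f)
  if (!any(above)) NA_real_ else f[which(above)[1]]
}

# Independent dispersion-relation oracle for the linear regime:
# sigma(q) = -Mc q^2 (f''(eta0) + alpha q^2)
dispersionSigma <- function(q, eta0, L, p = thermoParams()) {
  fpp <- p@R * p@T * (1 / eta0 + 1 / (1 - eta0)) - 2 * L
  -mobility(p) * q^2 * (fpp + p@alpha * q^2)
}

# Amplitude of the cos(q x) mode in an x-profile (projection).
modeAmplitude <- function(profile, k) {
  nx <- length(profile)
  x <- seq_len(nx) - 1L
  2 * mean((profile - mean(profile)) * cos(2 * pi * k * x / nx))
}
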