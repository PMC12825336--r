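#' Construct the channel grid
#'
#' Defaults describe the 20 um square channel resolved at 1 um: 20 cells
#' across, and a 256 um periodic segment along the channel axis (long
#' enough to host roughly ten droplets of channel-scale period).
#'
#' @param nx cells along the channel axis (periodic), >= 64.
#' @param nz cells across the channel, >= 4.
#' @param dx grid spacing, micrometres.
#' @return A [GridSpec-class].
#' @export
gridSpec <- function(nx = 256L, nz = 20L, dx = 1.0) {
  new("GridSpec", nx = as.integer(nx), nz = as.integer(nz), dx = dx)
}

#' Construct the solver configuration
#'
#' Defaults are the channel-study conditions: dt = 1 s reporting step, 2600
#' steps (30 min of observation after the 800 s observation lag), uniform
#' initial eta = 0.38 with seeded zero-mean noise of amplitude 1e-3, wall
#' value eta0 = 0.4 relaxed at k = 1e-5 /s.
#'
#' @param dt outer time step, s.
#' @param nSteps number of steps.
#' @param etaInit initial uniform order parameter.
#' @param etaWall wall-preferred order parameter.
#' @param kWall wall relaxation rate, 1/s.
#' @param noiseAmp symmetry-breaking noise amplitude.
#' @param seed RNG seed for the noise (NA for unseeded).
#' @param lagSteps observation-lag offset: observation time = (step -
#'   lagSteps) * dt.
#' @param snapshotSteps integer step indices at which to record snapshots.
#' @return A [SolverConfig-class].
#' @export
solverConfig <- function(dt = 1, nSteps = 2600L, etaInit = 0.38,
                         etaWall = 0.4, kWall = 1e-5, noiseAmp = 1e-3,
                         seed = NA_integer_, lagSteps = 800L,
                         snapshotSteps = snapshotStepsForMinutes()) {
  new("SolverConfig", dt = dt, nSteps = as.integer(nSteps),
      etaInit = etaInit, etaWall = etaWall, kWall = kWall,
      noiseAmp = noiseAmp, seed = as.integer(seed),
      lagSteps = as.integer(lagSteps),
      snapshotSteps = as.integer(snapshotSteps))
}

#' Map observation minutes to simulation step indices
#'
#' Observation clocks start lagSteps steps after the homogeneous initial
#' state (the handling lag between mixing and the first micrograph), so an
#' observation time of m minutes corresponds to step lagSteps + 60 m / dt.
#'
#' @param minutes observation times, minutes.
#' @param dt time step, s.
#' @param lagSteps observation-lag offset, steps.
#' @return Integer step indices.
#' @examples
#' snapshotStepsForMinutes(c(2, 5, 15, 30))  # 920 1100 1700 2600
#' @export
snapshotStepsForMinutes <- function(minutes = c(2, 5, 15, 30), dt = 1,
                                    lagSteps = 800L) {
  steps <- lagSteps + minutes * 60 / dt
  if (any(abs(steps - round(steps)) > 1e-9))
    stop("requested minutes are not an integer number of steps")
  as.integer(round(steps))
}

#' Initialise the order-parameter field
#'
#' Uniform etaInit plus seeded zero-mean uniform noise of amplitude
#' noiseAmp. The noise is mean-subtracted, so the field mean equals etaInit
#' to machine precision for every seed; a deterministic x-uniform start
#' (noiseAmp = 0) stays x-uniform under the dynamics.
#'
#' @param grid a [GridSpec-class].
#' @param cfg a [SolverConfig-class].
#' @return A [FieldState-class] at t = 0, step 0.
#' @export
initializeField <- function(grid, cfg) {
  eta <- matrix(cfg@etaInit, grid@nx, grid@nz)
  if (cfg@noiseAmp > 0) {
    if (!is.na(cfg@seed)) set.seed(cfg@seed)
    noise <- runif(grid@nx * grid@nz, -cfg@noiseAmp, cfg@noiseAmp)
    eta <- eta + (noise - mean(noise))
  }
  new("FieldState", eta = eta, t = 0, step = 0L)
}

# Per-step von Neumann sub-step count for the explicit scheme. The stiffest
# decay mode combines the checkerboard wavenumber (|k|^2 = 8/dx^2 on the
# 5-point stencil) with the largest positive free-energy curvature present
# in the field (largest near the composition extremes). 'safety' < 1 keeps
# the amplification factor away from the -1 stability edge.
.substepCount <- function(eta, dt, L, p, dxm, safety = 0.8) {
  RT <- p@R * p@T
  emin <- min(eta); emax <- max(eta)
  fppmax <- max(RT / (emin * (1 - emin)), RT / (emax * (1 - emax))) - 2 * L
  k2 <- 8 / dxm^2
  sigma <- mobility(p) * k2 * (p@alpha * k2 + max(fppmax, 0))
  max(1L, as.integer(ceiling(dt * sigma / (2 * safety))))
}

#' Advance the field by one Cahn-Hilliard step
#'
#' One outer step of dt seconds of the conserved dynamics
#' d eta/dt = div(Mc grad mu), with mu from [chemicalPotentialField()] at
#' the interaction parameter L(t) frozen over the step. The update is the
#' explicit flux-difference (conservative) discretisation, periodic along
#' x and zero-flux at the z walls for both eta and mu, so global mass is
#' conserved to round-off. Whenever dt exceeds the explicit stability bound
#' the step is internally divided into the smallest safe integer number of
#' sub-steps (see [stabilityCheck()]); the reported state always advances
#' by exactly dt.
#'
#' Values pushed outside (0,1) by at most 10 epsLog are clamped back to the
#' guard interval and reported via a warning; larger excursions abort with
#' a stability error naming the step.
#'
#' @param state a [FieldState-class].
#' @param grid a [GridSpec-class].
#' @param cfg a [SolverConfig-class].
#' @param schedule an [InteractionSchedule-class].
#' @return The advanced [FieldState-class] with attribute
#'   \code{"clamped"} (number of clamp events in this step).
#' @export
chStep <- function(state, grid, cfg, schedule = interactionSchedule()) {
  p <- schedule@thermo
  L <- interactionParameter(state@t, schedule)
  dxm <- grid@dx * 1e-6
  nsub <- .substepCount(state@eta, cfg@dt, L, p, dxm)
  eta <- state@eta + 0  # private copy: the kernel updates in place
  res <- ch_substeps_cpp(eta, nsub, cfg@dt / nsub, mobility(p), p@R * p@T,
                         L, p@alpha, dxm, p@epsLog)
  if (res$abort_sub > 0)
    stop(sprintf(
      "stability abort at step %d (sub-step %d/%d): eta left (0,1) by more than 10*epsLog",
      state@step + 1L, res$abort_sub, nsub))
  if (res$clamped > 0)
    warning(sprintf("step %d: %d guard-interval clamp event(s)",
                    state@step + 1L, res$clamped))
  out <- new("FieldState", eta = eta, t = state@t + cfg@dt,
             step = state@step + 1L)
  attr(out, "clamped") <- res$clamped
  out
}

#' Apply the wall-affinity boundary relaxation
#'
#' Both walls relax towards the preferred value eta0 = etaWall with simple
#' first-order kinetics, and the layer adjacent to each wall is decremented
#' by the identical amount so that the mass of every cross-channel column
#' is conserved exactly:
#' \preformatted{
#'   eta[i, 1]  <- eta[i, 1]  + k dt (eta0 - eta[i, 1])
#'   eta[i, 2]  <- eta[i, 2]  - k dt (eta0 - eta[i, 1])
#' }
#' and symmetrically for the j = nz, nz-1 wall.
#'
#' @inheritParams chStep
#' @return The updated [FieldState-class] (clock unchanged: the relaxation
#'   shares the step with [chStep()]).
#' @export
applyWallRelaxation <- function(state, cfg) {
  eta <- state@eta
  nz <- ncol(eta)
  if (nz < 4L) stop("wall relaxation requires nz >= 4")
  d1 <- cfg@kWall * cfg@dt * (cfg@etaWall - eta[, 1L])
  eta[, 1L] <- eta[, 1L] + d1
  eta[, 2L] <- eta[, 2L] - d1
  d2 <- cfg@kWall * cfg@dt * (cfg@etaWall - eta[, nz])
  eta[, nz] <- eta[, nz] + d2
  eta[, nz - 1L] <- eta[, nz - 1L] - d2
  new("FieldState", eta = eta, t = state@t, step = state@step)
}

#' Run the channel phase-separation simulation
#'
#' Initialises the field and alternates [chStep()] (conserved
#' Cahn-Hilliard update at the ramped interaction parameter) with
#' [applyWallRelaxation()] for each of the nSteps outer steps, recording
#' snapshots at the requested step indices and the total mass after every
#' step. Observation times of the snapshots are reported as
#' (step - lagSteps) * dt via [observationTimes()].
#'
#' @param grid a [GridSpec-class].
#' @param cfg a [SolverConfig-class].
#' @param schedule an [InteractionSchedule-class].
#' @param verbose print a progress line every \code{verboseEvery} steps.
#' @param verboseEvery step interval for progress lines.
#' @return A [Trajectory-class].
#' @examples
#' \donttest{
#' # the full channel-study run (about half a minute)
#' traj <- runSimulation(gridSpec(), solverConfig(seed = 1L))
#' }
#' @export
runSimulation <- function(grid, cfg, schedule = interactionSchedule(),
                          verbose = FALSE, verboseEvery = 200L) {
  state <- initializeField(grid, cfg)
  snaps <- list()
  if (0L %in% cfg@snapshotSteps) snaps <- list(state)
  mass <- numeric(cfg@nSteps)
  clamped <- 0L
  for (step in seq_len(cfg@nSteps)) {
    state <- withCallingHandlers(
      chStep(state, grid, cfg, schedule),
      warning = function(w) invokeRestart("muffleWarning"))
    clamped <- clamped + attr(state, "clamped")
    if (cfg@kWall > 0) state <- applyWallRelaxation(state, cfg)
    mass[step] <- sum(state@eta)
    if (step %in% cfg@snapshotSteps) snaps[[length(snaps) + 1L]] <- state
    if (verbose && step %% verboseEvery == 0L)
      message(sprintf("step %d/%d  t=%gs  mass=%.9g  eta=[%.4g, %.4g]",
                      step, cfg@nSteps, state@t, mass[step],
                      min(state@eta), max(state@eta)))
  }
  if (clamped > 0L)
    warning(sprintf("%d guard-interval clamp event(s) over the run", clamped))
  new("Trajectory", snapshots = snaps, grid = grid, config = cfg,
      schedule = schedule, massLedger = mass, clamped = clamped)
}

#' Explicit-stability report for the solver configuration
#'
#' Evaluates the explicit-scheme bounds for the stiffest scheduled
#' interaction L = L0 + a: the fourth-order (interfacial) bound
#' dx^4/(32 Mc alpha) and the anti-diffusion bound dx^2/(4 Mc |f''|) at the
#' most negative curvature f''(0.5) = 4RT - 2L. The configuration fails
#' when dt exceeds either bound; [chStep()] then sub-steps by (at least)
#' the suggested integer factor. The run-time sub-step count additionally
#' tracks the instantaneous composition extremes, which sharpen the bound
#' as the phases approach coexistence.
#'
#' @param grid a [GridSpec-class].
#' @param cfg a [SolverConfig-class].
#' @param schedule an [InteractionSchedule-class].
#' @return A list: \code{fourthOrderBound} and \code{antiDiffusionBound}
#'   (seconds), \code{maxStableDt}, \code{pass}, and the suggested
#'   \code{substepFactor}.
#' @export
stabilityCheck <- function(grid, cfg, schedule = interactionSchedule()) {
  p <- schedule@thermo
  Mc <- mobility(p)
  dxm <- grid@dx * 1e-6
  Lmax <- p@L0 + p@a
  fppMin <- 4 * p@R * p@T - 2 * Lmax
  fourth <- dxm^4 / (32 * Mc * p@alpha)
  anti <- if (fppMin < 0) dxm^2 / (4 * Mc * abs(fppMin)) else Inf
  maxDt <- min(fourth, anti)
  list(fourthOrderBound = fourth, antiDiffusionBound = anti,
       maxStableDt = maxDt, pass = cfg@dt <= maxDt,
       substepFactor = max(1L, as.integer(ceiling(cfg@dt / maxDt))))
}

#' Total mass of the field
#'
#' The plain sum of eta over all grid cells -- the quantity the conserved
#' dynamics and the compensated wall relaxation must hold constant.
#'
#' @param object a [FieldState-class] or [Trajectory-class] (for a
#'   trajectory, the final ledger entry).
#' @return Numeric total.
#' @name totalMass
NULL

#' @rdname totalMass
#' @export
setMethod("totalMass", "FieldState", function(object) sum(object@eta))

#' @rdname totalMass
#' @export
setMethod("totalMass", "Trajectory", function(object)
  object@massLedger[length(object@massLedger)])
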