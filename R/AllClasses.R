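#' Thermodynamic constants of the PEG/dextran regular-solution model
#'
#' Bundles every constant of the free-energy functional and its kinetics:
#' the gas constant \code{R} (J mol^-1 K^-1), temperature \code{T} (K),
#' diffusion constant \code{D0} (m^2 s^-1), gradient-energy coefficient
#' \code{alpha} (J m^2 mol^-1), baseline interaction \code{L0} (J mol^-1),
#' interaction ramp amplitude \code{a} (J mol^-1) and ramp rate \code{b}
#' (s^-1), plus the logarithm guard \code{epsLog} used when evaluating the
#' ideal-mixing entropy near the composition limits. The mobility
#' Mc = D0/(R T) is always derived via [mobility()], never stored.
#'
#' @slot R,T,D0,alpha,L0,a,b,epsLog numeric scalars, see description.
#' @seealso [thermoParams()] for the constructor with the model defaults.
#' @export
setClass("ThermoParams",
  representation(R = "numeric", T = "numeric", D0 = "numeric",
                 alpha = "numeric", L0 = "numeric", a = "numeric",
                 b = "numeric", epsLog = "numeric"),
  validity = function(object) {
    msg <- character()
    for (nm in c("R", "T", "D0", "alpha"))
      if (slot(object, nm) <= 0) msg <- c(msg, paste(nm, "must be > 0"))
    if (object@a < 0) msg <- c(msg, "a must be >= 0")
    if (object@b < 0) msg <- c(msg, "b must be >= 0")
    if (object@epsLog <= 0 || object@epsLog >= 0.01)
      msg <- c(msg, "epsLog must lie in (0, 0.01)")
    if (length(msg)) msg else TRUE
  })

#' Time-ramped interaction parameter schedule
#'
#' Wraps a [ThermoParams-class] object and represents the dehydration-driven
#' interaction ramp L(t) = L0 + a (1 - 10^(-b t)): as the channel wall
#' absorbs water the polymer concentrations rise and PEG/dextran become
#' increasingly incompatible. L(0) = L0 and L increases strictly towards the
#' supremum L0 + a.
#'
#' @slot thermo a [ThermoParams-class] object.
#' @seealso [interactionParameter()]
#' @export
setClass("InteractionSchedule",
  representation(thermo = "ThermoParams"))

#' A PEG/dextran composition point
#'
#' A point (c_peg, c_dex) in % w/v on the phase diagram.
#'
#' @slot cPeg,cDex non-negative concentrations, % w/v.
#' @seealso [composition()], [classifyComposition()]
#' @export
setClass("Composition",
  representation(cPeg = "numeric", cDex = "numeric"),
  validity = function(object) {
    if (object@cPeg < 0 || object@cDex < 0)
      "concentrations must be >= 0" else TRUE
  })

#' Empirical PEG/dextran binodal curve
#'
#' Three-parameter exponential-type (Merchuk-style) binodal
#' c_dex = A exp(B sqrt(c_peg) + C c_peg^3), positive and strictly
#' decreasing over the fitted PEG range. Compositions above the curve are
#' two-phase, compositions below are homogeneous.
#'
#' @slot coefA,coefB,coefC curve coefficients (A in % w/v; B, C shape
#'   terms, both negative for a decreasing curve).
#' @slot range fitted PEG range, % w/v; classification outside it is flagged
#'   as extrapolation.
#' @seealso [binodalModel()], [binodalCurve()], [classifyComposition()]
#' @export
setClass("BinodalModel",
  representation(coefA = "numeric", coefB = "numeric", coefC = "numeric",
                 range = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@coefA <= 0) msg <- c(msg, "A must be > 0")
    if (length(object@range) != 2L || diff(object@range) <= 0)
      msg <- c(msg, "range must be an increasing pair")
    else {
      p <- seq(object@range[1], object@range[2], length.out = 101L)
      g <- object@coefA * exp(object@coefB * sqrt(p) + object@coefC * p^3)
      if (any(!is.finite(g)) || any(g <= 0))
        msg <- c(msg, "curve must be positive over the fitted range")
      else if (any(diff(g) >= 0))
        msg <- c(msg, "curve must be strictly decreasing over the fitted range")
    }
    if (length(msg)) msg else TRUE
  })

#' Channel grid specification
#'
#' Discretisation of the quasi-1D channel segment: \code{nx} cells along the
#' channel axis (periodic), \code{nz} cells across the channel (no-flux
#' walls), grid spacing \code{dx} in micrometres. The physical channel width
#' is \code{nz * dx}.
#'
#' @slot nx,nz integer cell counts; \code{nx >= 64}, \code{nz >= 4}.
#' @slot dx grid spacing, micrometres.
#' @seealso [gridSpec()], [channelWidth()]
#' @export
setClass("GridSpec",
  representation(nx = "integer", nz = "integer", dx = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nx < 64L) msg <- c(msg, "nx must be >= 64")
    if (object@nz < 4L) msg <- c(msg, "nz must be >= 4")
    if (object@dx <= 0) msg <- c(msg, "dx must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Solver configuration
#'
#' Time stepping and boundary/initialisation choices for the channel
#' simulation. \code{dt} is the outer reporting step in seconds (the solver
#' sub-steps internally whenever the explicit stability bound demands it),
#' \code{etaInit} the uniform initial order parameter, \code{etaWall} the
#' wall-preferred value of the boundary relaxation, \code{kWall} its rate
#' (s^-1), \code{noiseAmp} the amplitude of the seeded zero-mean
#' symmetry-breaking noise, \code{lagSteps} the observation-lag offset used
#' to map simulation steps to observation times, and \code{snapshotSteps}
#' the step indices at which field snapshots are recorded.
#'
#' @slot dt,etaInit,etaWall,kWall,noiseAmp numeric scalars.
#' @slot nSteps,lagSteps,snapshotSteps,seed integers; \code{seed} may be
#'   \code{NA} for unseeded noise.
#' @seealso [solverConfig()], [runSimulation()]
#' @export
setClass("SolverConfig",
  representation(dt = "numeric", nSteps = "integer", etaInit = "numeric",
                 etaWall = "numeric", kWall = "numeric",
                 noiseAmp = "numeric", seed = "integer",
                 lagSteps = "integer", snapshotSteps = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
    if (object@nSteps < 1L) msg <- c(msg, "nSteps must be >= 1")
    if (object@etaInit <= 0 || object@etaInit >= 1)
      msg <- c(msg, "etaInit must lie in (0,1)")
    if (object@etaWall <= 0 || object@etaWall >= 1)
      msg <- c(msg, "etaWall must lie in (0,1)")
    if (object@kWall < 0 || object@kWall * object@dt >= 1)
      msg <- c(msg, "kWall must satisfy 0 <= kWall*dt < 1")
    if (object@noiseAmp < 0) msg <- c(msg, "noiseAmp must be >= 0")
    if (object@noiseAmp >= min(object@etaInit, 1 - object@etaInit))
      msg <- c(msg, "noiseAmp must be < min(etaInit, 1-etaInit)")
    if (length(object@snapshotSteps) &&
        (any(object@snapshotSteps < 0L) ||
         any(object@snapshotSteps > object@nSteps)))
      msg <- c(msg, "snapshotSteps must lie in [0, nSteps]")
    if (length(msg)) msg else TRUE
  })

#' State of the simulated order-parameter field
#'
#' The 2D dextran-fraction field eta(x, z) together with the simulation
#' clock. Rows index the channel axis x, columns the cross-section z.
#'
#' @slot eta numeric matrix with all values in (0,1).
#' @slot t elapsed simulation time, seconds.
#' @slot step integer step count.
#' @seealso [initializeField()], [chStep()], [totalMass()]
#' @export
setClass("FieldState",
  representation(eta = "matrix", t = "numeric", step = "integer"),
  validity = function(object) {
    if (!is.numeric(object@eta) || any(!is.finite(object@eta)))
      return("eta must be a finite numeric matrix")
    if (any(object@eta <= 0) || any(object@eta >= 1))
      return("eta values must lie strictly in (0,1)")
    TRUE
  })

#' Recorded simulation trajectory
#'
#' Ordered field snapshots plus a per-step mass ledger and an echo of the
#' inputs that produced them.
#'
#' @slot snapshots list of [FieldState-class] objects, times strictly
#'   increasing.
#' @slot grid,config,schedule echo of the simulation inputs.
#' @slot massLedger total mass (sum of eta) after each step.
#' @slot clamped total number of guard-interval clamp events.
#' @seealso [runSimulation()], [massLedger()], [observationTimes()]
#' @export
setClass("Trajectory",
  representation(snapshots = "list", grid = "GridSpec",
                 config = "SolverConfig", schedule = "InteractionSchedule",
                 massLedger = "numeric", clamped = "integer"),
  validity = function(object) {
    tt <- vapply(object@snapshots, function(s) s@t, numeric(1))
    if (length(tt) > 1L && any(diff(tt) <= 0))
      "snapshot times must be strictly increasing" else TRUE
  })

#' A set of segmented (or ground-truth) droplets
#'
#' Labelled droplets with physical-unit measurements. \code{mode} is
#' \code{"mask"} for pixel-mask sets produced by [segmentDroplets()] (the
#' label matrix is retained for point-in-component queries) and
#' \code{"disk"} for ground-truth circle sets built by
#' [dropletSetFromTruth()].
#'
#' @slot droplets data.frame with columns \code{id}, \code{x}, \code{z}
#'   (centroid, um), \code{area} (um^2), \code{equivDiameter} (um),
#'   \code{touchesBoundary}.
#' @slot channelLength,channelWidth source geometry, um.
#' @slot threshold segmentation threshold used (NA for disk mode).
#' @slot pxScale um per pixel (NA for disk mode).
#' @slot labels integer label matrix for mask mode, else NULL.
#' @slot mode "mask" or "disk".
#' @seealso [segmentDroplets()], [sizeStatistics()],
#'   [encapsulationEfficiency()]
#' @export
setClass("DropletSet",
  representation(droplets = "data.frame", channelLength = "numeric",
                 channelWidth = "numeric", threshold = "numeric",
                 pxScale = "numeric", labels = "ANY", mode = "character"),
  validity = function(object) {
    msg <- character()
    need <- c("id", "x", "z", "area", "equivDiameter", "touchesBoundary")
    if (!all(need %in% names(object@droplets)))
      msg <- c(msg, paste("droplets must have columns",
                          paste(need, collapse = ", ")))
    else if (anyDuplicated(object@droplets$id))
      msg <- c(msg, "droplet ids must be unique")
    if (!object@mode %in% c("mask", "disk"))
      msg <- c(msg, "mode must be 'mask' or 'disk'")
    if (length(msg)) msg else TRUE
  })

#' Summary statistics of a droplet population
#'
#' @slot n droplet count.
#' @slot mean,sd mean and sample standard deviation (n-1 denominator) of the
#'   equivalent diameters, um.
#' @slot cv coefficient of variation, percent (100 sd/mean).
#' @slot linearDensity droplets per um of channel length.
#' @seealso [sizeStatistics()]
#' @export
setClass("SizeStats",
  representation(n = "integer", mean = "numeric", sd = "numeric",
                 cv = "numeric", linearDensity = "numeric"))

#' Ordinary least-squares fit of droplet diameter against channel width
#'
#' @slot slope,intercept OLS coefficients (um per um, um).
#' @slot rSquared coefficient of determination in [0,1].
#' @seealso [widthDiameterRegression()]
#' @export
setClass("RegressionResult",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric"))

#' Ground truth for a generated synthetic channel image
#'
#' @slot droplets data.frame: \code{id}, \code{x}, \code{z} (disk centre,
#'   um), \code{diameter} (um), \code{isSatellite}.
#' @slot particles data.frame: \code{x}, \code{z} (um), \code{droplet}
#'   (parent droplet id, NA for background strays); empty until
#'   [generateParticlePlacements()] fills it.
#' @slot channelLength,channelWidth,pxScale rendering geometry, um and
#'   um/px.
#' @seealso [generateDropletImage()]
#' @export
setClass("GroundTruth",
  representation(droplets = "data.frame", particles = "data.frame",
                 channelLength = "numeric", channelWidth = "numeric",
                 pxScale = "numeric"))

#' Recipe for a synthetic fluorescence-like channel image
#'
#' Emulates a channel segment populated by linearly arranged bright
#' dextran-rich disks on a dark background: diameters from a truncated
#' normal distribution (truncation at 0 and the channel width), optional
#' satellite subpopulation, sequential placement with a minimum gap and
#' axial/lateral jitter, Gaussian point-spread blur and additive Gaussian
#' noise. Fully seeded.
#'
#' @slot channelLength,channelWidth,pxScale geometry, um and um/px.
#' @slot nDroplets requested droplet count.
#' @slot diameterMean,diameterSd main-mode truncated-normal parameters, um.
#' @slot satelliteFraction,satelliteMean,satelliteSd optional satellite
#'   subpopulation (fraction in [0,1], its own truncated normal).
#' @slot minGap minimum surface-to-surface gap, um.
#' @slot intensityDroplet,intensityBackground rendered intensity levels.
#' @slot psfSigma Gaussian blur sigma, um (0 disables).
#' @slot noiseSd additive Gaussian noise level (0 disables).
#' @slot seed integer RNG seed.
#' @seealso [syntheticImageSpec()], [generateDropletImage()]
#' @export
setClass("SyntheticImageSpec",
  representation(channelLength = "numeric", channelWidth = "numeric",
                 pxScale = "numeric", nDroplets = "integer",
                 diameterMean = "numeric", diameterSd = "numeric",
                 satelliteFraction = "numeric", satelliteMean = "numeric",
                 satelliteSd = "numeric", minGap = "numeric",
                 intensityDroplet = "numeric",
                 intensityBackground = "numeric", psfSigma = "numeric",
                 noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@diameterMean > object@channelWidth)
      msg <- c(msg, "diameterMean must be <= channelWidth")
    if (object@minGap < 0) msg <- c(msg, "minGap must be >= 0")
    if (object@satelliteFraction < 0 || object@satelliteFraction > 1)
      msg <- c(msg, "satelliteFraction must lie in [0,1]")
    if (object@pxScale <= 0) msg <- c(msg, "pxScale must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Diffusion-limited dehydration model parameters
#'
#' Water-loss fraction phi(t, w) of a channel of width w after time t,
#' referencing channel volume to wall area so concentration rise scales as
#' 1/w^2: quadratic mode phi = min(0.99, c t / w^2), exponential mode
#' phi = phiMax (1 - exp(-c t / w^2)). \code{rateCoefficient} c is in
#' um^2 s^-1 and absorbs permeability, humidity and geometry.
#'
#' @slot rateCoefficient effective water-loss coefficient, um^2 s^-1, > 0.
#' @slot scalingMode "quadratic" or "exponential".
#' @slot phiMax saturation water-loss fraction (exponential mode only).
#' @seealso [dehydrationParams()], [waterLossFraction()],
#'   [calibrateDehydration()]
#' @export
setClass("DehydrationParams",
  representation(rateCoefficient = "numeric", scalingMode = "character",
                 phiMax = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@rateCoefficient <= 0)
      msg <- c(msg, "rateCoefficient must be > 0")
    if (!object@scalingMode %in% c("quadratic", "exponential"))
      msg <- c(msg, "scalingMode must be 'quadratic' or 'exponential'")
    if (object@phiMax <= 0 || object@phiMax > 1)
      msg <- c(msg, "phiMax must lie in (0,1]")
    if (length(msg)) msg else TRUE
  })
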