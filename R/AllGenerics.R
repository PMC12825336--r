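#' @rdname mobility
#' @export
setGeneric("mobility", function(object) standardGeneric("mobility"))

#' @rdname totalMass
#' @export
setGeneric("totalMass", function(object) standardGeneric("totalMass"))

#' @rdname accessors
#' @export
setGeneric("etaField", function(object) standardGeneric("etaField"))

#' @rdname accessors
#' @export
setGeneric("simTime", function(object) standardGeneric("simTime"))

#' @rdname accessors
#' @export
setGeneric("droplets", function(object) standardGeneric("droplets"))

#' @rdname accessors
#' @export
setGeneric("snapshots", function(object) standardGeneric("snapshots"))

#' @rdname accessors
#' @export
setGeneric("massLedger", function(object) standardGeneric("massLedger"))

#' @rdname accessors
#' @export
setGeneric("observationTimes",
           function(object) standardGeneric("observationTimes"))

#' @rdname accessors
#' @export
setGeneric("channelWidth", function(object) standardGeneric("channelWidth"))

#' @rdname segmentDroplets
#' @export
setGeneric("segmentDroplets",
           function(x, ...) standardGeneric("segmentDroplets"))

# ---- accessors -------------------------------------------------------------

#' Accessors for the simulation and morphometrics containers
#'
#' \code{etaField} and \code{simTime} extract the order-parameter matrix and
#' the clock of a [FieldState-class]; \code{droplets} the measurement table
#' of a [DropletSet-class]; \code{snapshots}, \code{massLedger} and
#' \code{observationTimes} the recorded states, the per-step total mass and
#' the observation-lag-corrected snapshot times (seconds) of a
#' [Trajectory-class]; \code{channelWidth} the physical width of a
#' [GridSpec-class] in micrometres.
#'
#' @param object the container to access.
#' @return See description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("etaField", "FieldState", function(object) object@eta)

#' @rdname accessors
#' @export
setMethod("simTime", "FieldState", function(object) object@t)

#' @rdname accessors
#' @export
setMethod("droplets", "DropletSet", function(object) object@droplets)

#' @rdname accessors
#' @export
setMethod("snapshots", "Trajectory", function(object) object@snapshots)

#' @rdname accessors
#' @export
setMethod("massLedger", "Trajectory", function(object) object@massLedger)

#' @rdname accessors
#' @export
setMethod("observationTimes", "Trajectory", function(object) {
  vapply(object@snapshots, function(s) s@t, numeric(1)) -
    object@config@lagSteps * object@config@dt
})

#' @rdname accessors
#' @export
setMethod("channelWidth", "GridSpec", function(object) object@nz * object@dx)

# ---- show methods ----------------------------------------------------------

setMethod("show", "ThermoParams", function(object) {
  cat("ThermoParams: R =", object@R, "J/mol/K, T =", object@T, "K, Mc =",
      format(mobility(object), digits = 4), "mol m^2/J/s\n")
  cat("  D0 =", object@D0, "m^2/s, alpha =", object@alpha,
      "J m^2/mol\n  L0 =", object@L0, ", a =", object@a, "J/mol, b =",
      object@b, "/s, epsLog =", object@epsLog, "\n")
})

setMethod("show", "Composition", function(object) {
  cat(sprintf("Composition: %g%% PEG : %g%% DEX (w/v)\n",
              object@cPeg, object@cDex))
})

setMethod("show", "BinodalModel", function(object) {
  cat(sprintf(
    "BinodalModel: c_dex = %.4g exp(%.4g sqrt(c_peg) %+.4g c_peg^3), fitted on [%g, %g]%% PEG\n",
    object@coefA, object@coefB, object@coefC, object@range[1], object@range[2]))
})

setMethod("show", "FieldState", function(object) {
  cat(sprintf(
    "FieldState: %d x %d field, t = %g s (step %d), eta in [%.4g, %.4g], mean %.6g\n",
    nrow(object@eta), ncol(object@eta), object@t, object@step,
    min(object@eta), max(object@eta), mean(object@eta)))
})

setMethod("show", "Trajectory", function(object) {
  drift <- if (length(object@massLedger))
    max(abs(object@massLedger - object@massLedger[1])) / object@massLedger[1]
  else NA_real_
  cat(sprintf(
    "Trajectory: %d steps (dt = %g s), %d snapshots at steps %s\n",
    object@config@nSteps, object@config@dt, length(object@snapshots),
    paste(vapply(object@snapshots, function(s) s@step, integer(1)),
          collapse = ", ")))
  cat(sprintf("  relative mass drift %.3g, clamp events %d\n",
              drift, object@clamped))
})

setMethod("show", "DropletSet", function(object) {
  cat(sprintf(
    "DropletSet (%s): %d droplets in %g x %g um channel (threshold %s)\n",
    object@mode, nrow(object@droplets), object@channelLength,
    object@channelWidth, format(object@threshold)))
})

setMethod("show", "SizeStats", function(object) {
  cat(sprintf(
    "SizeStats: n = %d, mean = %.3g um, sd = %.3g um, CV = %.3g%%, %.3g droplets/um\n",
    object@n, object@mean, object@sd, object@cv, object@linearDensity))
})

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult: diameter = %.4g width %+.4g um, R^2 = %.5g\n",
              object@slope, object@intercept, object@rSquared))
})

setMethod("show", "DehydrationParams", function(object) {
  cat(sprintf("DehydrationParams (%s): rate = %.5g um^2/s%s\n",
              object@scalingMode, object@rateCoefficient,
              if (object@scalingMode == "exponential")
                sprintf(", phiMax = %.4g", object@phiMax) else ""))
})
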