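#' Construct the thermodynamic parameter set
#'
#' Defaults are the constants of the channel study: R = 8.31 J/mol/K,
#' T = 295 K, D0 = 1e-14 m^2/s, alpha = 3.5e-8 J m^2/mol, L0 = 7300 J/mol,
#' a = 10000 J/mol, b = 5e-3 /s. The mobility Mc = D0/(R T) follows from
#' these and is returned by [mobility()].
#'
#' @param R gas constant, J/mol/K.
#' @param T temperature, K.
#' @param D0 diffusion constant, m^2/s.
#' @param alpha gradient-energy coefficient, J m^2/mol.
#' @param L0 baseline interaction, J/mol.
#' @param a interaction ramp amplitude, J/mol.
#' @param b interaction ramp rate, 1/s.
#' @param epsLog guard for the entropy logarithms, dimensionless.
#' @return A [ThermoParams-class] object.
#' @examples
#' p <- thermoParams()
#' mobility(p)  # D0/(R*T)
#' @export
thermoParams <- function(R = 8.31, T = 295, D0 = 1e-14, alpha = 3.5e-8,
                         L0 = 7300, a = 10000, b = 5e-3, epsLog = 1e-6) {
  new("ThermoParams", R = R, T = T, D0 = D0, alpha = alpha, L0 = L0,
      a = a, b = b, epsLog = epsLog)
}

#' Mobility Mc = D0/(R T)
#'
#' @param object a [ThermoParams-class] or [InteractionSchedule-class].
#' @return The diffusivity parameter Mc in mol m^2 J^-1 s^-1.
#' @name mobility
NULL

#' @rdname mobility
#' @export
setMethod("mobility", "ThermoParams", function(object)
  object@D0 / (object@R * object@T))

#' @rdname mobility
#' @export
setMethod("mobility", "InteractionSchedule", function(object)
  mobility(object@thermo))

#' Construct an interaction-parameter schedule
#'
#' @param thermo a [ThermoParams-class] object.
#' @return An [InteractionSchedule-class].
#' @export
interactionSchedule <- function(thermo = thermoParams()) {
  new("InteractionSchedule", thermo = thermo)
}

#' Evaluate the time-ramped interaction parameter L(t)
#'
#' L(t) = L0 + a (1 - 10^(-b t)), the base-10 exponential ramp that models
#' the increasing PEG/dextran incompatibility as the channel dehydrates.
#' L(0) = L0 and L(t) increases strictly towards L0 + a.
#'
#' @param t time(s) since the homogeneous initial state, seconds; vectorised.
#' @param schedule an [InteractionSchedule-class].
#' @return Interaction parameter(s), J/mol.
#' @examples
#' s <- interactionSchedule()
#' interactionParameter(c(0, 200), s)  # 7300, 16300
#' @export
interactionParameter <- function(t, schedule = interactionSchedule()) {
  stopifnot(is(schedule, "InteractionSchedule"))
  if (any(t < 0)) stop("t must be >= 0")
  p <- schedule@thermo
  p@L0 + p@a * (1 - 10^(-p@b * t))
}

.checkGuard <- function(eta, p) {
  if (any(!is.finite(eta)))
    stop("eta contains non-finite values")
  if (any(eta < p@epsLog) || any(eta > 1 - p@epsLog))
    stop("eta outside the guarded interval [epsLog, 1-epsLog]")
}

#' Bulk free-energy density of the regular-solution model
#'
#' f(eta) = RT[eta ln eta + (1-eta) ln(1-eta)] + L eta (1-eta), the
#' ideal-mixing entropy plus the polymer-incompatibility interaction term.
#' Exactly symmetric about eta = 0.5; for L > 2RT the entropy/interaction
#' competition yields a double well and two coexisting phases.
#'
#' @param eta dextran fraction(s) in the guarded interval
#'   [epsLog, 1-epsLog]; vectorised.
#' @param L interaction parameter, J/mol.
#' @param p a [ThermoParams-class].
#' @return Free-energy density, J/mol.
#' @export
bulkFreeEnergyDensity <- function(eta, L, p = thermoParams()) {
  .checkGuard(eta, p)
  RT <- p@R * p@T
  RT * (eta * log(eta) + (1 - eta) * log(1 - eta)) + L * eta * (1 - eta)
}

#' Curvature f''(eta) of the bulk free energy
#'
#' f''(eta) = RT(1/eta + 1/(1-eta)) - 2L. Negative curvature marks the
#' spinodal region where a uniform mixture is unstable to infinitesimal
#' composition fluctuations; f'' = 0 at eta = 0.5 when L = 2RT (the critical
#' point).
#'
#' @inheritParams bulkFreeEnergyDensity
#' @return Second derivative, J/mol.
#' @export
spinodalCurvature <- function(eta, L, p = thermoParams()) {
  .checkGuard(eta, p)
  p@R * p@T * (1 / eta + 1 / (1 - eta)) - 2 * L
}

# 5-point Laplacian, periodic in x (rows), mirror/no-flux in z (cols);
# dx in metres. Shared by the R-level chemical potential and the tests'
# oracles; the compiled solver kernel implements the identical stencil.
.laplacian <- function(m, dxm) {
  nx <- nrow(m); nz <- ncol(m)
  up    <- m[c(nx, seq_len(nx - 1L)), , drop = FALSE]
  down  <- m[c(seq_len(nx)[-1L], 1L), , drop = FALSE]
  left  <- m[, c(1L, seq_len(nz - 1L)), drop = FALSE]   # mirror ghost
  right <- m[, c(seq_len(nz)[-1L], nz), drop = FALSE]
  (up + down + left + right - 4 * m) / dxm^2
}

#' Chemical potential field mu = dF/deta
#'
#' mu = RT ln(eta/(1-eta)) + L (1 - 2 eta) - alpha lap(eta), the variational
#' derivative of the free-energy functional whose gradient drives the
#' conserved Cahn-Hilliard flux. The Laplacian uses the channel stencil:
#' periodic along x (matrix rows), no-flux mirror ghosts at the z walls.
#'
#' @param field numeric matrix of eta values inside the guarded interval.
#' @param L interaction parameter, J/mol.
#' @param p a [ThermoParams-class].
#' @param grid a [GridSpec-class]; only the spacing \code{dx} (um) is used.
#' @return Matrix of chemical potentials, J/mol, same shape as \code{field}.
#' @export
chemicalPotentialField <- function(field, L, p = thermoParams(),
                                   grid = gridSpec()) {
  if (!is.matrix(field)) stop("field must be a matrix")
  .checkGuard(field, p)
  RT <- p@R * p@T
  RT * log(field / (1 - field)) + L * (1 - 2 * field) -
    p@alpha * .laplacian(field, grid@dx * 1e-6)
}
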