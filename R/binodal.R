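#' Construct a composition point
#'
#' @param cPeg,cDex PEG and dextran concentrations, % w/v.
#' @return A [Composition-class].
#' @export
composition <- function(cPeg, cDex) new("Composition", cPeg = cPeg, cDex = cDex)

#' Construct the empirical PEG/dextran binodal
#'
#' Default coefficients are a Merchuk-type curve
#' c_dex = A exp(B sqrt(c_peg) + C c_peg^3) anchored so that the 4%:4%
#' mixture is homogeneous while 5%:5% sits just inside the two-phase
#' region (symmetric fixed point g(c) = c at 4.9% w/v), with plausible
#' endpoints for a PEG ~8 kDa / dextran ~200 kDa system over 1-10% PEG.
#'
#' @param A,B,C curve coefficients.
#' @param range fitted PEG range, % w/v.
#' @return A [BinodalModel-class].
#' @export
binodalModel <- function(A = 19.34713585, B = -0.5182759059,
                         C = -0.001921449072, range = c(1, 10)) {
  new("BinodalModel", coefA = A, coefB = B, coefC = C, range = range)
}

#' Evaluate the binodal curve c_dex = g(c_peg)
#'
#' @param m a [BinodalModel-class].
#' @param cPeg PEG concentration(s), % w/v; vectorised.
#' @return Dextran concentration(s) on the binodal, % w/v.
#' @export
binodalCurve <- function(m, cPeg) {
  stopifnot(is(m, "BinodalModel"))
  m@coefA * exp(m@coefB * sqrt(cPeg) + m@coefC * cPeg^3)
}

.isTwoPhase <- function(cPeg, cDex, m) cDex > binodalCurve(m, cPeg)

#' Classify a composition as homogeneous or two-phase
#'
#' A composition is two-phase iff it lies strictly above the binodal,
#' c_dex > g(c_peg). Pure-water-like points below the curve remain
#' homogeneous and require dehydration (see [dilutionTrajectory()]) to
#' demix.
#'
#' @param c a [Composition-class].
#' @param m a [BinodalModel-class].
#' @return A list with \code{label} ("homogeneous" or "two_phase") and
#'   \code{extrapolated} (TRUE when c_peg falls outside the fitted range).
#' @examples
#' m <- binodalModel()
#' classifyComposition(composition(4, 4), m)$label  # homogeneous
#' classifyComposition(composition(5, 5), m)$label  # two_phase
#' @export
classifyComposition <- function(c, m = binodalModel()) {
  stopifnot(is(c, "Composition"))
  list(label = if (.isTwoPhase(c@cPeg, c@cDex, m)) "two_phase"
               else "homogeneous",
       extrapolated = c@cPeg < m@range[1] || c@cPeg > m@range[2])
}

#' Dehydration dilution trajectory
#'
#' Removing a water fraction phi at fixed polymer content scales both
#' concentrations by 1/(1-phi); the PEG:DEX ratio is preserved exactly, so
#' the composition moves outward along a ray from the origin.
#'
#' @param c0 initial [Composition-class].
#' @param waterLossFraction numeric vector of phi values in [0, 1).
#' @return data.frame with columns \code{phi}, \code{cPeg}, \code{cDex}.
#' @examples
#' dilutionTrajectory(composition(4, 4), 0.2)  # (5, 5)
#' @export
dilutionTrajectory <- function(c0, waterLossFraction) {
  stopifnot(is(c0, "Composition"))
  if (any(waterLossFraction < 0) || any(waterLossFraction >= 1))
    stop("water loss fraction must lie in [0, 1)")
  f <- 1 / (1 - waterLossFraction)
  data.frame(phi = waterLossFraction, cPeg = c0@cPeg * f, cDex = c0@cDex * f)
}

#' Concentration factor needed to cross the binodal
#'
#' The smallest factor f >= 1 such that f * c0 classifies two-phase, i.e.
#' the concentration rise a homogeneous mixture must accumulate through
#' dehydration before demixing starts. Found by bisection to relative
#' tolerance 1e-6; returns 1 when c0 is already two-phase, and NA (no
#' crossing) when even a tenfold concentration leaves the mixture
#' homogeneous.
#'
#' @param c0 a [Composition-class].
#' @param m a [BinodalModel-class].
#' @param fMax search cap for the factor (default 10).
#' @param tol relative bisection tolerance.
#' @return Numeric factor, or NA_real_ if no crossing below \code{fMax}.
#' @export
binodalCrossingFactor <- function(c0, m = binodalModel(), fMax = 10,
                                  tol = 1e-6) {
  stopifnot(is(c0, "Composition"))
  if (.isTwoPhase(c0@cPeg, c0@cDex, m)) return(1)
  if (!.isTwoPhase(fMax * c0@cPeg, fMax * c0@cDex, m)) return(NA_real_)
  lo <- 1; hi <- fMax
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (.isTwoPhase(mid * c0@cPeg, mid * c0@cDex, m)) hi <- mid else lo <- mid
  }
  hi
}

#' Read or write a binodal model as JSON
#'
#' The document stores a form identifier, the three coefficients and the
#' fitted range.
#'
#' @param m a [BinodalModel-class].
#' @param path file path.
#' @return \code{readBinodalModel} returns a [BinodalModel-class];
#'   \code{writeBinodalModel} the path, invisibly.
#' @export
writeBinodalModel <- function(m, path) {
  stopifnot(is(m, "BinodalModel"))
  jsonlite::write_json(
    list(form = "merchuk-exp", A = m@coefA, B = m@coefB, C = m@coefC, range = m@range),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBinodalModel
#' @export
readBinodalModel <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(d$form, "merchuk-exp"))
    stop("unsupported binodal form: ", d$form)
  binodalModel(A = d$A, B = d$B, C = d$C, range = d$range)
}

#' Export a classified phase-diagram grid as CSV
#'
#' @param m a [BinodalModel-class].
#' @param path output CSV path.
#' @param cPeg,cDex grid axes, % w/v.
#' @return The classified grid, invisibly (columns c_peg, c_dex, label).
#' @export
exportPhaseDiagram <- function(m, path,
                               cPeg = seq(1, 10, by = 0.25),
                               cDex = seq(0.25, 12, by = 0.25)) {
  g <- expand.grid(c_peg = cPeg, c_dex = cDex)
  g$label <- ifelse(.isTwoPhase(g$c_peg, g$c_dex, m), "two_phase",
                    "homogeneous")
  write.csv(g, path, row.names = FALSE)
  invisible(g)
}
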