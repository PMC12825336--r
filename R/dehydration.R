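#' Construct dehydration model parameters
#'
#' @param rateCoefficient effective water-loss coefficient c, um^2/s.
#' @param scalingMode "quadratic" (phi = min(0.99, c t / w^2)) or
#'   "exponential" (phi = phiMax (1 - exp(-c t / w^2))).
#' @param phiMax saturation water loss, exponential mode only.
#' @return A [DehydrationParams-class].
#' @export
dehydrationParams <- function(rateCoefficient,
                              scalingMode = c("quadratic", "exponential"),
                              phiMax = 0.99) {
  new("DehydrationParams", rateCoefficient = rateCoefficient,
      scalingMode = match.arg(scalingMode), phiMax = phiMax)
}

#' The four printed channel-series conditions
#'
#' Channel width (um), the symmetric PEG:DEX loading concentration tailored
#' to it (% w/v), and the observed onset of phase separation (minutes):
#' 1%:1% in 5 um (~3 min), 2%:2% in 10 um (~7 min), 3%:3% in 15 um
#' (~8 min), 4%:4% in 20 um (~10 min).
#'
#' @return data.frame with columns width, cPeg, cDex, onsetMin.
#' @export
channelConditions <- function() {
  data.frame(width = c(5, 10, 15, 20), cPeg = 1:4, cDex = 1:4,
             onsetMin = c(3, 7, 8, 10))
}

#' Water-loss fraction of a channel after time t
#'
#' Diffusion-limited dehydration through the channel wall: the absorbed
#' water volume scales with wall area while the reservoir scales with
#' channel volume, so the lost fraction rises as t/width^2. phi(0) = 0,
#' phi is strictly increasing in t and, at fixed t, decreasing in width.
#'
#' @param t time(s) since loading, seconds; vectorised.
#' @param width channel width, um.
#' @param p a [DehydrationParams-class].
#' @return Water-loss fraction(s) in [0, 1).
#' @export
waterLossFraction <- function(t, width, p) {
  stopifnot(is(p, "DehydrationParams"), all(t >= 0), width > 0)
  tau <- p@rateCoefficient * t / width^2
  switch(p@scalingMode,
         quadratic = pmin(0.99, tau),
         exponential = p@phiMax * (1 - exp(-tau)))
}

#' Predicted time until dehydration triggers phase separation
#'
#' The first time t at which the dilution trajectory of c0 under
#' [waterLossFraction()] crosses the binodal, i.e. phi(t) reaches
#' phi* = 1 - 1/f* with f* the [binodalCrossingFactor()]. Inverted by
#' root bracketing/bisection on phi(t) - phi*.
#'
#' @param c0 initial [Composition-class].
#' @param width channel width, um.
#' @param p a [DehydrationParams-class].
#' @param m a [BinodalModel-class].
#' @return Time in minutes, with attribute \code{"alreadySeparated"};
#'   0 when c0 is already two-phase, Inf when the model never reaches the
#'   required concentration factor.
#' @export
timeToSeparation <- function(c0, width, p, m = binodalModel()) {
  fstar <- binodalCrossingFactor(c0, m)
  if (is.na(fstar)) return(structure(Inf, alreadySeparated = FALSE))
  if (fstar <= 1) return(structure(0, alreadySeparated = TRUE))
  phiStar <- 1 - 1 / fstar
  reach <- switch(p@scalingMode, quadratic = 0.99, exponential = p@phiMax)
  if (phiStar >= reach) return(structure(Inf, alreadySeparated = FALSE))
  hi <- width^2 / p@rateCoefficient  # tau = 1
  while (waterLossFraction(hi, width, p) < phiStar) hi <- hi * 2
  t <- uniroot(function(t) waterLossFraction(t, width, p) - phiStar,
               c(0, hi), tol = 1e-9 * hi)$root
  structure(t / 60, alreadySeparated = FALSE)
}

#' Calibrate the dehydration model on observed onset times
#'
#' Least-squares fit of the rate coefficient (and, in exponential mode, the
#' saturation phiMax) minimising squared log-time residuals, so minute- and
#' few-minute-scale conditions weigh comparably. In quadratic mode the
#' log-residual problem is linear in log(c) and solved in closed form; in
#' exponential mode both parameters are fitted numerically.
#'
#' @param conditions data.frame with columns width (um), cPeg, cDex
#'   (% w/v) and onsetMin (minutes), e.g. [channelConditions()].
#' @param m a [BinodalModel-class].
#' @param scalingMode "quadratic" or "exponential".
#' @return A list: \code{params} ([DehydrationParams-class]) and
#'   \code{report}, a data.frame with per-condition observed and predicted
#'   onset times (minutes) and log residuals.
#' @examples
#' fit <- calibrateDehydration(channelConditions())
#' fit$report
#' @export
calibrateDehydration <- function(conditions, m = binodalModel(),
                                 scalingMode = c("quadratic",
                                                 "exponential")) {
  scalingMode <- match.arg(scalingMode)
  need <- c("width", "cPeg", "cDex", "onsetMin")
  if (!all(need %in% names(conditions)))
    stop("conditions must have columns ", paste(need, collapse = ", "))
  if (nrow(conditions) < 2L) stop("need at least 2 conditions")
  if (length(unique(conditions$width)) < 2L)
    stop("ill-posed calibration: all conditions share the same width")
  phiStar <- vapply(seq_len(nrow(conditions)), function(i) {
    f <- binodalCrossingFactor(
      composition(conditions$cPeg[i], conditions$cDex[i]), m)
    if (is.na(f)) stop("condition ", i, " never crosses the binodal")
    if (f <= 1) stop("condition ", i, " is already two-phase")
    1 - 1 / f
  }, numeric(1))
  tObs <- conditions$onsetMin * 60

  if (scalingMode == "quadratic") {
    # t = phi* w^2 / c  =>  log c = mean(log(phi* w^2) - log t_obs)
    logC <- mean(log(phiStar * conditions$width^2) - log(tObs))
    params <- dehydrationParams(exp(logC), "quadratic")
  } else {
    obj <- function(par) {
      cc <- exp(par[1])
      pm <- max(phiStar) + (1 - max(phiStar)) / (1 + exp(-par[2]))
      tPred <- -conditions$width^2 / cc * log(1 - phiStar / pm)
      sum((log(tPred) - log(tObs))^2)
    }
    fit <- optim(c(log(mean(phiStar * conditions$width^2 / tObs)), 0), obj,
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    pm <- max(phiStar) + (1 - max(phiStar)) / (1 + exp(-fit$par[2]))
    params <- dehydrationParams(exp(fit$par[1]), "exponential", phiMax = pm)
  }
  pred <- vapply(seq_len(nrow(conditions)), function(i)
    as.numeric(timeToSeparation(
      composition(conditions$cPeg[i], conditions$cDex[i]),
      conditions$width[i], params, m)), numeric(1))
  report <- data.frame(conditions,
                       predictedMin = pred,
                       logResidual = log(pred) - log(conditions$onsetMin))
  list(params = params, report = report)
}
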