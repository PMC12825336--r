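#' Construct a synthetic channel-image recipe
#'
#' Defaults emulate the 20 um channel condition of the size series: 140
#' droplets of mean 18.3 um with CV 16.3% (sd = 0.163 * 18.3 um), rendered
#' at 0.2 um/px with a 0.4 um Gaussian point spread and mild additive
#' noise. \code{channelLength = NA} auto-sizes the channel to fit the
#' requested droplet count.
#'
#' @param channelWidth channel width, um.
#' @param nDroplets droplet count.
#' @param diameterMean,diameterSd main-mode truncated normal, um.
#' @param channelLength channel length, um, or NA to auto-size.
#' @param pxScale um per pixel.
#' @param satelliteFraction fraction of droplets drawn from the satellite
#'   mode.
#' @param satelliteMean,satelliteSd satellite-mode truncated normal, um.
#' @param minGap minimum surface-to-surface gap, um.
#' @param intensityDroplet,intensityBackground rendered levels.
#' @param psfSigma Gaussian blur sigma, um.
#' @param noiseSd additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return A [SyntheticImageSpec-class].
#' @export
syntheticImageSpec <- function(channelWidth = 20, nDroplets = 140L,
                               diameterMean = 18.3,
                               diameterSd = 0.163 * 18.3,
                               channelLength = NA_real_, pxScale = 0.2,
                               satelliteFraction = 0, satelliteMean = 7,
                               satelliteSd = 2, minGap = 2,
                               intensityDroplet = 1,
                               intensityBackground = 0.1, psfSigma = 0.4,
                               noiseSd = 0.02, seed = 1L) {
  if (is.na(channelLength))
    channelLength <- ceiling(
      nDroplets * (diameterMean + 2 * minGap) + 4 * minGap)
  new("SyntheticImageSpec", channelLength = channelLength,
      channelWidth = channelWidth, pxScale = pxScale,
      nDroplets = as.integer(nDroplets), diameterMean = diameterMean,
      diameterSd = diameterSd, satelliteFraction = satelliteFraction,
      satelliteMean = satelliteMean, satelliteSd = satelliteSd,
      minGap = minGap, intensityDroplet = intensityDroplet,
      intensityBackground = intensityBackground, psfSigma = psfSigma,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' The four printed channel-size presets
#'
#' Emulation presets mirroring the published size series: channel widths
#' 5/10/15/20 um with loading concentrations 1-4% w/v, mean diameters
#' 4.6/9.3/14.1/18.3 um, CVs 9.8/14.6/12.1/16.3% and onset times
#' ~3/7/8/10 min.
#'
#' @return data.frame with columns width, conc, meanDiameter, cv, onsetMin.
#' @export
dropletPresets <- function() {
  data.frame(width = c(5, 10, 15, 20), conc = 1:4,
             meanDiameter = c(4.6, 9.3, 14.1, 18.3),
             cv = c(9.8, 14.6, 12.1, 16.3), onsetMin = c(3, 7, 8, 10))
}

# truncated-normal draw on (lo, hi] by rejection
.rtrunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x > lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic channel image with ground truth
#'
#' Draws droplet diameters from the truncated normal(s) of the spec,
#' places the disks sequentially along the channel axis with gap and
#' lateral jitter (single-file, non-overlapping by construction), rasterises
#' them at the droplet intensity on the background level, then applies
#' Gaussian point-spread blur and additive Gaussian noise. Identical
#' spec (including seed) gives a bit-identical image.
#'
#' @param spec a [SyntheticImageSpec-class].
#' @return list(image = numeric matrix (rows = channel axis),
#'   truth = [GroundTruth-class]).
#' @export
generateDropletImage <- function(spec) {
  stopifnot(is(spec, "SyntheticImageSpec"))
  set.seed(spec@seed)
  n <- spec@nDroplets
  isSat <- runif(n) < spec@satelliteFraction
  d <- numeric(n)
  if (any(!isSat))
    d[!isSat] <- .rtrunc(sum(!isSat), spec@diameterMean, spec@diameterSd,
                         0, spec@channelWidth)
  if (any(isSat))
    d[isSat] <- .rtrunc(sum(isSat), spec@satelliteMean, spec@satelliteSd,
                        0, spec@channelWidth)
  need <- sum(d) + (n + 3) * spec@minGap
  if (need > spec@channelLength)
    stop(sprintf(
      "infeasible packing: %d droplets need %.1f um but channelLength is %.1f um",
      n, need, spec@channelLength))
  slack <- (spec@channelLength - sum(d) - (n + 1) * spec@minGap) / n
  cx <- numeric(n); cz <- numeric(n)
  cursor <- spec@minGap
  for (k in seq_len(n)) {
    cursor <- cursor + runif(1, 0, slack)
    cx[k] <- cursor + d[k] / 2
    zSlack <- max(0, (spec@channelWidth - d[k]) / 2 - spec@pxScale)
    cz[k] <- spec@channelWidth / 2 + runif(1, -zSlack, zSlack)
    cursor <- cursor + d[k] + spec@minGap
  }
  nxp <- as.integer(round(spec@channelLength / spec@pxScale))
  nzp <- as.integer(round(spec@channelWidth / spec@pxScale))
  img <- matrix(spec@intensityBackground, nxp, nzp)
  for (k in seq_len(n)) {
    r <- d[k] / 2
    i0 <- max(1L, floor((cx[k] - r) / spec@pxScale))
    i1 <- min(nxp, ceiling((cx[k] + r) / spec@pxScale) + 1L)
    j0 <- max(1L, floor((cz[k] - r) / spec@pxScale))
    j1 <- min(nzp, ceiling((cz[k] + r) / spec@pxScale) + 1L)
    ii <- i0:i1; jj <- j0:j1
    px <- (ii - 0.5) * spec@pxScale
    pz <- (jj - 0.5) * spec@pxScale
    inside <- outer((px - cx[k])^2, (pz - cz[k])^2, "+") <= r^2
    img[ii, jj][inside] <- spec@intensityDroplet
  }
  if (spec@psfSigma > 0)
    img <- EBImage::gblur(img, sigma = spec@psfSigma / spec@pxScale)
  if (spec@noiseSd > 0)
    img <- img + matrix(rnorm(length(img), 0, spec@noiseSd), nxp, nzp)
  truth <- new("GroundTruth",
               droplets = data.frame(id = seq_len(n), x = cx, z = cz,
                                     diameter = d, isSatellite = isSat),
               particles = data.frame(x = numeric(), z = numeric(),
                                      droplet = integer()),
               channelLength = spec@channelLength,
               channelWidth = spec@channelWidth, pxScale = spec@pxScale)
  list(image = img, truth = truth)
}

#' Place encapsulated particles into ground-truth droplets
#'
#' Per-droplet particle counts are Poisson(lambda) with positions uniform
#' inside each disk; optionally a stray background population is added so
#' that the expected stray share of all particles is \code{missFraction}.
#'
#' @param truth a [GroundTruth-class] with droplets.
#' @param lambda mean particles per droplet, >= 0.
#' @param missFraction expected fraction of particles landing outside any
#'   droplet, in [0, 1).
#' @param seed RNG seed.
#' @return The [GroundTruth-class] with its \code{particles} table filled
#'   (columns x, z, droplet; droplet is NA for strays).
#' @export
generateParticlePlacements <- function(truth, lambda, missFraction = 0,
                                       seed = 1L) {
  stopifnot(is(truth, "GroundTruth"), lambda >= 0,
            missFraction >= 0, missFraction < 1)
  set.seed(as.integer(seed))
  d <- truth@droplets
  counts <- rpois(nrow(d), lambda)
  idx <- rep(seq_len(nrow(d)), counts)
  m <- length(idx)
  r <- (d$diameter[idx] / 2) * sqrt(runif(m)) * 0.999
  th <- runif(m, 0, 2 * pi)
  px <- d$x[idx] + r * cos(th)
  pz <- d$z[idx] + r * sin(th)
  parent <- d$id[idx]
  nStray <- if (missFraction > 0)
    rpois(1, missFraction / (1 - missFraction) * lambda * nrow(d)) else 0L
  if (nStray > 0) {
    sx <- sz <- numeric(0)
    while (length(sx) < nStray) {
      tx <- runif(nStray, 0, truth@channelLength)
      tz <- runif(nStray, 0, truth@channelWidth)
      free <- vapply(seq_along(tx), function(k)
        all((tx[k] - d$x)^2 + (tz[k] - d$z)^2 > (d$diameter / 2)^2),
        logical(1))
      sx <- c(sx, tx[free]); sz <- c(sz, tz[free])
    }
    px <- c(px, sx[seq_len(nStray)])
    pz <- c(pz, sz[seq_len(nStray)])
    parent <- c(parent, rep(NA_integer_, nStray))
  }
  truth@particles <- data.frame(x = px, z = pz, droplet = parent)
  truth
}

#' Build a solver-free droplet field fixture
#'
#' Paints tanh-profile disks (interface width ~2 dx) at etaHigh = 0.9 on an
#' etaLow = 0.3 background -- the shape of a phase-separated channel field
#' without running the solver, for exercising the morphometrics stage with
#' known geometry.
#'
#' @param grid a [GridSpec-class].
#' @param dropletTable data.frame with columns \code{x}, \code{z} (centres,
#'   um) and \code{diameter} (um); may be empty.
#' @param etaHigh,etaLow plateau values.
#' @return A [FieldState-class].
#' @export
generateFieldFixture <- function(grid, dropletTable,
                                 etaHigh = 0.9, etaLow = 0.3) {
  if (nrow(dropletTable)) {
    if (any(dropletTable$diameter > channelWidth(grid)))
      stop("droplet diameters must not exceed the channel width")
    n <- nrow(dropletTable)
    if (n > 1L) {
      for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
        dist <- sqrt((dropletTable$x[a] - dropletTable$x[b])^2 +
                     (dropletTable$z[a] - dropletTable$z[b])^2)
        if (dist < (dropletTable$diameter[a] + dropletTable$diameter[b]) / 2)
          stop("droplets ", a, " and ", b, " overlap")
      }
    }
  }
  px <- (seq_len(grid@nx) - 0.5) * grid@dx
  pz <- (seq_len(grid@nz) - 0.5) * grid@dx
  eta <- matrix(etaLow, grid@nx, grid@nz)
  for (k in seq_len(nrow(dropletTable))) {
    dist <- sqrt(outer((px - dropletTable$x[k])^2,
                       (pz - dropletTable$z[k])^2, "+"))
    bump <- (etaHigh - etaLow) *
      (1 - tanh((dist - dropletTable$diameter[k] / 2) / grid@dx)) / 2
    eta <- pmax(eta, etaLow + bump)
  }
  new("FieldState", eta = eta, t = 0, step = 0L)
}
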