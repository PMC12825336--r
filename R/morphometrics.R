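#' Segment dextran-rich droplets from a field or image
#'
#' Thresholds the array (strictly above \code{threshold}), labels
#' 8-connected components, discards components smaller than \code{minArea}
#' and measures each survivor in physical units: pixel-count area, centroid
#' and the equivalent-circle diameter 2 sqrt(area/pi). Components touching
#' the channel walls (and, for non-periodic inputs, the image ends) are
#' flagged. For simulated order-parameter fields use the matrix method with
#' \code{periodicX = TRUE} so droplets crossing the periodic seam are
#' stitched, or the [FieldState-class] method which does so by default and
#' applies the eta > 0.5 phase midpoint threshold.
#'
#' @param x numeric matrix (rows = channel axis) or a [FieldState-class].
#' @param threshold segmentation level; pixels strictly above it are
#'   foreground. Default 0.5, the midpoint of the two bulk phases.
#' @param minArea minimum retained component area, um^2 (default 2 px^2 at
#'   the given scale).
#' @param pxScale physical size of one pixel, um.
#' @param periodicX treat first/last rows as adjacent.
#' @param grid for the FieldState method, the [GridSpec-class] providing
#'   the scale.
#' @param ... passed through to the matrix method.
#' @return A [DropletSet-class] (mode "mask").
#' @name segmentDroplets
NULL

#' @rdname segmentDroplets
#' @export
setMethod("segmentDroplets", "matrix",
  function(x, threshold, minArea = 2 * pxScale^2, pxScale = 1,
           periodicX = FALSE) {
    if (any(!is.finite(x))) stop("array must be finite")
    if (threshold < min(x) || threshold > max(x))
      warning("threshold lies outside the array value range")
    nx <- nrow(x); nz <- ncol(x)
    lab <- label8_cpp(x > threshold, periodicX)
    n <- max(lab)
    if (n == 0L)
      return(new("DropletSet",
                 droplets = data.frame(id = integer(), x = numeric(),
                                       z = numeric(), area = numeric(),
                                       equivDiameter = numeric(),
                                       touchesBoundary = logical()),
                 channelLength = nx * pxScale, channelWidth = nz * pxScale,
                 threshold = threshold, pxScale = pxScale, labels = lab,
                 mode = "mask"))
    fg <- which(lab > 0L)
    id <- lab[fg]
    areaPx <- tabulate(id, n)
    ij <- arrayInd(fg, dim(lab))
    # pixel centres at (i - 0.5) * scale
    cx <- (vapply(split(ij[, 1L], id), mean, numeric(1)) - 0.5) * pxScale
    cz <- (vapply(split(ij[, 2L], id), mean, numeric(1)) - 0.5) * pxScale
    touch <- rep(FALSE, n)
    wall <- unique(c(lab[, 1L], lab[, nz]))
    if (!periodicX) wall <- unique(c(wall, lab[1L, ], lab[nx, ]))
    touch[wall[wall > 0L]] <- TRUE
    area <- areaPx * pxScale^2
    keep <- which(area >= minArea)
    relab <- integer(n)
    relab[keep] <- seq_along(keep)
    lab[] <- ifelse(lab > 0L, relab[lab], 0L)
    new("DropletSet",
        droplets = data.frame(id = seq_along(keep), x = cx[keep],
                              z = cz[keep], area = area[keep],
                              equivDiameter = 2 * sqrt(area[keep] / pi),
                              touchesBoundary = touch[keep],
                              row.names = NULL),
        channelLength = nx * pxScale, channelWidth = nz * pxScale,
        threshold = threshold, pxScale = pxScale, labels = lab,
        mode = "mask")
  })

#' @rdname segmentDroplets
#' @export
setMethod("segmentDroplets", "FieldState",
  function(x, grid = gridSpec(), threshold = 0.5, ...) {
    segmentDroplets(x@eta, threshold = threshold, pxScale = grid@dx,
                    periodicX = TRUE, ...)
  })

#' Build a ground-truth (disk-mode) droplet set
#'
#' Converts a [GroundTruth-class] droplet table into a [DropletSet-class]
#' of ideal disks (area pi d^2/4), e.g. to test counting statistics on
#' populations too large to rasterise.
#'
#' @param truth a [GroundTruth-class].
#' @return A [DropletSet-class] (mode "disk").
#' @export
dropletSetFromTruth <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  d <- truth@droplets
  new("DropletSet",
      droplets = data.frame(id = d$id, x = d$x, z = d$z,
                            area = pi * d$diameter^2 / 4,
                            equivDiameter = d$diameter,
                            touchesBoundary = FALSE, row.names = NULL),
      channelLength = truth@channelLength,
      channelWidth = truth@channelWidth, threshold = NA_real_,
      pxScale = NA_real_, labels = NULL, mode = "disk")
}

#' Size statistics of a droplet population
#'
#' Mean, sample standard deviation (n-1 denominator, the error-bar
#' convention), coefficient of variation in percent and linear number
#' density (droplets per um of channel length). Boundary-touching droplets
#' are excluded by default because partial objects bias the diameter.
#'
#' @param ds a [DropletSet-class].
#' @param excludeBoundary drop boundary-touching droplets first.
#' @return A [SizeStats-class].
#' @examples
#' # diameters 18, 20, 22 um -> mean 20, sd 2, CV 10%
#' @export
sizeStatistics <- function(ds, excludeBoundary = TRUE) {
  stopifnot(is(ds, "DropletSet"))
  d <- ds@droplets
  if (excludeBoundary) d <- d[!d$touchesBoundary, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no droplets to summarise (all filtered or empty set)")
  m <- mean(d$equivDiameter)
  s <- if (nrow(d) > 1L) sd(d$equivDiameter) else 0
  new("SizeStats", n = nrow(d), mean = m, sd = s, cv = 100 * s / m,
      linearDensity = nrow(d) / ds@channelLength)
}

#' Remove satellite droplets below a diameter cutoff
#'
#' Retains droplets with equivalent diameter >= \code{minDiameter}; the
#' label matrix of mask-mode sets is updated consistently. The channel
#' study used a 14 um cutoff to separate satellites from the main
#' population in the 20 um condition.
#'
#' @param ds a [DropletSet-class].
#' @param minDiameter cutoff, um.
#' @return The filtered [DropletSet-class].
#' @export
filterSatellites <- function(ds, minDiameter) {
  stopifnot(is(ds, "DropletSet"), minDiameter >= 0)
  keep <- ds@droplets$equivDiameter >= minDiameter
  out <- ds
  out@droplets <- ds@droplets[keep, , drop = FALSE]
  if (ds@mode == "mask" && !is.null(ds@labels)) {
    kept <- ds@droplets$id[keep]
    relab <- integer(max(ds@labels, 1L))
    relab[kept] <- seq_along(kept)
    lab <- ds@labels
    lab[] <- ifelse(lab > 0L, relab[lab], 0L)
    out@labels <- lab
    out@droplets$id <- seq_along(kept)
  }
  rownames(out@droplets) <- NULL
  out
}

#' Maximum-likelihood Gaussian fit of a diameter sample
#'
#' Sample mean and ML (1/n) standard deviation, the overlay convention for
#' diameter histograms.
#'
#' @param diameters numeric vector, um; n >= 3.
#' @return list(mu, sigma, degenerate); \code{degenerate} flags a
#'   zero-variance sample.
#' @export
gaussianFit <- function(diameters) {
  if (length(diameters) < 3L) stop("need at least 3 diameters")
  mu <- mean(diameters)
  sigma <- sqrt(mean((diameters - mu)^2))
  list(mu = mu, sigma = sigma, degenerate = sigma == 0)
}

#' Regress mean droplet diameter on channel width
#'
#' Ordinary least squares of the channel-size series, quantifying the
#' linear size-templating of confined droplet formation.
#'
#' @param width channel widths, um (>= 2 distinct values).
#' @param diameter mean droplet diameters, um.
#' @return A [RegressionResult-class].
#' @export
widthDiameterRegression <- function(width, diameter) {
  if (length(width) != length(diameter) || length(unique(width)) < 2L)
    stop("need matching vectors with at least 2 distinct widths")
  fit <- lm(diameter ~ width)
  new("RegressionResult", slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      rSquared = summary(fit)$r.squared)
}

#' Throughput extrapolation from linear droplet density
#'
#' @param linearDensity droplets per um of channel length.
#' @param channelsPerCm parallel channels per cm of device width.
#' @return list(dropletsPerCmChannel, dropletsPerCmWidth): the density
#'   scaled to one cm of channel, and that times the channel parallelism.
#' @examples
#' throughputEstimate(10 / 250, 100)  # 400 per cm channel, 40000 per cm width
#' @export
throughputEstimate <- function(linearDensity, channelsPerCm) {
  stopifnot(linearDensity >= 0, channelsPerCm > 0)
  perCm <- linearDensity * 1e4
  list(dropletsPerCmChannel = perCm,
       dropletsPerCmWidth = perCm * channelsPerCm)
}

# droplet id containing each point; 0 = background
.assignParticles <- function(ds, x, z) {
  if (ds@mode == "mask") {
    lab <- ds@labels
    i <- pmin(pmax(floor(x / ds@pxScale) + 1L, 1L), nrow(lab))
    j <- pmin(pmax(floor(z / ds@pxScale) + 1L, 1L), ncol(lab))
    lab[cbind(i, j)]
  } else {
    d <- ds@droplets
    vapply(seq_along(x), function(k) {
      hit <- which((x[k] - d$x)^2 + (z[k] - d$z)^2 <=
                     (d$equivDiameter / 2)^2)
      if (length(hit)) d$id[hit[1L]] else 0L
    }, integer(1))
  }
}

#' Encapsulation efficiency of a particle population
#'
#' Fraction of droplets containing at least one particle, from a
#' point-in-component test (pixel-mask lookup for segmented sets,
#' point-in-disk for ground-truth sets), plus the per-droplet occupancy
#' table.
#'
#' @param ds a [DropletSet-class].
#' @param particles data.frame with columns \code{x}, \code{z} (um).
#' @return list(efficiency, occupancy = data.frame(id, count),
#'   particleDroplet = per-particle droplet id (0 = background)).
#' @export
encapsulationEfficiency <- function(ds, particles) {
  stopifnot(is(ds, "DropletSet"))
  n <- nrow(ds@droplets)
  if (n == 0L) stop("empty droplet set")
  if (nrow(particles) == 0L)
    return(list(efficiency = 0,
                occupancy = data.frame(id = ds@droplets$id, count = 0L),
                particleDroplet = integer()))
  who <- .assignParticles(ds, particles$x, particles$z)
  counts <- tabulate(who[who > 0L], nbins = max(ds@droplets$id))
  counts <- counts[ds@droplets$id]
  list(efficiency = mean(counts > 0L),
       occupancy = data.frame(id = ds@droplets$id, count = counts),
       particleDroplet = who)
}
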