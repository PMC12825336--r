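test_that("segmentation recovers noise-free disks at both scales", {
  for (scale in c(1, 0.2)) {
    spec <- syntheticImageSpec(channelWidth = 20, nDroplets = 5L,
                               diameterMean = 18, diameterSd = 1e-9,
                               pxScale = scale, psfSigma = 0, noiseSd = 0,
                               seed = 21L)
    gen <- generateDropletImage(spec)
    ds <- segmentDroplets(gen$image, threshold = 0.5, pxScale = scale)
    expect_identical(nrow(droplets(ds)), 5L)
    expect_true(all(abs(droplets(ds)$equivDiameter - 18) <= scale + 0.1))
    # centroids match the truth within a pixel
    d <- droplets(ds)[order(droplets(ds)$x), ]
    tr <- gen$truth@droplets[order(gen$truth@droplets$x), ]
    expect_equal(d$x, tr$x, tolerance = scale)
    expect_equal(d$z, tr$z, tolerance = scale)
  }
})

test_that("small diameters are still recovered at fine scale", {
  # diameters 4-20 um at 0.2 um/px: one-pixel-equivalent accuracy
  for (dTrue in c(4, 8, 14, 20)) {
    g <- gridSpec(nx = 64L, nz = 24L, dx = 0.2)
    fx <- generateFieldFixture(g, data.frame(x = 6.4, z = 2.4,
                                             diameter = dTrue * 0.2))
    ds <- segmentDroplets(fx, grid = g)
    expect_identical(nrow(droplets(ds)), 1L)
  }
})

test_that("an all-background field segments to an empty set", {
  expect_warning(ds <- segmentDroplets(matrix(0, 100, 20), threshold = 0.5),
                 "outside the array value range")
  expect_identical(nrow(droplets(ds)), 0L)
  expect_error(sizeStatistics(ds), "no droplets")
})

test_that("8-connectivity joins diagonals; periodic stitching joins the seam", {
  m <- matrix(0, 64, 8)
  m[10, 3] <- 1; m[11, 4] <- 1; m[12, 3] <- 1   # diagonal chain
  ds <- segmentDroplets(m, threshold = 0.5, minArea = 0)
  expect_identical(nrow(droplets(ds)), 1L)
  m2 <- matrix(0, 64, 8)
  m2[c(1, 64), 4] <- 1                          # touching across the wrap
  dsP <- segmentDroplets(m2, threshold = 0.5, minArea = 0, periodicX = TRUE)
  expect_identical(nrow(droplets(dsP)), 1L)
  dsN <- segmentDroplets(m2, threshold = 0.5, minArea = 0, periodicX = FALSE)
  expect_identical(nrow(droplets(dsN)), 2L)
})

test_that("size statistics use the sample-sd convention", {
  truth <- new("GroundTruth",
               droplets = data.frame(id = 1:3, x = c(10, 40, 70), z = 10,
                                     diameter = c(18, 20, 22),
                                     isSatellite = FALSE),
               particles = data.frame(x = numeric(), z = numeric(),
                                      droplet = integer()),
               channelLength = 100, channelWidth = 20, pxScale = 1)
  st <- sizeStatistics(dropletSetFromTruth(truth))
  expect_identical(st@n, 3L)
  expect_equal(st@mean, 20)
  expect_equal(st@sd, 2)
  expect_equal(st@cv, 10)
  expect_equal(st@linearDensity, 3 / 100)
  # degenerate single-size population
  truth@droplets$diameter <- rep(10, 3)
  st2 <- sizeStatistics(dropletSetFromTruth(truth))
  expect_equal(c(st2@mean, st2@sd, st2@cv), c(10, 0, 0))
  # cv is scale invariant
  truth@droplets$diameter <- c(18, 20, 22) * 3.7
  expect_equal(sizeStatistics(dropletSetFromTruth(truth))@cv, 10)
})

test_that("satellite filtering trims the small mode and tightens the CV", {
  truth <- new("GroundTruth",
               droplets = data.frame(id = 1:3, x = c(10, 40, 70), z = 10,
                                     diameter = c(19, 20, 5),
                                     isSatellite = c(FALSE, FALSE, TRUE)),
               particles = data.frame(x = numeric(), z = numeric(),
                                      droplet = integer()),
               channelLength = 100, channelWidth = 20, pxScale = 1)
  ds <- dropletSetFromTruth(truth)
  expect_equal(sort(droplets(filterSatellites(ds, 14))$equivDiameter),
               c(19, 20))
  expect_identical(droplets(filterSatellites(ds, 0)),
                   droplets(ds))
  # generated bimodal mixtures: filtering raises the mean, lowers the CV
  set.seed(9)
  for (i in 1:5) {
    spec <- syntheticImageSpec(nDroplets = 60L, satelliteFraction = 0.2,
                               satelliteMean = 7, satelliteSd = 2,
                               pxScale = 0.5, seed = 300L + i)
    gen <- generateDropletImage(spec)
    ds2 <- segmentDroplets(gen$image, threshold = 0.55, pxScale = 0.5)
    flt <- filterSatellites(ds2, 14)
    expect_lte(nrow(droplets(flt)), nrow(droplets(ds2)))
    s0 <- sizeStatistics(ds2, excludeBoundary = FALSE)
    s1 <- sizeStatistics(flt, excludeBoundary = FALSE)
    expect_gte(s1@mean, s0@mean)
    expect_lte(s1@cv, s0@cv)
  }
})

test_that("Gaussian fit recovers seeded normal parameters", {
  set.seed(123)
  d <- rnorm(1e4, 18.3, 1.3)
  fit <- gaussianFit(d)
  expect_equal(fit$mu, 18.3, tolerance = 0.01)
  expect_equal(fit$sigma, 1.3, tolerance = 0.01)
  expect_false(fit$degenerate)
  expect_identical(gaussianFit(rev(d)), fit)  # order invariance
  flat <- gaussianFit(rep(7, 5))
  expect_equal(c(flat$mu, flat$sigma), c(7, 0))
  expect_true(flat$degenerate)
  expect_error(gaussianFit(c(1, 2)), "at least 3")
})

test_that("width-diameter regression reproduces the hand OLS", {
  w <- c(5, 10, 15, 20)
  d <- c(4.6, 9.3, 14.1, 18.3)
  # closed-form OLS oracle
  slope <- sum((w - mean(w)) * (d - mean(d))) / sum((w - mean(w))^2)
  intercept <- mean(d) - slope * mean(w)
  fit <- widthDiameterRegression(w, d)
  expect_equal(fit@slope, slope)          # 0.918
  expect_equal(fit@intercept, intercept)  # 0.10
  expect_equal(fit@slope, 0.918, tolerance = 1e-12)
  expect_equal(fit@intercept, 0.10, tolerance = 1e-9)
  expect_gt(fit@rSquared, 0.999)
  exact <- suppressWarnings(widthDiameterRegression(1:5, 2 * (1:5) + 3))
  expect_equal(exact@rSquared, 1)
  expect_error(widthDiameterRegression(c(5, 5), c(1, 2)), "distinct widths")
})

test_that("throughput arithmetic is exactly linear", {
  thr <- throughputEstimate(10 / 250, 100)
  expect_equal(thr$dropletsPerCmChannel, 400)
  expect_equal(thr$dropletsPerCmWidth, 40000)
  expect_equal(throughputEstimate(0, 100)$dropletsPerCmWidth, 0)
  a <- throughputEstimate(0.02, 50)
  b <- throughputEstimate(0.04, 50)
  c3 <- throughputEstimate(0.02, 150)
  expect_equal(b$dropletsPerCmChannel, 2 * a$dropletsPerCmChannel)
  expect_equal(c3$dropletsPerCmWidth, 3 * a$dropletsPerCmWidth)
})

test_that("encapsulation counting matches brute-force point-in-disk", {
  set.seed(4)
  truth <- new("GroundTruth",
               droplets = data.frame(id = 1:50,
                                     x = seq(15, by = 25, length.out = 50),
                                     z = 10, diameter = 18,
                                     isSatellite = FALSE),
               particles = data.frame(x = numeric(), z = numeric(),
                                      droplet = integer()),
               channelLength = 15 + 25 * 50, channelWidth = 20, pxScale = 1)
  truth <- generateParticlePlacements(truth, lambda = 1.2,
                                      missFraction = 0.1, seed = 8L)
  ds <- dropletSetFromTruth(truth)
  res <- encapsulationEfficiency(ds, truth@particles)
  # brute force oracle
  d <- droplets(ds)
  brute <- vapply(seq_len(nrow(d)), function(k)
    any((truth@particles$x - d$x[k])^2 + (truth@particles$z - d$z[k])^2 <=
          (d$equivDiameter[k] / 2)^2), logical(1))
  expect_equal(res$efficiency, mean(brute))
  expect_equal(res$occupancy$count > 0, brute)
  # placement truth agrees with geometry
  inDrop <- !is.na(truth@particles$droplet)
  expect_equal(res$particleDroplet > 0, inDrop)
  expect_equal(encapsulationEfficiency(ds,
    data.frame(x = numeric(), z = numeric()))$efficiency, 0)
})

test_that("mask-based encapsulation agrees with the rendered geometry", {
  spec <- syntheticImageSpec(nDroplets = 12L, pxScale = 0.5, psfSigma = 0,
                             noiseSd = 0, seed = 77L)
  gen <- generateDropletImage(spec)
  truth <- generateParticlePlacements(gen$truth, lambda = 2, seed = 78L)
  ds <- segmentDroplets(gen$image, threshold = 0.5, pxScale = 0.5)
  res <- encapsulationEfficiency(ds, truth@particles)
  expected <- mean(table(factor(truth@particles$droplet,
                                levels = gen$truth@droplets$id)) > 0)
  expect_equal(res$efficiency, expected)
})
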