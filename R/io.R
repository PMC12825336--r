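#' Default pipeline configuration
#'
#' A nested list mirroring the package's parameter objects; every default
#' is the channel-study value where one is printed. Stages: "simulate"
#' (phase-field run), "analyze" (morphometrics of the last snapshot or a
#' synthetic image), "synth" (image generation), "dehydration" (timing
#' calibration).
#'
#' @return Nested configuration list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L, outdir = ".", log_level = "info",
    stages = c("simulate", "analyze"),
    thermo = list(R = 8.31, T = 295, D0 = 1e-14, alpha = 3.5e-8,
                  L0 = 7300, a = 10000, b = 5e-3, eps_log = 1e-6),
    simulate = list(nx = 256L, nz = 20L, dx = 1.0, dt = 1.0,
                    n_steps = 2600L, eta_init = 0.38, eta_wall = 0.4,
                    k_wall = 1e-5, noise_amp = 1e-3, lag_steps = 800L,
                    snapshot_minutes = c(2, 5, 15, 30)),
    analyze = list(threshold = 0.5, min_area = 2, satellite_min_diameter = 0,
                   exclude_boundary = FALSE),
    synth = list(channel_width = 20, n_droplets = 140L,
                 diameter_mean = 18.3, diameter_sd = 2.9829,
                 px_scale = 0.2, satellite_fraction = 0, min_gap = 2,
                 psf_sigma = 0.4, noise_sd = 0.02),
    dehydration = list(mode = "quadratic"))
}

.mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown configuration key(s): ",
         paste0(path, bad, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "/"))
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

.validateConfig <- function(cfg) {
  s <- cfg$simulate
  bad <- character()
  if (s$dt <= 0) bad <- c(bad, "simulate/dt must be > 0")
  if (s$dx <= 0) bad <- c(bad, "simulate/dx must be > 0")
  if (s$n_steps < 1) bad <- c(bad, "simulate/n_steps must be >= 1")
  if (s$eta_init <= 0 || s$eta_init >= 1)
    bad <- c(bad, "simulate/eta_init must be in (0,1)")
  if (cfg$analyze$min_area < 0) bad <- c(bad, "analyze/min_area must be >= 0")
  if (!cfg$dehydration$mode %in% c("quadratic", "exponential"))
    bad <- c(bad, "dehydration/mode must be quadratic or exponential")
  known <- c("simulate", "analyze", "synth", "dehydration")
  unk <- setdiff(cfg$stages, known)
  if (length(unk)) bad <- c(bad, paste("unknown stage(s):",
                                       paste(unk, collapse = ", ")))
  if (length(bad)) stop("invalid configuration:\n  ",
                        paste(bad, collapse = "\n  "))
  cfg
}

#' Load a pipeline configuration file
#'
#' Reads a YAML document, fills unset values with [defaultConfig()] and
#' validates the result. Unknown keys (at any level) and out-of-range
#' values are rejected with messages naming the offending keys; an empty
#' file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  .validateConfig(.mergeConfig(defaultConfig(), user))
}

#' Write field snapshots as a 16-bit multi-page TIFF
#'
#' eta in (0,1) maps linearly onto the 16-bit range; the scale is recorded
#' in the run metadata so fields round-trip through [readFieldTIFF()].
#'
#' @param fields a [FieldState-class], list of them, or a
#'   [Trajectory-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeFieldTIFF <- function(fields, path) {
  if (is(fields, "Trajectory")) fields <- fields@snapshots
  if (is(fields, "FieldState")) fields <- list(fields)
  pages <- lapply(fields, function(s) t(s@eta))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeFieldTIFF
#' @param simTimes simulation clock values to attach to the restored
#'   states, seconds.
#' @return \code{readFieldTIFF}: list of [FieldState-class] objects.
#' @export
readFieldTIFF <- function(path, simTimes = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(k) {
    eta <- t(pages[[k]])
    eta[eta <= 0] <- 1e-6; eta[eta >= 1] <- 1 - 1e-6
    new("FieldState", eta = eta,
        t = if (is.null(simTimes)) 0 else simTimes[k], step = 0L)
  })
}

.writeJSON <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)

#' Run the configured analysis pipeline
#'
#' Executes the configured stages in order and writes every artifact under
#' \code{outdir}: the trajectory TIFF with its CSV mass ledger, droplet
#' tables and statistics JSON, synthetic images with truth tables, the
#' dehydration fit, a diameter histogram, and a JSON manifest recording the
#' resolved configuration, seed, package version and md5 checksum of every
#' output so each artifact is reproducible from the manifest alone. A
#' failing stage leaves earlier outputs in place, marks the failure in the
#' manifest, and returns a non-zero status.
#'
#' @param cfg configuration list from [loadConfig()] or [defaultConfig()].
#' @param outdir output directory (created if needed); defaults to
#'   \code{cfg$outdir}.
#' @return Invisibly, 0 on success / 1 on stage failure, with the manifest
#'   as attribute \code{"manifest"}.
#' @export
runPipeline <- function(cfg = defaultConfig(), outdir = cfg$outdir) {
  cfg <- .validateConfig(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  status <- 0L
  failure <- NULL
  lastField <- NULL
  lastImage <- NULL
  grid <- gridSpec(cfg$simulate$nx, cfg$simulate$nz, cfg$simulate$dx)

  emit <- function(name) outputs <<- c(outputs, file.path(outdir, name))
  for (stage in cfg$stages) {
    ok <- tryCatch({
      if (stage == "simulate") {
        th <- cfg$thermo
        sched <- interactionSchedule(thermoParams(
          R = th$R, T = th$T, D0 = th$D0, alpha = th$alpha, L0 = th$L0,
          a = th$a, b = th$b, epsLog = th$eps_log))
        s <- cfg$simulate
        sc <- solverConfig(
          dt = s$dt, nSteps = s$n_steps, etaInit = s$eta_init,
          etaWall = s$eta_wall, kWall = s$k_wall, noiseAmp = s$noise_amp,
          seed = cfg$seed, lagSteps = s$lag_steps,
          snapshotSteps = snapshotStepsForMinutes(s$snapshot_minutes,
                                                  s$dt, s$lag_steps))
        traj <- runSimulation(grid, sc, sched)
        writeFieldTIFF(traj, file.path(outdir, "trajectory.tif"))
        emit("trajectory.tif")
        write.csv(data.frame(step = seq_along(traj@massLedger),
                             mass = traj@massLedger),
                  file.path(outdir, "mass_ledger.csv"), row.names = FALSE)
        emit("mass_ledger.csv")
        lastField <- traj@snapshots[[length(traj@snapshots)]]
      } else if (stage == "synth") {
        sy <- cfg$synth
        gen <- generateDropletImage(syntheticImageSpec(
          channelWidth = sy$channel_width, nDroplets = sy$n_droplets,
          diameterMean = sy$diameter_mean, diameterSd = sy$diameter_sd,
          pxScale = sy$px_scale, satelliteFraction = sy$satellite_fraction,
          minGap = sy$min_gap, psfSigma = sy$psf_sigma,
          noiseSd = sy$noise_sd, seed = cfg$seed))
        img <- pmin(pmax(gen$image, 0), 1)
        tiff::writeTIFF(t(img), file.path(outdir, "synthetic.tif"),
                        bits.per.sample = 16L)
        emit("synthetic.tif")
        write.csv(gen$truth@droplets, file.path(outdir, "truth.csv"),
                  row.names = FALSE)
        emit("truth.csv")
        lastImage <- gen
      } else if (stage == "analyze") {
        an <- cfg$analyze
        ds <- if (!is.null(lastImage)) {
          mid <- (max(lastImage$image) + min(lastImage$image)) / 2
          segmentDroplets(lastImage$image, threshold = mid,
                          minArea = an$min_area,
                          pxScale = lastImage$truth@pxScale)
        } else {
          if (is.null(lastField)) stop("analyze needs simulate or synth first")
          segmentDroplets(lastField, grid = grid, threshold = an$threshold,
                          minArea = an$min_area)
        }
        if (an$satellite_min_diameter > 0)
          ds <- filterSatellites(ds, an$satellite_min_diameter)
        write.csv(droplets(ds), file.path(outdir, "droplets.csv"),
                  row.names = FALSE)
        emit("droplets.csv")
        st <- sizeStatistics(ds, excludeBoundary = an$exclude_boundary)
        .writeJSON(list(n = st@n, mean_um = st@mean, sd_um = st@sd,
                        cv_percent = st@cv,
                        linear_density_per_um = st@linearDensity),
                   file.path(outdir, "stats.json"))
        emit("stats.json")
        grDevices::png(file.path(outdir, "histogram.png"), 640, 480)
        graphics::hist(droplets(ds)$equivDiameter, breaks = 20,
                       main = "Droplet diameters",
                       xlab = "equivalent diameter (um)")
        grDevices::dev.off()
        emit("histogram.png")
      } else if (stage == "dehydration") {
        fit <- calibrateDehydration(channelConditions(),
                                    scalingMode = cfg$dehydration$mode)
        .writeJSON(list(mode = fit$params@scalingMode,
                        rate_coefficient_um2_per_s =
                          fit$params@rateCoefficient,
                        phi_max = fit$params@phiMax),
                   file.path(outdir, "dehydration_fit.json"))
        emit("dehydration_fit.json")
        write.csv(fit$report, file.path(outdir, "dehydration_predictions.csv"),
                  row.names = FALSE)
        emit("dehydration_predictions.csv")
      }
      TRUE
    }, error = function(e) {
      failure <<- list(stage = stage, message = conditionMessage(e))
      FALSE
    })
    if (!ok) { status <- 1L; break }
  }
  manifest <- list(
    package = "atpsDroplets",
    version = as.character(packageVersion("atpsDroplets")),
    seed = cfg$seed, config = cfg,
    outputs = lapply(outputs, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))),
    failure = failure)
  .writeJSON(manifest, file.path(outdir, "manifest.json"))
  structure(invisible(status), manifest = manifest)
}
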