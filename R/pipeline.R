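PIPELINE_MODES <- c("simulate-screen", "simulate-robustness",
                    "simulate-calibration", "quantify", "analyze", "qc",
                    "render")

#' Build a validated pipeline run configuration
#'
#' Central configuration object for [runPipeline()]. Parameter overrides
#' are named lists forwarded to [sensorParams()], [kineticParams()],
#' [compartmentPH()] and [acquisitionParams()]; all resolved values are
#' recorded in the run manifest.
#'
#' @param mode one of `simulate-screen`, `simulate-robustness`,
#'   `simulate-calibration`, `quantify`, `analyze`, `qc`, `render`.
#' @param out output directory (created if missing).
#' @param seed integer seed for every stochastic stage.
#' @param sensor,kinetics,compartments,acquisition named lists of parameter
#'   overrides.
#' @param egf EGF concentration for robustness simulation (ng/ml).
#' @param t EGF incubation time (minutes).
#' @param replicates screen repeats (simulate-screen).
#' @param effects named efficacy vector for planted targets
#'   (simulate-screen).
#' @param writeImages logical, write per-field TIFFs during simulation.
#' @param imageDir image directory (input for `quantify`/`render`, output
#'   when `writeImages`).
#' @param plateMap plate-map CSV path (input for `quantify`).
#' @param measurements measurements CSV path (input for
#'   `analyze`/`qc`/`render`).
#' @param well well address like "A01" (input for `render`).
#' @param plate plate id (input for `render`).
#' @param ssmdThreshold,log2fcThreshold hit-calling cutoffs (analyze).
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(mode, out, seed = 1L, sensor = list(),
                      kinetics = list(), compartments = list(),
                      acquisition = list(), egf = 4, t = 15,
                      replicates = 3L, effects = NULL, writeImages = FALSE,
                      imageDir = NULL, plateMap = NULL, measurements = NULL,
                      well = NULL, plate = NULL, ssmdThreshold = 1.0,
                      log2fcThreshold = 0.2) {
  if (!mode %in% PIPELINE_MODES)
    stop("unknown mode '", mode, "'; must be one of: ",
         paste(PIPELINE_MODES, collapse = ", "))
  if (missing(out) || !is.character(out) || length(out) != 1L)
    stop("'out' must be a single output directory path")
  needs <- switch(mode,
    "quantify" = c(imageDir = is.null(imageDir),
                   plateMap = is.null(plateMap)),
    "analyze" = c(measurements = is.null(measurements)),
    "qc" = c(measurements = is.null(measurements)),
    "render" = c(imageDir = is.null(imageDir), well = is.null(well),
                 plate = is.null(plate)),
    logical(0))
  if (any(needs))
    stop("mode '", mode, "' requires: ",
         paste(names(needs)[needs], collapse = ", "))
  cfg <- list(mode = mode, out = out, seed = as.integer(seed),
              sensor = sensor, kinetics = kinetics,
              compartments = compartments, acquisition = acquisition,
              egf = egf, t = t, replicates = as.integer(replicates),
              effects = effects, writeImages = isTRUE(writeImages),
              imageDir = imageDir, plateMap = plateMap,
              measurements = measurements, well = well, plate = plate,
              ssmdThreshold = ssmdThreshold,
              log2fcThreshold = log2fcThreshold)
  class(cfg) <- "RunConfig"
  cfg
}

resolveParams <- function(cfg) {
  list(sensor = do.call(sensorParams, cfg$sensor),
       kinetics = do.call(kineticParams, cfg$kinetics),
       comp = do.call(compartmentPH, cfg$compartments),
       acq = do.call(acquisitionParams, cfg$acquisition))
}

paramsAsList <- function(p) {
  lapply(p, function(obj) {
    s <- methods::slotNames(class(obj))
    stats::setNames(lapply(s, function(nm) methods::slot(obj, nm)), s)
  })
}

writeManifest <- function(cfg, params, outputs, dir) {
  manifest <- list(
    mode = cfg$mode, seed = cfg$seed,
    package = "fapscreen",
    version = as.character(utils::packageVersion("fapscreen")),
    parameters = paramsAsList(params),
    config = cfg[!names(cfg) %in% c("sensor", "kinetics", "compartments",
                                    "acquisition")],
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  path
}

#' Execute a pipeline stage
#'
#' Runs one stage of the simulate -> quantify -> analyze chain according to
#' the configuration: each simulate mode writes plate maps and measurement
#' CSVs (and TIFF images when requested), `quantify` turns images plus a
#' plate map into measurements, `analyze` turns measurements into
#' dual-flashlight and hit tables, `qc` writes the plate QC table, and
#' `render` writes a pseudocolor ratio PNG for one well. Every run writes a
#' JSON manifest with the resolved parameters, seed, package version and
#' MD5 checksums of the outputs; identical configurations and seeds yield
#' identical outputs.
#'
#' @param cfg a `RunConfig` from [runConfig()].
#' @return Invisibly, a named list of written file paths (including
#'   `manifest`).
#' @export
#' @examples
#' \donttest{
#' out <- tempfile("run")
#' cfg <- runConfig("simulate-robustness", out = out, seed = 1,
#'                  acquisition = list(imageSize = 64, cellCountMean = 8,
#'                                     fieldsPerWell = 2))
#' runPipeline(cfg)
#' }
runPipeline <- function(cfg) {
  if (!inherits(cfg, "RunConfig")) stop("'cfg' must come from runConfig()")
  if (!dir.exists(cfg$out)) dir.create(cfg$out, recursive = TRUE)
  p <- resolveParams(cfg)
  imgDir <- if (cfg$writeImages) {
    d <- if (is.null(cfg$imageDir)) file.path(cfg$out, "images") else
      cfg$imageDir
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    d
  } else NULL
  outputs <- list()
  emit <- function(name, path) outputs[[name]] <<- path

  if (cfg$mode == "simulate-screen") {
    sim <- simulateScreen(replicates = cfg$replicates, effects = cfg$effects,
                          kinetics = p$kinetics, sensor = p$sensor,
                          comp = p$comp, acq = p$acq, t = cfg$t,
                          seed = cfg$seed, imageDir = imgDir)
    emit("plate_map", writePlateMap(
      buildScreenLayouts(sprintf("PP%03d", 1:240), cfg$replicates),
      file.path(cfg$out, "plate_map.csv")))
    emit("measurements", writeMeasurements(
      sim$measurements, file.path(cfg$out, "measurements.csv")))
  } else if (cfg$mode == "simulate-robustness") {
    meas <- simulateRobustnessPlate(cfg$egf, p$kinetics, p$sensor, p$comp,
                                    p$acq, t = cfg$t, seed = cfg$seed,
                                    imageDir = imgDir)
    emit("plate_map", writePlateMap(buildRobustnessLayout(cfg$egf),
                                    file.path(cfg$out, "plate_map.csv")))
    emit("measurements", writeMeasurements(
      meas, file.path(cfg$out, "measurements.csv")))
  } else if (cfg$mode == "simulate-calibration") {
    sim <- simulateCalibrationPlate(p$sensor, p$acq, seed = cfg$seed,
                                    imageDir = imgDir)
    emit("plate_map", writePlateMap(buildCalibrationLayout(),
                                    file.path(cfg$out, "plate_map.csv")))
    emit("measurements", writeMeasurements(
      sim$measurements, file.path(cfg$out, "measurements.csv")))
    emit("calibration_series", writeCalibrationSeries(
      sim$series, file.path(cfg$out, "calibration_series.csv")))
    fit <- fitCalibration(sim$series)
    emit("sensor_fit", writeSensorParams(
      fit, file.path(cfg$out, "sensor_fit.json")))
  } else if (cfg$mode == "quantify") {
    meas <- quantifyPlate(cfg$imageDir, readPlateMap(cfg$plateMap))
    emit("measurements", writeMeasurements(
      meas, file.path(cfg$out, "measurements.csv")))
  } else if (cfg$mode == "analyze") {
    meas <- readMeasurements(cfg$measurements)
    ana <- analyzeScreen(meas)
    tab <- dualFlashlight(ana)
    emit("dual_flashlight", writeDualFlashlight(
      tab, file.path(cfg$out, "dual_flashlight.csv")))
    emit("hits", writeDualFlashlight(
      callHits(tab, cfg$ssmdThreshold, cfg$log2fcThreshold),
      file.path(cfg$out, "hits.csv")))
    emit("qc", writePlateQC(ana$qc, file.path(cfg$out, "qc.csv")))
  } else if (cfg$mode == "qc") {
    meas <- readMeasurements(cfg$measurements)
    emit("qc", writePlateQC(plateQC(meas), file.path(cfg$out, "qc.csv")))
  } else if (cfg$mode == "render") {
    map <- if (!is.null(cfg$plateMap)) readPlateMap(cfg$plateMap) else NULL
    row <- substr(cfg$well, 1, 1)
    col <- as.integer(substr(cfg$well, 2, nchar(cfg$well)))
    flds <- readWellImages(cfg$imageDir, cfg$plate, row, col)
    bg <- c(0, 0)
    if (!is.null(cfg$measurements)) {
      meas <- readMeasurements(cfg$measurements)
      par <- meas[meas$role == "parental_background", ]
      if (nrow(par) > 0L) bg <- estimateBackground(par)
    }
    rgb <- renderRatioImage(flds[[1]]@ch561, flds[[1]]@ch640, bg)
    emit("ratio_png", writeRatioPNG(
      rgb, file.path(cfg$out, sprintf("%s_%s_ratio.png", cfg$plate,
                                      cfg$well))))
  }
  outputs$manifest <- writeManifest(cfg, p, outputs, cfg$out)
  invisible(outputs)
}
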