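## ---- plate layout builders ------------------------------------------------

## Row-major empty 96-well grid.
emptyWellGrid <- function() {
  data.frame(row = rep(LETTERS[1:8], each = 12),
             col = rep(1:12, times = 8),
             role = NA_character_, target_id = NA_character_,
             egf_ng_ml = 0, knockdown_efficacy = 0,
             calibration_ph = NA_real_, stringsAsFactors = FALSE)
}

#' Build screen plate layouts
#'
#' Builds the siRNA screen design: three plates per replicate, each plate
#' carrying 80 target wells (columns 1-10, row-major), four clathrin
#' heavy-chain and four dynamin-2 positive-control wells (column 11, rows
#' A-D and E-H), and eight negative-control wells (column 12). Three plates
#' cover a 240-target library; every target appears exactly once per
#' replicate, at the same position in every replicate. All wells are
#' stimulated with `egf` ng/ml EGF.
#'
#' @param targetIds character vector of exactly 240 unique target ids.
#' @param replicates number of independent screen repeats (>= 1).
#' @param egf EGF concentration applied to every well, ng/ml.
#' @param positiveEfficacy knockdown efficacy of the positive controls.
#' @return List of `3 * replicates` [PlateLayout-class] objects.
#' @export
#' @examples
#' layouts <- buildScreenLayouts(sprintf("PP%03d", 1:240), replicates = 1)
#' table(wells(layouts[[1]])$role)
buildScreenLayouts <- function(targetIds, replicates = 3L, egf = 1,
                               positiveEfficacy = 0.9) {
  targetIds <- as.character(targetIds)
  if (length(targetIds) != 240L)
    stop("the screen design requires exactly 240 target ids")
  if (anyDuplicated(targetIds)) stop("target ids must be unique")
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("'replicates' must be >= 1")
  out <- vector("list", 3L * replicates)
  idx <- 0L
  for (r in seq_len(replicates)) {
    for (p in 1:3) {
      w <- emptyWellGrid()
      isTarget <- w$col <= 10
      w$role[isTarget] <- "target"
      ## row-major: A1..A10 take ids 1..10, B1..B10 ids 11..20, ...
      ids <- targetIds[(p - 1L) * 80L + 1:80]
      ord <- order(match(w$row[isTarget], LETTERS), w$col[isTarget])
      w$target_id[isTarget][ord] <- ids
      w$role[w$col == 11 & w$row %in% LETTERS[1:4]] <- "positive_chc"
      w$role[w$col == 11 & w$row %in% LETTERS[5:8]] <- "positive_dyn2"
      w$role[w$col == 12] <- "negative_control"
      w$egf_ng_ml <- egf
      w$knockdown_efficacy[w$role %in% c("positive_chc", "positive_dyn2")] <-
        positiveEfficacy
      idx <- idx + 1L
      out[[idx]] <- new("PlateLayout", plateId = sprintf("P%d", p),
                        replicateId = sprintf("R%d", r), wells = w)
    }
  }
  out
}

#' Build a robustness (half-plate control) layout
#'
#' Half the plate (columns 1-6) is left unstimulated, the other half
#' (columns 7-12) is stimulated at the given EGF concentration; used to
#' measure the assay Z'-factor at physiological EGF doses.
#'
#' @param egf EGF concentration of the stimulated half, ng/ml (> 0).
#' @return A [PlateLayout-class] with 48 unstimulated and 48 stimulated wells.
#' @export
buildRobustnessLayout <- function(egf) {
  if (!is.numeric(egf) || length(egf) != 1L || !is.finite(egf) || egf <= 0)
    stop("'egf' must be a single positive concentration")
  w <- emptyWellGrid()
  w$role <- ifelse(w$col <= 6, "unstimulated", "stimulated")
  w$egf_ng_ml <- ifelse(w$col <= 6, 0, egf)
  new("PlateLayout", plateId = sprintf("ROB-%g", egf), replicateId = "R1",
      wells = w)
}

#' Build a pH calibration plate layout
#'
#' Each of the 8 rows receives one buffer pH, evenly spaced from `phMin`
#' (row A) to `phMax` (row H); columns 1-7 are measurement wells and
#' columns 8-12 are reserved as parental-background wells, so every pH
#' level is the mean of 7 wells.
#'
#' @param phMin,phMax pH range (phMin < phMax).
#' @return A [PlateLayout-class].
#' @export
#' @examples
#' unique(wells(buildCalibrationLayout())$calibration_ph)
buildCalibrationLayout <- function(phMin = 5, phMax = 8) {
  if (!is.finite(phMin) || !is.finite(phMax) || phMin >= phMax)
    stop("'phMin' must be below 'phMax'")
  phByRow <- seq(phMin, phMax, length.out = 8)
  w <- emptyWellGrid()
  w$role <- ifelse(w$col <= 7, "calibration", "parental_background")
  w$calibration_ph <- ifelse(w$col <= 7, phByRow[match(w$row, LETTERS)],
                             NA_real_)
  new("PlateLayout", plateId = "CAL", replicateId = "R1", wells = w)
}

#' Build an all-parental background plate layout
#'
#' A plate of untagged (parental) cells used to estimate the per-channel
#' background signal; typically only a few of its wells need rendering.
#'
#' @param replicateId replicate label carried by the layout.
#' @return A [PlateLayout-class] with 96 parental-background wells.
#' @export
buildBackgroundLayout <- function(replicateId = "R1") {
  w <- emptyWellGrid()
  w$role <- "parental_background"
  new("PlateLayout", plateId = "BG", replicateId = as.character(replicateId),
      wells = w)
}

#' Flatten plate layouts to a plate-map table
#'
#' @param layouts a [PlateLayout-class] or list of them.
#' @return data.frame with columns `plate_id`, `replicate_id`, `row`, `col`,
#'   `role`, `target_id`, `egf_ng_ml`, `knockdown_efficacy`,
#'   `calibration_ph`.
#' @export
layoutTable <- function(layouts) {
  if (is(layouts, "PlateLayout")) layouts <- list(layouts)
  do.call(rbind, lapply(layouts, function(l) {
    cbind(data.frame(plate_id = l@plateId, replicate_id = l@replicateId,
                     stringsAsFactors = FALSE), l@wells)
  }))
}

#' Read / write plate-map CSVs
#' @param layouts a [PlateLayout-class] or list of them.
#' @param path file path.
#' @export
writePlateMap <- function(layouts, path) {
  utils::write.csv(layoutTable(layouts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePlateMap
#' @return `readPlateMap()` the plate-map data.frame.
#' @export
readPlateMap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "replicate_id", "row", "col", "role", "target_id",
            "egf_ng_ml", "knockdown_efficacy", "calibration_ph")
  if (!all(need %in% names(df)))
    stop("plate map must have columns: ", paste(need, collapse = ", "))
  df
}

## ---- rendering ------------------------------------------------------------

## Draw one cell and return sparse intensity segments (linear pixel indices
## plus per-pixel 640-channel photon density and the pH-ratio factor for the
## 561 channel). The cell is an axis-aligned ellipse centred at (cx, cy);
## the surface pool covers the whole footprint (top and bottom plasma
## membrane in 2-D projection) with extra weight in an edge rim; the
## endosomal pool is a set of punctate interior spots scaled to the cell
## size. Per-cell photon totals are exactly (1 - f) and f times the cell's
## label amount, so the aggregate 561/640 ratio obeys the two-pool mixing
## model regardless of geometry; photons falling outside the field are
## simply lost (they affect both channels equally).
paintCell <- function(S, cx, cy, a, b, f, rSurf, rEndo, photonScale) {
  ## per-cell label amount: Gamma with CV 0.15, truncated to protect the
  ## 16-bit range of the brightest compartment
  amount <- min(stats::rgamma(1, shape = 1 / 0.15^2, rate = 1 / 0.15^2), 1.4)
  xs <- max(1, floor(cx - a)):min(S, ceiling(cx + a))
  ys <- max(1, floor(cy - b)):min(S, ceiling(cy + b))
  q <- outer(((xs - cx) / a)^2, ((ys - cy) / b)^2, "+")
  toLin <- function(idx) {
    i <- ((idx - 1L) %% length(xs)) + 1L
    j <- ((idx - 1L) %/% length(xs)) + 1L
    (ys[j] - 1L) * S + xs[i]
  }
  cellIdx <- which(q <= 1)
  if (length(cellIdx) == 0L) return(list())
  rimIdx <- which(q <= 1 & q > 0.55)
  footprintArea <- pi * a * b          # nominal, border-independent
  rimArea <- footprintArea * 0.45
  segs <- list()
  surfTotal <- (1 - f) * amount * photonScale
  segs[[length(segs) + 1L]] <-
    list(lin = toLin(cellIdx), d = surfTotal * 0.8 / footprintArea,
         r = rSurf)
  if (length(rimIdx) > 0L)
    segs[[length(segs) + 1L]] <-
      list(lin = toLin(rimIdx), d = surfTotal * 0.2 / rimArea, r = rSurf)
  if (f > 0) {
    nP <- 12L + stats::rpois(1, 4)
    theta <- stats::runif(nP, 0, 2 * pi)
    rad <- sqrt(stats::runif(nP)) * sqrt(0.55)
    pxc <- cx + rad * a * cos(theta)
    pyc <- cy + rad * b * sin(theta)
    rp <- pmin(pmax(stats::runif(nP, 0.18, 0.26) * a, 1.2), 3.6)
    share <- f * amount * photonScale / nP
    for (s in seq_len(nP)) {
      px <- max(1, floor(pxc[s] - rp[s])):min(S, ceiling(pxc[s] + rp[s]))
      py <- max(1, floor(pyc[s] - rp[s])):min(S, ceiling(pyc[s] + rp[s]))
      d2 <- outer((px - pxc[s])^2, (py - pyc[s])^2, "+")
      hit <- which(d2 <= rp[s]^2)
      if (length(hit) == 0L) next
      i <- ((hit - 1L) %% length(px)) + 1L
      j <- ((hit - 1L) %/% length(px)) + 1L
      ## density per nominal spot area, so border truncation loses photons
      ## instead of concentrating them
      segs[[length(segs) + 1L]] <-
        list(lin = (py[j] - 1L) * S + px[i],
             d = share / (pi * rp[s]^2), r = rEndo)
    }
  }
  segs
}

## Cell centres for one field: jittered grid, emulating a near-confluent
## monolayer (cells touch but do not pile on top of each other). Returns a
## matrix with columns cx, cy, a, b.
layoutCells <- function(S, cellCountMean) {
  nCells <- stats::rpois(1, cellCountMean)
  if (nCells == 0L) return(matrix(numeric(0), ncol = 4))
  nSlots <- max(nCells, ceiling(1.25 * cellCountMean))
  nx <- ceiling(sqrt(nSlots))
  ny <- ceiling(nSlots / nx)
  pitchX <- S / nx; pitchY <- S / ny
  slots <- sample.int(nx * ny, nCells)
  sx <- ((slots - 1L) %% nx) + 1L
  sy <- ((slots - 1L) %/% nx) + 1L
  cx <- (sx - 0.5) * pitchX + stats::runif(nCells, -0.15, 0.15) * pitchX
  cy <- (sy - 0.5) * pitchY + stats::runif(nCells, -0.15, 0.15) * pitchY
  pitch <- min(pitchX, pitchY)
  a <- pmin(pmax(stats::runif(nCells, 0.32, 0.46) * pitch, 4), 14)
  b <- a * stats::runif(nCells, 0.70, 0.90)
  cbind(cx, cy, a, b)
}

## Camera model: Poisson shot noise on (signal + background), additive
## Gaussian read noise, rounding and 16-bit clamping.
cameraNoise <- function(lambda, background, readNoiseSD, S) {
  obs <- stats::rpois(length(lambda), lambda + background) +
    stats::rnorm(length(lambda), 0, readNoiseSD)
  obs <- round(obs)
  obs[obs < 0] <- 0
  obs[obs > 65535] <- 65535
  matrix(obs, nrow = S)
}

#' Render the dual-channel field images of one well
#'
#' Draws seeded synthetic 561/640 field images with the statistical
#' structure the downstream analysis assumes. The well's endosomal fraction
#' f is computed from the kinetics (with `keOccCme` scaled by
#' `1 - knockdown_efficacy`, and for dynamin-2 wells also `keCieMax`);
#' calibration wells instead place all label at the imposed buffer pH with
#' no internalization, and parental-background wells carry no receptor
#' signal at all. Cells are elliptical, with the surface pool spread over
#' the footprint plus an edge rim and the endosomal pool in interior
#' puncta. One well-level factor ~ Normal(1, wellCV) multiplies the
#' 561-excited channel of every field; Poisson shot noise, Gaussian read
#' noise and per-channel backgrounds are then added and the images clamped
#' to the 16-bit range. Fully reproducible given `seed`.
#'
#' @param spec one-row data.frame (or list) with fields `row`, `col`,
#'   `role`, `egf_ng_ml`, `knockdown_efficacy`, `calibration_ph`.
#' @param kinetics a [KineticParams-class].
#' @param sensor a [SensorParams-class].
#' @param comp a [CompartmentPH-class].
#' @param acq an [AcquisitionParams-class].
#' @param t EGF incubation time, minutes (>= 0).
#' @param seed integer RNG seed.
#' @return List of `fieldsPerWell` [FieldImage-class] objects, with
#'   attribute `f_true` (the endosomal fraction used).
#' @export
#' @examples
#' spec <- list(row = "A", col = 1, role = "stimulated", egf_ng_ml = 4,
#'              knockdown_efficacy = 0, calibration_ph = NA)
#' flds <- renderWell(spec, kineticParams(), sensorParams(), compartmentPH(),
#'                    acquisitionParams(imageSize = 64, cellCountMean = 8,
#'                                      fieldsPerWell = 2), seed = 7)
renderWell <- function(spec, kinetics, sensor, comp, acq, t = 15, seed = 1L) {
  stopifnot(is(kinetics, "KineticParams"), is(sensor, "SensorParams"),
            is(comp, "CompartmentPH"), is(acq, "AcquisitionParams"))
  if (!is.finite(t) || t < 0) stop("'t' must be >= 0 minutes")
  spec <- as.list(spec)
  role <- spec$role
  if (!role %in% WELL_ROLES) stop("unknown well role: ", role)
  hasSignal <- role != "parental_background"
  if (role == "calibration") {
    if (!is.finite(spec$calibration_ph))
      stop("calibration wells must carry calibration_ph")
    f <- 0
    phRim <- spec$calibration_ph
    phEndo <- spec$calibration_ph
  } else {
    kd <- spec$knockdown_efficacy
    if (is.null(kd) || !is.finite(kd)) kd <- 0
    kp <- kinetics
    kp@keOccCme <- kp@keOccCme * (1 - kd)
    if (identical(role, "positive_dyn2")) kp@keCieMax <- kp@keCieMax * (1 - kd)
    k <- effectiveRate(kp, spec$egf_ng_ml)
    f <- closedFormFraction(k, kp@kRec, t)
    phRim <- comp@phSurface
    phEndo <- comp@phEndosome
  }
  rSurf <- ratioAtPH(sensor, phRim)
  rEndo <- ratioAtPH(sensor, phEndo)
  out <- withRNG(seed,
                 renderWellFields(acq, hasSignal, f, rSurf, rEndo,
                                  wellAddress(spec$row, spec$col)))
  attr(out, "f_true") <- f
  out
}

## Field loop of renderWell, run under an already-seeded RNG.
renderWellFields <- function(acq, hasSignal, f, rSurf, rEndo, addr) {
  S <- acq@imageSize
  wellFactor <- max(stats::rnorm(1, 1, acq@wellCV), 0)
  out <- vector("list", acq@fieldsPerWell)
  for (fi in seq_len(acq@fieldsPerWell)) {
    lam561 <- numeric(S * S)
    lam640 <- numeric(S * S)
    if (hasSignal) {
      cells <- layoutCells(S, acq@cellCountMean)
      for (ci in seq_len(nrow(cells))) {
        segs <- paintCell(S, cells[ci, 1], cells[ci, 2], cells[ci, 3],
                          cells[ci, 4], f, rSurf, rEndo, acq@photonScale)
        for (seg in segs) {
          lam640[seg$lin] <- lam640[seg$lin] + seg$d
          lam561[seg$lin] <- lam561[seg$lin] + seg$d * seg$r
        }
      }
    }
    lam561 <- lam561 * wellFactor
    ch561 <- cameraNoise(lam561, acq@background561, acq@readNoiseSD, S)
    ch640 <- cameraNoise(lam640, acq@background640, acq@readNoiseSD, S)
    out[[fi]] <- fieldImage(ch561, ch640, well = addr, fieldIndex = fi)
  }
  out
}

## ---- TIFF IO --------------------------------------------------------------

#' Write / read well field images as multi-page TIFF
#'
#' Each field is one 16-bit multi-page TIFF with page order (ch561, ch640),
#' named `{plate}_{row}{col}_f{field}.tif`.
#'
#' @param fields list of [FieldImage-class] objects (one well).
#' @param dir output directory (created if missing).
#' @param plate plate id used in the filename.
#' @return Invisibly, the written file paths.
#' @export
writeFieldImages <- function(fields, dir, plate) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(fields, function(fl) {
    path <- file.path(dir, sprintf("%s_%s_f%d.tif", plate, fl@well,
                                   fl@fieldIndex))
    tiff::writeTIFF(list(fl@ch561 / 65535, fl@ch640 / 65535), path,
                    bits.per.sample = 16L)
    path
  }, character(1))
  invisible(paths)
}

#' @rdname writeFieldImages
#' @param row,col well address components.
#' @return `readWellImages()` a list of [FieldImage-class] objects.
#' @export
readWellImages <- function(dir, plate, row, col) {
  addr <- wellAddress(row, col)
  paths <- Sys.glob(file.path(dir, sprintf("%s_%s_f*.tif", plate, addr)))
  if (length(paths) == 0L)
    stop("no images found for well ", addr, " of plate ", plate)
  fi <- as.integer(sub(".*_f([0-9]+)\\.tif$", "\\1", paths))
  paths <- paths[order(fi)]; fi <- sort(fi)
  mapply(function(p, i) {
    pages <- tiff::readTIFF(p, all = TRUE)
    if (length(pages) != 2L) stop("expected 2 pages (ch561, ch640) in ", p)
    fieldImage(round(pages[[1]] * 65535), round(pages[[2]] * 65535),
               well = addr, fieldIndex = i)
  }, paths, fi, SIMPLIFY = FALSE)
}

## ---- plate-level simulation ----------------------------------------------

#' Render and measure a whole plate
#'
#' Streams through the wells of a layout: renders each well's fields with a
#' per-well seed derived from `seed`, measures raw channel means, and
#' optionally writes the images to disk. Rendering a subset of wells gives
#' bit-identical results to rendering them inside the full plate.
#'
#' @param layout a [PlateLayout-class].
#' @param kinetics,sensor,comp,acq model parameter objects.
#' @param t EGF incubation time, minutes.
#' @param seed integer master seed for the plate.
#' @param imageDir if non-NULL, directory to write per-field TIFFs.
#' @param wellIndices optional integer vector of layout rows to render
#'   (default all 96).
#' @return data.frame of raw (uncorrected) well measurements.
#' @export
simulatePlate <- function(layout, kinetics = kineticParams(),
                          sensor = sensorParams(), comp = compartmentPH(),
                          acq = acquisitionParams(), t = 15, seed = 1L,
                          imageDir = NULL, wellIndices = NULL) {
  stopifnot(is(layout, "PlateLayout"))
  w <- layout@wells
  seeds <- deriveSeeds(seed, nrow(w))
  if (is.null(wellIndices)) wellIndices <- seq_len(nrow(w))
  rows <- lapply(wellIndices, function(i) {
    flds <- renderWell(w[i, ], kinetics, sensor, comp, acq, t = t,
                       seed = seeds[i])
    if (!is.null(imageDir)) writeFieldImages(flds, imageDir, layout@plateId)
    m <- measureWell(flds)
    data.frame(plate_id = layout@plateId, replicate_id = layout@replicateId,
               row = w$row[i], col = w$col[i], role = w$role[i],
               target_id = w$target_id[i], egf_ng_ml = w$egf_ng_ml[i],
               knockdown_efficacy = w$knockdown_efficacy[i],
               calibration_ph = w$calibration_ph[i],
               i561_mean = m$i561_mean, i640_mean = m$i640_mean,
               n_pixels = m$n_pixels, sat_frac = m$sat_frac,
               f_true = attr(flds, "f_true"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Render n parental wells of a background plate and estimate (bg561, bg640).
simulateBackgroundWells <- function(nWells, acq, seed, replicateId = "R1",
                                    imageDir = NULL) {
  bgLayout <- buildBackgroundLayout(replicateId)
  meas <- simulatePlate(bgLayout, acq = acq, seed = seed, imageDir = imageDir,
                        wellIndices = seq_len(nWells))
  list(measurements = meas, background = estimateBackground(meas))
}

#' Simulate and quantify a robustness plate
#'
#' Renders a half-control / half-stimulated plate plus a companion strip of
#' parental-background wells, background-corrects the well ratios and
#' returns the measurement table; [plateQC()] on it yields the Z'-factor.
#'
#' @param egf EGF concentration of the stimulated half, ng/ml.
#' @param kinetics,sensor,comp,acq model parameter objects.
#' @param t incubation time, minutes.
#' @param seed integer seed.
#' @param backgroundWells number of parental wells rendered for background
#'   estimation.
#' @param imageDir optional directory for TIFF output.
#' @param epsilon low-signal threshold passed to [applyBackground()].
#' @return data.frame of corrected well measurements (robustness plate plus
#'   background wells).
#' @export
#' @examples
#' \donttest{
#' meas <- simulateRobustnessPlate(4, acq = acquisitionParams(imageSize = 64,
#'   cellCountMean = 8, fieldsPerWell = 2), seed = 1)
#' plateQC(meas)
#' }
simulateRobustnessPlate <- function(egf = 4, kinetics = kineticParams(),
                                    sensor = sensorParams(),
                                    comp = compartmentPH(),
                                    acq = acquisitionParams(), t = 15,
                                    seed = 1L, backgroundWells = 8L,
                                    imageDir = NULL,
                                    epsilon = DEFAULT_EPSILON) {
  seeds <- deriveSeeds(seed, 2L)
  bg <- simulateBackgroundWells(backgroundWells, acq, seeds[1],
                                imageDir = imageDir)
  meas <- simulatePlate(buildRobustnessLayout(egf), kinetics, sensor, comp,
                        acq, t = t, seed = seeds[2], imageDir = imageDir)
  rbind(applyBackground(meas, bg$background, epsilon),
        applyBackground(bg$measurements, bg$background, epsilon))
}

#' Simulate and quantify a pH calibration plate
#'
#' Renders a calibration plate (rows at pH `phMin`..`phMax`, 7 measurement
#' wells per row, parental wells in the remaining columns), corrects ratios
#' against the on-plate parental background, and summarises each pH level
#' as mean +/- SD of its 7 wells.
#'
#' @param sensor a [SensorParams-class] (the ground truth being emulated).
#' @param acq an [AcquisitionParams-class].
#' @param phMin,phMax pH range by row.
#' @param seed integer seed.
#' @param imageDir optional directory for TIFF output.
#' @param epsilon low-signal threshold passed to [applyBackground()].
#' @return List with `measurements` (corrected well table) and `series`
#'   (calibration series data.frame, see [calibrationSeries()]).
#' @export
simulateCalibrationPlate <- function(sensor = sensorParams(),
                                     acq = acquisitionParams(),
                                     phMin = 5, phMax = 8, seed = 1L,
                                     imageDir = NULL,
                                     epsilon = DEFAULT_EPSILON) {
  layout <- buildCalibrationLayout(phMin, phMax)
  meas <- simulatePlate(layout, sensor = sensor, acq = acq, seed = seed,
                        imageDir = imageDir)
  bg <- estimateBackground(meas[meas$role == "parental_background", ])
  meas <- applyBackground(meas, bg, epsilon)
  cal <- meas[meas$role == "calibration" & is.finite(meas$ratio), ]
  agg <- do.call(rbind, lapply(split(cal, cal$calibration_ph), function(d) {
    data.frame(ph = d$calibration_ph[1], mean_ratio = mean(d$ratio),
               sd = stats::sd(d$ratio), n_wells = nrow(d))
  }))
  agg <- agg[order(agg$ph), ]
  rownames(agg) <- NULL
  list(measurements = meas,
       series = calibrationSeries(agg$ph, agg$mean_ratio, agg$sd,
                                  agg$n_wells))
}

#' Simulate a full siRNA screen
#'
#' Builds the screen layouts, renders every well (1 ng/ml EGF, 15 min by
#' default) with positive controls at 0.9 knockdown efficacy and target
#' efficacies taken from `effects`, estimates the per-replicate background
#' from companion parental wells, and returns corrected measurements plus
#' the plate maps. With `imageDir` set, all field images are written as
#' multi-page TIFFs and the plate map as CSV alongside.
#'
#' @param targetIds 240 unique target ids (default `PP001..PP240`).
#' @param replicates number of screen repeats.
#' @param effects named numeric vector of true knockdown efficacies for a
#'   subset of targets (default: all-null screen).
#' @param kinetics,sensor,comp,acq model parameter objects.
#' @param egf EGF concentration, ng/ml.
#' @param t incubation time, minutes.
#' @param seed integer master seed.
#' @param backgroundWells parental wells rendered per replicate.
#' @param imageDir optional directory for TIFF + plate-map output.
#' @param epsilon low-signal threshold passed to [applyBackground()].
#' @return List with `measurements` (corrected well table over all plates),
#'   `plateMap` (design table) and `background` (per-replicate estimates).
#' @export
simulateScreen <- function(targetIds = sprintf("PP%03d", 1:240),
                           replicates = 3L, effects = NULL,
                           kinetics = kineticParams(),
                           sensor = sensorParams(), comp = compartmentPH(),
                           acq = acquisitionParams(), egf = 1, t = 15,
                           seed = 1L, backgroundWells = 8L,
                           imageDir = NULL, epsilon = DEFAULT_EPSILON) {
  layouts <- buildScreenLayouts(targetIds, replicates, egf = egf)
  if (!is.null(effects)) {
    if (is.null(names(effects)) || any(!names(effects) %in% targetIds))
      stop("'effects' must be a named vector over target ids")
    if (any(!is.finite(effects) | effects < 0 | effects > 1))
      stop("'effects' must lie in [0, 1]")
    layouts <- lapply(layouts, function(l) {
      hit <- match(l@wells$target_id, names(effects))
      l@wells$knockdown_efficacy[!is.na(hit)] <- effects[hit[!is.na(hit)]]
      l
    })
  }
  replicates <- as.integer(replicates)
  seeds <- matrix(deriveSeeds(seed, replicates * 4L), nrow = replicates)
  meas <- list(); bgs <- list()
  for (r in seq_len(replicates)) {
    repId <- sprintf("R%d", r)
    bg <- simulateBackgroundWells(backgroundWells, acq, seeds[r, 1],
                                  replicateId = repId, imageDir = imageDir)
    bgs[[repId]] <- bg$background
    repLayouts <- Filter(function(l) l@replicateId == repId, layouts)
    for (p in seq_along(repLayouts)) {
      raw <- simulatePlate(repLayouts[[p]], kinetics, sensor, comp, acq,
                           t = t, seed = seeds[r, 1L + p],
                           imageDir = imageDir)
      meas[[length(meas) + 1L]] <- applyBackground(raw, bg$background,
                                                   epsilon)
    }
    meas[[length(meas) + 1L]] <- applyBackground(bg$measurements,
                                                 bg$background, epsilon)
  }
  measurements <- do.call(rbind, meas)
  rownames(measurements) <- NULL
  plateMap <- layoutTable(layouts)
  if (!is.null(imageDir))
    writePlateMap(layouts, file.path(imageDir, "plate_map.csv"))
  list(measurements = measurements, plateMap = plateMap,
       background = bgs)
}
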