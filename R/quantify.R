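## Default low-signal threshold for the corrected 640 denominator: 1% of the
## 16-bit intensity range.
DEFAULT_EPSILON <- 655.35

#' Measure raw channel means of one well
#'
#' Averages each channel over all pixels of all fields of the well — the
#' mean of the stitched mosaic, computed without materialising the mosaic.
#'
#' @param fields non-empty list of [FieldImage-class] objects with equal
#'   shapes.
#' @return List with `i561_mean`, `i640_mean`, `n_pixels`, and `sat_frac`
#'   (fraction of pixels at the 16-bit ceiling, across both channels).
#' @export
#' @examples
#' f <- fieldImage(matrix(200, 8, 8), matrix(100, 8, 8))
#' measureWell(list(f))
measureWell <- function(fields) {
  if (!is.list(fields) || length(fields) == 0L)
    stop("'fields' must be a non-empty list of FieldImage objects")
  if (!all(vapply(fields, is, logical(1), "FieldImage")))
    stop("'fields' must contain FieldImage objects")
  dims <- lapply(fields, function(f) dim(f@ch561))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("all fields of a well must have the same shape")
  s561 <- sum(vapply(fields, function(f) sum(f@ch561), numeric(1)))
  s640 <- sum(vapply(fields, function(f) sum(f@ch640), numeric(1)))
  nPix <- sum(vapply(fields, function(f) length(f@ch561), numeric(1)))
  nSat <- sum(vapply(fields, function(f)
    sum(f@ch561 >= 65535) + sum(f@ch640 >= 65535), numeric(1)))
  list(i561_mean = s561 / nPix, i640_mean = s640 / nPix, n_pixels = nPix,
       sat_frac = nSat / (2 * nPix))
}

#' Estimate per-channel background from parental wells
#'
#' Parental (untagged) cells carry no reporter, so their raw channel means
#' estimate the acellular + autofluorescence background. The estimate is the
#' per-channel mean over the supplied parental-well measurements.
#'
#' @param parentalMeasurements data.frame with columns `i561_mean`,
#'   `i640_mean` (rows are parental-background wells).
#' @return Named numeric vector `c(bg561, bg640)`.
#' @export
estimateBackground <- function(parentalMeasurements) {
  m <- parentalMeasurements
  if (!is.data.frame(m) || nrow(m) == 0L)
    stop("need at least one parental-background well measurement")
  if (!all(c("i561_mean", "i640_mean") %in% names(m)))
    stop("measurements must have i561_mean and i640_mean columns")
  c(bg561 = mean(m$i561_mean), bg640 = mean(m$i640_mean))
}

#' Background-corrected 561/640 well ratio
#'
#' Subtracts the per-channel background from the raw well means and forms
#' the ratio of corrected means. When the corrected 640 denominator falls
#' below `epsilon` the ratio is withheld and the well flagged `low_signal`
#' instead of erroring.
#'
#' @param m list or one-row data.frame with `i561_mean`, `i640_mean`
#'   (optionally `sat_frac`, `role`).
#' @param bg numeric vector `c(bg561, bg640)`.
#' @param epsilon minimum corrected 640 mean (default 1% of the 16-bit
#'   range).
#' @return List with `ratio` (NA when flagged) and `qc_flags` (character,
#'   semicolon-separated among `low_signal`, `clipped`, `background_well`).
#' @export
#' @examples
#' correctedRatio(list(i561_mean = 200, i640_mean = 100), c(50, 20),
#'                epsilon = 1)
correctedRatio <- function(m, bg, epsilon = DEFAULT_EPSILON) {
  if (!is.finite(epsilon) || epsilon <= 0) stop("'epsilon' must be > 0")
  m <- as.list(m)
  bg <- as.numeric(bg)
  if (length(bg) != 2L || any(!is.finite(bg)))
    stop("'bg' must be two finite numbers (bg561, bg640)")
  num <- m$i561_mean - bg[1]
  den <- m$i640_mean - bg[2]
  flags <- character()
  if (!is.null(m$role) && identical(m$role, "parental_background"))
    flags <- c(flags, "background_well")
  if (!is.null(m$sat_frac) && is.finite(m$sat_frac) && m$sat_frac > 1e-3)
    flags <- c(flags, "clipped")
  if (den < epsilon) {
    flags <- c(flags, "low_signal")
    ratio <- NA_real_
  } else {
    ratio <- num / den
  }
  list(ratio = ratio, qc_flags = paste(flags, collapse = ";"))
}

#' Apply background correction to a measurement table
#'
#' Vectorised [correctedRatio()] over a raw measurement table; adds columns
#' `bg561`, `bg640`, `ratio` and `qc_flags`.
#'
#' @param measurements raw measurement data.frame (see [simulatePlate()]).
#' @param bg numeric vector `c(bg561, bg640)`.
#' @param epsilon low-signal threshold.
#' @return The measurement table with correction columns added.
#' @export
applyBackground <- function(measurements, bg, epsilon = DEFAULT_EPSILON) {
  cr <- lapply(seq_len(nrow(measurements)), function(i)
    correctedRatio(measurements[i, ], bg, epsilon))
  measurements$bg561 <- as.numeric(bg[1])
  measurements$bg640 <- as.numeric(bg[2])
  measurements$ratio <- vapply(cr, function(x) x$ratio, numeric(1))
  measurements$qc_flags <- vapply(cr, function(x) x$qc_flags, character(1))
  measurements
}

#' Quantify a plate from images on disk
#'
#' Reads the per-field multi-page TIFFs of every well listed in the plate
#' map, measures raw channel means, estimates the background from the
#' parental wells present in the map (same plate if available, otherwise
#' any parental wells in the map) and returns the corrected measurement
#' table.
#'
#' @param imageDir directory holding `{plate}_{row}{col}_f{field}.tif`
#'   files.
#' @param plateMap plate-map data.frame (see [readPlateMap()]).
#' @param epsilon low-signal threshold.
#' @return Corrected measurement data.frame.
#' @export
quantifyPlate <- function(imageDir, plateMap, epsilon = DEFAULT_EPSILON) {
  raw <- do.call(rbind, lapply(seq_len(nrow(plateMap)), function(i) {
    w <- plateMap[i, ]
    flds <- readWellImages(imageDir, w$plate_id, w$row, w$col)
    m <- measureWell(flds)
    cbind(w, data.frame(i561_mean = m$i561_mean, i640_mean = m$i640_mean,
                        n_pixels = m$n_pixels, sat_frac = m$sat_frac))
  }))
  out <- list()
  for (pid in unique(raw$plate_id)) {
    sub <- raw[raw$plate_id == pid, ]
    par <- sub[sub$role == "parental_background", ]
    if (nrow(par) == 0L)
      par <- raw[raw$role == "parental_background", ]
    if (nrow(par) == 0L)
      stop("no parental-background wells available for background estimation")
    out[[pid]] <- applyBackground(sub, estimateBackground(par), epsilon)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a measurement table as CSV
#' @param measurements measurement data.frame.
#' @param path file path.
#' @export
writeMeasurements <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMeasurements
#' @return `readMeasurements()` the measurement data.frame.
#' @export
readMeasurements <- function(path) utils::read.csv(path,
                                                   stringsAsFactors = FALSE)

#' RenderParams: display settings for ratio images
#'
#' Display range of the ratio and the 640-channel intensity thresholds used
#' for brightness (saturation) modulation.
#'
#' @slot ratioLow,ratioHigh numeric display range of the ratio.
#' @slot satLow,satHigh numeric 640-channel thresholds: pixels below
#'   `satLow` render black, pixels above `satHigh` at full brightness.
#' @export
setClass("RenderParams",
         representation(ratioLow = "numeric", ratioHigh = "numeric",
                        satLow = "numeric", satHigh = "numeric"))

setValidity("RenderParams", function(object) {
  if (!(object@ratioLow < object@ratioHigh))
    return("ratioLow must be below ratioHigh")
  if (!(object@satLow < object@satHigh))
    return("satLow must be below satHigh")
  TRUE
})

#' Construct ratio-image render parameters
#' @param ratioLow,ratioHigh ratio display range.
#' @param satLow,satHigh 640-channel brightness thresholds.
#' @return A [RenderParams-class] object.
#' @export
renderParams <- function(ratioLow = 0.4, ratioHigh = 2.0, satLow = 200,
                         satHigh = 5000) {
  new("RenderParams", ratioLow = ratioLow, ratioHigh = ratioHigh,
      satLow = satLow, satHigh = satHigh)
}

#' Render an intensity-modulated pseudocolor ratio image
#'
#' Computes the per-pixel background-corrected 561/640 ratio, clamps it to
#' the display range and maps it through a temperature lookup table (blue =
#' low, red = high). Pixel brightness is modulated linearly by the raw
#' 640-channel intensity between `satLow` (black, suppressing regions
#' outside cells) and `satHigh` (full saturation).
#'
#' @param ch561,ch640 numeric intensity matrices of equal shape.
#' @param bg numeric vector `c(bg561, bg640)`.
#' @param params a [RenderParams-class].
#' @return Numeric array (rows x cols x 3) of RGB values in [0, 1].
#' @export
renderRatioImage <- function(ch561, ch640, bg = c(0, 0),
                             params = renderParams()) {
  stopifnot(is(params, "RenderParams"))
  validObject(params)
  if (!identical(dim(ch561), dim(ch640)))
    stop("channel images must have identical shapes")
  num <- ch561 - bg[1]
  den <- ch640 - bg[2]
  ratio <- ifelse(den > 0, num / pmax(den, .Machine$double.eps),
                  params@ratioLow)
  u <- (pmin(pmax(ratio, params@ratioLow), params@ratioHigh) -
          params@ratioLow) / (params@ratioHigh - params@ratioLow)
  lut <- grDevices::colorRamp(c("blue", "cyan", "green", "yellow", "red"))
  rgb <- lut(as.vector(u)) / 255
  bright <- (ch640 - params@satLow) / (params@satHigh - params@satLow)
  bright <- pmin(pmax(as.vector(bright), 0), 1)
  out <- array(0, dim = c(nrow(ch561), ncol(ch561), 3))
  for (k in 1:3) out[, , k] <- matrix(rgb[, k] * bright, nrow = nrow(ch561))
  out
}

#' Write a ratio render as PNG
#' @param rgb RGB array from [renderRatioImage()].
#' @param path file path.
#' @export
writeRatioPNG <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}
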