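#' 561/640 ratio at a given pH
#'
#' Evaluates the calibration sigmoid
#' \deqn{R(pH) = R_{base} + (R_{acid} - R_{base}) / (1 + 10^{h (pH - pKa)})}
#' The 640-excited emission per receptor is pH-independent, while the
#' 561-excited FRET component increases at acidic pH, so the ratio decreases
#' strictly with pH between the plateaus `rAcid` and `rBase`.
#'
#' @param params a [SensorParams-class].
#' @param ph numeric vector of pH values.
#' @return Numeric vector of ratios in (rBase, rAcid).
#' @export
#' @examples
#' sp <- sensorParams()
#' ratioAtPH(sp, c(5.5, 7.4))
ratioAtPH <- function(params, ph) {
  stopifnot(is(params, "SensorParams"))
  validObject(params)
  if (!is.numeric(ph) || length(ph) == 0L || any(!is.finite(ph)))
    stop("'ph' must be finite numeric")
  params@rBase + (params@rAcid - params@rBase) /
    (1 + 10^(params@hill * (ph - params@pKa)))
}

#' Invert the calibration sigmoid
#'
#' Analytic inverse of [ratioAtPH()]:
#' pH = pKa + log10((rAcid - r)/(r - rBase)) / hill.
#'
#' @param params a [SensorParams-class].
#' @param ratio numeric vector of ratios strictly inside (rBase, rAcid).
#' @return Numeric vector of pH values.
#' @export
phFromRatio <- function(params, ratio) {
  stopifnot(is(params, "SensorParams"))
  validObject(params)
  if (!is.numeric(ratio) || any(!is.finite(ratio)))
    stop("'ratio' must be finite numeric")
  if (any(ratio <= params@rBase) || any(ratio >= params@rAcid))
    stop("'ratio' must lie strictly inside (rBase, rAcid)")
  params@pKa + log10((params@rAcid - ratio) / (ratio - params@rBase)) /
    params@hill
}

#' Endosomal receptor fraction from a well ratio
#'
#' Two-compartment mixing model. With surface receptors at `phSurface` and
#' endosomal receptors at `phEndosome`, and pH-independent per-receptor
#' 640-excited emission, the well ratio is affine in the endosomal fraction
#' f: \eqn{R_{obs} = R_{surf} + f (R_{endo} - R_{surf})}. This inverts that
#' relation and clips the result to [0, 1], flagging when clipping occurred
#' (measurement noise can push observed ratios slightly outside the
#' calibration range).
#'
#' @param params a [SensorParams-class].
#' @param rObs numeric vector of observed (background-corrected) well ratios.
#' @param comp a [CompartmentPH-class].
#' @return Numeric vector of fractions in [0, 1] with attribute `clipped`
#'   (logical vector marking clipped entries).
#' @export
#' @examples
#' f <- endosomalFraction(sensorParams(), 1.543, compartmentPH())
#' attr(f, "clipped")
endosomalFraction <- function(params, rObs, comp = compartmentPH()) {
  stopifnot(is(params, "SensorParams"), is(comp, "CompartmentPH"))
  validObject(comp)
  if (!is.numeric(rObs) || any(!is.finite(rObs)))
    stop("'rObs' must be finite numeric")
  rSurf <- ratioAtPH(params, comp@phSurface)
  rEndo <- ratioAtPH(params, comp@phEndosome)
  if (abs(rEndo - rSurf) < .Machine$double.eps * 100)
    stop("degenerate compartments: surface and endosomal ratios coincide")
  f <- (rObs - rSurf) / (rEndo - rSurf)
  clipped <- f < 0 | f > 1
  f <- pmin(pmax(f, 0), 1)
  attr(f, "clipped") <- clipped
  f
}

#' Predicted well ratio for a given endosomal fraction
#'
#' Forward direction of the mixing model used by [endosomalFraction()].
#'
#' @inheritParams endosomalFraction
#' @param f numeric vector of endosomal fractions in [0, 1].
#' @return Numeric vector of predicted ratios.
#' @export
mixingRatio <- function(params, f, comp = compartmentPH()) {
  stopifnot(is(params, "SensorParams"), is(comp, "CompartmentPH"))
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("'f' must be a fraction in [0, 1]")
  rSurf <- ratioAtPH(params, comp@phSurface)
  rEndo <- ratioAtPH(params, comp@phEndosome)
  rSurf + f * (rEndo - rSurf)
}

#' Build a calibration series table
#'
#' @param ph numeric, strictly increasing pH values.
#' @param meanRatio numeric, mean well ratio at each pH.
#' @param sd numeric, SD across wells (default 0).
#' @param nWells integer, wells per point (default 1).
#' @return data.frame with columns `ph`, `mean_ratio`, `sd`, `n_wells`.
#' @export
calibrationSeries <- function(ph, meanRatio, sd = 0, nWells = 1L) {
  if (length(ph) != length(meanRatio))
    stop("'ph' and 'meanRatio' lengths differ")
  if (is.unsorted(ph, strictly = TRUE))
    stop("'ph' must be strictly increasing")
  sd <- rep_len(sd, length(ph)); nWells <- rep_len(as.integer(nWells), length(ph))
  if (any(sd < 0)) stop("'sd' must be non-negative")
  if (any(nWells < 1L)) stop("'nWells' must be >= 1")
  data.frame(ph = ph, mean_ratio = meanRatio, sd = sd, n_wells = nWells)
}

#' Fit the pH calibration sigmoid
#'
#' Least-squares fit of the four-parameter sigmoid of [ratioAtPH()] to a
#' calibration series (Levenberg-Marquardt). Starting values are taken from
#' the data (plateaus from the extreme points, pKa from the half-maximum
#' crossing, hill = 1).
#'
#' @param series data.frame as returned by [calibrationSeries()] (columns
#'   `ph`, `mean_ratio`; optional `sd`, `n_wells`).
#' @param weights optional per-point weights for weighted least squares.
#' @return A [SensorParams-class] object with attributes `rss` (residual sum
#'   of squares), `estimates` (named vector) and `fit` (the `nls` object).
#' @export
#' @examples
#' ser <- calibrationSeries(seq(5, 8, length.out = 8),
#'                          ratioAtPH(sensorParams(), seq(5, 8, length.out = 8)))
#' fitCalibration(ser)
fitCalibration <- function(series, weights = NULL) {
  need <- c("ph", "mean_ratio")
  if (!is.data.frame(series) || !all(need %in% names(series)))
    stop("'series' must be a data.frame with columns ph and mean_ratio")
  ph <- series$ph; y <- series$mean_ratio
  keep <- is.finite(ph) & is.finite(y)
  ph <- ph[keep]; y <- y[keep]
  if (length(unique(ph)) < 4L)
    stop("calibration fit needs >= 4 distinct pH points")
  if (!is.null(weights)) {
    weights <- rep_len(weights, length(series$ph))[keep]
    if (any(!is.finite(weights) | weights < 0)) stop("invalid weights")
  } else {
    weights <- rep(1, length(ph))
  }
  ord <- order(ph); ph <- ph[ord]; y <- y[ord]; weights <- weights[ord]
  rAcid0 <- max(y); rBase0 <- min(y)
  span <- rAcid0 - rBase0
  if (span <= 0) stop("calibration series has no dynamic range")
  ## pKa start: pH where the curve crosses its half-maximum
  half <- rBase0 + span / 2
  pKa0 <- stats::approx(y, ph, xout = half, ties = mean)$y
  if (!is.finite(pKa0)) pKa0 <- stats::median(ph)
  dat <- data.frame(ph = ph, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ rBase + (rAcid - rBase) / (1 + 10^(hill * (ph - pKa))),
      data = dat, weights = weights,
      start = list(pKa = pKa0, hill = 1,
                   rAcid = rAcid0 + 0.05 * span, rBase = rBase0 - 0.05 * span),
      lower = c(pKa = 1, hill = 1e-3, rAcid = 1e-8, rBase = 1e-8),
      upper = c(pKa = 13, hill = 50, rAcid = 100, rBase = 100),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("calibration fit did not converge: ",
                             conditionMessage(e)))
  est <- stats::coef(fit)
  out <- sensorParams(pKa = est[["pKa"]], hill = est[["hill"]],
                      rAcid = est[["rAcid"]], rBase = est[["rBase"]])
  attr(out, "rss") <- sum(weights * stats::residuals(fit)^2)
  attr(out, "estimates") <- est
  attr(out, "fit") <- fit
  out
}

#' Read / write calibration series CSV
#'
#' Column layout: `ph`, `mean_ratio`, `sd`, `n_wells`.
#'
#' @param path file path.
#' @return `readCalibrationSeries()` a calibration series data.frame.
#' @export
readCalibrationSeries <- function(path) {
  df <- utils::read.csv(path)
  calibrationSeries(df$ph, df$mean_ratio,
                    sd = if ("sd" %in% names(df)) df$sd else 0,
                    nWells = if ("n_wells" %in% names(df)) df$n_wells else 1L)
}

#' @rdname readCalibrationSeries
#' @param series calibration series data.frame.
#' @export
writeCalibrationSeries <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Serialize fitted sensor parameters as JSON
#'
#' JSON keys: `pKa`, `hill`, `r_acid`, `r_base`.
#'
#' @param params a [SensorParams-class].
#' @param path file path.
#' @export
writeSensorParams <- function(params, path) {
  stopifnot(is(params, "SensorParams"))
  jsonlite::write_json(list(pKa = params@pKa, hill = params@hill,
                            r_acid = params@rAcid, r_base = params@rBase),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSensorParams
#' @return `readSensorParams()` a [SensorParams-class].
#' @export
readSensorParams <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sensorParams(pKa = x$pKa, hill = x$hill, rAcid = x$r_acid, rBase = x$r_base)
}
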