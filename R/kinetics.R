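#' Effective internalization rate at a given EGF concentration
#'
#' Blends three first-order components by receptor occupancy:
#' occupied-receptor clathrin-mediated internalization (saturating at
#' `kdCme`, abolished by kinase inhibition or CME block), the slow
#' constitutive rate of unoccupied receptors, and a clathrin-independent
#' component that only becomes appreciable at high, saturating EGF
#' (half-saturation `kdCie`):
#' \deqn{k(EGF) = occ \cdot k_{CME} \cdot [!inhibited] + (1 - occ) k_{basal}
#'   + occ_{CIE} \cdot k_{CIE}}
#' with occ = EGF/(kdCme + EGF) and occCIE = EGF/(kdCie + EGF). The result is
#' non-decreasing in EGF.
#'
#' @param params a [KineticParams-class].
#' @param egf EGF concentration(s), ng/ml, >= 0.
#' @return Effective rate(s), per minute.
#' @export
#' @examples
#' effectiveRate(kineticParams(), c(0, 1, 4, 200))
effectiveRate <- function(params, egf) {
  stopifnot(is(params, "KineticParams"))
  validObject(params)
  if (!is.numeric(egf) || any(!is.finite(egf)) || any(egf < 0))
    stop("'egf' must be finite and non-negative")
  occ <- egf / (params@kdCme + egf)
  occCie <- egf / (params@kdCie + egf)
  cme <- if (params@kinaseInhibited || params@cmeBlocked) 0 else params@keOccCme
  occ * cme + (1 - occ) * params@keBasal + occCie * params@keCieMax
}

## Closed form of the two-pool model dS/dt = -kS + kRec E, dE/dt = kS - kRec E
## with S(0) = 1, E(0) = 0 (impermeant label, instantaneous surface labeling):
## E(t) = (k / (k + kRec)) (1 - exp(-(k + kRec) t)).
closedFormFraction <- function(k, kRec, times) {
  lam <- k + kRec
  if (lam <= 0) return(rep(0, length(times)))
  (k / lam) * (1 - exp(-lam * times))
}

#' Simulate an endosomal-fraction time course
#'
#' Solves the surface/endosome two-pool model with effective internalization
#' rate k = [effectiveRate()] and recycling `kRec`, from an all-surface
#' initial condition, via its closed form
#' \eqn{f(t) = (k/(k + k_{rec})) (1 - e^{-(k + k_{rec}) t})}.
#'
#' @param params a [KineticParams-class].
#' @param egf EGF concentration, ng/ml.
#' @param times numeric vector of minutes, sorted, starting at >= 0.
#' @return data.frame with columns `time_min` and `f_endo`.
#' @export
#' @examples
#' simulateFraction(kineticParams(), egf = 4, times = c(0, 5, 15))
simulateFraction <- function(params, egf, times) {
  stopifnot(is(params, "KineticParams"))
  if (!is.numeric(times) || length(times) == 0L || any(!is.finite(times)))
    stop("'times' must be finite numeric")
  if (is.unsorted(times)) stop("'times' must be sorted")
  if (times[1] < 0) stop("'times' must be >= 0")
  k <- effectiveRate(params, egf)
  data.frame(time_min = times,
             f_endo = closedFormFraction(k, params@kRec, times))
}

#' Simulate a dose-response of well ratios
#'
#' Runs the kinetics for each EGF concentration for `t` minutes and converts
#' the endosomal fraction into the well 561/640 ratio through the mixing
#' model (surface pool at the stop-buffer pH, endosomal pool at endosomal
#' pH). Without inhibition the ratio is non-decreasing in EGF; with a kinase
#' inhibitor the low-dose response collapses to the 0-EGF value while a
#' residual clathrin-independent component persists at saturating EGF.
#'
#' @param params a [KineticParams-class] (its `kinaseInhibited` flag is
#'   overridden by `inhibited`).
#' @param sensor a [SensorParams-class].
#' @param comp a [CompartmentPH-class].
#' @param concs EGF concentrations, ng/ml.
#' @param t incubation time, minutes (> 0).
#' @param inhibited logical, apply kinase inhibition.
#' @return data.frame with columns `egf_ng_ml`, `f_endo`, `ratio`.
#' @export
simulateDoseResponse <- function(params, sensor, comp, concs, t = 15,
                                 inhibited = FALSE) {
  stopifnot(is(params, "KineticParams"), is(sensor, "SensorParams"),
            is(comp, "CompartmentPH"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0)
    stop("'t' must be a single positive time in minutes")
  p <- params
  p@kinaseInhibited <- isTRUE(inhibited)
  f <- vapply(concs, function(cc)
    simulateFraction(p, cc, c(0, t))$f_endo[2], numeric(1))
  data.frame(egf_ng_ml = concs, f_endo = f,
             ratio = mixingRatio(sensor, f, comp))
}

#' Simulate a radioligand uptake series
#'
#' Quasi-steady-state early uptake: surface-bound ligand stays at
#' `surfaceLevel` while internalized ligand accumulates linearly at rate
#' `ke * surfaceLevel`. Each observation carries independent multiplicative
#' Gaussian measurement noise of CV `noiseCv`. Valid in the early linear
#' regime (a few minutes), before recycling and degradation bend the curve.
#'
#' @param ke internalization rate constant, per minute.
#' @param times timepoints, minutes.
#' @param surfaceLevel surface-bound counts.
#' @param noiseCv measurement CV (>= 0).
#' @param seed integer RNG seed; the series is reproducible given the seed.
#' @return data.frame with columns `time_min`, `internal`, `surface`.
#' @export
#' @examples
#' simulateUptake(0.5, times = 1:5, seed = 1)
simulateUptake <- function(ke, times, surfaceLevel = 1e5, noiseCv = 0.01,
                           seed = 1L) {
  if (!is.numeric(times) || length(times) == 0L || any(!is.finite(times)))
    stop("'times' must be a non-empty finite numeric vector")
  if (!is.finite(ke) || ke < 0) stop("'ke' must be finite and non-negative")
  if (!is.finite(noiseCv) || noiseCv < 0) stop("'noiseCv' must be >= 0")
  withRNG(seed, {
    n <- length(times)
    eSurf <- stats::rnorm(n, 0, noiseCv)
    eInt <- stats::rnorm(n, 0, noiseCv)
    surface <- pmax(surfaceLevel * (1 + eSurf), 0)
    internal <- pmax(ke * times * surfaceLevel * (1 + eInt), 0)
    data.frame(time_min = times, internal = internal, surface = surface)
  })
}

#' Estimate the internalization rate constant from an In/Sur plot
#'
#' Regresses internalized/surface ligand against time through the origin
#' over the first `nPoints` timepoints; the slope is the specific
#' internalization rate constant Ke of occupied receptors.
#'
#' @param series data.frame with columns `time_min`, `internal`, `surface`
#'   (see [simulateUptake()]).
#' @param nPoints number of early timepoints to use (default 5, >= 2).
#' @return Ke estimate, per minute.
#' @export
#' @examples
#' estimateKe(simulateUptake(0.5, 1:5, noiseCv = 0, seed = 1))
estimateKe <- function(series, nPoints = 5L) {
  need <- c("time_min", "internal", "surface")
  if (!is.data.frame(series) || !all(need %in% names(series)))
    stop("'series' must have columns time_min, internal, surface")
  nPoints <- as.integer(nPoints)
  if (nPoints < 2L) stop("'nPoints' must be >= 2")
  n <- min(nPoints, nrow(series))
  if (n < 2L) stop("need at least 2 timepoints")
  s <- series[seq_len(n), ]
  if (any(s$surface <= 0)) stop("surface counts must be positive over the used points")
  y <- s$internal / s$surface
  sum(s$time_min * y) / sum(s$time_min^2)
}

#' Time at which a trajectory reaches its plateau
#'
#' Returns the earliest sampled time at which `f_endo` is within `relTol`
#' (relative to the final sampled value) of that final value and stays
#' within it for all later samples. The final sample always qualifies, so a
#' non-empty sampled trajectory reports at latest its last timepoint; a
#' constant-zero trajectory plateaus at its first sample.
#'
#' @param tc data.frame with columns `time_min`, `f_endo` (a time course
#'   from [simulateFraction()]).
#' @param relTol relative tolerance in (0, 1).
#' @return Time in minutes, or `NA` if never within tolerance.
#' @export
plateauTime <- function(tc, relTol = 0.05) {
  if (!is.data.frame(tc) || !all(c("time_min", "f_endo") %in% names(tc)) ||
      nrow(tc) == 0L)
    stop("'tc' must be a non-empty time course")
  if (!is.finite(relTol) || relTol <= 0 || relTol >= 1)
    stop("'relTol' must lie in (0, 1)")
  f <- tc$f_endo
  fin <- f[length(f)]
  ok <- abs(f - fin) <= relTol * abs(fin)
  ## earliest index from which every later sample is also within tolerance
  settled <- rev(cumprod(rev(ok))) == 1
  if (!any(settled)) return(NA_real_)
  tc$time_min[which(settled)[1]]
}

#' Read / write time-course and uptake CSVs
#' @param path file path.
#' @param x data.frame to write.
#' @export
writeSeriesCSV <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSeriesCSV
#' @export
readSeriesCSV <- function(path) utils::read.csv(path)
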