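test_that("ratio sigmoid hits its midpoint, limits and endosome/medium fold", {
  sp <- sensorParams()
  expect_equal(ratioAtPH(sp, sp@pKa), (1.95 + 0.40) / 2)
  expect_equal(ratioAtPH(sp, 14), 0.40, tolerance = 1e-6)
  expect_equal(ratioAtPH(sp, 0.1), 1.95, tolerance = 1e-6)
  # endosomal vs medium contrast of the default calibration
  expect_equal(ratioAtPH(sp, 5.5) / ratioAtPH(sp, 7.4), 2.999652,
               tolerance = 1e-6)
  expect_error(ratioAtPH(sp, NaN), "finite")
  expect_error(ratioAtPH(sp, Inf), "finite")
})

test_that("ratio sigmoid is strictly decreasing for any valid parameters", {
  set.seed(11)
  for (i in 1:25) {
    sp <- sensorParams(pKa = runif(1, 4, 9), hill = runif(1, 0.3, 3),
                       rBase = runif(1, 0.1, 1),
                       rAcid = runif(1, 1.1, 4))
    ## sample within the numerically resolvable transition window
    ph <- sort(runif(40, sp@pKa - 4 / sp@hill, sp@pKa + 4 / sp@hill))
    expect_true(all(diff(ratioAtPH(sp, ph)) < 0))
  }
})

test_that("invalid sensor parameters are rejected", {
  expect_error(sensorParams(rAcid = 0.3, rBase = 0.4), "rAcid")
  expect_error(sensorParams(hill = 0), "hill")
  expect_error(sensorParams(pKa = 15), "pKa")
})

test_that("ratio -> pH inversion is exact and respects the open interval", {
  sp <- sensorParams()
  expect_equal(phFromRatio(sp, 1.175), 6.6)
  expect_error(phFromRatio(sp, sp@rAcid), "strictly inside")
  expect_error(phFromRatio(sp, sp@rBase), "strictly inside")
  set.seed(4)
  ph <- runif(100, 5, 8)
  back <- phFromRatio(sp, ratioAtPH(sp, ph))
  expect_lt(max(abs(back - ph)), 1e-9)
  r <- ratioAtPH(sp, phFromRatio(sp, seq(0.5, 1.9, by = 0.1)))
  expect_equal(r, seq(0.5, 1.9, by = 0.1), tolerance = 1e-9)
})

test_that("endosomal fraction inverts the two-pool mixture and clips with a flag", {
  sp <- sensorParams()
  comp <- compartmentPH()
  rSurf <- ratioAtPH(sp, comp@phSurface)
  rEndo <- ratioAtPH(sp, comp@phEndosome)
  expect_equal(as.numeric(endosomalFraction(sp, rSurf, comp)), 0)
  expect_equal(as.numeric(endosomalFraction(sp, rEndo, comp)), 1)
  # frozen from the closed-form inversion with the default calibration
  f <- endosomalFraction(sp, 1.543, comp)
  expect_equal(as.numeric(f), 0.7872001, tolerance = 1e-6)
  expect_false(attr(f, "clipped"))
  # affine round trip
  fr <- seq(0, 1, by = 0.01)
  back <- endosomalFraction(sp, mixingRatio(sp, fr, comp), comp)
  expect_lt(max(abs(as.numeric(back) - fr)), 1e-12)
  # noise outside the calibration range clips and flags
  lo <- endosomalFraction(sp, rSurf - 0.05, comp)
  hi <- endosomalFraction(sp, rEndo + 0.05, comp)
  expect_identical(as.numeric(lo), 0)
  expect_identical(as.numeric(hi), 1)
  expect_true(attr(lo, "clipped") && attr(hi, "clipped"))
  # degenerate compartments
  flat <- compartmentPH(phSurface = 7.4, phEndosome = 7.4 - 1e-14,
                        phMedium = 7.4)
  expect_error(endosomalFraction(sp, 1, flat), "degenerate")
})

# Independent check for the least-squares fit: coarse grid over (pKa, hill)
# with the plateaus profiled out by linear least squares at each grid point.
gridSearchFit <- function(ph, y) {
  best <- list(rss = Inf)
  for (pKa in seq(6.0, 7.2, by = 0.02)) {
    for (hill in seq(0.5, 1.8, by = 0.05)) {
      s <- 1 / (1 + 10^(hill * (ph - pKa)))
      co <- stats::coef(stats::lm(y ~ s))
      rss <- sum((y - co[1] - co[2] * s)^2)
      if (rss < best$rss)
        best <- list(rss = rss, pKa = pKa, hill = hill,
                     rBase = unname(co[1]), rAcid = unname(co[1] + co[2]))
    }
  }
  best
}

test_that("calibration fit recovers known parameters", {
  sp <- sensorParams()
  ph <- seq(5, 8, length.out = 8)
  clean <- calibrationSeries(ph, ratioAtPH(sp, ph))
  fit <- fitCalibration(clean)
  expect_equal(fit@pKa, 6.6, tolerance = 1e-4)
  expect_equal(fit@hill, 1.0, tolerance = 1e-3)
  expect_lt(attr(fit, "rss"), 1e-10)
  # with noise, still close; grid-search oracle agrees with the optimiser
  set.seed(21)
  noisy <- calibrationSeries(ph, ratioAtPH(sp, ph) + rnorm(8, 0, 0.02))
  nfit <- fitCalibration(noisy)
  expect_equal(nfit@pKa, 6.6, tolerance = 0.1)
  oracle <- gridSearchFit(ph, noisy$mean_ratio)
  expect_equal(nfit@pKa, oracle$pKa, tolerance = 0.05)
  expect_equal(nfit@hill, oracle$hill, tolerance = 0.1)
  expect_lte(attr(nfit, "rss"), oracle$rss + 1e-10)
  expect_error(fitCalibration(calibrationSeries(ph[1:3],
                                                ratioAtPH(sp, ph[1:3]))),
               ">= 4")
})

test_that("calibration series and fitted parameters round-trip through files", {
  sp <- sensorParams(pKa = 6.45, hill = 1.2, rAcid = 2.1, rBase = 0.35)
  ph <- seq(5, 8, length.out = 8)
  ser <- calibrationSeries(ph, ratioAtPH(sp, ph), sd = 0.01, nWells = 7L)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeCalibrationSeries(ser, csv)
  expect_equal(readCalibrationSeries(csv), ser)
  js <- withr::local_tempfile(fileext = ".json")
  writeSensorParams(sp, js)
  back <- readSensorParams(js)
  expect_equal(back@pKa, sp@pKa)
  expect_equal(back@rAcid, sp@rAcid)
  expect_error(calibrationSeries(c(5, 5, 6), c(1, 1, 1)), "increasing")
})
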