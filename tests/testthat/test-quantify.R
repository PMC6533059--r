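test_that("well measurement equals the stitched-mosaic mean", {
  f1 <- fieldImage(matrix(200, 8, 8), matrix(100, 8, 8))
  m <- measureWell(list(f1))
  expect_equal(m$i561_mean, 200)
  expect_equal(m$i640_mean, 100)
  expect_equal(m$n_pixels, 64)
  # four fields: stitched mean is the mean of the field means (equal sizes)
  set.seed(8)
  flds <- lapply(1:4, function(i)
    fieldImage(matrix(runif(64, 0, 1000), 8, 8),
               matrix(runif(64, 0, 500), 8, 8), fieldIndex = i))
  m4 <- measureWell(flds)
  expect_equal(m4$i561_mean,
               mean(vapply(flds, function(f) mean(f@ch561), numeric(1))))
  mosaic561 <- do.call(cbind, lapply(flds, function(f) f@ch561))
  expect_equal(m4$i561_mean, mean(mosaic561))
  expect_equal(m4$n_pixels, 256)
  bad <- fieldImage(matrix(1, 4, 4), matrix(1, 4, 4))
  expect_error(measureWell(list(f1, bad)), "same shape")
  expect_error(measureWell(list()), "non-empty")
})

test_that("background estimation averages parental wells per channel", {
  one <- data.frame(i561_mean = 50, i640_mean = 20)
  expect_equal(unname(estimateBackground(one)), c(50, 20))
  two <- data.frame(i561_mean = c(40, 60), i640_mean = c(20, 20))
  expect_equal(unname(estimateBackground(two)), c(50, 20))
  expect_error(estimateBackground(two[0, ]), "at least one")
})

test_that("corrected ratio follows the printed arithmetic and flags low signal", {
  r <- correctedRatio(list(i561_mean = 200, i640_mean = 100), c(50, 20),
                      epsilon = 1)
  expect_equal(r$ratio, 150 / 80)
  expect_identical(r$qc_flags, "")
  low <- correctedRatio(list(i561_mean = 200, i640_mean = 20), c(50, 20),
                        epsilon = 1)
  expect_true(is.na(low$ratio))
  expect_match(low$qc_flags, "low_signal")
  id <- correctedRatio(list(i561_mean = 300, i640_mean = 150), c(0, 0),
                       epsilon = 1)
  expect_equal(id$ratio, 2)
  clip <- correctedRatio(list(i561_mean = 200, i640_mean = 100,
                              sat_frac = 0.01), c(0, 0), epsilon = 1)
  expect_match(clip$qc_flags, "clipped")
  expect_error(correctedRatio(list(i561_mean = 1, i640_mean = 1), c(0, 0),
                              epsilon = 0), "epsilon")
})

test_that("ratios are invariant to a common intensity rescaling", {
  set.seed(17)
  for (i in 1:20) {
    m <- list(i561_mean = runif(1, 500, 5000), i640_mean = runif(1, 800, 4000))
    bg <- c(runif(1, 10, 100), runif(1, 10, 100))
    k <- runif(1, 0.1, 10)
    r1 <- correctedRatio(m, bg, epsilon = 1e-6)
    r2 <- correctedRatio(list(i561_mean = k * m$i561_mean,
                              i640_mean = k * m$i640_mean), k * bg,
                         epsilon = 1e-6)
    expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
  }
})

test_that("ratio rendering applies saturation modulation and the temperature map", {
  rp <- renderParams(ratioLow = 0.5, ratioHigh = 2, satLow = 100,
                     satHigh = 1000)
  ch640 <- matrix(c(50, 5000, 5000, 500), 2, 2)
  ch561 <- matrix(c(100, 2500, 2.6 * 5000, 500), 2, 2)
  img <- renderRatioImage(ch561, ch640, bg = c(0, 0), params = rp)
  expect_equal(dim(img), c(2, 2, 3))
  # ch640 below satLow renders black regardless of ratio
  expect_equal(img[1, 1, ], c(0, 0, 0))
  # low ratio at full saturation renders full-brightness blue
  expect_equal(img[2, 1, ], c(0, 0, 1))
  # high ratio at full saturation renders red
  expect_equal(img[1, 2, ], c(1, 0, 0))
  # partial saturation scales brightness linearly: ratio 1 maps to u = 1/3,
  # i.e. hue (0, 1, 2/3) on the 5-point temperature ramp
  expect_equal(img[2, 2, ], c(0, 1, 2 / 3) * (500 - 100) / (1000 - 100),
               tolerance = 1e-6)
  # uniform ratio image renders one hue
  u561 <- matrix(1.25, 3, 3); u640 <- matrix(1e4, 3, 3)
  uimg <- renderRatioImage(u561 * u640 / 1e4 * 1e4, u640, c(0, 0), rp)
  expect_equal(length(unique(as.vector(uimg[, , 1]))), 1)
  expect_error(renderRatioImage(matrix(1, 2, 2), matrix(1, 3, 3)),
               "identical shapes")
  expect_error(renderParams(ratioLow = 2, ratioHigh = 1), "ratioLow")
  p <- withr::local_tempfile(fileext = ".png")
  writeRatioPNG(img, p)
  expect_true(file.exists(p))
})

test_that("quantifying written images reproduces in-memory measurements", {
  acq <- testAcq()
  d <- withr::local_tempdir()
  l <- buildCalibrationLayout()
  keep <- which(wells(l)$col %in% c(1, 8))   # 8 calibration + 8 parental
  raw <- simulatePlate(l, acq = acq, seed = 31, imageDir = d,
                       wellIndices = keep)
  map <- cbind(data.frame(plate_id = plateId(l), replicate_id = "R1"),
               wells(l)[keep, ])
  fromDisk <- quantifyPlate(d, map, epsilon = testEpsilon)
  inMem <- applyBackground(raw,
                           estimateBackground(
                             raw[raw$role == "parental_background", ]),
                           epsilon = testEpsilon)
  expect_equal(fromDisk$i561_mean, inMem$i561_mean, tolerance = 1e-9)
  expect_equal(fromDisk$ratio, inMem$ratio, tolerance = 1e-9)
  expect_equal(fromDisk$qc_flags, inMem$qc_flags)
})
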