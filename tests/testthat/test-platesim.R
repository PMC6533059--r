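test_that("screen layouts reproduce the 80 + 8 + 4 + 4 design over 240 targets", {
  ids <- sprintf("PP%03d", 1:240)
  layouts <- buildScreenLayouts(ids, replicates = 3)
  expect_length(layouts, 9)
  for (l in layouts) {
    counts <- table(wells(l)$role)
    expect_equal(unname(counts["target"]), 80)
    expect_equal(unname(counts["negative_control"]), 8)
    expect_equal(unname(counts["positive_chc"]), 4)
    expect_equal(unname(counts["positive_dyn2"]), 4)
    expect_equal(sum(counts), 96)
  }
  for (r in paste0("R", 1:3)) {
    reps <- Filter(function(l) replicateId(l) == r, layouts)
    covered <- unlist(lapply(reps, function(l)
      wells(l)$target_id[wells(l)$role == "target"]))
    expect_setequal(covered, ids)
    expect_equal(anyDuplicated(covered), 0)
  }
  # controls sit at identical positions in every replicate
  pos <- lapply(layouts, function(l)
    wells(l)[wells(l)$role != "target", c("row", "col", "role")])
  expect_true(all(vapply(pos, identical, logical(1), pos[[1]])))
  expect_identical(layoutTable(buildScreenLayouts(ids, 2)),
                   layoutTable(buildScreenLayouts(ids, 2)))
  expect_error(buildScreenLayouts(ids[1:100]), "240")
  expect_error(buildScreenLayouts(c(ids[-1], ids[2])), "unique")
})

test_that("robustness layout splits the plate 48/48", {
  l <- buildRobustnessLayout(4)
  counts <- table(wells(l)$role)
  expect_equal(unname(counts["stimulated"]), 48)
  expect_equal(unname(counts["unstimulated"]), 48)
  expect_equal(sum(counts), 96)
  expect_true(all(wells(l)$egf_ng_ml[wells(l)$role == "stimulated"] == 4))
  expect_true(all(wells(l)$egf_ng_ml[wells(l)$role == "unstimulated"] == 0))
  expect_identical(buildRobustnessLayout(2), buildRobustnessLayout(2))
  expect_error(buildRobustnessLayout(0), "positive")
})

test_that("calibration layout spans pH 5-8 by row with 7 wells per level", {
  l <- buildCalibrationLayout(5, 8)
  w <- wells(l)
  byRow <- vapply(LETTERS[1:8], function(r)
    unique(w$calibration_ph[w$row == r & w$role == "calibration"]),
    numeric(1))
  expect_equal(unname(byRow), seq(5, 8, by = 3 / 7), tolerance = 1e-12)
  expect_true(all(diff(byRow) > 0))
  expect_equal(sum(w$role == "calibration"), 56)
  for (r in LETTERS[1:8])
    expect_equal(sum(w$role == "calibration" & w$row == r), 7)
  expect_equal(sum(w$role == "parental_background"), 40)
  expect_error(buildCalibrationLayout(8, 5), "below")
})

test_that("well rendering is a pure function of spec and seed", {
  acq <- testAcq()
  args <- list(makeSpec(), kineticParams(), sensorParams(), compartmentPH(),
               acq)
  a <- do.call(renderWell, c(args, seed = 42))
  b <- do.call(renderWell, c(args, seed = 42))
  expect_identical(lapply(a, function(f) f@ch561),
                   lapply(b, function(f) f@ch561))
  expect_identical(lapply(a, function(f) f@ch640),
                   lapply(b, function(f) f@ch640))
  c <- do.call(renderWell, c(args, seed = 43))
  expect_false(identical(a[[1]]@ch561, c[[1]]@ch561))
  expect_length(a, acq@fieldsPerWell)
  expect_error(renderWell(makeSpec(role = "nonsense"), kineticParams(),
                          sensorParams(), compartmentPH(), acq),
               "unknown well role")
  expect_error(renderWell(makeSpec(role = "calibration"), kineticParams(),
                          sensorParams(), compartmentPH(), acq),
               "calibration_ph")
})

test_that("parental wells carry only background after correction", {
  acq <- testAcq()
  meas <- do.call(rbind, lapply(1:4, function(s) {
    flds <- renderWell(makeSpec(role = "parental_background", col = s),
                       kineticParams(), sensorParams(), compartmentPH(),
                       acq, seed = s)
    as.data.frame(measureWell(flds))
  }))
  bg <- estimateBackground(meas)
  expect_equal(unname(bg["bg561"]), acq@background561, tolerance = 0.02)
  expect_equal(unname(bg["bg640"]), acq@background640, tolerance = 0.02)
  r <- correctedRatio(c(as.list(meas[1, ]), role = "parental_background"),
                      bg)
  expect_true(is.na(r$ratio))
  expect_match(r$qc_flags, "low_signal")
  expect_match(r$qc_flags, "background_well")
})

test_that("rendered wells recover the mixing-model ratio within 3 well CVs", {
  acq <- testAcq()
  sp <- sensorParams(); comp <- compartmentPH()
  bg <- c(acq@background561, acq@background640)
  for (s in 1:8) {
    spec <- makeSpec(egf = c(0, 1, 4, 20)[(s %% 4) + 1])
    flds <- renderWell(spec, kineticParams(), sp, comp, acq, seed = 100 + s)
    pred <- mixingRatio(sp, attr(flds, "f_true"), comp)
    r <- correctedRatio(measureWell(flds), bg, epsilon = testEpsilon)
    expect_lt(abs(r$ratio / pred - 1), 3 * acq@wellCV)
  }
  # calibration wells image the sensor at the imposed buffer pH
  cal <- renderWell(makeSpec(role = "calibration", calPH = 5.5),
                    kineticParams(), sp, comp, acq, seed = 201)
  r <- correctedRatio(measureWell(cal), bg, epsilon = testEpsilon)
  expect_lt(abs(r$ratio / ratioAtPH(sp, 5.5) - 1), 3 * acq@wellCV)
})

test_that("negative-control ratio variability converges to the well CV", {
  acq <- testAcq()
  meas <- simulateRobustnessPlate(4, acq = acq, seed = 77,
                                  epsilon = testEpsilon)
  un <- meas$ratio[meas$role == "unstimulated"]
  st <- meas$ratio[meas$role == "stimulated"]
  expect_equal(length(un), 48)
  # sample CV of 48 wells: sampling SD of the CV is about cv/sqrt(2*47)
  expect_gt(sd(un) / mean(un), 0.02)
  expect_lt(sd(un) / mean(un), 0.045)
  expect_gt(sd(st) / mean(st), 0.02)
  expect_lt(sd(st) / mean(st), 0.045)
})

test_that("plate simulation is deterministic and subsettable", {
  acq <- testAcq()
  l <- buildRobustnessLayout(4)
  full <- simulatePlate(l, acq = acq, seed = 5, wellIndices = 1:4)
  again <- simulatePlate(l, acq = acq, seed = 5, wellIndices = 1:4)
  expect_identical(full, again)
  sub <- simulatePlate(l, acq = acq, seed = 5, wellIndices = 3:4)
  expect_equal(sub$i561_mean, full$i561_mean[3:4])
})

test_that("field images round-trip through 16-bit multi-page TIFF", {
  acq <- testAcq()
  flds <- renderWell(makeSpec(col = 7), kineticParams(), sensorParams(),
                     compartmentPH(), acq, seed = 12)
  d <- withr::local_tempdir()
  paths <- writeFieldImages(flds, d, "PX")
  expect_length(paths, acq@fieldsPerWell)
  expect_match(basename(paths[1]), "^PX_A07_f1\\.tif$")
  back <- readWellImages(d, "PX", "A", 7)
  for (i in seq_along(flds)) {
    expect_identical(back[[i]]@ch561, flds[[i]]@ch561)
    expect_identical(back[[i]]@ch640, flds[[i]]@ch640)
  }
  expect_error(readWellImages(d, "PX", "B", 1), "no images")
})

test_that("plate maps round-trip through CSV", {
  layouts <- buildScreenLayouts(sprintf("PP%03d", 1:240), 1)
  p <- withr::local_tempfile(fileext = ".csv")
  writePlateMap(layouts, p)
  back <- readPlateMap(p)
  expect_equal(nrow(back), 3 * 96)
  expect_equal(back$target_id[back$role == "target"],
               layoutTable(layouts)$target_id[
                 layoutTable(layouts)$role == "target"])
})
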