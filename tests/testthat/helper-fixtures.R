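# Shared desk-scale fixtures. Small fields keep the image-based tests fast;
# the photon budget is scaled so per-pixel densities match the default
# geometry and wells stay clear of the low-signal threshold.
testAcq <- function(...) {
  acquisitionParams(imageSize = 64L, cellCountMean = 12, fieldsPerWell = 2L,
                    photonScale = 1e6, ...)
}

testEpsilon <- 100

makeSpec <- function(role = "stimulated", row = "A", col = 1, egf = 4,
                     kd = 0, calPH = NA_real_) {
  list(row = row, col = col, role = role, egf_ng_ml = egf,
       knockdown_efficacy = kd, calibration_ph = calPH)
}

# Measurement-level screen generator (no imaging): well ratios drawn from the
# statistical model the renderer implements, i.e. true mixing ratio times a
# Normal(1, cv) well factor. Used for the statistics-only properties.
makeScreenTable <- function(effects = NULL, replicates = 3, cv = 0.03,
                            seed = 1, egf = 1, t = 15) {
  set.seed(seed)
  kin <- kineticParams()
  sp <- sensorParams()
  comp <- compartmentPH()
  layouts <- buildScreenLayouts(sprintf("PP%03d", 1:240), replicates,
                                egf = egf)
  map <- layoutTable(layouts)
  if (!is.null(effects)) {
    hit <- match(map$target_id, names(effects))
    map$knockdown_efficacy[!is.na(hit)] <- effects[hit[!is.na(hit)]]
  }
  f <- vapply(seq_len(nrow(map)), function(i) {
    kp <- kin
    kp@keOccCme <- kp@keOccCme * (1 - map$knockdown_efficacy[i])
    if (map$role[i] == "positive_dyn2")
      kp@keCieMax <- kp@keCieMax * (1 - map$knockdown_efficacy[i])
    closed <- simulateFraction(kp, map$egf_ng_ml[i], c(0, t))
    closed$f_endo[2]
  }, numeric(1))
  map$ratio <- mixingRatio(sp, f, comp) * rnorm(nrow(map), 1, cv)
  map
}
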