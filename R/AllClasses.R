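#' @import methods
NULL

## Well roles recognised on a plate map. Kept as a plain character vector so
## plate-map CSVs round-trip without factor surprises.
WELL_ROLES <- c("negative_control", "positive_chc", "positive_dyn2", "target",
                "parental_background", "calibration", "stimulated",
                "unstimulated")

#' Valid well roles
#'
#' Returns the set of well roles understood by the plate layout builders,
#' the renderer and the screen statistics.
#'
#' @return Character vector of role names.
#' @export
#' @examples
#' wellRoles()
wellRoles <- function() WELL_ROLES

#' SensorParams: pH response of the 561/640 excitation ratio
#'
#' Four-parameter protonation (Henderson-Hasselbalch/Hill) sigmoid describing
#' how the far-red emission ratio under 561 nm versus 640 nm excitation of the
#' FAP-bound tandem dye depends on pH. The 640-excited emission is
#' pH-independent; the 561-excited (Cy3 FRET) component rises at acidic pH, so
#' the ratio is high in endosomes and low at the cell surface.
#'
#' @slot pKa numeric, apparent pKa of the donor (pH units, in (0, 14)).
#' @slot hill numeric, Hill slope of the transition (> 0).
#' @slot rAcid numeric, ratio plateau at strongly acidic pH.
#' @slot rBase numeric, ratio plateau at strongly basic pH (< rAcid, > 0).
#'
#' @seealso [sensorParams()], [ratioAtPH()], [fitCalibration()]
#' @export
setClass("SensorParams",
         representation(pKa = "numeric", hill = "numeric",
                        rAcid = "numeric", rBase = "numeric"))

setValidity("SensorParams", function(object) {
  msg <- character()
  for (s in c("pKa", "hill", "rAcid", "rBase")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msg)) return(msg)
  if (object@pKa <= 0 || object@pKa >= 14) msg <- c(msg, "pKa must lie in (0, 14)")
  if (object@hill <= 0) msg <- c(msg, "hill must be > 0")
  if (object@rBase <= 0) msg <- c(msg, "rBase must be > 0")
  if (object@rAcid <= object@rBase) msg <- c(msg, "rAcid must exceed rBase")
  if (length(msg)) msg else TRUE
})

#' Construct sensor calibration parameters
#'
#' Defaults give a ~3-fold ratio increase between pH 7.4 (medium) and pH 5.5
#' (endosomes), the contrast observed for the FAP-EGFR/MG-Bis-SA reporter.
#'
#' @param pKa apparent pKa (pH units).
#' @param hill Hill slope (dimensionless, > 0).
#' @param rAcid ratio plateau at low pH.
#' @param rBase ratio plateau at high pH.
#' @return A [SensorParams-class] object.
#' @export
#' @examples
#' sp <- sensorParams()
#' ratioAtPH(sp, 5.5) / ratioAtPH(sp, 7.4)  # ~3
sensorParams <- function(pKa = 6.6, hill = 1.0, rAcid = 1.95, rBase = 0.40) {
  new("SensorParams", pKa = pKa, hill = hill, rAcid = rAcid, rBase = rBase)
}

setMethod("show", "SensorParams", function(object) {
  cat("SensorParams (pH -> 561/640 ratio sigmoid)\n")
  cat(sprintf("  pKa: %.3f  hill: %.3f  rAcid: %.3f  rBase: %.3f\n",
              object@pKa, object@hill, object@rAcid, object@rBase))
})

#' CompartmentPH: pH of the receptor pools
#'
#' The two-pool mixing model places surface receptors at the stop-buffer pH
#' (the ice-cold pH 8 HEPES buffer used to halt trafficking and magnify the
#' surface/endosome contrast) and internalized receptors at endosomal pH.
#' `phMedium` is carried for dose-response simulations before the stop step.
#'
#' @slot phSurface numeric, pH seen by surface receptors at imaging (default 8.0).
#' @slot phEndosome numeric, endosomal lumen pH (default 5.5).
#' @slot phMedium numeric, extracellular medium pH during uptake (default 7.4).
#' @export
setClass("CompartmentPH",
         representation(phSurface = "numeric", phEndosome = "numeric",
                        phMedium = "numeric"))

setValidity("CompartmentPH", function(object) {
  v <- c(object@phSurface, object@phEndosome, object@phMedium)
  if (length(v) != 3L || !all(is.finite(v)))
    return("all compartment pH values must be single finite numbers")
  if (!(object@phEndosome < object@phMedium))
    return("phEndosome must be below phMedium")
  if (!(object@phMedium <= object@phSurface))
    return("phMedium must not exceed phSurface")
  TRUE
})

#' Construct compartment pH settings
#' @param phSurface surface pool pH at imaging (stop buffer).
#' @param phEndosome endosomal pool pH.
#' @param phMedium medium pH during uptake.
#' @return A [CompartmentPH-class] object.
#' @export
compartmentPH <- function(phSurface = 8.0, phEndosome = 5.5, phMedium = 7.4) {
  new("CompartmentPH", phSurface = phSurface, phEndosome = phEndosome,
      phMedium = phMedium)
}

setMethod("show", "CompartmentPH", function(object) {
  cat(sprintf("CompartmentPH: surface %.2f | endosome %.2f | medium %.2f\n",
              object@phSurface, object@phEndosome, object@phMedium))
})

#' KineticParams: receptor internalization rate constants
#'
#' Rate constants (per minute) of the two-pool surface/endosome model. The
#' ligand-occupied, kinase-dependent clathrin-mediated component saturates
#' with EGF occupancy at `kdCme`; a clathrin-independent component saturates
#' at the higher `kdCie`; unoccupied receptors internalize at the slow
#' constitutive rate `keBasal`; endosomal receptors recycle at `kRec`.
#' `kinaseInhibited` models an EGFR kinase inhibitor (e.g. PD158780), which
#' abolishes the CME component only; `cmeBlocked` models clathrin heavy chain
#' or dynamin-2 depletion.
#'
#' @slot keOccCme numeric, CME rate of occupied receptors (/min).
#' @slot keCieMax numeric, clathrin-independent rate at saturating EGF (/min).
#' @slot keBasal numeric, constitutive rate of unoccupied receptors (/min).
#' @slot kRec numeric, recycling rate endosome -> surface (/min).
#' @slot kdCme numeric, half-saturating EGF for the CME component (ng/ml).
#' @slot kdCie numeric, half-saturating EGF for the CIE component (ng/ml).
#' @slot kinaseInhibited logical flag.
#' @slot cmeBlocked logical flag.
#' @export
setClass("KineticParams",
         representation(keOccCme = "numeric", keCieMax = "numeric",
                        keBasal = "numeric", kRec = "numeric",
                        kdCme = "numeric", kdCie = "numeric",
                        kinaseInhibited = "logical", cmeBlocked = "logical"))

setValidity("KineticParams", function(object) {
  msg <- character()
  for (s in c("keOccCme", "keCieMax", "keBasal", "kRec", "kdCme", "kdCie")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("'%s' must be a single finite non-negative number", s))
  }
  if (length(msg)) return(msg)
  if (object@kdCme <= 0) msg <- c(msg, "kdCme must be > 0")
  if (object@kdCie <= object@kdCme) msg <- c(msg, "kdCie must exceed kdCme")
  for (s in c("kinaseInhibited", "cmeBlocked"))
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be TRUE or FALSE", s))
  if (length(msg)) msg else TRUE
})

#' Construct internalization kinetic parameters
#'
#' Defaults place the occupied-receptor CME rate at 0.50/min (the midpoint of
#' In/Sur estimates in gene-edited HeLa cells) and reproduce the qualitative
#' assay behaviour: near-complete kinase-inhibitor block at low EGF, a
#' residual kinase-insensitive component at saturating EGF, and an
#' endosomal-fraction plateau by 15 min.
#'
#' @param keOccCme,keCieMax,keBasal,kRec rates per minute.
#' @param kdCme,kdCie half-saturating EGF concentrations (ng/ml).
#' @param kinaseInhibited,cmeBlocked logical flags.
#' @return A [KineticParams-class] object.
#' @export
#' @examples
#' kp <- kineticParams()
#' effectiveRate(kp, egf = 1)  # ~0.178/min
kineticParams <- function(keOccCme = 0.50, keCieMax = 0.10, keBasal = 0.01,
                          kRec = 0.05, kdCme = 2, kdCie = 20,
                          kinaseInhibited = FALSE, cmeBlocked = FALSE) {
  new("KineticParams", keOccCme = keOccCme, keCieMax = keCieMax,
      keBasal = keBasal, kRec = kRec, kdCme = kdCme, kdCie = kdCie,
      kinaseInhibited = kinaseInhibited, cmeBlocked = cmeBlocked)
}

setMethod("show", "KineticParams", function(object) {
  cat("KineticParams (/min)\n")
  cat(sprintf("  keOccCme: %.3f  keCieMax: %.3f  keBasal: %.3f  kRec: %.3f\n",
              object@keOccCme, object@keCieMax, object@keBasal, object@kRec))
  cat(sprintf("  kdCme: %.1f ng/ml  kdCie: %.1f ng/ml  kinaseInhibited: %s  cmeBlocked: %s\n",
              object@kdCme, object@kdCie, object@kinaseInhibited,
              object@cmeBlocked))
})

#' AcquisitionParams: synthetic imaging settings
#'
#' Controls the synthetic dual-channel field renderer: geometry, photon
#' budget, camera noise and the plate-level well effect. `photonScale` is the
#' expected number of 640-excited photons collected per receptor-unit (one
#' labeled cell carries on average one receptor-unit). `wellCV` is the
#' coefficient of variation of the well-level multiplicative factor applied
#' to the 561-excited channel, the dominant well-to-well noise of the assay.
#'
#' @slot fieldsPerWell integer, image fields captured per well (default 4).
#' @slot imageSize integer, field edge length in pixels (square fields).
#' @slot cellCountMean numeric, mean cells per field.
#' @slot background561 numeric, additive background in the 561 channel.
#' @slot background640 numeric, additive background in the 640 channel.
#' @slot readNoiseSD numeric, Gaussian read noise SD (intensity units).
#' @slot photonScale numeric, photons per receptor-unit.
#' @slot wellCV numeric, CV of the well-level 561-channel factor.
#' @export
setClass("AcquisitionParams",
         representation(fieldsPerWell = "integer", imageSize = "integer",
                        cellCountMean = "numeric",
                        background561 = "numeric", background640 = "numeric",
                        readNoiseSD = "numeric", photonScale = "numeric",
                        wellCV = "numeric"))

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (object@fieldsPerWell < 1L) msg <- c(msg, "fieldsPerWell must be >= 1")
  if (object@imageSize < 16L) msg <- c(msg, "imageSize must be >= 16 pixels")
  if (object@cellCountMean <= 0) msg <- c(msg, "cellCountMean must be > 0")
  for (s in c("background561", "background640", "readNoiseSD", "photonScale",
              "wellCV")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("'%s' must be a single finite non-negative number", s))
  }
  if (length(msg)) msg else TRUE
})

#' Construct acquisition parameters
#' @param fieldsPerWell fields imaged per well.
#' @param imageSize field edge in pixels.
#' @param cellCountMean mean cells per field.
#' @param background561,background640 channel background offsets.
#' @param readNoiseSD Gaussian read noise SD.
#' @param photonScale photons per receptor-unit.
#' @param wellCV CV of the well-level 561-channel factor.
#' @return An [AcquisitionParams-class] object.
#' @export
acquisitionParams <- function(fieldsPerWell = 4L, imageSize = 256L,
                              cellCountMean = 30, background561 = 80,
                              background640 = 40, readNoiseSD = 2,
                              photonScale = 2.5e6, wellCV = 0.03) {
  new("AcquisitionParams", fieldsPerWell = as.integer(fieldsPerWell),
      imageSize = as.integer(imageSize), cellCountMean = cellCountMean,
      background561 = background561, background640 = background640,
      readNoiseSD = readNoiseSD, photonScale = photonScale, wellCV = wellCV)
}

setMethod("show", "AcquisitionParams", function(object) {
  cat("AcquisitionParams\n")
  cat(sprintf("  %d field(s)/well, %dx%d px, ~%.0f cells/field\n",
              object@fieldsPerWell, object@imageSize, object@imageSize,
              object@cellCountMean))
  cat(sprintf("  bg561: %.0f  bg640: %.0f  readNoiseSD: %.1f  photonScale: %.3g  wellCV: %.3f\n",
              object@background561, object@background640, object@readNoiseSD,
              object@photonScale, object@wellCV))
})

#' PlateLayout: a 96-well plate map
#'
#' Holds the per-well design of one physical plate: role, siRNA target, EGF
#' dose, knockdown efficacy and (for calibration plates) imposed buffer pH.
#' The `wells` slot is a 96-row data frame with columns `row` (A-H), `col`
#' (1-12), `role`, `target_id`, `egf_ng_ml`, `knockdown_efficacy`,
#' `calibration_ph`.
#'
#' @slot plateId character scalar.
#' @slot replicateId character scalar.
#' @slot wells data.frame of 96 well specifications.
#' @seealso [buildScreenLayouts()], [buildRobustnessLayout()],
#'   [buildCalibrationLayout()]
#' @export
setClass("PlateLayout",
         representation(plateId = "character", replicateId = "character",
                        wells = "data.frame"))

setValidity("PlateLayout", function(object) {
  msg <- character()
  if (length(object@plateId) != 1L || is.na(object@plateId))
    msg <- c(msg, "plateId must be a single string")
  if (length(object@replicateId) != 1L || is.na(object@replicateId))
    msg <- c(msg, "replicateId must be a single string")
  w <- object@wells
  need <- c("row", "col", "role", "target_id", "egf_ng_ml",
            "knockdown_efficacy", "calibration_ph")
  if (!all(need %in% names(w)))
    return(paste("wells must have columns:", paste(need, collapse = ", ")))
  if (nrow(w) != 96L) msg <- c(msg, "a plate layout must have exactly 96 wells")
  if (anyDuplicated(paste(w$row, w$col))) msg <- c(msg, "duplicated (row, col)")
  if (!all(w$row %in% LETTERS[1:8])) msg <- c(msg, "rows must be A-H")
  if (!all(w$col %in% 1:12)) msg <- c(msg, "columns must be 1-12")
  if (!all(w$role %in% WELL_ROLES))
    msg <- c(msg, "unknown well role(s)")
  cal <- w$role == "calibration"
  if (any(cal) && !all(is.finite(w$calibration_ph[cal])))
    msg <- c(msg, "calibration wells must carry calibration_ph")
  tgt <- w$role == "target"
  if (any(tgt) && any(is.na(w$target_id[tgt]) | w$target_id[tgt] == ""))
    msg <- c(msg, "target wells must carry target_id")
  if (any(!is.finite(w$egf_ng_ml) | w$egf_ng_ml < 0))
    msg <- c(msg, "egf_ng_ml must be finite and non-negative")
  kd <- w$knockdown_efficacy
  if (any(!is.finite(kd) | kd < 0 | kd > 1))
    msg <- c(msg, "knockdown_efficacy must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlateLayout", function(object) {
  cat(sprintf("PlateLayout '%s' (replicate %s)\n", object@plateId,
              object@replicateId))
  print(table(role = object@wells$role))
})

#' Accessors for PlateLayout
#' @param object a [PlateLayout-class].
#' @return `wells()` the 96-row well data frame; `plateId()` /
#'   `replicateId()` the identifiers.
#' @export
setGeneric("wells", function(object) standardGeneric("wells"))
#' @rdname wells
#' @export
setMethod("wells", "PlateLayout", function(object) object@wells)

#' @rdname wells
#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))
#' @rdname wells
#' @export
setMethod("plateId", "PlateLayout", function(object) object@plateId)

#' @rdname wells
#' @export
setGeneric("replicateId", function(object) standardGeneric("replicateId"))
#' @rdname wells
#' @export
setMethod("replicateId", "PlateLayout", function(object) object@replicateId)

#' FieldImage: one dual-channel image field
#'
#' A single microscope field of a well: the 561-nm-excited emission image
#' (FRET channel) and the 640-nm-excited emission image (direct MG channel),
#' both far-red emission, same shape, non-negative intensities.
#'
#' @slot ch561 numeric matrix, 561-excited emission.
#' @slot ch640 numeric matrix, 640-excited emission.
#' @slot well character, well address such as "A01".
#' @slot fieldIndex integer, 1-based field number within the well.
#' @export
setClass("FieldImage",
         representation(ch561 = "matrix", ch640 = "matrix",
                        well = "character", fieldIndex = "integer"))

setValidity("FieldImage", function(object) {
  msg <- character()
  if (!identical(dim(object@ch561), dim(object@ch640)))
    msg <- c(msg, "channel images must have identical shapes")
  if (any(object@ch561 < 0) || any(object@ch640 < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(object@well) != 1L) msg <- c(msg, "well must be a single string")
  if (length(object@fieldIndex) != 1L || object@fieldIndex < 1L)
    msg <- c(msg, "fieldIndex must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a FieldImage
#' @param ch561,ch640 numeric matrices of equal shape.
#' @param well well address string.
#' @param fieldIndex 1-based field number.
#' @return A [FieldImage-class] object.
#' @export
fieldImage <- function(ch561, ch640, well = "A01", fieldIndex = 1L) {
  new("FieldImage", ch561 = ch561, ch640 = ch640, well = well,
      fieldIndex = as.integer(fieldIndex))
}

setMethod("show", "FieldImage", function(object) {
  cat(sprintf("FieldImage %s field %d: %d x %d px, mean561 %.1f, mean640 %.1f\n",
              object@well, object@fieldIndex, nrow(object@ch561),
              ncol(object@ch561), mean(object@ch561), mean(object@ch640)))
})

## Well address helper: "A01" style.
wellAddress <- function(row, col) sprintf("%s%02d", row, as.integer(col))
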