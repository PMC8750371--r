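#' @include AllGenerics.R
NULL

VALUE_KINDS <- c("activity_Bq_per_mL", "suv_bw", "sul", "hounsfield",
                 "probability")
TIMEPOINTS  <- c("BL", "FU1", "FU2")
PERCIST_CATEGORIES <- c("CR", "PR", "SD", "PD")

#' Virtual base class for objects living on a 3D voxel lattice
#'
#' Stores the lattice geometry shared by volumes, masks and label maps:
#' voxel spacing in mm and the world coordinate of the first voxel centre.
#' Voxel indices are 1-based in R; world coordinates are
#' \code{origin + (index - 1) * spacing}, so all geometric computation
#' (e.g. the SULpeak sphere search) happens in world millimetres and is
#' correct for anisotropic voxels.
#'
#' @slot spacing numeric(3), mm per voxel, strictly positive.
#' @slot origin numeric(3), world mm of voxel (1,1,1).
#' @export
setClass("VoxelGrid", representation("VIRTUAL",
  spacing = "numeric",
  origin  = "numeric"))

validVoxelGrid <- function(object) {
  msg <- character()
  if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3 || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (mm)")
  if (length(msg)) msg else TRUE
}
setValidity("VoxelGrid", validVoxelGrid)

#' A 3D scalar image with declared value semantics
#'
#' The central container for PET and CT data. The value kind is always
#' declared by the producer (file manifest, conversion function), never
#' inferred from the data, so that activity concentration, SUV, SUL,
#' Hounsfield units and probabilities cannot be silently confused.
#'
#' @slot values 3D numeric array, all finite.
#' @slot valueKind one of \code{"activity_Bq_per_mL"}, \code{"suv_bw"},
#'   \code{"sul"}, \code{"hounsfield"}, \code{"probability"}.
#' @seealso [imageVolume()], [readVolume()], [toSUVbw()], [toSUL()]
#' @export
setClass("ImageVolume", contains = "VoxelGrid", representation(
  values    = "array",
  valueKind = "character"))

setValidity("ImageVolume", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3 || any(d < 1))
    msg <- c(msg, "values must be a 3D array with all dimensions >= 1")
  if (length(object@valueKind) != 1 ||
      !object@valueKind %in% VALUE_KINDS)
    msg <- c(msg, sprintf("valueKind must be one of: %s",
                          paste(VALUE_KINDS, collapse = ", ")))
  nbad <- sum(!is.finite(object@values))
  if (nbad > 0)
    msg <- c(msg, sprintf("values contain %d non-finite voxel(s)", nbad))
  if (length(msg)) msg else TRUE
})

#' A binary segmentation or organ mask on a voxel lattice
#'
#' @slot values 3D logical array.
#' @seealso [binaryMask()], [readMask()], [labelLesions()]
#' @export
setClass("BinaryMask", contains = "VoxelGrid", representation(
  values = "array"))

setValidity("BinaryMask", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3 || any(d < 1))
    msg <- c(msg, "values must be a 3D array with all dimensions >= 1")
  if (!is.logical(object@values))
    msg <- c(msg, "mask values must be logical")
  if (anyNA(object@values))
    msg <- c(msg, "mask values must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Integer-labelled connected lesion components
#'
#' Produced by [labelLesions()]: 0 is background, labels 1..K are connected
#' lesion components under the declared connectivity, numbered by first
#' voxel in storage scan order (x fastest, z slowest).
#'
#' @slot labels 3D integer array.
#' @slot connectivity 6, 18 or 26.
#' @export
setClass("LesionLabelMap", contains = "VoxelGrid", representation(
  labels       = "array",
  connectivity = "integer"))

setValidity("LesionLabelMap", function(object) {
  msg <- character()
  d <- dim(object@labels)
  if (length(d) != 3 || any(d < 1))
    msg <- c(msg, "labels must be a 3D array")
  if (!is.integer(object@labels) || anyNA(object@labels))
    msg <- c(msg, "labels must be an NA-free integer array")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    msg <- c(msg, "connectivity must be 6, 18 or 26")
  k <- max(object@labels)
  if (k > 0 && !setequal(setdiff(unique(as.vector(object@labels)), 0L),
                         seq_len(k)))
    msg <- c(msg, "labels must be contiguous 1..K")
  if (length(msg)) msg else TRUE
})

#' Per-acquisition scan metadata
#'
#' Holds the anthropometrics and dosimetry needed for SUV/SUL conversion
#' plus the expert PERCIST category for follow-up acquisitions. Injected
#' activity is required already decay-corrected to scan start; no decay
#' chain is computed here.
#'
#' @slot patientId character scalar.
#' @slot timepoint \code{"BL"}, \code{"FU1"} or \code{"FU2"}.
#' @slot injectedActivity Bq, > 0.
#' @slot weight kg, > 0.
#' @slot height m, > 0.
#' @slot sex \code{"female"} or \code{"male"}.
#' @slot percist \code{"CR"}, \code{"PR"}, \code{"SD"}, \code{"PD"} or
#'   \code{NA}; only allowed on follow-up timepoints.
#' @export
setClass("AcquisitionMeta", representation(
  patientId        = "character",
  timepoint        = "character",
  injectedActivity = "numeric",
  weight           = "numeric",
  height           = "numeric",
  sex              = "character",
  percist          = "character"))

setValidity("AcquisitionMeta", function(object) {
  msg <- character()
  if (!object@timepoint %in% TIMEPOINTS)
    msg <- c(msg, "timepoint must be BL, FU1 or FU2")
  for (s in c("injectedActivity", "weight", "height")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive value", s))
  }
  if (!object@sex %in% c("female", "male"))
    msg <- c(msg, "sex must be 'female' or 'male'")
  if (!is.na(object@percist)) {
    if (!object@percist %in% PERCIST_CATEGORIES)
      msg <- c(msg, "percist must be CR, PR, SD or PD")
    if (object@timepoint == "BL")
      msg <- c(msg, "percist labels are only defined for follow-up timepoints")
  }
  if (length(msg)) msg else TRUE
})

#' One patient's longitudinal acquisitions
#'
#' Baseline plus one or two follow-up acquisitions, with the patient's
#' organ masks. All volumes of one patient must share a lattice: the
#' pipeline assumes pre-registered input (registration is upstream).
#'
#' @slot baseline list(volume = ImageVolume, mask = BinaryMask,
#'   meta = AcquisitionMeta).
#' @slot followups list of such lists, length >= 1, in temporal order.
#' @slot organMasks list(bone = BinaryMask, liver = BinaryMask).
#' @export
setClass("PatientTimeline", representation(
  baseline   = "list",
  followups  = "list",
  organMasks = "list"))

setValidity("PatientTimeline", function(object) {
  msg <- character()
  checkAcq <- function(a, what) {
    if (!is.list(a) || !all(c("volume", "mask", "meta") %in% names(a)))
      return(sprintf("%s must be a list(volume, mask, meta)", what))
    NULL
  }
  msg <- c(msg, checkAcq(object@baseline, "baseline"))
  if (length(object@followups) < 1)
    msg <- c(msg, "at least one follow-up acquisition is required")
  for (i in seq_along(object@followups))
    msg <- c(msg, checkAcq(object@followups[[i]], sprintf("followups[[%d]]", i)))
  if (!all(c("bone", "liver") %in% names(object@organMasks)))
    msg <- c(msg, "organMasks must contain 'bone' and 'liver'")
  if (!length(msg)) {
    ref <- object@baseline$volume
    allGrids <- c(list(object@baseline$mask),
                  unlist(lapply(object@followups,
                                function(a) list(a$volume, a$mask)),
                         recursive = FALSE),
                  object@organMasks[c("bone", "liver")])
    for (g in allGrids)
      if (!sameLattice(ref, g)) {
        msg <- c(msg, "all volumes and masks of one patient must share a lattice")
        break
      }
  }
  msg <- msg[!vapply(msg, is.null, logical(1))]
  if (length(msg)) unlist(msg) else TRUE
})

#' The four imaging biomarkers of one acquisition
#'
#' SULpeak (highest mean SUL in a 1.2-cm spherical VOI centred on a
#' segmentation voxel), total metabolic tumor volume, total lesion
#' glycolysis, and the PET Bone/Liver Indices, plus per-lesion statistics.
#' For an empty segmentation all volumes are 0 and SULpeak carries an
#' undefined flag (NA value).
#'
#' @slot sulPeak g/mL; NA when undefined (empty segmentation).
#' @slot sulPeakCenter integer(3) voxel index of the retained VOI centre,
#'   or NA.
#' @slot mtvTotal mL.
#' @slot tlgTotal mL (SUV-weighted).
#' @slot pbi percent of bone volume occupied by bone lesions.
#' @slot pli percent of liver volume occupied by liver lesions.
#' @slot perLesion data.frame with columns label, voxels, mtv_ml, suv_mean,
#'   tlg, organ.
#' @export
setClass("BiomarkerPanel", representation(
  sulPeak       = "numeric",
  sulPeakCenter = "integer",
  mtvTotal      = "numeric",
  tlgTotal      = "numeric",
  pbi           = "numeric",
  pli           = "numeric",
  perLesion     = "data.frame"))

setValidity("BiomarkerPanel", function(object) {
  msg <- character()
  if (object@mtvTotal < 0) msg <- c(msg, "mtvTotal must be >= 0")
  for (s in c("pbi", "pli")) {
    v <- slot(object, s)
    if (!is.na(v) && (v < 0 || v > 100))
      msg <- c(msg, sprintf("%s must lie in [0, 100]", s))
  }
  if (nrow(object@perLesion) > 0 &&
      abs(object@tlgTotal - sum(object@perLesion$tlg)) >
        1e-8 * max(1, abs(object@tlgTotal)))
    msg <- c(msg, "tlgTotal must equal the sum of per-lesion TLGs")
  if (length(msg)) msg else TRUE
})

## ---- lattice helpers shared across modules ----

#' Test whether two grid objects share a lattice
#'
#' Shape, spacing and origin must agree (spacing/origin to within 1e-6 mm).
#' All inter-volume operations require this and fail loudly otherwise.
#'
#' @param a,b [VoxelGrid-class] derivatives.
#' @return TRUE or FALSE.
#' @export
sameLattice <- function(a, b) {
  identical(gridDim(a), gridDim(b)) &&
    all(abs(spacing(a) - spacing(b)) < 1e-6) &&
    all(abs(worldOrigin(a) - worldOrigin(b)) < 1e-6)
}

stopIfLatticeMismatch <- function(a, b, what = "inputs") {
  if (!sameLattice(a, b))
    stop(sprintf("lattice mismatch: %s must share shape, spacing and origin",
                 what), call. = FALSE)
  invisible(TRUE)
}

## ---- constructors ----

#' Construct an ImageVolume
#'
#' @param values 3D numeric array.
#' @param spacing numeric(3) mm per voxel.
#' @param origin numeric(3) world mm of voxel (1,1,1).
#' @param valueKind declared value semantics; see [valueKind()].
#' @return An [ImageVolume-class].
#' @examples
#' v <- imageVolume(array(1, c(4, 4, 4)), spacing = c(2, 2, 2),
#'                  valueKind = "suv_bw")
#' voxelVolumeML(v)
#' @export
imageVolume <- function(values, spacing, origin = c(0, 0, 0),
                        valueKind = "suv_bw") {
  storage.mode(values) <- "double"
  new("ImageVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), valueKind = valueKind)
}

#' Construct a BinaryMask
#'
#' @param values 3D logical (or coercible 0/1) array.
#' @param spacing numeric(3) mm per voxel.
#' @param origin numeric(3) world mm of voxel (1,1,1).
#' @return A [BinaryMask-class].
#' @export
binaryMask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.logical(values)) {
    v <- as.logical(values != 0)
    dim(v) <- dim(values)
    values <- v
  }
  new("BinaryMask", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct an AcquisitionMeta record
#'
#' @param patientId patient identifier.
#' @param timepoint "BL", "FU1" or "FU2".
#' @param injectedActivity injected activity in Bq, decay-corrected to scan
#'   start.
#' @param weight body weight, kg.
#' @param height body height, m.
#' @param sex "female" or "male".
#' @param percist expert PERCIST category for follow-ups (CR/PR/SD/PD), or NA.
#' @return An [AcquisitionMeta-class].
#' @export
acquisitionMeta <- function(patientId, timepoint, injectedActivity, weight,
                            height, sex, percist = NA_character_) {
  new("AcquisitionMeta", patientId = as.character(patientId),
      timepoint = timepoint, injectedActivity = injectedActivity,
      weight = weight, height = height, sex = sex,
      percist = as.character(percist))
}

## ---- accessors ----

#' @rdname spacing
#' @export
setMethod("spacing", "VoxelGrid", function(x) x@spacing)

#' @rdname worldOrigin
#' @export
setMethod("worldOrigin", "VoxelGrid", function(x) x@origin)

#' @rdname gridDim
#' @export
setMethod("gridDim", "ImageVolume", function(x) dim(x@values))

#' @rdname gridDim
#' @export
setMethod("gridDim", "BinaryMask", function(x) dim(x@values))

#' @rdname gridDim
#' @export
setMethod("gridDim", "LesionLabelMap", function(x) dim(x@labels))

#' @rdname voxelVolumeML
#' @export
setMethod("voxelVolumeML", "VoxelGrid", function(x) prod(x@spacing) / 1000)

#' @rdname voxelData
#' @export
setMethod("voxelData", "ImageVolume", function(x) x@values)

#' @rdname voxelData
#' @export
setMethod("voxelData", "BinaryMask", function(x) x@values)

#' @rdname voxelData
#' @export
setMethod("voxelData", "LesionLabelMap", function(x) x@labels)

#' @rdname valueKind
#' @export
setMethod("valueKind", "ImageVolume", function(x) x@valueKind)

#' @rdname nLesions
#' @export
setMethod("nLesions", "LesionLabelMap", function(x) max(x@labels))

## ---- show methods ----

setMethod("show", "ImageVolume", function(object) {
  d <- gridDim(object)
  cat(sprintf("ImageVolume  %d x %d x %d  [%s]\n", d[1], d[2], d[3],
              object@valueKind))
  cat(sprintf("  spacing: %.6g x %.6g x %.6g mm   origin: (%.6g, %.6g, %.6g)\n",
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@origin[1], object@origin[2], object@origin[3]))
  cat(sprintf("  range: [%.4g, %.4g]\n", min(object@values),
              max(object@values)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- gridDim(object)
  cat(sprintf("BinaryMask  %d x %d x %d   %d foreground voxel(s) (%.3g mL)\n",
              d[1], d[2], d[3], sum(object@values),
              sum(object@values) * voxelVolumeML(object)))
})

setMethod("show", "LesionLabelMap", function(object) {
  cat(sprintf("LesionLabelMap  %d lesion(s), connectivity %d\n",
              nLesions(object), object@connectivity))
})

setMethod("show", "AcquisitionMeta", function(object) {
  cat(sprintf("AcquisitionMeta  %s @ %s  %s, %.1f kg, %.2f m, %.1f MBq%s\n",
              object@patientId, object@timepoint, object@sex, object@weight,
              object@height, object@injectedActivity / 1e6,
              if (is.na(object@percist)) "" else
                sprintf(", PERCIST %s", object@percist)))
})

setMethod("show", "BiomarkerPanel", function(object) {
  cat("BiomarkerPanel\n")
  cat(sprintf("  SULpeak : %s g/mL\n",
              if (is.na(object@sulPeak)) "undefined (empty segmentation)"
              else sprintf("%.4f", object@sulPeak)))
  cat(sprintf("  MTV     : %.4f mL\n", object@mtvTotal))
  cat(sprintf("  TLG     : %.4f\n", object@tlgTotal))
  cat(sprintf("  PBI     : %s %%\n", formatOptional(object@pbi)))
  cat(sprintf("  PLI     : %s %%\n", formatOptional(object@pli)))
  cat(sprintf("  lesions : %d\n", nrow(object@perLesion)))
})

formatOptional <- function(x) if (is.na(x)) "NA" else sprintf("%.4f", x)

setMethod("show", "PatientTimeline", function(object) {
  cat(sprintf("PatientTimeline  %s: baseline + %d follow-up(s)\n",
              object@baseline$meta@patientId, length(object@followups)))
})
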