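#' @include AllClasses.R labeling.R
NULL

sphereOffsets <- function(spacing, radiusMM) {
  nmax <- floor(radiusMM / spacing)
  g <- expand.grid(di = -nmax[1]:nmax[1], dj = -nmax[2]:nmax[2],
                   dk = -nmax[3]:nmax[3])
  d2 <- (g$di * spacing[1])^2 + (g$dj * spacing[2])^2 + (g$dk * spacing[3])^2
  as.matrix(g[d2 <= radiusMM^2 + 1e-9, , drop = FALSE])
}

#' SULpeak: highest mean SUL in a spherical VOI centred on the segmentation
#'
#' For every voxel of the segmentation taken as candidate centre, a
#' 1.2-cm-diameter sphere is formed from all voxels whose centres lie
#' within 6 mm (world distance, inclusive) of the candidate's centre —
#' the sphere is *not* restricted to the segmentation, only its centre is,
#' so the retained VOI is not necessarily centred on the hottest voxel.
#' The VOI with the highest mean SUL is kept. Spheres reaching beyond the
#' image border are truncated to existing voxels.
#'
#' @param sul [ImageVolume-class] in SUL units.
#' @param mask [BinaryMask-class] lesion segmentation on the same lattice.
#' @param sphereDiameterMM VOI diameter in mm (default 12, the PERCIST
#'   1.2-cm sphere, approx. 1 mL).
#' @return list(value = peak mean SUL in g/mL, center = integer(3) voxel
#'   index of the retained centre, nSphereVoxels = sphere size at that
#'   centre). For an empty mask, `value` and `center` are NA (undefined).
#' @export
sulPeak <- function(sul, mask, sphereDiameterMM = 12.0) {
  stopifnot(is(sul, "ImageVolume"), is(mask, "BinaryMask"))
  stopIfLatticeMismatch(sul, mask, "SUL volume and mask")
  centers <- which(mask@values)
  if (length(centers) == 0)
    return(list(value = NA_real_, center = rep(NA_integer_, 3),
                nSphereVoxels = NA_integer_))
  d <- gridDim(sul)
  off <- sphereOffsets(spacing(sul), sphereDiameterMM / 2)
  ci <- ((centers - 1L) %% d[1]) + 1L
  cj <- (((centers - 1L) %/% d[1]) %% d[2]) + 1L
  ck <- ((centers - 1L) %/% (d[1] * d[2])) + 1L
  sums <- numeric(length(centers))
  cnts <- integer(length(centers))
  v <- sul@values
  for (o in seq_len(nrow(off))) {
    ni <- ci + off[o, 1]; nj <- cj + off[o, 2]; nk <- ck + off[o, 3]
    ok <- ni >= 1L & ni <= d[1] & nj >= 1L & nj <= d[2] &
          nk >= 1L & nk <= d[3]
    lin <- (nk[ok] - 1L) * (d[1] * d[2]) + (nj[ok] - 1L) * d[1] + ni[ok]
    sums[ok] <- sums[ok] + v[lin]
    cnts[ok] <- cnts[ok] + 1L
  }
  means <- sums / cnts
  best <- which(means == max(means))[1]  # tie -> first centre in scan order
  list(value = means[best],
       center = c(ci[best], cj[best], ck[best]),
       nSphereVoxels = cnts[best])
}

#' Per-lesion MTV, SUVmean and TLG
#'
#' For each labelled lesion: MTV (voxel count times voxel volume, mL),
#' SUVmean (arithmetic mean of the SUV over the lesion's voxels) and
#' TLG = MTV x SUVmean.
#'
#' @param labelmap [LesionLabelMap-class].
#' @param suv [ImageVolume-class] on the same lattice (SUV body-weight
#'   units by convention).
#' @return data.frame with columns `label, voxels, mtv_ml, suv_mean, tlg`.
#' @export
lesionStats <- function(labelmap, suv) {
  stopifnot(is(labelmap, "LesionLabelMap"), is(suv, "ImageVolume"))
  stopIfLatticeMismatch(labelmap, suv, "label map and SUV volume")
  K <- nLesions(labelmap)
  vv <- voxelVolumeML(labelmap)
  if (K == 0)
    return(data.frame(label = integer(), voxels = integer(),
                      mtv_ml = numeric(), suv_mean = numeric(),
                      tlg = numeric()))
  inl <- labelmap@labels > 0L
  lab <- labelmap@labels[inl]
  val <- suv@values[inl]
  n <- tabulate(lab, nbins = K)
  s <- vapply(split(val, factor(lab, levels = seq_len(K))), sum, numeric(1))
  mtv <- n * vv
  suvMean <- s / n
  data.frame(label = seq_len(K), voxels = n, mtv_ml = mtv,
             suv_mean = suvMean, tlg = mtv * suvMean)
}

#' Assign each lesion to bone, liver or other
#'
#' A lesion is tagged `bone` (resp. `liver`) iff strictly more than
#' `majority` of its voxels lie inside the organ mask; bone takes
#' precedence when both fractions exceed the majority (overlapping organ
#' masks are tolerated but reported via a message).
#'
#' @param labelmap [LesionLabelMap-class].
#' @param bone,liver [BinaryMask-class] organ masks on the same lattice.
#' @param majority fraction in (0, 1); default 0.5 (strict majority).
#' @return character vector of length K with values "bone", "liver",
#'   "other".
#' @export
assignOrgans <- function(labelmap, bone, liver, majority = 0.5) {
  stopifnot(is(labelmap, "LesionLabelMap"))
  stopIfLatticeMismatch(labelmap, bone, "label map and bone mask")
  stopIfLatticeMismatch(labelmap, liver, "label map and liver mask")
  K <- nLesions(labelmap)
  if (K == 0) return(character(0))
  if (any(bone@values & liver@values))
    message("assignOrgans: bone and liver masks overlap; ",
            "bone takes precedence")
  inl <- labelmap@labels > 0L
  lab <- factor(labelmap@labels[inl], levels = seq_len(K))
  n <- tabulate(lab, nbins = K)
  fb <- tabulate(lab[bone@values[inl]], nbins = K) / n
  fl <- tabulate(lab[liver@values[inl]], nbins = K) / n
  ifelse(fb > majority, "bone", ifelse(fl > majority, "liver", "other"))
}

organIndex <- function(labelmap, organMask, tags, organ, volumeWithin) {
  organVoxels <- sum(organMask@values)
  if (organVoxels == 0)
    stop(sprintf("empty %s mask: index undefined", organ), call. = FALSE)
  sel <- which(tags == organ)
  if (length(sel) == 0) return(0)
  if (volumeWithin == "full") {
    lesionVoxels <- sum(labelmap@labels %in% sel)
  } else {
    lesionVoxels <- sum(labelmap@labels %in% sel & organMask@values)
  }
  100 * lesionVoxels / organVoxels
}

#' PET Bone Index (PBI)
#'
#' Skeletal tumor burden: 100 x (volume of lesions tagged bone) / (total
#' bone volume). By default a bone lesion contributes its full volume even
#' where it overflows the bone mask; set `volumeWithin = "intramask"` to
#' count only the intra-mask part.
#'
#' @param labelmap [LesionLabelMap-class].
#' @param bone [BinaryMask-class] bone mask (non-empty).
#' @param liver optional [BinaryMask-class]; supplied when tags must be
#'   recomputed with liver precedence rules.
#' @param tags optional precomputed organ tags from [assignOrgans()].
#' @param majority majority fraction for organ assignment.
#' @param volumeWithin "full" or "intramask".
#' @return PBI in percent.
#' @export
petBoneIndex <- function(labelmap, bone, liver = NULL, tags = NULL,
                         majority = 0.5,
                         volumeWithin = c("full", "intramask")) {
  volumeWithin <- match.arg(volumeWithin)
  if (is.null(tags)) {
    if (is.null(liver))
      liver <- binaryMask(array(FALSE, gridDim(labelmap)),
                          spacing(labelmap), worldOrigin(labelmap))
    tags <- assignOrgans(labelmap, bone, liver, majority)
  }
  organIndex(labelmap, bone, tags, "bone", volumeWithin)
}

#' PET Liver Index (PLI)
#'
#' Hepatic tumor burden: 100 x (volume of lesions tagged liver) / (total
#' liver volume). Symmetric to [petBoneIndex()].
#'
#' @param labelmap [LesionLabelMap-class].
#' @param liver [BinaryMask-class] liver mask (non-empty).
#' @param bone optional [BinaryMask-class] for bone-precedence tagging.
#' @inheritParams petBoneIndex
#' @return PLI in percent.
#' @export
petLiverIndex <- function(labelmap, liver, bone = NULL, tags = NULL,
                          majority = 0.5,
                          volumeWithin = c("full", "intramask")) {
  volumeWithin <- match.arg(volumeWithin)
  if (is.null(tags)) {
    if (is.null(bone))
      bone <- binaryMask(array(FALSE, gridDim(labelmap)),
                         spacing(labelmap), worldOrigin(labelmap))
    tags <- assignOrgans(labelmap, bone, liver, majority)
  }
  organIndex(labelmap, liver, tags, "liver", volumeWithin)
}

#' Compute the full four-biomarker panel for one acquisition
#'
#' Composes [labelLesions()], [sulPeak()], [lesionStats()],
#' [assignOrgans()], [petBoneIndex()] and [petLiverIndex()]. SULpeak is
#' computed on the SUL volume and TLG on the SUV (body-weight) volume,
#' each biomarker in its conventional units; both volumes are therefore
#' inputs. SULpeak is a single per-acquisition value over the pooled
#' segmentation (all lesions).
#'
#' @param sul [ImageVolume-class], SUL units.
#' @param suv [ImageVolume-class], SUV body-weight units.
#' @param mask [BinaryMask-class] lesion segmentation.
#' @param organs list(bone = [BinaryMask-class], liver = [BinaryMask-class]).
#' @param connectivity lesion component connectivity (6/18/26).
#' @param sphereDiameterMM SULpeak VOI diameter, mm.
#' @param majority organ-assignment majority fraction.
#' @param volumeWithin PBI/PLI numerator rule, "full" or "intramask".
#' @return A [BiomarkerPanel-class].
#' @export
biomarkerPanel <- function(sul, suv, mask, organs, connectivity = 26L,
                           sphereDiameterMM = 12.0, majority = 0.5,
                           volumeWithin = "full") {
  stopIfLatticeMismatch(sul, suv, "SUL and SUV volumes")
  stopIfLatticeMismatch(sul, mask, "volumes and lesion mask")
  lm <- labelLesions(mask, connectivity)
  peak <- sulPeak(sul, mask, sphereDiameterMM)
  stats <- lesionStats(lm, suv)
  tags <- assignOrgans(lm, organs$bone, organs$liver, majority)
  stats$organ <- if (nrow(stats)) tags else character(0)
  pbi <- petBoneIndex(lm, organs$bone, tags = tags,
                      volumeWithin = volumeWithin)
  pli <- petLiverIndex(lm, organs$liver, tags = tags,
                       volumeWithin = volumeWithin)
  new("BiomarkerPanel",
      sulPeak = peak$value,
      sulPeakCenter = as.integer(peak$center),
      mtvTotal = sum(stats$mtv_ml),
      tlgTotal = sum(stats$tlg),
      pbi = pbi, pli = pli,
      perLesion = stats)
}

#' Flatten a BiomarkerPanel to a one-row data.frame
#'
#' @param x a [BiomarkerPanel-class].
#' @param row.names,optional,... passed for generic compatibility, unused.
#' @return data.frame with columns sul_peak, mtv_total_ml, tlg_total, pbi,
#'   pli, n_lesions.
#' @export
as.data.frame.BiomarkerPanel <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(sul_peak = x@sulPeak, mtv_total_ml = x@mtvTotal,
             tlg_total = x@tlgTotal, pbi = x@pbi, pli = x@pli,
             n_lesions = nrow(x@perLesion))
}
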