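#' @include AllClasses.R morphology.R suv.R biomarkers.R
NULL

#' Specification of the synthetic whole-body phantom
#'
#' Stylised whole-body FDG PET geometry: an elliptic body of background
#' SUV about 1, a liver ellipsoid of SUV about 2, a spinal column and a
#' pelvic bar as bone compartments, and non-overlapping spherical lesions
#' of SUV 3-15 placed in bone, liver or soft tissue. Follow-up
#' acquisitions rescale lesion intensity and volume by planted response
#' factors from which the PERCIST category is derived. Ground truth
#' (lesion supports, organ masks, analytic biomarkers) is exact and
#' recomputable from the spec plus a seed.
#'
#' @slot dim integer(3) grid shape (default 96 x 96 x 192).
#' @slot spacing numeric(3) voxel size in mm (default 3 mm isotropic).
#' @slot backgroundSUV soft-tissue background SUV (default 1.0).
#' @slot liverSUV liver background SUV (default 2.0).
#' @slot lesionCountMean Poisson mean lesion count per patient (min 1,
#'   default 8).
#' @slot lesionDiameterRangeMM sampling range of lesion diameters
#'   (default 8-40 mm in soft tissue; capped lower inside bone and liver
#'   so lesions stay majority-inside their organ).
#' @slot lesionSUVRange sampling range of lesion SUV amplitude (3-15).
#' @slot siteProbs probabilities of bone / liver / other lesion sites.
#' @slot psfFWHMMM Gaussian PSF full width at half maximum, mm (default 6).
#' @slot noiseSD additive Gaussian noise sd in SUV units (default 0.05),
#'   clipped at 0.
#' @slot responderFraction planted fraction of responders (default 0.5).
#' @slot crFraction fraction of responders with complete response.
#' @slot pdFraction fraction of non-responders with progressive disease.
#' @slot responderSUVFactorRange,responderVolFactorRange follow-up
#'   multipliers (< 1) for responder lesions.
#' @slot sdSUVFactorRange,sdVolFactorRange stable-disease multipliers
#'   (about 1).
#' @slot pdSUVFactorRange,pdVolFactorRange progressive-disease multipliers
#'   (> 1).
#' @slot newLesionProb probability that a PD follow-up gains a new lesion.
#' @slot secondFollowupProb probability of a second follow-up acquisition.
#' @export
setClass("PhantomSpec", representation(
  dim                     = "integer",
  spacing                 = "numeric",
  backgroundSUV           = "numeric",
  liverSUV                = "numeric",
  lesionCountMean         = "numeric",
  lesionDiameterRangeMM   = "numeric",
  lesionSUVRange          = "numeric",
  siteProbs               = "numeric",
  psfFWHMMM               = "numeric",
  noiseSD                 = "numeric",
  responderFraction       = "numeric",
  crFraction              = "numeric",
  pdFraction              = "numeric",
  responderSUVFactorRange = "numeric",
  responderVolFactorRange = "numeric",
  sdSUVFactorRange        = "numeric",
  sdVolFactorRange        = "numeric",
  pdSUVFactorRange        = "numeric",
  pdVolFactorRange        = "numeric",
  newLesionProb           = "numeric",
  secondFollowupProb      = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@dim) != 3 || any(object@dim < 8))
    msg <- c(msg, "dim must be 3 values >= 8")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  for (s in c("lesionDiameterRangeMM", "lesionSUVRange",
              "responderSUVFactorRange", "responderVolFactorRange",
              "sdSUVFactorRange", "sdVolFactorRange",
              "pdSUVFactorRange", "pdVolFactorRange")) {
    v <- slot(object, s)
    if (length(v) != 2 || any(v <= 0) || v[1] > v[2])
      msg <- c(msg, sprintf("%s must be an increasing positive pair", s))
  }
  if (max(slot(object, "responderSUVFactorRange")) > 1)
    msg <- c(msg, "responder SUV factors must be < 1")
  if (min(slot(object, "pdSUVFactorRange")) < 1)
    msg <- c(msg, "PD SUV factors must be >= 1")
  for (s in c("responderFraction", "crFraction", "pdFraction",
              "newLesionProb", "secondFollowupProb")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0,1]", s))
  }
  if (length(object@siteProbs) != 3 ||
      abs(sum(object@siteProbs) - 1) > 1e-9)
    msg <- c(msg, "siteProbs must be 3 probabilities summing to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' All arguments default to the study conditions described in
#' [PhantomSpec-class].
#'
#' @param dim,spacing grid geometry.
#' @param backgroundSUV,liverSUV background uptake levels.
#' @param lesionCountMean,lesionDiameterRangeMM,lesionSUVRange,siteProbs
#'   lesion model.
#' @param psfFWHMMM,noiseSD acquisition degradation model.
#' @param responderFraction,crFraction,pdFraction planted class structure.
#' @param responderSUVFactorRange,responderVolFactorRange,sdSUVFactorRange,sdVolFactorRange,pdSUVFactorRange,pdVolFactorRange
#'   follow-up response factors.
#' @param newLesionProb,secondFollowupProb longitudinal structure.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = c(96L, 96L, 192L), spacing = c(3, 3, 3),
                        backgroundSUV = 1.0, liverSUV = 2.0,
                        lesionCountMean = 8, lesionDiameterRangeMM = c(8, 40),
                        lesionSUVRange = c(3, 15),
                        siteProbs = c(bone = 0.5, liver = 0.2, other = 0.3),
                        psfFWHMMM = 6, noiseSD = 0.05,
                        responderFraction = 0.5, crFraction = 0.2,
                        pdFraction = 0.5,
                        responderSUVFactorRange = c(0.3, 0.6),
                        responderVolFactorRange = c(0.4, 0.8),
                        sdSUVFactorRange = c(0.95, 1.05),
                        sdVolFactorRange = c(0.95, 1.05),
                        pdSUVFactorRange = c(1.1, 1.4),
                        pdVolFactorRange = c(1.0, 1.3),
                        newLesionProb = 0.7, secondFollowupProb = 0.75) {
  new("PhantomSpec", dim = as.integer(dim), spacing = as.numeric(spacing),
      backgroundSUV = backgroundSUV, liverSUV = liverSUV,
      lesionCountMean = lesionCountMean,
      lesionDiameterRangeMM = as.numeric(lesionDiameterRangeMM),
      lesionSUVRange = as.numeric(lesionSUVRange),
      siteProbs = as.numeric(siteProbs), psfFWHMMM = psfFWHMMM,
      noiseSD = noiseSD, responderFraction = responderFraction,
      crFraction = crFraction, pdFraction = pdFraction,
      responderSUVFactorRange = as.numeric(responderSUVFactorRange),
      responderVolFactorRange = as.numeric(responderVolFactorRange),
      sdSUVFactorRange = as.numeric(sdSUVFactorRange),
      sdVolFactorRange = as.numeric(sdVolFactorRange),
      pdSUVFactorRange = as.numeric(pdSUVFactorRange),
      pdVolFactorRange = as.numeric(pdVolFactorRange),
      newLesionProb = newLesionProb,
      secondFollowupProb = secondFollowupProb)
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec  %d x %d x %d @ %.3g mm, ~%g lesions/patient, PSF %.3g mm, noise sd %.3g\n",
              object@dim[1], object@dim[2], object@dim[3],
              object@spacing[1], object@lesionCountMean, object@psfFWHMMM,
              object@noiseSD))
})

## ---- geometry helpers ----

phantomCoords <- function(spec) {
  d <- spec@dim; sp <- spec@spacing
  list(x = (seq_len(d[1]) - 1) * sp[1],
       y = (seq_len(d[2]) - 1) * sp[2],
       z = (seq_len(d[3]) - 1) * sp[3],
       extent = (d - 1) * sp)
}

ellipsoidMask <- function(spec, centerFrac, semiFrac) {
  co <- phantomCoords(spec)
  c0 <- centerFrac * co$extent
  a <- semiFrac * co$extent
  d <- spec@dim
  qx <- ((co$x - c0[1]) / a[1])^2
  qy <- ((co$y - c0[2]) / a[2])^2
  qz <- ((co$z - c0[3]) / a[3])^2
  q <- rep(qx, times = d[2] * d[3]) +
       rep(rep(qy, each = d[1]), times = d[3]) +
       rep(qz, each = d[1] * d[2])
  m <- q <= 1
  dim(m) <- d
  m
}

cylinderMaskZ <- function(spec, cxFrac, cyFrac, radiusMM, zFracRange) {
  co <- phantomCoords(spec); d <- spec@dim
  cx <- cxFrac * co$extent[1]; cy <- cyFrac * co$extent[2]
  r2 <- (rep((co$x - cx)^2, times = d[2]) +
         rep((co$y - cy)^2, each = d[1])) <= radiusMM^2
  zin <- co$z >= zFracRange[1] * co$extent[3] &
         co$z <= zFracRange[2] * co$extent[3]
  m <- rep(r2, times = d[3]) & rep(zin, each = d[1] * d[2])
  dim(m) <- d
  m
}

cylinderMaskX <- function(spec, cyFrac, czFrac, radiusMM, xFracRange) {
  co <- phantomCoords(spec); d <- spec@dim
  cy <- cyFrac * co$extent[2]; cz <- czFrac * co$extent[3]
  r2yz <- (rep((co$y - cy)^2, times = d[3]) +
           rep((co$z - cz)^2, each = d[2])) <= radiusMM^2
  xin <- co$x >= xFracRange[1] * co$extent[1] &
         co$x <= xFracRange[2] * co$extent[1]
  m <- rep(xin, times = d[2] * d[3]) & rep(r2yz, each = d[1])
  dim(m) <- d
  m
}

phantomAnatomy <- function(spec) {
  body <- ellipsoidMask(spec, centerFrac = c(0.5, 0.5, 0.5),
                        semiFrac = c(0.45, 0.42, 0.49))
  liver <- ellipsoidMask(spec, centerFrac = c(0.64, 0.46, 0.60),
                         semiFrac = c(0.17, 0.15, 0.09))
  liver <- liver & body
  # spine: posterior mid-line column; pelvis: transverse bar
  minext <- min(phantomCoords(spec)$extent[1:2])
  spine <- cylinderMaskZ(spec, 0.5, 0.66, radiusMM = 0.085 * minext,
                         zFracRange = c(0.18, 0.92))
  pelvis <- cylinderMaskX(spec, 0.58, 0.22, radiusMM = 0.07 * minext,
                          xFracRange = c(0.2, 0.8))
  bone <- (spine | pelvis) & body & !liver
  list(body = body, bone = bone, liver = liver)
}

sphereVoxels <- function(d, sp, centerMM, radiusMM) {
  rng <- function(ax) {
    lo <- max(1L, ceiling((centerMM[ax] - radiusMM) / sp[ax]) + 1L)
    hi <- min(d[ax], floor((centerMM[ax] + radiusMM) / sp[ax]) + 1L)
    if (lo > hi) integer(0) else lo:hi
  }
  ix <- rng(1); iy <- rng(2); iz <- rng(3)
  if (!length(ix) || !length(iy) || !length(iz)) return(integer(0))
  dx2 <- ((ix - 1) * sp[1] - centerMM[1])^2
  dy2 <- ((iy - 1) * sp[2] - centerMM[2])^2
  dz2 <- ((iz - 1) * sp[3] - centerMM[3])^2
  q <- rep(dx2, times = length(iy) * length(iz)) +
       rep(rep(dy2, each = length(ix)), times = length(iz)) +
       rep(dz2, each = length(ix) * length(iy))
  keep <- q <= radiusMM^2 + 1e-9
  ii <- rep(ix, times = length(iy) * length(iz))[keep]
  jj <- rep(rep(iy, each = length(ix)), times = length(iz))[keep]
  kk <- rep(iz, each = length(ix) * length(iy))[keep]
  (kk - 1L) * (d[1] * d[2]) + (jj - 1L) * d[1] + ii
}

## ---- lesion placement ----

drawLesions <- function(spec, anatomy, nLesions, maxRetries = 500L) {
  d <- spec@dim; sp <- spec@spacing
  siteNames <- c("bone", "liver", "other")
  sitePools <- list(bone = which(anatomy$bone),
                    liver = which(anatomy$liver),
                    other = which(anatomy$body & !anatomy$bone &
                                  !anatomy$liver))
  # organ lesions use a reduced diameter range so they remain
  # majority-inside their thin organ compartments
  diamRange <- list(
    bone  = c(spec@lesionDiameterRangeMM[1],
              min(spec@lesionDiameterRangeMM[2], 18)),
    liver = c(spec@lesionDiameterRangeMM[1],
              min(spec@lesionDiameterRangeMM[2], 26)),
    other = spec@lesionDiameterRangeMM)
  lesions <- list()
  for (l in seq_len(nLesions)) {
    placed <- FALSE
    for (try in seq_len(maxRetries)) {
      site <- sample(siteNames, 1, prob = spec@siteProbs)
      pool <- sitePools[[site]]
      if (!length(pool)) next
      cidx <- pool[sample.int(length(pool), 1)]
      ci <- ((cidx - 1L) %% d[1]) + 1L
      cj <- (((cidx - 1L) %/% d[1]) %% d[2]) + 1L
      ck <- ((cidx - 1L) %/% (d[1] * d[2])) + 1L
      centerMM <- c((ci - 1) * sp[1], (cj - 1) * sp[2], (ck - 1) * sp[3])
      dr <- diamRange[[site]]
      diam <- stats::runif(1, dr[1], dr[2])
      r <- diam / 2
      # margin keeps supports disconnected (26-adjacency) even after
      # PD follow-up growth (volume factor up to 1.3 ~ 9% radius growth)
      clash <- FALSE
      for (p in lesions)
        if (sqrt(sum((centerMM - p$centerMM)^2)) <
            1.1 * (r + p$radiusMM) + 2 * max(sp)) { clash <- TRUE; break }
      if (clash) next
      lesions[[length(lesions) + 1]] <- list(
        centerMM = centerMM, radiusMM = r, site = site,
        suv = stats::runif(1, spec@lesionSUVRange[1], spec@lesionSUVRange[2]))
      placed <- TRUE
      break
    }
    if (!placed && length(lesions) == 0)
      stop("infeasible lesion placement after bounded retries",
           call. = FALSE)
  }
  lesions
}

paintAcquisition <- function(spec, anatomy, lesions, suvFactor = 1,
                             volFactor = 1) {
  d <- spec@dim
  img <- array(0, dim = d)
  img[anatomy$body] <- spec@backgroundSUV
  img[anatomy$liver] <- spec@liverSUV
  gt <- array(FALSE, dim = d)
  perLesion <- list()
  for (l in lesions) {
    r <- l$radiusMM * volFactor^(1 / 3)
    amp <- max(spec@backgroundSUV, l$suv * suvFactor)
    vox <- sphereVoxels(d, spec@spacing, l$centerMM, r)
    if (!length(vox)) next
    img[vox] <- amp
    gt[vox] <- TRUE
    perLesion[[length(perLesion) + 1]] <- list(
      centerMM = l$centerMM, radiusMM = r, suv = amp, site = l$site,
      voxels = length(vox))
  }
  list(img = img, gt = gt, perLesion = perLesion)
}

degradeImage <- function(spec, img) {
  img <- gaussianSmooth3D(img, spec@spacing, spec@psfFWHMMM)
  if (spec@noiseSD > 0)
    img <- pmax(img + stats::rnorm(length(img), 0, spec@noiseSD), 0)
  dim(img) <- spec@dim
  img
}

analyticTruth <- function(spec, anatomy, painted) {
  vv <- prod(spec@spacing) / 1000
  per <- painted$perLesion
  if (!length(per))
    return(list(n_lesions = 0L, mtv_ml = 0, tlg = 0, pbi = 0, pli = 0))
  boneVox <- sum(anatomy$bone); liverVox <- sum(anatomy$liver)
  d <- spec@dim
  tagOf <- function(l) {
    vox <- sphereVoxels(d, spec@spacing, l$centerMM, l$radiusMM)
    fb <- mean(anatomy$bone[vox]); fl <- mean(anatomy$liver[vox])
    if (fb > 0.5) "bone" else if (fl > 0.5) "liver" else "other"
  }
  tags <- vapply(per, tagOf, character(1))
  nvox <- vapply(per, function(l) l$voxels, numeric(1))
  suvs <- vapply(per, function(l) l$suv, numeric(1))
  list(n_lesions = length(per),
       mtv_ml = sum(nvox) * vv,
       tlg = sum(nvox * vv * suvs),
       pbi = 100 * sum(nvox[tags == "bone"]) / boneVox,
       pli = 100 * sum(nvox[tags == "liver"]) / liverVox,
       tags = tags)
}

drawCategory <- function(spec, responder) {
  if (responder) {
    if (stats::runif(1) < spec@crFraction) "CR" else "PR"
  } else {
    if (stats::runif(1) < spec@pdFraction) "PD" else "SD"
  }
}

categoryFactors <- function(spec, category) {
  switch(category,
    CR = list(suv = 0, vol = 0),
    PR = list(suv = stats::runif(1, spec@responderSUVFactorRange[1],
                                 spec@responderSUVFactorRange[2]),
              vol = stats::runif(1, spec@responderVolFactorRange[1],
                                 spec@responderVolFactorRange[2])),
    SD = list(suv = stats::runif(1, spec@sdSUVFactorRange[1],
                                 spec@sdSUVFactorRange[2]),
              vol = stats::runif(1, spec@sdVolFactorRange[1],
                                 spec@sdVolFactorRange[2])),
    PD = list(suv = stats::runif(1, spec@pdSUVFactorRange[1],
                                 spec@pdSUVFactorRange[2]),
              vol = stats::runif(1, spec@pdVolFactorRange[1],
                                 spec@pdVolFactorRange[2])))
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Generate one synthetic patient (baseline + follow-ups) with ground truth
#'
#' Builds the stylised anatomy, places lesions, paints the baseline SUV
#' image, then derives each follow-up by rescaling lesion intensity and
#' volume with planted response factors: CR removes all lesions, PR
#' shrinks them, SD leaves them near-unchanged, PD grows them and may add
#' a new lesion. The PERCIST category is the planted category. Ground
#' truth masks are the pre-PSF lesion supports; truth biomarkers
#' (MTV/TLG/PBI/PLI) are computed from the piecewise-constant pre-noise,
#' pre-PSF model. The same seed reproduces the patient bit for bit.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer seed for this patient.
#' @param patientId identifier string.
#' @param responder planted class; NA draws it with probability
#'   `responderFraction`.
#' @return list(timeline = [PatientTimeline-class], truth = list with
#'   planted category, per-acquisition analytic biomarkers and responder
#'   flag).
#' @export
generatePatient <- function(spec, seed, patientId = "P001",
                            responder = NA) {
  stopifnot(is(spec, "PhantomSpec"))
  withSeed(seed, {
    anatomy <- phantomAnatomy(spec)
    if (is.na(responder))
      responder <- stats::runif(1) < spec@responderFraction
    category <- drawCategory(spec, responder)
    nFU <- 1L + as.integer(stats::runif(1) < spec@secondFollowupProb)
    nLes <- max(1L, stats::rpois(1, spec@lesionCountMean))
    lesions <- drawLesions(spec, anatomy, nLes)

    weight <- stats::runif(1, 55, 90)
    height <- stats::runif(1, 1.50, 1.85)
    activity <- stats::runif(1, 200, 350) * 1e6
    sp <- spec@spacing

    mkVol <- function(arr) imageVolume(arr, sp, c(0, 0, 0), "suv_bw")
    mkMask <- function(arr) binaryMask(arr, sp, c(0, 0, 0))

    blPaint <- paintAcquisition(spec, anatomy, lesions)
    blMeta <- acquisitionMeta(patientId, "BL", activity, weight, height,
                              "female")
    baseline <- list(volume = mkVol(degradeImage(spec, blPaint$img)),
                     mask = mkMask(blPaint$gt), meta = blMeta)
    truthAcq <- list(BL = analyticTruth(spec, anatomy, blPaint))

    followups <- vector("list", nFU)
    for (f in seq_len(nFU)) {
      fac <- categoryFactors(spec, category)
      fuLesions <- lesions
      if (category == "CR") fuLesions <- list()
      if (category == "PD" && stats::runif(1) < spec@newLesionProb) {
        extra <- drawLesionsExtra(spec, anatomy, fuLesions)
        if (!is.null(extra)) fuLesions <- c(fuLesions, list(extra))
      }
      fuPaint <- paintAcquisition(spec, anatomy, fuLesions,
                                  suvFactor = if (category == "CR") 1
                                              else fac$suv,
                                  volFactor = if (category == "CR") 1
                                              else fac$vol)
      tp <- sprintf("FU%d", f)
      fuMeta <- acquisitionMeta(patientId, tp, activity, weight, height,
                                "female", percist = category)
      followups[[f]] <- list(volume = mkVol(degradeImage(spec, fuPaint$img)),
                             mask = mkMask(fuPaint$gt), meta = fuMeta)
      truthAcq[[tp]] <- analyticTruth(spec, anatomy, fuPaint)
    }

    timeline <- new("PatientTimeline", baseline = baseline,
                    followups = followups,
                    organMasks = list(bone = mkMask(anatomy$bone),
                                      liver = mkMask(anatomy$liver)))
    list(timeline = timeline,
         truth = list(patient_id = patientId, responder = responder,
                      category = category, acquisitions = truthAcq,
                      lesions = lesions, seed = seed))
  })
}

drawLesionsExtra <- function(spec, anatomy, existing, maxRetries = 200L) {
  d <- spec@dim; sp <- spec@spacing
  pool <- which(anatomy$body)
  for (try in seq_len(maxRetries)) {
    cidx <- pool[sample.int(length(pool), 1)]
    ci <- ((cidx - 1L) %% d[1]) + 1L
    cj <- (((cidx - 1L) %/% d[1]) %% d[2]) + 1L
    ck <- ((cidx - 1L) %/% (d[1] * d[2])) + 1L
    centerMM <- c((ci - 1) * sp[1], (cj - 1) * sp[2], (ck - 1) * sp[3])
    diam <- stats::runif(1, spec@lesionDiameterRangeMM[1],
                         min(spec@lesionDiameterRangeMM[2], 20))
    r <- diam / 2
    ok <- TRUE
    for (p in existing)
      if (sqrt(sum((centerMM - p$centerMM)^2)) <
          1.1 * (r + p$radiusMM) + 2 * max(sp)) {
        ok <- FALSE; break
      }
    if (ok)
      return(list(centerMM = centerMM, radiusMM = r, site = "other",
                  suv = stats::runif(1, spec@lesionSUVRange[1],
                                     spec@lesionSUVRange[2])))
  }
  NULL
}

patientSeed <- function(masterSeed, i) {
  as.integer((as.numeric(masterSeed) * 1000003 + i * 7919) %% 2147483629)
}

#' Deterministic cohort plan (per-patient seeds and planted classes)
#'
#' Class assignment is deterministic: the first
#' `round(n * responderFraction)` patients are responders, so a cohort of
#' 60 at fraction 0.5 always contains exactly 30 planted responders.
#' Per-patient seeds are derived arithmetically from the master seed.
#'
#' @param spec a [PhantomSpec-class].
#' @param nPatients cohort size (>= 2; both classes must be present).
#' @param seed master seed.
#' @return data.frame(patient_id, seed, responder).
#' @export
cohortPlan <- function(spec, nPatients, seed) {
  if (nPatients < 2) stop("need at least 2 patients", call. = FALSE)
  nResp <- round(nPatients * spec@responderFraction)
  if (nResp == 0 || nResp == nPatients)
    stop("cohort must contain both responders and non-responders",
         call. = FALSE)
  data.frame(patient_id = sprintf("P%03d", seq_len(nPatients)),
             seed = vapply(seq_len(nPatients), patientSeed,
                           integer(1), masterSeed = seed),
             responder = seq_len(nPatients) <= nResp)
}

#' Generate a synthetic cohort
#'
#' Runs [generatePatient()] for every row of the [cohortPlan()]. With
#' `outDir`, writes a NIfTI tree (one directory per patient: PET, lesion
#' mask and organ masks per acquisition), a cohort `manifest.csv` and a
#' `truth.csv` table, holding only one patient in memory at a time; the
#' in-memory form (default) returns all timelines.
#'
#' @param spec a [PhantomSpec-class].
#' @param nPatients cohort size.
#' @param seed master seed.
#' @param outDir optional output directory.
#' @return With `outDir`: list(manifest, truth) data.frames (files
#'   written). Otherwise list(patients = list of [generatePatient()]
#'   results, plan, truth).
#' @export
generateCohort <- function(spec, nPatients, seed, outDir = NULL) {
  plan <- cohortPlan(spec, nPatients, seed)
  truthRows <- list()
  manifestRows <- list()
  patients <- if (is.null(outDir)) vector("list", nPatients) else NULL
  if (!is.null(outDir))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nPatients)) {
    pt <- generatePatient(spec, plan$seed[i], plan$patient_id[i],
                          responder = plan$responder[i])
    for (tp in names(pt$truth$acquisitions)) {
      t <- pt$truth$acquisitions[[tp]]
      truthRows[[length(truthRows) + 1]] <- data.frame(
        patient_id = plan$patient_id[i], timepoint = tp,
        responder = pt$truth$responder, category = pt$truth$category,
        n_lesions = t$n_lesions, mtv_ml = t$mtv_ml, tlg = t$tlg,
        pbi = t$pbi, pli = t$pli)
    }
    if (is.null(outDir)) {
      patients[[i]] <- pt
    } else {
      pdir <- file.path(outDir, plan$patient_id[i])
      dir.create(pdir, showWarnings = FALSE)
      tl <- pt$timeline
      writeVolume(tl@organMasks$bone, file.path(pdir, "bone.nii.gz"))
      writeVolume(tl@organMasks$liver, file.path(pdir, "liver.nii.gz"))
      acqs <- c(list(tl@baseline), tl@followups)
      for (a in acqs) {
        tp <- a$meta@timepoint
        petP <- file.path(pdir, sprintf("pet_%s.nii.gz", tp))
        mskP <- file.path(pdir, sprintf("mask_%s.nii.gz", tp))
        writeVolume(a$volume, petP)
        writeVolume(a$mask, mskP)
        manifestRows[[length(manifestRows) + 1]] <- data.frame(
          patient_id = plan$patient_id[i], timepoint = tp,
          pet_path = file.path(plan$patient_id[i],
                               sprintf("pet_%s.nii.gz", tp)),
          mask_path = file.path(plan$patient_id[i],
                                sprintf("mask_%s.nii.gz", tp)),
          bone_path = file.path(plan$patient_id[i], "bone.nii.gz"),
          liver_path = file.path(plan$patient_id[i], "liver.nii.gz"),
          value_kind = "suv_bw",
          injected_activity_MBq = a$meta@injectedActivity / 1e6,
          weight_kg = a$meta@weight, height_m = a$meta@height,
          sex = a$meta@sex,
          percist = ifelse(is.na(a$meta@percist), "", a$meta@percist))
      }
    }
  }
  truth <- do.call(rbind, truthRows)
  if (is.null(outDir)) {
    list(patients = patients, plan = plan, truth = truth)
  } else {
    manifest <- do.call(rbind, manifestRows)
    writeReport(manifest, file.path(outDir, "manifest.csv"))
    writeReport(truth, file.path(outDir, "truth.csv"))
    list(manifest = manifest, truth = truth)
  }
}

#' Simulate an imperfect automatic segmentation from a ground-truth mask
#'
#' Stand-in for a trained segmentation network's output, used to exercise
#' the evaluation and concordance stages on synthetic data: per lesion
#' component the contour is randomly eroded or dilated by one voxel layer,
#' small components are dropped with a probability that rises as
#' components shrink (mimicking missed low-contrast lesions), and a few
#' spurious components are added inside the body.
#'
#' @param mask ground-truth [BinaryMask-class].
#' @param body [BinaryMask-class] region in which spurious components may
#'   appear.
#' @param seed integer seed.
#' @param pErode,pDilate probabilities of the one-layer contour
#'   perturbation per lesion.
#' @param pDropSmall drop probability for components below
#'   `smallVoxels` voxels.
#' @param smallVoxels size threshold defining a small component.
#' @param meanFP Poisson mean number of spurious components.
#' @param fpRadiusRangeMM radius range of spurious spheres, mm.
#' @param connectivity component connectivity.
#' @return A [BinaryMask-class].
#' @export
perturbMask <- function(mask, body, seed, pErode = 0.35, pDilate = 0.35,
                        pDropSmall = 0.5, smallVoxels = 30,
                        meanFP = 0.8, fpRadiusRangeMM = c(4, 8),
                        connectivity = 26L) {
  stopifnot(is(mask, "BinaryMask"), is(body, "BinaryMask"))
  withSeed(seed, {
    d <- gridDim(mask)
    sp <- spacing(mask)
    lm <- labelLesions(mask, connectivity)
    out <- array(FALSE, dim = d)
    K <- nLesions(lm)
    for (k in seq_len(K)) {
      comp <- lm@labels == k
      n <- sum(comp)
      if (n <= smallVoxels && stats::runif(1) < pDropSmall) next
      u <- stats::runif(1)
      if (u < pErode) comp <- binaryErode3D(comp, 1L)
      else if (u < pErode + pDilate) comp <- binaryDilate3D(comp, 1L)
      out <- out | comp
    }
    nFP <- stats::rpois(1, meanFP)
    if (nFP > 0) {
      pool <- which(body@values & !mask@values)
      for (f in seq_len(nFP)) {
        if (!length(pool)) break
        cidx <- pool[sample.int(length(pool), 1)]
        ci <- ((cidx - 1L) %% d[1]) + 1L
        cj <- (((cidx - 1L) %/% d[1]) %% d[2]) + 1L
        ck <- ((cidx - 1L) %/% (d[1] * d[2])) + 1L
        centerMM <- c((ci - 1) * sp[1], (cj - 1) * sp[2], (ck - 1) * sp[3])
        r <- stats::runif(1, fpRadiusRangeMM[1], fpRadiusRangeMM[2])
        out[sphereVoxels(d, sp, centerMM, r)] <- TRUE
      }
    }
    binaryMask(out, sp, worldOrigin(mask))
  })
}
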