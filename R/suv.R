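#' @include AllClasses.R
NULL

#' Janmahasatian lean body mass
#'
#' Sex-specific lean body mass from weight and height:
#' \deqn{LBM_{female} = 9270 W / (8780 + 244\,BMI)}
#' \deqn{LBM_{male}   = 9270 W / (6680 + 216\,BMI)}
#' with \eqn{BMI = W / H^2}. This is the normalisation mass behind SUL,
#' the PERCIST uptake quantity.
#'
#' @param weight body weight, kg (> 0).
#' @param height body height, m (> 0).
#' @param sex "female" or "male".
#' @return Lean body mass, kg.
#' @examples
#' leanBodyMass(70, 1.70, "female")  # 44.17 kg
#' @export
leanBodyMass <- function(weight, height, sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (!is.finite(weight) || weight <= 0 || !is.finite(height) || height <= 0)
    stop("weight and height must be positive", call. = FALSE)
  bmi <- weight / height^2
  if (sex == "female") 9270 * weight / (8780 + 244 * bmi)
  else                 9270 * weight / (6680 + 216 * bmi)
}

#' Convert a PET activity volume to SUV (body weight)
#'
#' Voxelwise \eqn{SUV_{BW} = C \cdot W_g / A} with C the activity
#' concentration in Bq/mL, \eqn{W_g} the body weight in grams and A the
#' injected activity in Bq (decay-corrected to scan start).
#'
#' @param pet [ImageVolume-class] with `valueKind == "activity_Bq_per_mL"`.
#' @param meta [AcquisitionMeta-class].
#' @return An [ImageVolume-class] with `valueKind == "suv_bw"`.
#' @export
toSUVbw <- function(pet, meta) {
  stopifnot(is(pet, "ImageVolume"), is(meta, "AcquisitionMeta"))
  if (valueKind(pet) != "activity_Bq_per_mL")
    stop(sprintf("toSUVbw expects activity_Bq_per_mL input, got %s",
                 valueKind(pet)), call. = FALSE)
  f <- meta@weight * 1000 / meta@injectedActivity
  imageVolume(pet@values * f, spacing(pet), worldOrigin(pet), "suv_bw")
}

#' Convert a PET activity volume to SUL (lean body mass)
#'
#' As [toSUVbw()] but normalised by the Janmahasatian lean body mass:
#' \eqn{SUL = C \cdot LBM_g / A}. SUL relates to SUV by the spatially
#' constant factor LBM/W.
#'
#' @inheritParams toSUVbw
#' @return An [ImageVolume-class] with `valueKind == "sul"`.
#' @export
toSUL <- function(pet, meta) {
  stopifnot(is(pet, "ImageVolume"), is(meta, "AcquisitionMeta"))
  if (valueKind(pet) != "activity_Bq_per_mL")
    stop(sprintf("toSUL expects activity_Bq_per_mL input, got %s",
                 valueKind(pet)), call. = FALSE)
  lbm <- leanBodyMass(meta@weight, meta@height, meta@sex)
  f <- lbm * 1000 / meta@injectedActivity
  imageVolume(pet@values * f, spacing(pet), worldOrigin(pet), "sul")
}

#' Rescale an SUV (body-weight) volume to SUL
#'
#' Uses the identity SUL = SUV_BW * LBM / W, for inputs already stored in
#' SUV units.
#'
#' @param suv [ImageVolume-class] with `valueKind == "suv_bw"`.
#' @param meta [AcquisitionMeta-class].
#' @return An [ImageVolume-class] with `valueKind == "sul"`.
#' @export
suvToSul <- function(suv, meta) {
  stopifnot(is(suv, "ImageVolume"), is(meta, "AcquisitionMeta"))
  if (valueKind(suv) != "suv_bw")
    stop(sprintf("suvToSul expects suv_bw input, got %s", valueKind(suv)),
         call. = FALSE)
  f <- leanBodyMass(meta@weight, meta@height, meta@sex) / meta@weight
  imageVolume(suv@values * f, spacing(suv), worldOrigin(suv), "sul")
}

#' Clip an SUV/SUL volume to a fixed range
#'
#' Emulates the network input preprocessing in which SUV is limited to
#' \[0, 5\] (an SUV of 2.5 being a common malignancy threshold, the window
#' keeps lesion contrast while discarding extreme uptake). This is a
#' preprocessing step only: biomarkers are always computed from unclipped
#' volumes, since clipping at 5 would corrupt SULpeak and TLG of hot
#' lesions.
#'
#' @param v [ImageVolume-class] with `valueKind` "suv_bw" or "sul".
#' @param lo,hi clip bounds, `lo < hi`.
#' @return A clipped [ImageVolume-class], same `valueKind`.
#' @export
clipSUV <- function(v, lo = 0, hi = 5) {
  stopifnot(is(v, "ImageVolume"))
  if (!valueKind(v) %in% c("suv_bw", "sul"))
    stop("clipSUV expects an SUV or SUL volume", call. = FALSE)
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  imageVolume(pmin(pmax(v@values, lo), hi), spacing(v), worldOrigin(v),
              valueKind(v))
}
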