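#' Voxel spacing in millimetres
#'
#' @param x a [VoxelGrid-class] derivative.
#' @return Numeric vector of length 3, mm per voxel along (x, y, z).
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' World-space origin of the voxel (1,1,1) centre, in millimetres
#'
#' @param x a [VoxelGrid-class] derivative.
#' @return Numeric vector of length 3.
#' @export
setGeneric("worldOrigin", function(x) standardGeneric("worldOrigin"))

#' Grid dimensions
#'
#' @param x a [VoxelGrid-class] derivative.
#' @return Integer vector of length 3.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Voxel volume in millilitres
#'
#' @param x a [VoxelGrid-class] derivative.
#' @return Scalar, \code{prod(spacing(x)) / 1000} mL.
#' @export
setGeneric("voxelVolumeML", function(x) standardGeneric("voxelVolumeML"))

#' Voxel data array
#'
#' @param x a [VoxelGrid-class] derivative.
#' @return The underlying 3D array (numeric for volumes, logical for masks,
#'   integer for label maps).
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Declared value semantics of a volume
#'
#' @param x an [ImageVolume-class].
#' @return One of \code{"activity_Bq_per_mL"}, \code{"suv_bw"}, \code{"sul"},
#'   \code{"hounsfield"}, \code{"probability"}.
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' Number of labelled lesions
#'
#' @param x a [LesionLabelMap-class].
#' @return Integer count of connected lesion components.
#' @export
setGeneric("nLesions", function(x) standardGeneric("nLesions"))
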