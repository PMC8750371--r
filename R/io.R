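#' @include AllClasses.R
NULL

niftiGeometry <- function(img) {
  pd <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  # world position of voxel (1,1,1): xform maps 0-based indices
  org <- as.numeric(xf[1:3, 4])
  list(spacing = abs(as.numeric(pd)), origin = org)
}

#' Read a 3D NIfTI volume
#'
#' Loads a NIfTI-1 file (.nii or .nii.gz) into an [ImageVolume-class].
#' The value kind is never inferred from the file and must be declared by
#' the caller (normally from the cohort manifest).
#'
#' @param path path to a NIfTI-1 file.
#' @param valueKind declared value semantics of the stored voxels.
#' @return An [ImageVolume-class] with spacing in mm.
#' @export
readVolume <- function(path, valueKind) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3)
    stop(sprintf("expected 3D volume, got %dD image in %s", length(d), path),
         call. = FALSE)
  vals <- as.array(img)
  attributes(vals) <- list(dim = d)
  nbad <- sum(!is.finite(vals))
  if (nbad > 0)
    stop(sprintf("%d non-finite voxel(s) in %s", nbad, path), call. = FALSE)
  g <- niftiGeometry(img)
  imageVolume(vals, spacing = g$spacing, origin = g$origin,
              valueKind = valueKind)
}

#' Read a binary mask from NIfTI
#'
#' Any non-zero voxel is foreground. The mask inherits the file's lattice.
#'
#' @param path path to a NIfTI-1 file.
#' @return A [BinaryMask-class].
#' @export
readMask <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3)
    stop(sprintf("expected 3D mask, got %dD image in %s", length(d), path),
         call. = FALSE)
  vals <- as.array(img)
  attributes(vals) <- list(dim = d)
  if (anyNA(vals))
    stop(sprintf("%d NA voxel(s) in mask %s", sum(is.na(vals)), path),
         call. = FALSE)
  g <- niftiGeometry(img)
  binaryMask(vals != 0, spacing = g$spacing, origin = g$origin)
}

asNiftiWithGeometry <- function(values, spacing, origin) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing
  m <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(m, code = 2L)
  img
}

#' Write a volume or mask to NIfTI
#'
#' Volumes are stored as float64 (bit-exact round trip), masks as uint8
#' with values in \{0, 1\}.
#'
#' @param x an [ImageVolume-class] or [BinaryMask-class].
#' @param path destination .nii or .nii.gz path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  if (is(x, "BinaryMask")) {
    v <- x@values * 1L
    dim(v) <- dim(x@values)
    img <- asNiftiWithGeometry(v, spacing(x), worldOrigin(x))
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else if (is(x, "ImageVolume")) {
    img <- asNiftiWithGeometry(x@values, spacing(x), worldOrigin(x))
    RNifti::writeNifti(img, path, datatype = "double")
  } else stop("writeVolume expects an ImageVolume or BinaryMask")
  invisible(path)
}

#' Write tabular records as CSV (optionally mirrored to JSON)
#'
#' Writes a header even for zero rows; numeric columns keep full double
#' precision.
#'
#' @param rows data.frame of homogeneous records.
#' @param path destination .csv path.
#' @param json optional path for a JSON mirror of the same records.
#' @return `path`, invisibly.
#' @export
writeReport <- function(rows, path, json = NULL) {
  stopifnot(is.data.frame(rows))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  fmt <- rows
  for (j in seq_along(fmt))
    if (is.double(fmt[[j]]))
      fmt[[j]] <- vapply(fmt[[j]], function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 17L),
        character(1))
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(json))
    jsonlite::write_json(rows, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  invisible(path)
}

#' Read a report CSV written by [writeReport()]
#'
#' @param path .csv path.
#' @return data.frame.
#' @export
readReport <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

MANIFEST_COLUMNS <- c("patient_id", "timepoint", "pet_path", "mask_path",
                      "value_kind", "injected_activity_MBq", "weight_kg",
                      "height_m", "sex", "percist")

#' Read a cohort manifest
#'
#' The manifest is one CSV row per acquisition with columns
#' `patient_id, timepoint, pet_path, mask_path, value_kind,
#' injected_activity_MBq, weight_kg, height_m, sex, percist`
#' (plus optional `bone_path`, `liver_path` on the baseline row).
#' Relative file paths are resolved against the manifest's directory.
#'
#' @param path manifest .csv path.
#' @return data.frame with resolved absolute paths.
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MANIFEST_COLUMNS, names(m))
  if (length(missing))
    stop(sprintf("manifest is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  root <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(is.na(p) | p == "" | grepl("^/", p),
                                p, file.path(root, p))
  for (col in intersect(c("pet_path", "mask_path", "bone_path", "liver_path"),
                        names(m)))
    m[[col]] <- resolve(m[[col]])
  m
}

manifestMeta <- function(row) {
  acquisitionMeta(patientId = row$patient_id, timepoint = row$timepoint,
                  injectedActivity = row$injected_activity_MBq * 1e6,
                  weight = row$weight_kg, height = row$height_m,
                  sex = row$sex,
                  percist = if (is.null(row$percist) || is.na(row$percist) ||
                                row$percist == "") NA_character_
                            else row$percist)
}
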