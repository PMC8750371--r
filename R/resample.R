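#' @include AllClasses.R
NULL

#' Resample a volume onto the lattice of a reference volume
#'
#' Trilinear interpolation in world coordinates, used to bring CT onto the
#' PET grid. Target voxel centres falling outside the moving volume's field
#' of view receive `fill` (default: the minimum of the moving volume, i.e.
#' air for CT).
#'
#' @param moving [ImageVolume-class] to resample.
#' @param reference [ImageVolume-class] whose lattice defines the output.
#' @param fill value for out-of-field voxels.
#' @return An [ImageVolume-class] on the reference lattice, with the
#'   moving volume's `valueKind`.
#' @export
resampleToGrid <- function(moving, reference,
                           fill = min(voxelData(moving))) {
  stopifnot(is(moving, "ImageVolume"), is(reference, "ImageVolume"))
  dref <- gridDim(reference)
  if (any(dref < 1) || prod(dref) == 0)
    stop("degenerate reference lattice", call. = FALSE)
  if (sameLattice(moving, reference))
    return(imageVolume(moving@values, spacing(reference),
                       worldOrigin(reference), valueKind(moving)))

  dmov <- gridDim(moving)
  sp <- spacing(moving); om <- worldOrigin(moving)
  # world coords of every reference voxel centre -> continuous moving index
  ax <- (worldOrigin(reference)[1] + (seq_len(dref[1]) - 1) *
           spacing(reference)[1] - om[1]) / sp[1] + 1
  ay <- (worldOrigin(reference)[2] + (seq_len(dref[2]) - 1) *
           spacing(reference)[2] - om[2]) / sp[2] + 1
  az <- (worldOrigin(reference)[3] + (seq_len(dref[3]) - 1) *
           spacing(reference)[3] - om[3]) / sp[3] + 1

  gx <- rep(ax, times = dref[2] * dref[3])
  gy <- rep(rep(ay, each = dref[1]), times = dref[3])
  gz <- rep(az, each = dref[1] * dref[2])

  inside <- gx >= 1 & gx <= dmov[1] & gy >= 1 & gy <= dmov[2] &
            gz >= 1 & gz <= dmov[3]
  out <- rep(as.numeric(fill), prod(dref))

  if (any(inside)) {
    gx <- gx[inside]; gy <- gy[inside]; gz <- gz[inside]
    x0 <- pmin(floor(gx), dmov[1] - 1); x0 <- pmax(x0, 1)
    y0 <- pmin(floor(gy), dmov[2] - 1); y0 <- pmax(y0, 1)
    z0 <- pmin(floor(gz), dmov[3] - 1); z0 <- pmax(z0, 1)
    fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
    if (dmov[1] == 1) { x0 <- rep(1, length(gx)); fx <- 0 }
    if (dmov[2] == 1) { y0 <- rep(1, length(gy)); fy <- 0 }
    if (dmov[3] == 1) { z0 <- rep(1, length(gz)); fz <- 0 }
    v <- moving@values
    idx <- function(i, j, k) (k - 1) * dmov[1] * dmov[2] + (j - 1) * dmov[1] + i
    x1 <- pmin(x0 + 1, dmov[1]); y1 <- pmin(y0 + 1, dmov[2])
    z1 <- pmin(z0 + 1, dmov[3])
    val <-
      v[idx(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
      v[idx(x1, y0, z0)] * fx       * (1 - fy) * (1 - fz) +
      v[idx(x0, y1, z0)] * (1 - fx) * fy       * (1 - fz) +
      v[idx(x1, y1, z0)] * fx       * fy       * (1 - fz) +
      v[idx(x0, y0, z1)] * (1 - fx) * (1 - fy) * fz +
      v[idx(x1, y0, z1)] * fx       * (1 - fy) * fz +
      v[idx(x0, y1, z1)] * (1 - fx) * fy       * fz +
      v[idx(x1, y1, z1)] * fx       * fy       * fz
    out[inside] <- val
  }
  dim(out) <- dref
  imageVolume(out, spacing(reference), worldOrigin(reference),
              valueKind(moving))
}
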