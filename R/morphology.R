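#' @include AllClasses.R
NULL

convolveAlong <- function(m, w) {
  r <- (length(w) - 1L) %/% 2L
  d <- nrow(m)
  out <- matrix(0, d, ncol(m))
  for (t in -r:r) {
    src <- (1 + max(0, t)):(d + min(0, t))
    dst <- (1 - min(0, t)):(d - max(0, t))
    out[dst, ] <- out[dst, ] + w[t + r + 1] * m[src, , drop = FALSE]
  }
  out
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Models the scanner point spread function as an isotropic (in world mm)
#' Gaussian applied axis by axis, with the kernel truncated at 3 sigma and
#' renormalised. Zero padding at the image border (whole-body phantoms
#' keep the body away from the border, so edge effects are negligible).
#'
#' @param arr 3D numeric array.
#' @param spacing numeric(3), mm per voxel.
#' @param fwhmMM full width at half maximum of the PSF, mm; 0 is a no-op.
#' @return smoothed array of the same dimensions.
#' @export
gaussianSmooth3D <- function(arr, spacing, fwhmMM) {
  if (fwhmMM <= 0) return(arr)
  d <- dim(arr)
  sigmaVox <- fwhmMM / (2 * sqrt(2 * log(2))) / spacing
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    r <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(-r:r, sd = s)
    w <- w / sum(w)
    perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    a <- aperm(arr, perm)
    da <- dim(a)
    dim(a) <- c(da[1], da[2] * da[3])
    a <- convolveAlong(a, w)
    dim(a) <- da
    arr <- aperm(a, order(perm))
  }
  arr
}

shiftLogical <- function(m, t) {
  d <- nrow(m)
  out <- matrix(FALSE, d, ncol(m))
  src <- (1 + max(0, t)):(d + min(0, t))
  dst <- (1 - min(0, t)):(d - max(0, t))
  out[dst, ] <- m[src, , drop = FALSE]
  out
}

morphStep <- function(arr, dilate) {
  d <- dim(arr)
  for (ax in 1:3) {
    perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    a <- aperm(arr, perm)
    da <- dim(a)
    dim(a) <- c(da[1], da[2] * da[3])
    if (dilate) a <- a | shiftLogical(a, 1L) | shiftLogical(a, -1L)
    else        a <- a & shiftLogical(a, 1L) & shiftLogical(a, -1L)
    dim(a) <- da
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Binary dilation / erosion with the 6-connected structuring element
#'
#' Used by the segmentation-degradation model (simulated automatic
#' contours) to thicken or thin lesion components voxel layer by voxel
#' layer.
#'
#' @param arr 3D logical array.
#' @param steps number of one-voxel morphology steps.
#' @return 3D logical array.
#' @export
binaryDilate3D <- function(arr, steps = 1L) {
  for (s in seq_len(steps)) arr <- morphStep(arr, TRUE)
  arr
}

#' @rdname binaryDilate3D
#' @export
binaryErode3D <- function(arr, steps = 1L) {
  for (s in seq_len(steps)) arr <- morphStep(arr, FALSE)
  arr
}
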