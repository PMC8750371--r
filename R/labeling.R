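#' @include AllClasses.R
NULL

connectivityOffsets <- function(connectivity) {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  ord <- abs(g$di) + abs(g$dj) + abs(g$dk)
  keep <- switch(as.character(connectivity),
                 "6" = ord <= 1, "18" = ord <= 2, "26" = ord <= 3,
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  as.matrix(g[keep, , drop = FALSE])
}

#' Label connected lesion components in a binary mask
#'
#' Flood-fill connected-component labeling under 6-, 18- or 26-connectivity
#' (26 by default: diagonal voxel chains that an expert would outline as one
#' lesion merge into one component). Labels are deterministic: components
#' are numbered by their first voxel in storage scan order (x fastest, z
#' slowest). An empty mask yields K = 0.
#'
#' @param mask [BinaryMask-class].
#' @param connectivity 6, 18 or 26.
#' @return A [LesionLabelMap-class].
#' @export
labelLesions <- function(mask, connectivity = 26L) {
  stopifnot(is(mask, "BinaryMask"))
  connectivity <- as.integer(connectivity)
  d <- gridDim(mask)
  labels <- array(0L, dim = d)
  idx <- which(mask@values)
  if (length(idx) > 0) {
    off <- connectivityOffsets(connectivity)
    noff <- nrow(off)
    lookup <- integer(prod(d))
    lookup[idx] <- seq_along(idx)
    i0 <- ((idx - 1L) %% d[1]) + 1L
    j0 <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
    k0 <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
    lab <- integer(length(idx))
    K <- 0L
    for (s in seq_along(idx)) {
      if (lab[s] != 0L) next
      K <- K + 1L
      lab[s] <- K
      frontier <- s
      while (length(frontier) > 0) {
        fi <- rep(i0[frontier], each = noff) + off[, 1]
        fj <- rep(j0[frontier], each = noff) + off[, 2]
        fk <- rep(k0[frontier], each = noff) + off[, 3]
        ok <- fi >= 1L & fi <= d[1] & fj >= 1L & fj <= d[2] &
              fk >= 1L & fk <= d[3]
        nidx <- (fk[ok] - 1L) * (d[1] * d[2]) + (fj[ok] - 1L) * d[1] + fi[ok]
        p <- lookup[nidx]
        p <- unique(p[p > 0L])
        p <- p[lab[p] == 0L]
        lab[p] <- K
        frontier <- p
      }
    }
    labels[idx] <- lab
  }
  new("LesionLabelMap", labels = labels, connectivity = connectivity,
      spacing = spacing(mask), origin = worldOrigin(mask))
}
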