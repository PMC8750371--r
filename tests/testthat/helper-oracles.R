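# Independent brute-force oracles and small fixture builders.
# These deliberately use different algorithms from the package
# implementations (triple loops, label relaxation) so that agreement is
# meaningful.

mkVol <- function(arr, sp = c(1, 1, 1), origin = c(0, 0, 0),
                  kind = "sul") {
  imageVolume(arr, spacing = sp, origin = origin, valueKind = kind)
}

mkMask <- function(arr, sp = c(1, 1, 1), origin = c(0, 0, 0)) {
  binaryMask(arr, spacing = sp, origin = origin)
}

# exhaustive sphere-mean search: for every mask voxel, loop over every
# voxel of the volume and collect those within the world radius
bruteSulPeak <- function(vol, mask, diameterMM = 12) {
  arr <- voxelData(vol); m <- voxelData(mask)
  sp <- spacing(vol); d <- dim(arr)
  r <- diameterMM / 2
  coords <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                  k = seq_len(d[3])))
  world <- sweep(coords - 1, 2, sp, `*`)
  centers <- which(m)
  if (!length(centers)) return(list(value = NA_real_, center = NA))
  best <- -Inf; bestCenter <- NULL
  for (c0 in centers) {
    w0 <- world[c0, ]
    d2 <- (world[, 1] - w0[1])^2 + (world[, 2] - w0[2])^2 +
          (world[, 3] - w0[3])^2
    inSphere <- d2 <= r^2 + 1e-9
    mu <- mean(arr[inSphere])
    if (mu > best + 1e-15) { best <- mu; bestCenter <- coords[c0, ] }
  }
  list(value = best, center = as.integer(bestCenter))
}

# connected components by iterative minimum-label relaxation
bruteComponents <- function(m, connectivity) {
  d <- dim(m)
  ids <- array(0L, d)
  ids[m] <- seq_len(sum(m))
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  ord <- abs(offs$di) + abs(offs$dj) + abs(offs$dk)
  offs <- offs[ord <= c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)], ]
  repeat {
    changed <- FALSE
    for (v in which(m)) {
      i <- ((v - 1) %% d[1]) + 1
      j <- (((v - 1) %/% d[1]) %% d[2]) + 1
      k <- ((v - 1) %/% (d[1] * d[2])) + 1
      for (o in seq_len(nrow(offs))) {
        ni <- i + offs$di[o]; nj <- j + offs$dj[o]; nk <- k + offs$dk[o]
        if (ni < 1 || ni > d[1] || nj < 1 || nj > d[2] ||
            nk < 1 || nk > d[3]) next
        if (m[ni, nj, nk] && ids[ni, nj, nk] < ids[i, j, k]) {
          ids[i, j, k] <- ids[ni, nj, nk]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  ids
}

# partition-equality check between two labelings (labels may differ)
samePartition <- function(a, b) {
  fa <- as.vector(a); fb <- as.vector(b)
  if (!identical(fa > 0, fb > 0)) return(FALSE)
  fg <- fa > 0
  length(unique(paste(fa[fg], fb[fg]))) ==
    length(unique(fa[fg])) &&
  length(unique(fa[fg])) == length(unique(fb[fg]))
}

# per-component detection oracle using bruteComponents
bruteDetection <- function(gt, pred, threshold = 0.5, connectivity = 26) {
  gl <- bruteComponents(gt, connectivity)
  pl <- bruteComponents(pred, connectivity)
  tp <- 0L; fn <- 0L; fp <- 0L
  for (lab in setdiff(unique(as.vector(gl)), 0L)) {
    comp <- gl == lab
    if (sum(comp & pred) / sum(comp) >= threshold) tp <- tp + 1L
    else fn <- fn + 1L
  }
  for (lab in setdiff(unique(as.vector(pl)), 0L)) {
    comp <- pl == lab
    if (sum(comp & gt) / sum(comp) < threshold) fp <- fp + 1L
  }
  list(tp = tp, fn = fn, fp = fp)
}

# Mann-Whitney pair-counting AUC estimate (responder scores should be
# smaller, i.e. concordant pair when delta_resp < delta_nonresp)
pairCountAUC <- function(deltas, responder) {
  r <- deltas[responder]; n <- deltas[!responder]
  tot <- 0
  for (a in r) for (b in n)
    tot <- tot + (a < b) + 0.5 * (a == b)
  tot / (length(r) * length(n))
}

randomMask <- function(d, pForeground = 0.1) {
  m <- array(runif(prod(d)) < pForeground, dim = d)
  m
}

# small cuboid helper: set a box of a 3D array to TRUE
setBox <- function(arr, xr, yr, zr, value = TRUE) {
  arr[xr, yr, zr] <- value
  arr
}
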