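test_that("SULpeak of a constant volume is that constant", {
  v <- mkVol(array(2, c(12, 12, 12)), sp = c(2, 2, 2))
  m <- mkMask(setBox(array(FALSE, c(12, 12, 12)), 5:7, 5:7, 5:7),
              sp = c(2, 2, 2))
  p <- sulPeak(v, m)
  expect_equal(p$value, 2)
})

test_that("2 mm single hot voxel: 123-voxel sphere, peak 132/123", {
  d <- c(15, 15, 15)
  arr <- array(1, d); arr[8, 8, 8] <- 10
  m <- array(FALSE, d); m[8, 8, 8] <- TRUE
  p <- sulPeak(mkVol(arr, sp = c(2, 2, 2)), mkMask(m, sp = c(2, 2, 2)))
  expect_equal(p$nSphereVoxels, 123L)
  expect_equal(p$value, 132 / 123)
  expect_equal(p$center, c(8L, 8L, 8L))
})

test_that("the retained VOI need not be centred on the hottest voxel", {
  # hottest segmented voxel sits alone; a cooler segmented voxel next to
  # an unsegmented hot cluster wins the sphere-mean search
  d <- c(20, 20, 7)
  arr <- array(0, d)
  arr[3, 3, 4] <- 10                       # hottest, isolated
  arr[14:16, 14:16, 3:5] <- 8              # cluster, outside the mask
  m <- array(FALSE, d)
  m[3, 3, 4] <- TRUE
  m[13, 15, 4] <- TRUE                     # adjacent to the cluster
  sul <- mkVol(arr, sp = c(2, 2, 2)); msk <- mkMask(m, sp = c(2, 2, 2))
  p <- sulPeak(sul, msk)
  expect_equal(p$center, c(13L, 15L, 4L))
  o <- bruteSulPeak(sul, msk)
  expect_equal(p$value, o$value)
})

test_that("SULpeak matches the exhaustive oracle and is monotone", {
  set.seed(77)
  for (rep in 1:8) {
    d <- c(sample(6:12, 1), sample(6:12, 1), sample(5:9, 1))
    sp <- runif(3, 1.5, 4)
    arr <- array(runif(prod(d), 0, 8), d)
    m <- randomMask(d, 0.08)
    if (!any(m)) m[sample(prod(d), 3)] <- TRUE
    sul <- mkVol(arr, sp = sp); msk <- mkMask(m, sp = sp)
    p <- sulPeak(sul, msk)
    o <- bruteSulPeak(sul, msk)
    expect_equal(p$value, o$value, tolerance = 1e-12,
                 info = sprintf("rep %d", rep))
    # adding activity anywhere never decreases the peak
    arr2 <- arr; arr2[sample(prod(d), 5)] <- arr2[sample(prod(d), 5)] + 3
    expect_gte(sulPeak(mkVol(arr2, sp = sp), msk)$value, p$value)
  }
})

test_that("SULpeak flags an empty segmentation as undefined", {
  v <- mkVol(array(1, c(5, 5, 5)))
  p <- sulPeak(v, mkMask(array(FALSE, c(5, 5, 5))))
  expect_true(is.na(p$value))
})

test_that("lesion statistics: MTV, SUVmean and TLG arithmetic", {
  # 100 voxels at 2 mm isotropic (0.008 mL), uniform SUV 5
  d <- c(10, 10, 4)
  m <- setBox(array(FALSE, d), 1:10, 1:10, 2)
  arr <- array(0, d); arr[, , 2] <- 5
  lm <- labelLesions(mkMask(m, sp = c(2, 2, 2)))
  st <- lesionStats(lm, mkVol(arr, sp = c(2, 2, 2), kind = "suv_bw"))
  expect_equal(nrow(st), 1)
  expect_equal(st$mtv_ml, 0.8)
  expect_equal(st$tlg, 4.0)
  # equally split SUVs {2, 4} -> mean 3
  arr2 <- arr; arr2[1:5, , 2] <- 2; arr2[6:10, , 2] <- 4
  st2 <- lesionStats(lm, mkVol(arr2, sp = c(2, 2, 2), kind = "suv_bw"))
  expect_equal(st2$suv_mean, 3)
})

test_that("total TLG is conserved under connectivity change and relabeling", {
  set.seed(13)
  for (rep in 1:10) {
    d <- c(9, 9, 7)
    m <- randomMask(d, 0.25)
    arr <- array(runif(prod(d), 0, 10), d)
    suv <- mkVol(arr, sp = c(2, 3, 2.5), kind = "suv_bw")
    msk <- mkMask(m, sp = c(2, 3, 2.5))
    tlgs <- vapply(c(6, 18, 26), function(conn)
      sum(lesionStats(labelLesions(msk, conn), suv)$tlg), numeric(1))
    expect_equal(tlgs[1], tlgs[2], tolerance = 1e-12)
    expect_equal(tlgs[2], tlgs[3], tolerance = 1e-12)
    # direct sum over mask voxels is the invariant quantity
    expect_equal(tlgs[1], sum(arr[m]) * prod(c(2, 3, 2.5)) / 1000,
                 tolerance = 1e-12)
  }
})

test_that("organ assignment follows the strict-majority rule with bone precedence", {
  d <- c(10, 10, 5)
  les <- setBox(array(FALSE, d), 1:5, 1:2, 1)       # 10 voxels
  lm <- labelLesions(mkMask(les))
  boneAll <- mkMask(setBox(array(FALSE, d), 1:10, 1:10, 1))
  liverNone <- mkMask(array(FALSE, d))
  expect_equal(assignOrgans(lm, boneAll, liverNone), "bone")
  # 40% inside liver -> other
  liver40 <- mkMask(setBox(array(FALSE, d), 1:2, 1:2, 1))
  boneNone <- mkMask(array(FALSE, d))
  expect_equal(assignOrgans(lm, boneNone, liver40), "other")
  # 60% bone and 60% liver (overlapping masks) -> bone
  organ60 <- mkMask(setBox(array(FALSE, d), 1:3, 1:2, 1))
  expect_message(tags <- assignOrgans(lm, organ60, organ60), "overlap")
  expect_equal(tags, "bone")
  # exactly 50% is not a strict majority
  organ50 <- mkMask(setBox(array(FALSE, d), 1:5, 1, 1))
  expect_equal(assignOrgans(lm, organ50, liverNone), "other")
})

test_that("PBI and PLI are percent volume ratios with additive numerators", {
  d <- c(20, 20, 10)
  bone <- setBox(array(FALSE, d), 1:20, 1:10, 1:10)   # 2000 voxels
  les <- array(FALSE, d)
  les <- setBox(les, 1:5, 1:2, 1)                      # 10 voxels in bone
  les <- setBox(les, 10:13, 3:7, 3)                    # 20 voxels in bone
  lm <- labelLesions(mkMask(les))
  none <- mkMask(array(FALSE, d))
  pbi <- petBoneIndex(lm, mkMask(bone), liver = none)
  expect_equal(pbi, 100 * 30 / 2000)                   # 1.5%
  expect_equal(petBoneIndex(labelLesions(none), mkMask(bone), liver = none),
               0)
  expect_error(petBoneIndex(lm, none, liver = none), "empty")
  # PLI of the liver used as its own single lesion is 100%
  liver <- setBox(array(FALSE, d), 14:18, 14:18, 5:8)
  lmLiver <- labelLesions(mkMask(liver))
  expect_equal(petLiverIndex(lmLiver, mkMask(liver), bone = none), 100)
})

test_that("the panel composes its parts and flags empty segmentations", {
  d <- c(16, 16, 10); sp <- c(3, 3, 3)
  arr <- array(1, d)
  les <- setBox(array(FALSE, d), 4:6, 4:6, 4:6)
  arr[les] <- 6
  bone <- setBox(array(FALSE, d), 3:8, 3:8, 2:9)
  liver <- setBox(array(FALSE, d), 11:14, 11:14, 4:8)
  sul <- mkVol(arr * 0.75, sp = sp, kind = "sul")
  suv <- mkVol(arr, sp = sp, kind = "suv_bw")
  organs <- list(bone = mkMask(bone, sp = sp), liver = mkMask(liver, sp = sp))
  pan <- biomarkerPanel(sul, suv, mkMask(les, sp = sp), organs)
  lm <- labelLesions(mkMask(les, sp = sp))
  expect_equal(pan@sulPeak, sulPeak(sul, mkMask(les, sp = sp))$value)
  expect_equal(pan@tlgTotal, sum(lesionStats(lm, suv)$tlg))
  expect_equal(pan@mtvTotal, 27 * prod(sp) / 1000)
  expect_equal(pan@pbi, petBoneIndex(lm, organs$bone, liver = organs$liver))
  expect_equal(pan@pli, 0)
  empty <- biomarkerPanel(sul, suv, mkMask(array(FALSE, d), sp = sp), organs)
  expect_true(is.na(empty@sulPeak))
  expect_equal(empty@mtvTotal, 0)
  expect_equal(empty@tlgTotal, 0)
})

test_that("volume ratios survive uniform lattice refinement", {
  # one world geometry (spherical lesion inside a grid-aligned bone box)
  # rendered at 2 mm and 1 mm: PBI changes only by discretization error
  renderPBI <- function(h) {
    n <- as.integer(72 / h)
    d <- c(n, n, n)
    ax <- (seq_len(n) - 1) * h
    inSphere <- function(c0, r) {
      q <- outer(outer((ax - c0[1])^2, (ax - c0[2])^2, `+`),
                 (ax - c0[3])^2, `+`)
      q <= r^2
    }
    les <- inSphere(c(32, 32, 32), 16)
    bone <- array(FALSE, d)
    bone[ax >= 8 & ax < 64, ax >= 8 & ax < 64, ax >= 8 & ax < 64] <- TRUE
    lm <- labelLesions(mkMask(les, sp = rep(h, 3)))
    petBoneIndex(lm, mkMask(bone, sp = rep(h, 3)),
                 liver = mkMask(array(FALSE, d), sp = rep(h, 3)))
  }
  p1 <- renderPBI(1); p05 <- renderPBI(0.5)
  expect_gt(p1, 0)
  expect_lt(abs(p1 - p05) / p05, 0.01)
})
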