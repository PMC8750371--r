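# Small grids keep the suite fast; the geometry and all rates are the
# generator defaults unless a test needs a specific degenerate setting.
smallSpec <- function(...) {
  phantomSpec(dim = c(48, 48, 96), spacing = c(4, 4, 4), ...)
}

test_that("the same seed reproduces a patient bit for bit", {
  s <- smallSpec()
  p1 <- generatePatient(s, seed = 101)
  p2 <- generatePatient(s, seed = 101)
  expect_identical(p1, p2)
  p3 <- generatePatient(s, seed = 102)
  expect_false(identical(voxelData(p1$timeline@baseline$volume),
                         voxelData(p3$timeline@baseline$volume)))
})

test_that("noiseless PSF-free phantoms: measured panels equal analytic truth", {
  s <- smallSpec(psfFWHMMM = 0, noiseSD = 0)
  for (seed in c(31, 32)) {
    pt <- generatePatient(s, seed)
    tl <- pt$timeline
    acqs <- c(list(tl@baseline), tl@followups)
    for (a in acqs) {
      tr <- pt$truth$acquisitions[[a$meta@timepoint]]
      sul <- suvToSul(a$volume, a$meta)
      pan <- biomarkerPanel(sul, a$volume, a$mask, tl@organMasks)
      expect_lt(abs(pan@mtvTotal - tr$mtv_ml), voxelVolumeML(a$mask) + 1e-12)
      if (tr$tlg > 0)
        expect_lt(abs(pan@tlgTotal - tr$tlg) / tr$tlg, 1e-6)
      expect_equal(pan@pbi, tr$pbi)
      expect_equal(pan@pli, tr$pli)
      expect_equal(nrow(pan@perLesion), tr$n_lesions)
    }
  }
})

test_that("PSF and noise reduce the measured SUVmean of hot lesions", {
  clean <- smallSpec(psfFWHMMM = 0, noiseSD = 0)
  blurred <- smallSpec()                       # defaults: 6 mm PSF + noise
  p0 <- generatePatient(clean, seed = 8)
  p1 <- generatePatient(blurred, seed = 8)     # same layout, same RNG path
  m0 <- lesionStats(labelLesions(p0$timeline@baseline$mask),
                    p0$timeline@baseline$volume)
  m1 <- lesionStats(labelLesions(p1$timeline@baseline$mask),
                    p1$timeline@baseline$volume)
  expect_identical(voxelData(p0$timeline@baseline$mask),
                   voxelData(p1$timeline@baseline$mask))
  expect_true(all(m1$suv_mean < m0$suv_mean))
})

test_that("complete response empties the follow-up and drops PLI to zero", {
  s <- smallSpec(crFraction = 1, psfFWHMMM = 0, noiseSD = 0,
                 siteProbs = c(bone = 0.3, liver = 0.5, other = 0.2),
                 lesionCountMean = 10)
  pt <- generatePatient(s, seed = 61, responder = TRUE)
  expect_equal(pt$truth$category, "CR")
  blT <- pt$truth$acquisitions$BL
  fuT <- pt$truth$acquisitions$FU1
  expect_equal(fuT$mtv_ml, 0)
  expect_equal(fuT$pbi, 0)
  expect_equal(fuT$pli, 0)
  expect_false(any(voxelData(pt$timeline@followups[[1]]$mask)))
  if (blT$pli > 0)
    expect_equal(as.numeric(deltaBiomarker(blT$pli, fuT$pli)), -100)
})

test_that("progressive disease with a new lesion raises the true TLG", {
  s <- smallSpec(pdFraction = 1, newLesionProb = 1,
                 psfFWHMMM = 0, noiseSD = 0)
  hits <- 0
  for (seed in c(71, 72, 73)) {
    pt <- generatePatient(s, seed, responder = FALSE)
    expect_equal(pt$truth$category, "PD")
    bl <- pt$truth$acquisitions$BL; fu <- pt$truth$acquisitions$FU1
    expect_gt(fu$tlg, bl$tlg)
    if (fu$n_lesions > bl$n_lesions) hits <- hits + 1
  }
  expect_gt(hits, 0)
})

test_that("cohort plan is deterministic with exact planted class counts", {
  s <- smallSpec()
  plan <- cohortPlan(s, 60, seed = 7)
  expect_equal(sum(plan$responder), 30)
  expect_identical(plan, cohortPlan(s, 60, seed = 7))
  expect_error(cohortPlan(phantomSpec(responderFraction = 0), 10, 1), "both")
})

test_that("a written cohort tree reloads into identical volumes and truth", {
  s <- phantomSpec(dim = c(32, 32, 64), spacing = c(5, 5, 5))
  dir <- file.path(tempdir(), "cohort-test")
  on.exit(unlink(dir, recursive = TRUE))
  out <- generateCohort(s, 3, seed = 5, outDir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  m <- readManifest(file.path(dir, "manifest.csv"))
  expect_setequal(unique(m$patient_id), c("P001", "P002", "P003"))
  # reload one acquisition and compare with in-memory regeneration
  mem <- generateCohort(s, 3, seed = 5)
  expect_equal(out$truth, mem$truth)
  row <- m[m$patient_id == "P002" & m$timepoint == "BL", ]
  v <- readVolume(row$pet_path, row$value_kind)
  expect_identical(voxelData(v),
                   voxelData(mem$patients[[2]]$timeline@baseline$volume))
  msk <- readMask(row$mask_path)
  expect_identical(voxelData(msk),
                   voxelData(mem$patients[[2]]$timeline@baseline$mask))
})

test_that("mask perturbation is seeded, in-body and component-structured", {
  s <- smallSpec(psfFWHMMM = 0, noiseSD = 0)
  pt <- generatePatient(s, seed = 55)
  mask <- pt$timeline@baseline$mask
  body <- binaryMask(voxelData(pt$timeline@baseline$volume) > 0.5,
                     spacing(mask), worldOrigin(mask))
  p1 <- perturbMask(mask, body, seed = 9)
  p2 <- perturbMask(mask, body, seed = 9)
  expect_identical(voxelData(p1), voxelData(p2))
  p3 <- perturbMask(mask, body, seed = 10)
  d <- diceScore(mask, p1)
  expect_gt(as.numeric(d), 0.2)     # still resembles the truth
  expect_lt(as.numeric(d), 1)       # but is degraded
  expect_false(identical(voxelData(p1), voxelData(p3)))
})
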