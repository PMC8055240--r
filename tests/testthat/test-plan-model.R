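test_that("timeline chains beam-on and beam-off periods", {
  d <- array(1, c(2, 2, 2))
  plan <- treatmentPlan(list(d, d), beamOn = c(2, 3), beamOff = 0.06,
                        prescription = 2)
  tl <- buildTimeline(plan)
  expect_equal(tl$start, c(0, 2.06))
  expect_equal(tl$end, c(2, 5.06))
  expect_equal(totalTime(plan), 5.06)
  single <- treatmentPlan(list(d), beamOn = 1.7, prescription = 1)
  expect_equal(buildTimeline(single)$end, 1.7)
})

test_that("total time is the sum of all beam periods on random plans", {
  set.seed(5)
  for (i in 1:5) {
    plan <- tinyPlan(nShots = sample(2:6, 1))
    tl <- buildTimeline(plan)
    expect_equal(tl$end[nShots(plan)],
                 sum(beamOn(plan)) + sum(beamOff(plan)))
    expect_true(all(diff(tl$start) > 0))
  }
})

test_that("plan validity rejects constructed invariant breaches", {
  d <- array(1, c(2, 2, 2))
  expect_error(treatmentPlan(list(d, d), beamOn = c(1, -1),
                             prescription = 1), "beamOn")
  expect_error(treatmentPlan(list(d, d), beamOn = c(1, 1),
                             beamOff = c(0.06, 0.06), prescription = 1),
               "beamOff")
  expect_error(treatmentPlan(list(d, array(1, c(3, 3, 3))),
                             beamOn = c(1, 1), prescription = 1),
               "lattice")
  expect_error(treatmentPlan(list(d, -d), beamOn = c(1, 1),
                             prescription = 1), "negative")
})

test_that("voxel exposures carry per-shot rates in delivery order", {
  d1 <- array(0, c(2, 2, 2))
  d2 <- array(0, c(2, 2, 2))
  d2[1, 1, 1] <- 3
  plan <- treatmentPlan(list(d1, d2), beamOn = c(2, 1.5),
                        prescription = 3)
  e <- planExposure(plan, c(1, 1, 1))
  expect_equal(e@rates, c(0, 2))
  expect_equal(e@durations, beamOn(plan))
  # dropping zero-rate segments leaves a single effective segment
  eDrop <- planExposure(plan, c(1, 1, 1), dropZero = TRUE)
  expect_length(eDrop@rates, 1)
  expect_equal(eDrop@rates, 2)
})

test_that("zero-rate segments do not change Phi or BED", {
  set.seed(31)
  plan <- tinyPlan(nShots = 4)
  plan@doses[[2]][] <- 0
  p <- repairParams()
  v <- sample(prod(dim(plan@doses[[1]])), 5)
  for (vox in v) {
    keep <- planExposure(plan, vox)
    drop <- planExposure(plan, vox, dropZero = TRUE)
    expect_equal(bedVoxel(drop, p), bedVoxel(keep, p), tolerance = 1e-12)
  }
})

test_that("dose is conserved under reordering and gap edits", {
  set.seed(37)
  plan <- tinyPlan(nShots = 5)
  D <- totalDose(plan)
  perm <- sample(5)
  expect_equal(totalDose(applySequence(plan, perm)), D)
  expect_equal(totalDose(insertGap(plan, 2, 15)), D)
})

test_that("plan bundles round-trip through manifest plus NIfTI", {
  plan <- makePlan(seed = 2, nShots = 3, prescription = 12,
                   totalTime = 25)
  dir <- file.path(tempdir(), "bundle-roundtrip")
  writePlanBundle(plan, dir)
  back <- readPlanBundle(dir)
  expect_equal(caseId(back), caseId(plan))
  expect_equal(prescriptionDose(back), prescriptionDose(plan))
  expect_equal(beamOn(back), beamOn(plan), tolerance = 1e-12)
  expect_equal(beamOff(back), beamOff(plan), tolerance = 1e-12)
  expect_equal(voxelSpacing(back), voxelSpacing(plan))
  # doses survive up to float32 storage precision
  for (k in seq_len(nShots(plan))) {
    expect_equal(shotDose(back, k), shotDose(plan, k), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  unlink(dir, recursive = TRUE)
})

test_that("bundle reader fills the default repositioning gap and validates", {
  plan <- makePlan(seed = 2, nShots = 3, prescription = 12,
                   totalTime = 25)
  dir <- file.path(tempdir(), "bundle-legacy")
  writePlanBundle(plan, dir)
  mf <- file.path(dir, "manifest.json")
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)

  # legacy manifest without beam_off gets the 0.06 min default
  m2 <- m
  m2$beam_off_min <- NULL
  jsonlite::write_json(m2, mf, auto_unbox = TRUE, digits = NA)
  expect_equal(beamOff(readPlanBundle(dir)), c(0.06, 0.06))

  # wrong beam_off length is rejected, naming the field
  m3 <- m
  m3$beam_off_min <- c(0.06)
  jsonlite::write_json(m3, mf, auto_unbox = TRUE, digits = NA)
  expect_error(readPlanBundle(dir), "beam_off_min")

  # missing volume is rejected, naming the shot
  jsonlite::write_json(m, mf, auto_unbox = TRUE, digits = NA)
  file.remove(file.path(dir, m$shots$dose_file[2]))
  expect_error(readPlanBundle(dir), "missing dose volume")
  unlink(dir, recursive = TRUE)
})
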