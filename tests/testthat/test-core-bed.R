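test_that("repair rate conversion follows mu = ln2 / half-time", {
  expect_equal(repairRate(log(2)), 1)
  expect_equal(repairRate(12), 0.057762, tolerance = 1e-5)
  expect_equal(repairRate(6), 2 * repairRate(12))
  expect_error(repairRate(0), "positive")
  expect_error(repairRate(-3), "positive")
})

test_that("repair parameter invariants are enforced", {
  p <- repairParams()
  expect_equal(alphaBeta(p), 2.47)
  mu <- repairRates(p)
  expect_true(mu[["fast"]] >= mu[["slow"]])
  expect_error(repairParams(alphaBeta = -1), "alphaBeta")
  expect_error(repairParams(halfTimeFast = 200, halfTimeSlow = 100),
               "exceed")
  expect_error(repairParams(partitionFast = 1.2), "partitionFast")
})

test_that("self protraction term matches its closed form and limits", {
  expect_equal(phiSelf(0, 1, 1), 0)
  # acute / no-repair limit tends to d^2
  expect_equal(phiSelf(2, 3, 1e-9), 36, tolerance = 1e-6)
  # frozen from the quadrature oracle: 2 exp(-1)
  expect_equal(phiSelf(1, 1, 1), 0.7357589, tolerance = 1e-6)
  expect_error(phiSelf(1, 1, 0), "mu")
  expect_error(phiSelf(1, -1, 1), "duration")
})

test_that("cross protraction term decays with the repair interval", {
  # complete repair
  expect_lt(phiCross(1, 1, 1, 1, interval = 1e4, mu = 1), 1e-12)
  # no-repair acute limit 2 d_j d_k
  expect_equal(phiCross(3e9, 1e-9, 4e9, 1e-9, 0, 1e-9), 24,
               tolerance = 1e-6)
  # acute unit doses one fast half-time apart halve their interaction
  expect_equal(phiCross(1e7, 1e-7, 1e7, 1e-7, 1, log(2)), 1,
               tolerance = 1e-5)
  expect_error(phiCross(1, 1, 1, 1, interval = -1, mu = 1), "interval")
  taus <- seq(0, 30, by = 5)
  vals <- phiCross(1, 2, 1, 2, taus, mu = 0.06)
  expect_true(all(diff(vals) < 0))
})

test_that("protocol Phi sums self and cross terms on the absolute timeline", {
  expect_equal(phiProtocol(voxelExposure(numeric(0), numeric(0)), 1), 0)
  e1 <- voxelExposure(1.3, 2.1)
  expect_equal(phiProtocol(e1, 0.5), phiSelf(1.3, 2.1, 0.5))
  # frozen from the quadrature oracle: two acute 6 Gy shots, 0.06 min
  # apart, fast repair half-time 12 min
  e2 <- acuteExposure(c(6, 6), 0.06)
  expect_equal(phiProtocol(e2, log(2) / 12), 143.750893, tolerance = 1e-5)
})

test_that("Phi is invariant under time reversal of the protocol", {
  set.seed(41)
  for (i in 1:20) {
    e <- randomExposure()
    rev <- voxelExposure(rev(e@rates), rev(e@durations), rev(e@intervals))
    for (mu in c(repairRate(11.4), repairRate(129.6))) {
      expect_equal(phiProtocol(rev, mu), phiProtocol(e, mu),
                   tolerance = 1e-12)
    }
  }
})

test_that("closed-form Phi agrees with the quadrature oracle", {
  set.seed(7)
  mus <- repairRates(repairParams())
  for (i in 1:30) {
    e <- randomExposure()
    for (mu in mus) {
      phi <- phiProtocol(e, mu)
      ref <- phiNumericOracle(e, mu)
      expect_equal(phi, ref, tolerance = 1e-6)
    }
  }
  # instantaneous-repair limit: Phi scales as 2 R^2 t / mu -> 0
  expect_lt(phiProtocol(randomExposure(), 1e6), 1e-3)
})

test_that("voxel BED reproduces the acute and complete-repair closed forms", {
  p <- repairParams()
  expect_equal(bedVoxel(voxelExposure(0, 5), p), 0)
  # single acute 13 Gy shot: D (1 + D / (alpha/beta))
  expect_equal(bedVoxel(acuteExposure(13, numeric(0)), p),
               13 + 13^2 / 2.47, tolerance = 1e-5)
  # two acute 6 Gy shots with complete repair in between
  expect_equal(bedVoxel(acuteExposure(c(6, 6), 1e7), p),
               12 + 2 * 36 / 2.47, tolerance = 1e-5)
})

test_that("BED limits hold: acute, complete repair, instantaneous repair", {
  set.seed(13)
  p <- repairParams()
  doses <- runif(4, 1, 5)
  D <- sum(doses)
  # all durations and intervals -> 0: acute limit D (1 + D/ab)
  expect_equal(bedVoxel(acuteExposure(doses, rep(1e-9, 3)), p),
               D * (1 + D / 2.47), tolerance = 1e-5)
  # all intervals -> Inf: sum of per-shot acute BEDs
  expect_equal(bedVoxel(acuteExposure(doses, rep(1e9, 3)), p),
               sum(doses * (1 + doses / 2.47)), tolerance = 1e-5)
  # mu -> Inf: BED -> D
  pFast <- repairParams(halfTimeFast = 1e-9, halfTimeSlow = 1e-9)
  e <- voxelExposure(doses, rep(1, 4), rep(0.5, 3))
  expect_equal(bedVoxel(e, pFast), D, tolerance = 1e-5)
})

test_that("partition coefficient 1 reduces to mono-exponential repair", {
  set.seed(17)
  e <- randomExposure()
  pm <- repairParams(partitionFast = 1)
  manual <- sum(e@rates * e@durations) +
    phiProtocol(e, repairRate(11.4)) / 2.47
  expect_equal(bedVoxel(e, pm), manual, tolerance = 1e-12)
})

test_that("bi-exponential BED is bracketed by the mono-exponential ones", {
  set.seed(19)
  pBi <- repairParams()
  pFast <- repairParams(partitionFast = 1)
  pSlow <- repairParams(halfTimeFast = 129.6, partitionFast = 1)
  for (i in 1:10) {
    e <- randomExposure()
    b <- bedVoxel(e, pBi)
    expect_gte(b, bedVoxel(e, pFast) - 1e-9)
    expect_lte(b, bedVoxel(e, pSlow) + 1e-9)
  }
})

test_that("BED strictly decreases when a spanned interval grows", {
  set.seed(23)
  p <- repairParams()
  for (i in 1:10) {
    e <- randomExposure(nMax = 4)
    if (length(e@rates) < 2 || any(e@rates == 0)) next
    j <- sample(length(e@intervals), 1)
    e2 <- e
    e2@intervals[j] <- e2@intervals[j] + 5
    expect_lt(bedVoxel(e2, p), bedVoxel(e, p))
  }
})

test_that("grid BED equals the per-voxel evaluation and respects bounds", {
  set.seed(29)
  plan <- tinyPlan(nShots = 5, dim = c(7, 7, 7))
  p <- repairParams()
  bed <- bedGrid(plan, p)
  # loop oracle over every voxel
  idx <- seq_len(prod(dim(bedValues(bed))))
  loop <- vapply(idx, function(v) bedVoxel(planExposure(plan, v), p),
                 numeric(1))
  expect_equal(as.vector(bedValues(bed)), loop, tolerance = 1e-12)
  D <- totalDose(plan)
  expect_true(all(bedValues(bed) >= as.vector(D) - 1e-9))
  expect_true(all(bedValues(bed) <= D * (1 + D / 2.47) + 1e-9))
  expect_identical(bedValues(bed)[D == 0], numeric(0))  # no zero voxels drawn
})

test_that("uniform exposure gives a constant BED grid", {
  d <- array(1.5, c(3, 3, 3))
  plan <- treatmentPlan(list(d, d), beamOn = c(2, 2), prescription = 3)
  v <- bedValues(bedGrid(plan, repairParams()))
  expect_equal(max(v) - min(v), 0, tolerance = 1e-12)
})
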