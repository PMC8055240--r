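test_that("re-sequencing permutes shots and conserves physical dose", {
  set.seed(53)
  plan <- tinyPlan(nShots = 4)
  expect_equal(applySequence(plan, 1:4), plan)
  perm <- c(3, 1, 4, 2)
  rp <- applySequence(plan, perm)
  expect_equal(shotIds(rp), shotIds(plan)[perm])
  expect_equal(beamOn(rp), beamOn(plan)[perm])
  expect_equal(beamOff(rp), beamOff(plan))  # slot-attached
  expect_equal(totalDose(rp), totalDose(plan))
  expect_error(applySequence(plan, c(1, 1, 2, 3)), "permutation")
})

test_that("reversing the delivery order leaves the shell mean BED unchanged", {
  plan <- makePlan(seed = 31, nShots = 5, prescription = 12,
                   totalTime = 30)
  sh <- extractShell(plan)
  p <- repairParams()
  fwd <- directShellMean(plan, p, sh)
  rev <- directShellMean(applySequence(plan, 5:1), p, sh)
  expect_equal(rev, fwd, tolerance = 1e-12)
})

test_that("exhaustive search matches a naive per-permutation loop", {
  p <- repairParams()
  for (n in c(3, 4)) {
    plan <- makePlan(seed = 60 + n, nShots = n, prescription = 12,
                     totalTime = 25)
    sh <- extractShell(plan)
    ex <- exhaustiveSearch(plan, p, shell = sh)
    expect_equal(ex$count, factorial(n))
    # brute force: full grid BED for every ordering
    perms <- GammaBED:::.allPerms(n)
    vals <- apply(perms, 1, function(pp) {
      directShellMean(applySequence(plan, pp), p, sh)
    })
    expect_equal(ex$min$meanBED, min(vals), tolerance = 1e-9)
    expect_equal(ex$max$meanBED, max(vals), tolerance = 1e-9)
    expect_equal(directShellMean(applySequence(plan, ex$min$permutation),
                                 p, sh),
                 min(vals), tolerance = 1e-9)
    # reversal degeneracy: extremes are attained at least twice
    expect_gte(sum(abs(vals - min(vals)) < 1e-9), 2)
  }
})

test_that("oversized exhaustive requests are refused with the sequence count", {
  d <- array(1, c(2, 2, 2))
  plan <- treatmentPlan(rep(list(d), 13), beamOn = rep(1, 13),
                        prescription = 13)
  expect_error(exhaustiveSearch(plan), "6.227\\d*e\\+09")
})

test_that("the pyramidal heuristic groups high rates mid-schedule", {
  expect_equal(heuristicMaxSequence(c(1, 2, 3, 4, 5)), c(1, 3, 5, 4, 2))
  expect_equal(heuristicMaxSequence(rep(2, 4)), 1:4)
  expect_equal(heuristicMaxSequence(c(5, 1)), c(2, 1))
  # the top rates end up adjacent
  perm <- heuristicMaxSequence(c(0.1, 9, 0.2, 8, 0.3, 7))
  posTop <- sort(match(c(2, 4, 6), perm))
  expect_equal(diff(posTop), c(1, 1))
})

test_that("the spread-out heuristic alternates strong and weak shots", {
  expect_equal(heuristicMinSequence(c(1, 2, 3, 4, 5)), c(5, 1, 4, 2, 3))
  expect_equal(heuristicMinSequence(rep(1, 3)), 1:3)
  # with two shots both heuristics coincide up to reversal, and so do
  # their BEDs
  plan <- acutePlan(c(6, 4), prescription = 10)
  sh <- extractShell(plan)
  p <- repairParams()
  rates <- shotMeanDoseRate(plan, sh)
  bMin <- directShellMean(applySequence(plan, heuristicMinSequence(rates)),
                          p, sh)
  bMax <- directShellMean(applySequence(plan, heuristicMaxSequence(rates)),
                          p, sh)
  expect_equal(bMin, bMax, tolerance = 1e-12)
})

test_that("heuristic sequences stay within the exhaustive extremes", {
  p <- repairParams()
  for (i in 1:6) {
    n <- 4 + (i %% 3)
    plan <- makePlan(seed = 70 + i, nShots = n, prescription = 13,
                     totalTime = 24 + i)
    sh <- extractShell(plan)
    ex <- exhaustiveSearch(plan, p, shell = sh)
    rates <- shotMeanDoseRate(plan, sh)
    hMin <- directShellMean(applySequence(plan,
                                          heuristicMinSequence(rates)),
                            p, sh)
    hMax <- directShellMean(applySequence(plan,
                                          heuristicMaxSequence(rates)),
                            p, sh)
    expect_gte(hMin, ex$min$meanBED - 1e-9)
    expect_lte(hMax, ex$max$meanBED + 1e-9)
  }
})

test_that("delta_rel is the relative min-to-max range", {
  expect_equal(round(deltaRel(61.95, 60.67, 63.33), 2), 4.29)
  expect_equal(deltaRel(50, 45, 55), 20)
  expect_equal(deltaRel(70, 62, 62), 0)
  expect_error(deltaRel(0, 1, 2), "positive")
})

test_that("paired t-test matches the closed-form hand computation", {
  r <- pairedTTest(c(1, 2, 3), c(2, 4, 6))
  # d = (-1, -2, -3): mean -2, sd 1, t = -2 / (1/sqrt(3))
  expect_equal(r$t, -2 * sqrt(3), tolerance = 1e-6)
  expect_equal(r$df, 2)
  expect_equal(r$p, 0.0741799, tolerance = 1e-5)
  expect_error(pairedTTest(1:3, 1:4), "equal length")
  expect_error(pairedTTest(1:3, 1:3), "zero-variance")
})

test_that("cohort summary reproduces the published per-group statistics", {
  tab <- readCohortTable(system.file("extdata", "cohort_results.csv",
                                     package = "GammaBED"))
  s <- cohortSummary(tab)
  g <- s$groups
  expect_equal(round(g$meanBedOrig, 2), c(58.00, 67.93))
  expect_equal(round(g$meanTime, 2), c(42.72, 40.69))
  expect_equal(round(g$meanDeltaRel, 2), c(7.47, 7.25))
  expect_equal(round(g$spreadPct, 1), c(22.9, 24.8))
  expect_equal(round(s$overall$meanDeltaRel, 2), 7.34)
  expect_equal(round(s$overall$heuristicIncreasePct, 1), 2.6)
  expect_equal(round(s$overall$heuristicDecreasePct, 1), 4.7)
  expect_equal(round(s$overall$groupRatioPct), 17)
  expect_equal(round(s$tTests$gy12$p, 4), 0.0011)
  expect_equal(round(s$tTests$gy13$p, 4), 0.0010)
  expect_lt(s$tTests$all$p, 1e-4)
})

test_that("degenerate cohorts give zero spreads and unit group ratio", {
  rows <- data.frame(case = sprintf("c%d", 1:4),
                     dose_gy = c(12, 12, 13, 13), time_min = 30,
                     n_iso = 5, bed_orig = 60, bed_min = 60,
                     bed_max = 60, delta_rel_pct = 0)
  s <- cohortSummary(rows)
  expect_equal(s$groups$spreadPct, c(0, 0))
  expect_equal(s$overall$groupRatioPct, 0)
  expect_null(s$tTests$all)
})
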