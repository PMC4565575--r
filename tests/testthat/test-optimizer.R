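toyProblem <- function(...) {
  optimizationProblem(toySlabPhantom(), tissueDefaults(),
                      centerToOuter = 8, activeTip = 20, radius = 0.6,
                      marginWidth = 3,
                      settings = solverSettings(fpTol = 5e-3), ...)
}

test_that("objective equals the hand-computed weighted coverage sum", {
  ph <- toySlabPhantom()
  arr <- starArray(c(24, 24, 30), c(0, 0, 1), centerToOuter = 8,
                   activeTip = 20, radius = 0.6)
  plan <- treatmentPlan(ph, arr, starSchedule(arr),
                        settings = solverSettings(fpTol = 5e-3),
                        marginWidth = 3)
  sols <- solveSchedule(plan)
  res <- planObjective(plan, weights = c(1, 0.5, 0.5), solutions = sols)
  # recompute each component by direct voxel counting
  cum <- cumulativeField(sols)
  tm <- tumorMask(ph)
  mm <- safetyMargin(ph, 3)
  ov <- normalMask(ph) & !mm
  tumor <- sum(cum[tm] >= 400) / sum(tm)
  margin <- sum(cum[mm] >= 350) / sum(mm)
  over <- sum(cum[ov] >= 800) / sum(ov)
  expect_equal(res$tumor, tumor, tolerance = 1e-12)
  expect_equal(res$margin, margin, tolerance = 1e-12)
  expect_equal(res$overreach, over, tolerance = 1e-12)
  expect_equal(res$score, tumor + 0.5 * margin - 0.5 * over,
               tolerance = 1e-12)
  # perfect coverage with no overreach would score w1 + w2 = 1.5
  expect_lte(res$score, 1.5)
})

test_that("objective refuses plans that collide with critical structures", {
  ph <- makePhantom(c(40, 40, 50), 2,
                    tumors = list(list(center = c(40, 40, 50),
                                       diameter = 12)),
                    vessel = list(point = c(56, 40, 0),
                                  direction = c(0, 0, 1), radius = 3))
  arr <- starArray(c(50, 40, 50), c(0, 0, 1), centerToOuter = 8,
                   activeTip = 20, radius = 1.5)
  plan <- treatmentPlan(ph, arr, starSchedule(arr))
  expect_error(planObjective(plan), "inadmissible")
})

test_that("voltage-grid search matches exhaustive enumeration", {
  prob <- toyProblem()
  vgrid <- c(600, 1000, 1400)
  st <- optimizerSettings(nCenters = 1, nDirections = 1, depthOffsets = 0,
                          vCenterOuterGrid = vgrid,
                          vOuterOuterGrid = 1200, budget = 10, coarsen = 2,
                          descentPasses = 0)
  res <- optimizePlan(prob, st, seed = 3)
  # independent exhaustive enumeration over the same 3-point grid
  coarse <- coarsenPhantom(prob$phantom, 2)
  tm <- tumorMask(prob$phantom)
  idx <- arrayInd(which(tm), dim(tm))
  centroid <- gridOrigin(prob$phantom) +
    (colMeans(idx) - 0.5) * voxelSpacing(prob$phantom)
  best <- NULL
  for (v in vgrid) {
    arr <- starArray(centroid, c(0, 0, 1), centerToOuter = 8,
                     activeTip = 20, radius = 0.6)
    plan <- treatmentPlan(coarse, arr, starSchedule(arr, vCenterOuter = v),
                          tissues = prob$tissues, settings = prob$settings,
                          marginWidth = 3)
    sc <- planObjective(plan, prob$weights)
    if (is.null(best) || sc$score > best$score + 1e-12)
      best <- list(v = v, score = sc$score)
  }
  expect_equal(res$coarseScore$score, best$score, tolerance = 1e-9)
  entries <- scheduleEntries(res$plan@schedule)
  expect_identical(unique(entries$voltage[entries$cathode == 5]), best$v)
})

test_that("optimizer trace is monotone and runs are seed-reproducible", {
  prob <- toyProblem()
  st <- optimizerSettings(nCenters = 3, centerRadius = 3, depthOffsets = 0,
                          vCenterOuterGrid = c(800, 1200),
                          vOuterOuterGrid = 1200, budget = 6, coarsen = 2,
                          descentPasses = 0)
  r1 <- optimizePlan(prob, st, seed = 9)
  ok <- !is.na(r1$trace$best_score)
  expect_true(all(diff(r1$trace$best_score[ok]) >= -1e-12))
  r2 <- optimizePlan(prob, st, seed = 9)
  expect_identical(r1$trace, r2$trace)
  expect_equal(r1$score$score, r2$score$score, tolerance = 1e-15)
  # returned plan is admissible and within the device current cap
  expect_identical(nrow(checkCollisions(r1$plan@array, r1$plan@phantom)), 0L)
  expect_true(all(r1$score$currents <= prob$currentCap))
})

test_that("infeasible problems raise an error listing the violated constraint", {
  # voltage grid outside the allowed bounds: no admissible candidate
  prob <- toyProblem(voltageBounds = c(500, 700))
  st <- optimizerSettings(nCenters = 1, vCenterOuterGrid = 1000,
                          vOuterOuterGrid = 1200, descentPasses = 0)
  expect_error(optimizePlan(prob, st, seed = 1), "voltage outside bounds")
})
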