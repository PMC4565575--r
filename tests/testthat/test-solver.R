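test_that("conductivity ramp has the documented closed form", {
  # plateaus
  expect_identical(sigmaOfE(0, 0.2, 3.5, 400, 800), 0.2)
  expect_identical(sigmaOfE(400, 0.2, 3.5, 400, 800), 0.2)
  expect_equal(sigmaOfE(1600, 0.2, 3.5, 400, 800), 0.7, tolerance = 1e-12)
  expect_equal(sigmaOfE(800, 0.2, 3.5, 400, 800), 0.7, tolerance = 1e-12)
  # midpoint of the raised-cosine ramp: sigma0 * (1 + factor) / 2
  mid <- sigmaOfE(600, 0.2, 3.5, 400, 800)
  expect_equal(mid, 0.2 * (1 + 3.5) / 2, tolerance = 1e-12)
  expect_true(mid > 0.2 && mid < 0.7)
  # linear variant at the quarter point
  expect_equal(sigmaOfE(500, 0.2, 3.5, 400, 800, shape = "linear"),
               0.2 * (1 + 2.5 * 0.25), tolerance = 1e-12)
  # monotone over the ramp
  e <- seq(0, 1000, by = 10)
  expect_true(all(diff(sigmaOfE(e, 0.2, 3.5, 400, 800)) >= 0))
  expect_error(sigmaOfE(-1, 0.2, 3.5, 400, 800), ">= 0")
})

test_that("potential respects the discrete maximum principle", {
  s <- solvedTwoNeedle1mm()$sol
  expect_gte(min(potentialGrid(s)), 0)
  expect_lte(max(potentialGrid(s)), 1000)
  expect_true(all(fieldMagnitude(s) >= 0))
})

test_that("current is linear in conductivity and voltage without electroporation", {
  fx <- twoNeedleFixture(1)
  st <- solverSettings(epEnabled = FALSE)
  base <- solvedTwoNeedle1mm()$sol
  doubled <- solvePair(fx$phantom,
                       scaleTissueConductivity(tissueDefaults(), 2),
                       fx$masks, c(1, 2), 1000, st)
  expect_equal(predictedCurrent(doubled), 2 * predictedCurrent(base),
               tolerance = 1e-6)
  half <- solvePair(fx$phantom, tissueDefaults(), fx$masks, c(1, 2), 500, st)
  expect_equal(predictedCurrent(half), predictedCurrent(base) / 2,
               tolerance = 1e-6)
  # median tumor-region field scales linearly with voltage
  mid <- array(FALSE, dim(labelArray(fx$phantom)))
  mid[16:25, 11:20, 21:40] <- TRUE
  expect_equal(median(fieldMagnitude(half)[mid]),
               median(fieldMagnitude(base)[mid]) / 2, tolerance = 1e-6)
})

test_that("electroporation can only increase the predicted current", {
  fx <- twoNeedleFixture(1)
  base <- solvedTwoNeedle1mm()$sol
  ep <- solvePair(fx$phantom, tissueDefaults(), fx$masks, c(1, 2), 1000,
                  solverSettings(epEnabled = TRUE))
  expect_gte(predictedCurrent(ep), predictedCurrent(base))
  expect_true(all(ep@conductivity >= base@conductivity - 1e-12))
})

test_that("unconverged fixed point reports a finite mismatch when allowed", {
  fx <- twoNeedleFixture(1)
  st <- solverSettings(fpMaxit = 1, allowUnconverged = TRUE)
  expect_silent(sol <- solvePair(fx$phantom, tissueDefaults(), fx$masks,
                                 c(1, 2), 1000, st))
  expect_false(sol@converged)
  expect_true(is.finite(currentBalance(sol)))
  # and the same settings without the escape hatch raise a convergence error
  st2 <- solverSettings(fpMaxit = 1)
  expect_error(solvePair(fx$phantom, tissueDefaults(), fx$masks, c(1, 2),
                         1000, st2), "did not converge")
})

test_that("solver rejects empty or overlapping pair masks and negative fields", {
  fx <- twoNeedleFixture(1)
  expect_error(solvePair(fx$phantom, tissueDefaults(), fx$masks, c(1, 9),
                         1000), "nonempty")
  m <- fx$masks
  m[["2"]] <- m[["1"]]
  expect_error(solvePair(fx$phantom, tissueDefaults(), m, c(1, 2), 1000),
               "disjoint")
})

test_that("persistent-sigma mode never lowers later-pair currents", {
  plan <- ectCaseFixture(1, spacing = 2)
  masks <- rasterizeElectrodes(plan@array, plan@phantom)
  indep <- solveSchedule(plan, masks)
  planP <- plan
  planP@settings$persistentSigma <- TRUE
  pers <- solveSchedule(planP, masks)
  iIndep <- vapply(indep, predictedCurrent, numeric(1))
  iPers <- vapply(pers, predictedCurrent, numeric(1))
  expect_equal(iPers[1], iIndep[1], tolerance = 1e-9)
  expect_true(all(iPers >= iIndep - 1e-9))
})

test_that("predicted current is stable under mesh refinement", {
  i1 <- predictedCurrent(solvedTwoNeedle1mm()$sol)
  i05 <- predictedCurrent(solvedTwoNeedleHalf()$sol)
  expect_lt(abs(i05 - i1) / i05, 0.03)
})

test_that("symmetric two-needle fixture balances anode and cathode currents", {
  s <- solvedTwoNeedle1mm()$sol
  expect_lt(currentBalance(s), 1e-6)
  expect_error(currentBalance(
    solvePair(solvedTwoNeedle1mm()$fx$phantom, tissueDefaults(),
              solvedTwoNeedle1mm()$fx$masks, c(1, 2), 0)), "undefined")
})
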