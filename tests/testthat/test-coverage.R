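test_that("cumulative field is the voxelwise max and is idempotent", {
  cs <- solvedCase2mm()
  cum <- cumulativeField(cs$sols)
  expect_identical(cumulativeField(cs$sols[1]), fieldMagnitude(cs$sols[[1]]))
  expect_identical(cumulativeField(c(cs$sols, cs$sols[1])), cum)
  for (s in cs$sols) expect_true(all(cum >= fieldMagnitude(s)))
  # permutation invariance
  expect_identical(cumulativeField(rev(cs$sols)), cum)
})

test_that("coverage fraction counts thresholded voxels inclusively", {
  mask <- array(FALSE, c(4, 4, 2))
  mask[1:4, 1:4, 1] <- TRUE
  f <- array(0, c(4, 4, 2))
  f[1:2, 1:4, 1] <- 500
  f[3:4, 1:4, 1] <- 300
  expect_identical(coverageFraction(f, mask, 400), 0.5)
  expect_identical(coverageFraction(f, mask, 0), 1)
  expect_identical(coverageFraction(f, mask, 1000), 0)
  expect_identical(coverageFraction(f, mask, 300), 1) # inclusive
  expect_error(coverageFraction(f, array(FALSE, c(4, 4, 2)), 1), "empty")
})

test_that("coverage-volume histogram is nonincreasing with correct endpoints", {
  cs <- solvedCase2mm()
  cum <- cumulativeField(cs$sols)
  tm <- tumorMask(cs$plan@phantom)
  th <- seq(0, 1500, by = 100)
  cvh <- coverageVolumeHistogram(cum, tm, th)
  expect_identical(cvh$fraction[1], 1)
  expect_true(all(diff(cvh$fraction) <= 0))
  expect_equal(cvh$fraction,
               vapply(th, function(t) coverageFraction(cum, tm, t),
                      numeric(1)))
  expect_error(coverageVolumeHistogram(cum, tm, c(100, 50)), "ascending")
  # uniform field: unit step at the field value (inclusive at the value)
  u <- array(450, dim(tm))
  expect_identical(coverageVolumeHistogram(u, tm, c(0, 450, 450.1))$fraction,
                   c(1, 1, 0))
})

test_that("coverage report summarises per-pair progression consistently", {
  cs <- solvedCase2mm()
  rep <- coverageReport(cs$plan, cs$sols)
  pp <- rep@perPair
  expect_identical(nrow(pp), 8L)
  # running cumulative coverage is nondecreasing over the pair sequence
  expect_true(all(diff(pp$cumulative_tumor_coverage) >= -1e-12))
  expect_equal(pp$cumulative_tumor_coverage[8],
               unname(rep@summary["tumor_coverage_e_rev"]), tolerance = 1e-12)
  expect_equal(tumorCoverageAt(rep, 0), 1)
  expect_true(all(cvhTable(rep)$tumor_fraction >= 0 &
                    cvhTable(rep)$tumor_fraction <= 1))
})

test_that("scaling all voltages up never decreases coverage without electroporation", {
  plan <- ectCaseFixture(1, spacing = 2,
                         settings = solverSettings(epEnabled = FALSE))
  masks <- rasterizeElectrodes(plan@array, plan@phantom)
  sols <- solveSchedule(plan, masks)
  up <- plan
  up@schedule@entries$voltage <- up@schedule@entries$voltage * 1.1
  solsUp <- solveSchedule(up, masks)
  cum <- cumulativeField(sols)
  cumUp <- cumulativeField(solsUp)
  tm <- tumorMask(plan@phantom)
  for (th in c(100, 250, 400, 600, 800))
    expect_gte(coverageFraction(cumUp, tm, th),
               coverageFraction(cum, tm, th))
})

test_that("coverage report exports to JSON, CSV and NIfTI", {
  cs <- solvedCase2mm()
  rep <- coverageReport(cs$plan, cs$sols)
  d <- tempfile()
  paths <- exportCoverageReport(rep, d, fieldNifti = TRUE,
                                spacing = voxelSpacing(cs$plan@phantom),
                                origin = gridOrigin(cs$plan@phantom))
  expect_true(all(file.exists(unlist(paths))))
  back <- jsonlite::read_json(paths$summary, simplifyVector = TRUE)
  expect_equal(back$tumor_coverage_e_rev,
               unname(rep@summary["tumor_coverage_e_rev"]),
               tolerance = 1e-12)
  cvh <- read.csv(paths$cvh)
  expect_equal(cvh$tumor_fraction, rep@cvh$tumor_fraction,
               tolerance = 1e-12)
  vol <- RNifti::readNifti(paths$field)
  expect_equal(max(vol), max(rep@cumulativeField), tolerance = 1e-6)
})

test_that("robustness sweep is seed-deterministic and brackets the nominal plan", {
  plan <- twoPairCasePlan()
  r0 <- robustnessSweep(plan, shiftRadius = 0, sigmaScale = 0, nMembers = 0)
  expect_identical(r0$min, r0$nominal)
  expect_identical(r0$max, r0$nominal)
  r <- robustnessSweep(plan, shiftRadius = 1, sigmaScale = 0.2,
                       nMembers = 3, seed = 11)
  expect_lte(r$min, r$nominal)
  expect_gte(r$max, r$nominal)
  expect_true(all(r$values >= 0 & r$values <= 1))
  r2 <- robustnessSweep(plan, shiftRadius = 1, sigmaScale = 0.2,
                        nMembers = 3, seed = 11)
  expect_identical(r$values, r2$values)
})

test_that("robustness ensemble members match brute-force re-solves", {
  plan <- twoPairCasePlan()
  n <- 2
  r <- robustnessSweep(plan, shiftRadius = 1.5, sigmaScale = 0.2,
                       nMembers = n, seed = 5, includeNominal = FALSE)
  expect_identical(length(r$values), as.integer(n))
  # regenerate the same perturbations independently and re-solve
  set.seed(5)
  codes <- tissueProperties(plan@tissues)$code
  vals <- numeric(0)
  for (m in seq_len(n)) {
    els <- lapply(electrodes(plan@array), function(e) {
      repeat {
        v <- runif(3, -1, 1)
        if (sum(v^2) <= 1) break
      }
      needleElectrode(e@id, e@entry + 1.5 * v, e@tip + 1.5 * v,
                      e@activeTipLength, e@radius)
    })
    arr <- electrodeArray(els, insertionDirection(plan@array))
    tis <- scaleTissueConductivity(
      plan@tissues, setNames(runif(length(codes), 0.8, 1.2),
                             as.character(codes)))
    p <- treatmentPlan(plan@phantom, arr, plan@schedule, tis,
                       plan@settings, plan@marginWidth)
    cum <- cumulativeField(solveSchedule(p))
    erev <- tissueProperties(tis)$e_rev[tissueProperties(tis)$code == 1]
    vals <- c(vals, coverageFraction(cum, tumorMask(plan@phantom), erev))
  }
  expect_equal(r$values, vals, tolerance = 1e-12)
  expect_identical(r$min, min(vals))
})
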