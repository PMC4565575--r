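test_that("sphere voxelization matches brute-force voxel-center membership", {
  shape <- c(40, 40, 40)
  ph <- makePhantom(shape, 1,
                    tumors = list(list(center = c(20, 20, 20),
                                       diameter = 20.3)))
  expect_identical(sum(tumorMask(ph)),
                   bruteSphereCount(shape, 1, c(20, 20, 20), 20.3 / 2))
  # and is close to the analytic sphere volume
  vol <- sum(tumorMask(ph)) * 1
  expect_lt(abs(vol - 4 / 3 * pi * 10.15^3) / (4 / 3 * pi * 10.15^3), 0.05)
})

test_that("voxelized sphere volume converges to the analytic volume", {
  # 20 mm sphere at 0.25 mm spacing: volume error < 2%
  shape <- c(96, 96, 96)
  ph <- makePhantom(shape, 0.25,
                    tumors = list(list(center = c(12, 12, 12),
                                       diameter = 20)))
  vol <- sum(tumorMask(ph)) * 0.25^3
  expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
})

test_that("empty configuration yields an all-background phantom", {
  ph <- makePhantom(c(10, 12, 14), 0.8)
  expect_true(all(labelArray(ph) == 0L))
  expect_identical(dim(labelArray(ph)), c(10L, 12L, 14L))
})

test_that("overlapping or out-of-grid solids raise configuration errors", {
  expect_error(
    makePhantom(c(40, 40, 40), 1,
                tumors = list(list(center = c(20, 20, 20), diameter = 20)),
                bone = list(normal = c(1, 0, 0), offset = 25, thickness = 5)),
    "overlap")
  expect_error(
    makePhantom(c(40, 40, 40), 1,
                tumors = list(list(center = c(5, 20, 20), diameter = 20))),
    "outside the grid")
})

test_that("tumor, vessel and bone masks are pairwise disjoint", {
  ph <- makePhantom(c(60, 60, 40), 1,
                    tumors = list(list(center = c(20, 20, 20), diameter = 16)),
                    vessel = list(point = c(40, 40, 0),
                                  direction = c(0, 0, 1), radius = 3),
                    bone = list(normal = c(1, 0, 0), offset = 52,
                                thickness = 8))
  expect_false(any(tumorMask(ph) & vesselMask(ph)))
  expect_false(any(tumorMask(ph) & boneMask(ph)))
  expect_false(any(vesselMask(ph) & boneMask(ph)))
  expect_true(all(c(sum(tumorMask(ph)), sum(vesselMask(ph)),
                    sum(boneMask(ph))) > 0))
})

test_that("safety margin matches brute-force distance computation", {
  # fine spacing so the voxel shell approximates the analytic shell
  shape <- c(72, 72, 72)
  sp <- 0.5
  ph <- makePhantom(shape, sp,
                    tumors = list(list(center = c(18, 18, 18),
                                       diameter = 20)))
  m <- safetyMargin(ph, 5)
  # brute force: distance from each normal voxel center to the nearest
  # tumor voxel center, via direct minimum over the tumor voxel list
  tm <- tumorMask(ph)
  tidx <- which(tm)
  ti <- arrayInd(tidx, shape)
  tx <- (ti[, 1] - 0.5) * sp; ty <- (ti[, 2] - 0.5) * sp
  tz <- (ti[, 3] - 0.5) * sp
  # sample a band of candidate voxels to keep the brute force affordable
  cand <- which(!tm)
  ci <- arrayInd(cand, shape)
  cx <- (ci[, 1] - 0.5) * sp; cy <- (ci[, 2] - 0.5) * sp
  cz <- (ci[, 3] - 0.5) * sp
  keep <- abs(cx - 18) <= 17 & abs(cy - 18) <= 17 & abs(cz - 18) <= 17
  set.seed(7)
  pick <- sample(which(keep), 4000)
  inMargin <- vapply(pick, function(r) {
    min((tx - cx[r])^2 + (ty - cy[r])^2 + (tz - cz[r])^2) <= 25
  }, logical(1))
  expect_identical(unname(m[cand[pick]]), unname(inMargin))
  # shell volume sanity: 4/3 pi (15^3 - 10^3) within a voxelization margin
  shell <- 4 / 3 * pi * (15^3 - 10^3)
  expect_lt(abs(sum(m) * sp^3 - shell) / shell, 0.06)
})

test_that("safety margin is empty at width 0, disjoint from tumor, and monotone in width", {
  ph <- smallTumorPhantom()
  expect_false(any(safetyMargin(ph, 0)))
  m3 <- safetyMargin(ph, 3)
  m5 <- safetyMargin(ph, 5)
  expect_false(any(m3 & tumorMask(ph)))
  expect_true(all(m5[m3])) # width 3 mask contained in width 5 mask
  expect_gt(sum(m5), sum(m3))
  expect_error(safetyMargin(ph, -1), ">= 0")
})

test_that("safety margin excludes vessel and bone voxels", {
  ph <- makePhantom(c(50, 40, 40), 1,
                    tumors = list(list(center = c(20, 20, 20), diameter = 16)),
                    vessel = list(point = c(32, 20, 0),
                                  direction = c(0, 0, 1), radius = 2.5))
  m <- safetyMargin(ph, 5)
  expect_false(any(m & vesselMask(ph)))
  expect_true(any(m)) # still a nonempty belt elsewhere
})

test_that("distance transform agrees with pairwise brute force on a tiny grid", {
  set.seed(42)
  d <- c(7, 6, 5)
  sp <- c(0.8, 1.1, 1.4)
  mask <- array(runif(prod(d)) < 0.12, d)
  mask[3, 3, 3] <- TRUE
  dt <- ectoplan:::cpp_edt_sq(array(as.integer(mask), d), sp)
  idx <- which(mask)
  mi <- arrayInd(idx, d)
  for (p in seq_len(prod(d))) {
    pi <- arrayInd(p, d)
    dd <- min(((mi[, 1] - pi[1]) * sp[1])^2 + ((mi[, 2] - pi[2]) * sp[2])^2 +
                ((mi[, 3] - pi[3]) * sp[3])^2)
    expect_equal(dt[p], dd, tolerance = 1e-12)
  }
})

test_that("phantom round-trips through NIfTI", {
  ph <- makePhantom(c(24, 20, 18), c(0.5, 0.5, 1),
                    origin = c(-3, 2, 0),
                    tumors = list(list(center = c(3, 6, 9), diameter = 7)))
  f <- tempfile(fileext = ".nii.gz")
  writeVolumeNifti(ph, f)
  ph2 <- readPhantomNifti(f)
  expect_identical(labelArray(ph2), labelArray(ph))
  expect_equal(voxelSpacing(ph2), voxelSpacing(ph), tolerance = 1e-6)
  expect_equal(gridOrigin(ph2), gridOrigin(ph), tolerance = 1e-5)
})

test_that("phantom builds from a YAML config with mm units", {
  cfg <- list(shape = c(30, 30, 30), spacing_mm = 1,
              tumors = list(list(center_mm = c(15, 15, 15),
                                 diameter_mm = 10)),
              vessel = list(point_mm = c(25, 15, 0), direction = c(0, 0, 1),
                            radius_mm = 2))
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  ph <- phantomFromConfig(f)
  ph2 <- phantomFromConfig(cfg)
  expect_identical(labelArray(ph), labelArray(ph2))
  expect_true(sum(tumorMask(ph)) > 0 && sum(vesselMask(ph)) > 0)
})
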