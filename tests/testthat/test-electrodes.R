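test_that("star array reproduces the clinical spacings", {
  arr <- starArray(c(0, 0, 0), c(0, 0, 1), centerToOuter = 10)
  tips <- vapply(electrodes(arr), function(e) e@tip, numeric(3))
  ids <- electrodeIds(arr)
  ctr <- tips[, ids == 5]
  for (i in 1:4)
    expect_equal(sqrt(sum((tips[, ids == i] - ctr)^2)), 10, tolerance = 1e-9)
  # adjacent peripheral pairs: 1.4 cm after rounding to one decimal
  d12 <- sqrt(sum((tips[, ids == 1] - tips[, ids == 2])^2))
  expect_identical(round(d12 / 10, 1), 1.4)
  # diagonal (opposite) peripheral distance is twice the star radius
  d13 <- sqrt(sum((tips[, ids == 1] - tips[, ids == 3])^2))
  expect_equal(d13, 20, tolerance = 1e-9)
})

test_that("star needles are parallel and rotation leaves geometry invariant", {
  u <- c(1, 2, 3) / sqrt(14)
  arr <- starArray(c(10, 10, 10), u)
  dirs <- vapply(electrodes(arr), function(e) {
    v <- e@tip - e@entry
    v / sqrt(sum(v^2))
  }, numeric(3))
  for (i in 1:5) expect_equal(unname(dirs[, i]), u, tolerance = 1e-12)
  # pairwise tip distances are invariant under a different insertion
  # direction (rigid rotation of the whole array)
  pd <- function(a) {
    tips <- vapply(electrodes(a), function(e) e@tip, numeric(3))
    sort(as.vector(dist(t(tips))))
  }
  arr2 <- starArray(c(10, 10, 10), c(0, 1, 0))
  expect_equal(pd(arr), pd(arr2), tolerance = 1e-9)
})

test_that("non-parallel needles are rejected by validity", {
  e1 <- needleElectrode(1, c(0, 0, 0), c(0, 0, 30))
  e2 <- needleElectrode(2, c(10, 0, 0), c(10, 2, 30)) # ~3.8 deg off
  expect_error(electrodeArray(list(e1, e2), c(0, 0, 1)), "deviates")
})

test_that("star schedule follows the clinical pairing and pulse count", {
  arr <- starArray(c(0, 0, 0), c(0, 0, 1))
  s <- starSchedule(arr)
  e <- scheduleEntries(s)
  expect_identical(nrow(e), 8L)
  expect_identical(totalPulses(s), 64L)
  expect_identical(paste(e$anode, e$cathode, sep = "-"),
                   c("1-2", "1-4", "2-3", "3-4", "2-5", "1-5", "3-5", "4-5"))
  expect_identical(e$voltage, c(rep(1200, 4), rep(1000, 4)))
  # every 1000 V pair involves the central electrode (id 5)
  expect_true(all(e$cathode[e$voltage == 1000] == 5))
  s1 <- starSchedule(arr, nPulses = 1)
  expect_identical(totalPulses(s1), 8L)
})

test_that("non-star arrays are rejected by the star scheduler", {
  e1 <- needleElectrode(1, c(0, 0, 0), c(0, 0, 30))
  e2 <- needleElectrode(2, c(10, 0, 0), c(10, 0, 30))
  expect_error(starSchedule(electrodeArray(list(e1, e2))), "pulseSchedule")
})

test_that("voltage-to-distance ratio matches the clinical rule of thumb", {
  arr <- starArray(c(0, 0, 0), c(0, 0, 1), centerToOuter = 10)
  s <- scheduleEntries(starSchedule(arr))
  co <- s[s$anode == 1 & s$cathode == 5, ]
  expect_equal(voltageToDistanceRatio(co, arr), 1000, tolerance = 1e-9)
  oo <- s[s$anode == 1 & s$cathode == 2, ]
  expect_equal(voltageToDistanceRatio(oo, arr), 1200 / sqrt(2), # ~849 V/cm
               tolerance = 1e-9)
  z <- oo; z$voltage <- 0
  expect_identical(voltageToDistanceRatio(z, arr), 0)
})

test_that("axis-aligned needle rasterizes to a straight voxel column", {
  ph <- makePhantom(c(20, 20, 50), 1)
  e <- needleElectrode(1, c(10.5, 10.5, 0), c(10.5, 10.5, 40),
                       activeTipLength = 30, radius = 0.4)
  m <- rasterizeElectrodes(electrodeArray(list(e)), ph)[["1"]]
  idx <- arrayInd(which(m), dim(m))
  expect_identical(nrow(idx), 30L)
  expect_identical(length(unique(idx[, 1])), 1L)
  expect_identical(length(unique(idx[, 2])), 1L)
  expect_identical(sort(idx[, 3]), 11:40)
})

test_that("rasterized mask voxel count is monotone in radius", {
  ph <- makePhantom(c(30, 30, 50), 0.5)
  counts <- vapply(c(0.4, 0.8, 1.2), function(r) {
    e <- needleElectrode(1, c(7.6, 7.6, 0), c(7.6, 7.6, 20),
                         activeTipLength = 15, radius = r)
    sum(rasterizeElectrodes(electrodeArray(list(e)), ph)[["1"]])
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("rasterization rejects tips outside the grid and overlapping electrodes", {
  ph <- makePhantom(c(20, 20, 30), 1)
  out <- needleElectrode(1, c(10, 10, 0), c(10, 10, 40),
                         activeTipLength = 30)
  expect_error(rasterizeElectrodes(electrodeArray(list(out)), ph),
               "outside the grid")
  a <- needleElectrode(1, c(10, 10, 0), c(10, 10, 25), activeTipLength = 20,
                       radius = 0.6)
  b <- needleElectrode(2, c(10.4, 10, 0), c(10.4, 10, 25),
                       activeTipLength = 20, radius = 0.6)
  expect_error(rasterizeElectrodes(electrodeArray(list(a, b)), ph),
               "overlap")
})

test_that("two separated electrodes rasterize to disjoint masks", {
  fx <- twoNeedleFixture(1)
  expect_false(any(fx$masks[[1]] & fx$masks[[2]]))
  expect_lte(abs(sum(fx$masks[[1]]) - sum(fx$masks[[2]])), 1)
})

test_that("collision check flags vessel and bone intersections", {
  ph <- makePhantom(c(60, 40, 40), 1,
                    vessel = list(point = c(30, 20, 0),
                                  direction = c(0, 0, 1), radius = 3),
                    bone = list(normal = c(1, 0, 0), offset = 50,
                                thickness = 9))
  through <- needleElectrode(1, c(29.5, 19.5, 0), c(29.5, 19.5, 35),
                             activeTipLength = 30)
  v <- checkCollisions(electrodeArray(list(through)), ph)
  expect_identical(v$tissue, "vessel")
  clear <- needleElectrode(1, c(10, 10, 0), c(10, 10, 35),
                           activeTipLength = 30)
  expect_identical(nrow(checkCollisions(electrodeArray(list(clear)), ph)), 0L)
  # radius inflation: a shaft whose axis clears the bone voxel centers by
  # 0.5 mm collides at radius 0.6 but not at radius 0.3
  near <- needleElectrode(1, c(50, 19.5, 0), c(50, 19.5, 35),
                          activeTipLength = 30, radius = 0.6)
  vb <- checkCollisions(electrodeArray(list(near)), ph)
  expect_true("bone" %in% vb$tissue)
  thin <- needleElectrode(1, c(50, 19.5, 0), c(50, 19.5, 35),
                          activeTipLength = 30, radius = 0.3)
  expect_false("bone" %in% checkCollisions(electrodeArray(list(thin)), ph)$tissue)
})

test_that("plan JSON round-trips electrodes, schedule and tissues", {
  arr <- starArray(c(20, 20, 12), c(0, 0, 1))
  plan <- treatmentPlan(smallTumorPhantom(), arr, starSchedule(arr))
  f <- tempfile(fileext = ".json")
  writePlanJson(plan, f)
  p2 <- readPlanJson(f, phantom = plan@phantom)
  expect_equal(scheduleEntries(p2@schedule), scheduleEntries(plan@schedule))
  expect_equal(tissueProperties(p2@tissues), tissueProperties(plan@tissues))
  e1 <- electrodes(plan@array); e2 <- electrodes(p2@array)
  for (i in seq_along(e1)) {
    expect_identical(e2[[i]]@id, e1[[i]]@id)
    expect_equal(e2[[i]]@tip, e1[[i]]@tip, tolerance = 1e-12)
    expect_equal(e2[[i]]@entry, e1[[i]]@entry, tolerance = 1e-12)
  }
  expect_identical(p2@marginWidth, plan@marginWidth)
})
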