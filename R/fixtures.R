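## Deterministic generation of study-like and validation fixtures.

#' Study-like head-and-neck case fixture
#'
#' A complete plan emulating the clinical configuration this package
#' models: a near-spherical lymph-node metastasis (diameter 20.3 mm for
#' lesion 1, 20.6 mm for lesion 2), a 4 mm-radius vessel cylinder 8 mm
#' from the tumor surface, a bone slab at the far grid edge, the 5-needle
#' star array centered on the tumor (1 cm center-to-outer spacing, 3 cm
#' active tips) and the clinical pulse schedule (1200 V outer-outer then
#' 1000 V center-outer, 8 pulses per pair, 64 total). The native planning
#' resolution is 0.57 mm; pass a coarser `spacing` for fast analyses. The
#' vessel and bone placement is synthetic (chosen so that a naively
#' shifted trajectory collides with the vessel); the construction is fully
#' deterministic.
#'
#' @param metastasis 1 or 2 (sets the tumor diameter).
#' @param spacing isotropic voxel size in mm (default 0.57).
#' @param settings solver settings for the returned plan.
#' @return a [TreatmentPlan-class].
#' @export
ectCaseFixture <- function(metastasis = 1, spacing = 0.57,
                           settings = solverSettings()) {
  stopifnot(metastasis %in% c(1, 2))
  diameter <- if (metastasis == 1) 20.3 else 20.6
  # domain sized so the insulating boundary stays >= 1.5 array diameters
  # (30 mm) away from every electrode
  L <- c(80, 80, 90)
  shape <- round(L / spacing)
  ctr <- c(40, 40, 45)
  phantom <- makePhantom(
    shape, spacing,
    tumors = list(list(center = ctr, diameter = diameter)),
    vessel = list(point = c(ctr[1] + diameter / 2 + 12, ctr[2], 0),
                  direction = c(0, 0, 1), radius = 4),
    bone = list(normal = c(0, 1, 0), offset = 74, thickness = 10))
  arr <- starArray(ctr, c(0, 0, 1), centerToOuter = 10, activeTip = 30,
                   radius = 0.6)
  arr <- clipEntriesToGrid(arr, phantom)
  sched <- starSchedule(arr)
  treatmentPlan(phantom, arr, sched, tissueDefaults(), settings,
                marginWidth = 5)
}

#' Two-needle analytic validation fixture
#'
#' A homogeneous soft-tissue block with two parallel needles (radius
#' 0.5 mm, axis separation 10 mm, 30 mm active tips) padded per the solver
#' boundary policy. With electroporation disabled, the predicted current
#' can be checked against the closed-form conductance per unit length of
#' two parallel cylinders, `G/L = pi * sigma / acosh(d / (2 a))`.
#'
#' @param spacing isotropic voxel size in mm (<= 1).
#' @return list: `phantom`, `array`, `masks` (rasterized electrode masks),
#'   `separation_mm`, `radius_mm`, `activeTip_mm`.
#' @export
twoNeedleFixture <- function(spacing = 0.5) {
  if (spacing > 1) stop("spacing must be <= 1 mm for this fixture")
  L <- c(41, 31, 60)
  shape <- round(L / spacing)
  phantom <- makePhantom(shape, spacing)
  tipz <- 45
  # axes at x = 15.25 / 25.25 keep the needles off voxel faces at the
  # fixture's 0.5 and 1 mm spacings, so the two rasters are exact
  # translates of each other
  mk <- function(id, x) needleElectrode(
    id, entry = c(x, 15.25, 0), tip = c(x, 15.25, tipz),
    activeTipLength = 30, radius = 0.5)
  arr <- electrodeArray(list(mk(1L, 15.25), mk(2L, 25.25)))
  list(phantom = phantom, array = arr,
       masks = rasterizeElectrodes(arr, phantom),
       separation_mm = 10, radius_mm = 0.5, activeTip_mm = 30)
}

#' Closed-form two-cylinder current
#'
#' Analytic current between two parallel cylindrical conductors of radius
#' `a` and axis separation `d` in an infinite homogeneous medium,
#' per-unit-length conductance `pi * sigma / acosh(d/(2a))` times the
#' active length.
#'
#' @param sigma medium conductivity (S/m).
#' @param voltage applied voltage (V).
#' @param separation_mm axis separation d (mm).
#' @param radius_mm cylinder radius a (mm).
#' @param length_mm active length (mm).
#' @return current in A.
#' @export
twoCylinderCurrent <- function(sigma, voltage, separation_mm, radius_mm,
                               length_mm) {
  G <- pi * sigma / acosh(separation_mm / (2 * radius_mm)) *
    (length_mm / 1000)
  G * voltage
}

#' Small slab fixture for optimizer and objective tests
#'
#' A coarse, quickly solvable phantom: small tumor sphere centered in a
#' modest grid, no vessel or bone, 2 mm default spacing. Intended for
#' exhaustive-enumeration checks of the optimizer.
#'
#' @param spacing voxel size (mm).
#' @param tumorDiameter tumor diameter (mm).
#' @return a [VoxelPhantom-class].
#' @export
toySlabPhantom <- function(spacing = 2, tumorDiameter = 12) {
  L <- c(48, 48, 60)
  shape <- round(L / spacing)
  makePhantom(shape, spacing,
              tumors = list(list(center = c(24, 24, 30),
                                 diameter = tumorDiameter)))
}
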