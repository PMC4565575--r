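## Needle electrodes, the star array, rasterization and collision checks.

#' Construct a needle electrode
#'
#' @param id integer electrode label.
#' @param entry,tip world points (mm); the needle runs from `entry` to
#'   `tip`, with the distal `activeTipLength` mm conductive.
#' @param activeTipLength active (uninsulated) tip length in mm; default
#'   30 mm as for clinical single long needle electrodes.
#' @param radius needle radius in mm. The hardware radius is not part of
#'   the clinical protocol; 0.6 mm is a typical long-needle value and is an
#'   assumption of this package.
#' @return a [NeedleElectrode-class].
#' @export
needleElectrode <- function(id, entry, tip, activeTipLength = 30,
                            radius = 0.6) {
  new("NeedleElectrode", id = as.integer(id), entry = as.numeric(entry),
      tip = as.numeric(tip), activeTipLength = as.numeric(activeTipLength),
      radius = as.numeric(radius))
}

#' Construct an electrode array from needles
#'
#' @param electrodes list of [NeedleElectrode-class] objects.
#' @param insertionDirection shared unit direction; defaults to the
#'   direction of the first needle. All needles must be parallel to it
#'   within 1 degree.
#' @return an [ElectrodeArray-class].
#' @export
electrodeArray <- function(electrodes, insertionDirection = NULL) {
  if (is.null(insertionDirection)) {
    e1 <- electrodes[[1]]
    insertionDirection <- .unit(e1@tip - e1@entry)
  }
  new("ElectrodeArray", electrodes = electrodes,
      insertionDirection = as.numeric(.unit(insertionDirection)))
}

# deterministic orthonormal basis of the plane normal to u
.planeBasis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- .unit(c(u[2] * ref[3] - u[3] * ref[2],
                u[3] * ref[1] - u[1] * ref[3],
                u[1] * ref[2] - u[2] * ref[1]))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Build the 5-electrode star array
#'
#' One central needle through `center` and four peripheral needles at
#' `centerToOuter` mm from it, at 90 degree angular spacing in the plane
#' normal to the insertion direction (a square: with the clinical 1 cm
#' center-to-outer distance, adjacent peripheral needles are 1.4 cm apart).
#' Peripheral needles carry ids 1-4 (counter-clockwise); the central needle
#' is id 5. All tips lie at equal depth and the active tip is centered on
#' `center` along the insertion direction.
#'
#' @param center world point (mm) the central needle passes through
#'   (typically the tumor center).
#' @param insertionDirection nonzero direction vector of all needles.
#' @param centerToOuter center-to-center distance (mm) from the central to
#'   each peripheral needle; clinical default 10 mm.
#' @param activeTip active tip length (mm), default 30.
#' @param radius needle radius (mm), default 0.6.
#' @param entryDistance distance (mm) from each tip back along the
#'   insertion direction to the nominal entry point, default 60. Use
#'   [clipEntriesToGrid()] to move entries onto the grid face.
#' @return an [ElectrodeArray-class] of 5 parallel needles.
#' @examples
#' arr <- starArray(c(0, 0, 0), c(0, 0, 1))
#' # adjacent peripheral needles are sqrt(2) * 10 mm ~ 1.4 cm apart
#' @export
starArray <- function(center, insertionDirection, centerToOuter = 10,
                      activeTip = 30, radius = 0.6, entryDistance = 60) {
  u <- .unit(insertionDirection)
  b <- .planeBasis(u)
  offsets <- list(b$e1, b$e2, -b$e1, -b$e2) # ids 1..4, counter-clockwise
  tipCenter <- center + (activeTip / 2) * u
  mk <- function(id, lateral) {
    tip <- tipCenter + lateral
    needleElectrode(id, entry = tip - entryDistance * u, tip = tip,
                    activeTipLength = activeTip, radius = radius)
  }
  els <- c(lapply(1:4, function(i) mk(i, centerToOuter * offsets[[i]])),
           list(mk(5L, c(0, 0, 0))))
  electrodeArray(els, u)
}

#' Move nominal entry points onto a grid face
#'
#' Slides each needle's entry point along its own axis to the point where
#' the trajectory crosses the grid boundary (nudged half a voxel inside, so
#' the entry maps to an in-grid voxel for trajectory export).
#'
#' @param array an [ElectrodeArray-class].
#' @param phantom the [VoxelPhantom-class] defining the grid.
#' @return a new [ElectrodeArray-class].
#' @export
clipEntriesToGrid <- function(array, phantom) {
  sp <- voxelSpacing(phantom)
  o <- gridOrigin(phantom)
  hi <- o + dim(labelArray(phantom)) * sp
  eps <- min(sp) / 2
  els <- lapply(electrodes(array), function(e) {
    u <- .unit(e@tip - e@entry)
    # largest t such that tip - t*u stays inside [o, hi]
    tmax <- Inf
    for (a in 1:3) {
      if (u[a] > 0) tmax <- min(tmax, (e@tip[a] - o[a]) / u[a])
      else if (u[a] < 0) tmax <- min(tmax, (e@tip[a] - hi[a]) / u[a])
    }
    tmax <- max(e@activeTipLength, tmax - eps)
    needleElectrode(e@id, entry = e@tip - tmax * u, tip = e@tip,
                    activeTipLength = e@activeTipLength, radius = e@radius)
  })
  electrodeArray(els, insertionDirection(array))
}

# TRUE if the array has the 5-needle star topology: ids 1-5 with needle 5
# equidistant (within tol) from the four others
.isStar <- function(array, tol = 1e-6) {
  ids <- electrodeIds(array)
  if (length(ids) != 5L || !setequal(ids, 1:5)) return(FALSE)
  tips <- vapply(electrodes(array), function(e) e@tip, numeric(3))
  colnames(tips) <- as.character(ids)
  ctr <- tips[, "5"]
  d <- vapply(as.character(1:4), function(i) sqrt(sum((tips[, i] - ctr)^2)),
              numeric(1))
  diff(range(d)) <= tol * max(d)
}

#' Star pulse-pair schedule
#'
#' The clinical protocol for the 5-needle star: the four adjacent
#' outer-outer pairs at `vOuterOuter` (1200 V) followed by the four
#' center-outer pairs at `vCenterOuter` (1000 V), each pair receiving
#' `nPulses` pulses of `pulseDurationUs` microseconds (8 x 100 us; 64
#' pulses in total for one lesion). Pair order: 1-2, 1-4, 2-3, 3-4, then
#' 2-5, 1-5, 3-5, 4-5.
#'
#' @param array a 5-needle star [ElectrodeArray-class] (ids 1-4 peripheral,
#'   5 central); other arrays are rejected — build a [pulseSchedule()]
#'   explicitly for generic arrays.
#' @param vCenterOuter,vOuterOuter pair voltages (V).
#' @param nPulses pulses per pair.
#' @param pulseDurationUs pulse duration (us).
#' @return a [PulseSchedule-class] with 8 entries.
#' @export
starSchedule <- function(array, vCenterOuter = 1000, vOuterOuter = 1200,
                         nPulses = 8, pulseDurationUs = 100) {
  if (!.isStar(array))
    stop("array is not a 5-needle star; use pulseSchedule() with an explicit pair list")
  pairs <- rbind(c(1, 2), c(1, 4), c(2, 3), c(3, 4),
                 c(2, 5), c(1, 5), c(3, 5), c(4, 5))
  volts <- c(rep(vOuterOuter, 4), rep(vCenterOuter, 4))
  pulseSchedule(pairs, volts, nPulses, pulseDurationUs)
}

#' Construct a pulse schedule from explicit pairs
#'
#' @param pairs 2-column matrix of electrode id pairs (anode, cathode), one
#'   row per entry, delivered in row order.
#' @param voltages voltage (V) per entry (recycled if scalar).
#' @param nPulses,pulseDurationUs pulses per pair and pulse duration (us).
#' @return a [PulseSchedule-class].
#' @export
pulseSchedule <- function(pairs, voltages, nPulses = 8,
                          pulseDurationUs = 100) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  new("PulseSchedule", entries = data.frame(
    anode = pairs[, 1], cathode = pairs[, 2],
    voltage = as.numeric(rep_len(voltages, nrow(pairs))),
    n_pulses = as.integer(rep_len(nPulses, nrow(pairs))),
    pulse_duration_us = as.numeric(rep_len(pulseDurationUs, nrow(pairs)))))
}

# needle axis separation (mm) for a schedule entry; for parallel needles
# this equals the tip center-to-center distance
.pairDistance <- function(array, anode, cathode) {
  ids <- electrodeIds(array)
  ea <- electrodes(array)[[match(anode, ids)]]
  ec <- electrodes(array)[[match(cathode, ids)]]
  .distToLine(ea@tip, ec@tip, .unit(ec@tip - ec@entry))
}

#' Voltage-to-distance ratio of a schedule entry
#'
#' The rule-of-thumb field estimate used with long needle electrodes:
#' applied voltage divided by the center-to-center electrode distance,
#' adjusted in practice to approximately 1000 V/cm.
#'
#' @param entry one row of [scheduleEntries()] (or a list with `anode`,
#'   `cathode`, `voltage`).
#' @param array the [ElectrodeArray-class] the ids refer to.
#' @return ratio in V/cm.
#' @export
voltageToDistanceRatio <- function(entry, array) {
  d_mm <- .pairDistance(array, entry$anode, entry$cathode)
  if (d_mm <= 1e-9) stop("coincident electrodes: pair distance is zero")
  entry$voltage / (d_mm / 10)
}

#' Rasterize active tips into the voxel grid
#'
#' Each electrode's active-tip segment is converted to the set of voxels
#' whose centers lie within the needle radius of the segment (inclusive),
#' plus the voxels the segment itself traverses (the axis is inside the
#' needle, so a sub-voxel-radius needle still rasterizes to a connected
#' column). These voxels carry the boundary potential in the field solve.
#' The insulated shaft above the active tip (entry to the start of the
#' active segment, clipped to the grid) is rasterized the same way and
#' attached as the `"shaft"` attribute of each mask: during a solve it is
#' modelled as non-conductive, shielding the tissue it passes through.
#'
#' @param array an [ElectrodeArray-class].
#' @param phantom the [VoxelPhantom-class] defining the grid.
#' @return named list of logical 3-D masks, one per electrode id
#'   (names are the ids), each carrying attributes `wireGeom` (sub-cell
#'   boundary coupling factor) and `shaft` (logical mask of the insulated
#'   shaft).
#' @export
rasterizeElectrodes <- function(array, phantom) {
  shape <- dim(labelArray(phantom))
  sp <- voxelSpacing(phantom)
  o <- gridOrigin(phantom)
  ax <- .axisCenters(shape, sp, o)

  # voxels within rIncl of segment [a, b] (flat face at a, optionally a
  # rounded cap at b), plus voxels the segment traverses; silently clipped
  # to the grid. The flat face models the transition into the insulated
  # shaft; the rounded cap models the needle tip.
  rasterSegment <- function(a, b, rIncl, capB = FALSE) {
    m <- array(FALSE, shape)
    len <- sqrt(sum((b - a)^2))
    if (len == 0) return(m)
    lo <- pmin(a, b) - rIncl - sp
    hi <- pmax(a, b) + rIncl + sp
    rng <- lapply(1:3, function(ai) which(ax[[ai]] >= lo[ai] & ax[[ai]] <= hi[ai]))
    if (all(lengths(rng) > 0)) {
      sub <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
      px <- ax[[1]][sub$i]; py <- ax[[2]][sub$j]; pz <- ax[[3]][sub$k]
      u <- (b - a) / len
      t <- ((px - a[1]) * u[1] + (py - a[2]) * u[2] + (pz - a[3]) * u[3])
      r2 <- (px - a[1])^2 + (py - a[2])^2 + (pz - a[3])^2 - t^2
      keep <- t >= -1e-9 & t <= len + 1e-9 & r2 <= rIncl^2 + 1e-9
      if (capB)
        keep <- keep | ((px - b[1])^2 + (py - b[2])^2 + (pz - b[3])^2 <=
                          rIncl^2 + 1e-9)
      m[cbind(sub$i, sub$j, sub$k)[keep, , drop = FALSE]] <- TRUE
    }
    nstep <- max(2L, ceiling(len / (min(sp) / 4)))
    # nudge sample endpoints inward so a segment end lying exactly on a
    # voxel face does not claim the voxel beyond it
    eps <- min(min(sp) * 1e-3, len / 4) / len
    t <- seq(eps, 1 - eps, length.out = nstep)
    pts <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
                 a[3] + t * (b[3] - a[3]))
    inb <- pts[, 1] >= o[1] & pts[, 1] <= o[1] + shape[1] * sp[1] &
      pts[, 2] >= o[2] & pts[, 2] <= o[2] + shape[2] * sp[2] &
      pts[, 3] >= o[3] & pts[, 3] <= o[3] + shape[3] * sp[3]
    if (any(inb)) {
      vox <- sweep(sweep(pts[inb, , drop = FALSE], 2, o, "-"), 2, sp, "/")
      vox <- pmin(pmax(floor(vox), 0),
                  matrix(shape - 1L, nrow(vox), 3, byrow = TRUE)) + 1L
      m[unique(vox)] <- TRUE
    }
    m
  }

  masks <- list()
  for (e in electrodes(array)) {
    seg <- .activeSegment(e)
    if (!.insideGrid(seg$a, shape, sp, o) || !.insideGrid(seg$b, shape, sp, o))
      stop(sprintf("active tip of electrode %d lies outside the grid", e@id))
    wire <- .wireCalibrate(e, phantom)
    m <- rasterSegment(seg$a, seg$b, wire$rIncl, capB = TRUE)
    if (!any(m))
      stop(sprintf("electrode %d rasterizes to no voxels", e@id))
    # sub-cell boundary treatment: per-voxel geometric coupling factor (m)
    attr(m, "wireGeom") <-
      2 * pi * (e@activeTipLength / sum(m) / 1000) / wire$lnr
    shaft <- rasterSegment(e@entry, seg$a, e@radius)
    shaft[m] <- FALSE # the junction voxel belongs to the active tip
    attr(m, "shaft") <- shaft
    masks[[as.character(e@id)]] <- m
  }
  for (i in seq_along(masks)) for (j in seq_len(i - 1L)) {
    if (any(masks[[i]] & masks[[j]]))
      stop(sprintf("electrodes %s and %s overlap on the grid (too close for this spacing)",
                   names(masks)[j], names(masks)[i]))
  }
  masks
}

#' Check electrode trajectories against vessels and bone
#'
#' An admissible plan requires that no needle shaft (entry to tip, inflated
#' by the needle radius) intersects a vessel or bone voxel. Intersection is
#' tested against voxel centers, consistent with the phantom's voxel-center
#' membership convention.
#'
#' @param array an [ElectrodeArray-class].
#' @param phantom a [VoxelPhantom-class].
#' @return data.frame of violations with columns `electrode` and `tissue`
#'   (zero rows for an admissible plan).
#' @export
checkCollisions <- function(array, phantom) {
  shape <- dim(labelArray(phantom))
  sp <- voxelSpacing(phantom)
  o <- gridOrigin(phantom)
  lab <- labelArray(phantom)
  out <- data.frame(electrode = integer(), tissue = character())
  crit <- which(lab == .LABELS[["vessel"]] | lab == .LABELS[["bone"]])
  if (!length(crit)) return(out)
  idx <- arrayInd(crit, shape)
  px <- o[1] + (idx[, 1] - 0.5) * sp[1]
  py <- o[2] + (idx[, 2] - 0.5) * sp[2]
  pz <- o[3] + (idx[, 3] - 0.5) * sp[3]
  codes <- lab[crit]
  for (e in electrodes(array)) {
    d2 <- .distSqToSegment(px, py, pz, e@entry, e@tip)
    hit <- d2 <= e@radius^2 + 1e-9
    if (any(hit)) {
      for (code in unique(codes[hit])) {
        out <- rbind(out, data.frame(
          electrode = e@id,
          tissue = names(.LABELS)[match(code, .LABELS)]))
      }
    }
  }
  out
}
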