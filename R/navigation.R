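## Navigation export and placement-error metrics.

#' Mark planned trajectories in a volume
#'
#' Writes the planned needle trajectories into a copy of the input volume
#' the way an image-guided navigation workflow expects them: the entry and
#' tip of every needle are marked by setting the containing voxel's
#' intensity to `markerValue` (3000 by default, a value far outside the
#' soft-tissue intensity range). The marker voxel is the voxel containing
#' the world point (`floor((world - origin)/spacing)`); single voxels, no
#' spheres. Because the guidance system controls entry point and angle but
#' not depth, the planned insertion length (entry-to-tip distance, mm) is
#' reported per electrode for intra-operative ruler measurement.
#'
#' @param volume 3-D array, or a [VoxelPhantom-class] whose label volume is
#'   marked.
#' @param array an [ElectrodeArray-class]; all entries and tips must map to
#'   in-grid voxels.
#' @param markerValue intensity written at marker voxels.
#' @param spacing,origin grid geometry (mm); taken from the phantom when
#'   `volume` is a [VoxelPhantom-class].
#' @return a [TrajectoryExport-class]. If two markers fall into one voxel a
#'   warning is raised, the voxel is marked once and both markers are
#'   listed.
#' @export
markTrajectories <- function(volume, array, markerValue = 3000,
                             spacing = NULL, origin = NULL) {
  if (is(volume, "VoxelPhantom")) {
    spacing <- voxelSpacing(volume)
    origin <- gridOrigin(volume)
    volume <- labelArray(volume)
  }
  if (is.null(spacing) || is.null(origin))
    stop("spacing and origin are required for a bare array volume")
  shape <- dim(volume)
  markers <- data.frame(electrode = integer(), role = character(),
                        i = integer(), j = integer(), k = integer(),
                        x = numeric(), y = numeric(), z = numeric())
  for (e in electrodes(array)) {
    for (role in c("entry", "tip")) {
      p <- if (role == "entry") e@entry else e@tip
      i0 <- .worldToIndex0(p, spacing, origin)
      if (any(i0 < 0) || any(i0 >= shape))
        stop(sprintf("%s of electrode %d maps outside the grid", role, e@id))
      markers <- rbind(markers, data.frame(
        electrode = e@id, role = role,
        i = i0[1] + 1L, j = i0[2] + 1L, k = i0[3] + 1L,
        x = p[1], y = p[2], z = p[3]))
    }
  }
  vox <- markers[, c("i", "j", "k")]
  if (anyDuplicated(vox))
    warning("two markers fall into the same voxel; the voxel is marked once, both markers are listed")
  out <- volume
  if (nrow(vox)) out[as.matrix(unique(vox))] <- markerValue
  lens <- data.frame(
    electrode = electrodeIds(array),
    insertion_length_mm = vapply(electrodes(array), function(e)
      sqrt(sum((e@tip - e@entry)^2)), numeric(1)))
  new("TrajectoryExport", volume = out, markers = markers,
      markerValue = as.numeric(markerValue), insertionLengths = lens)
}

#' Electrode placement error
#'
#' Distance (3-D, point to line) from an achieved entry point to the
#' planned trajectory, in mm and in pixels of the planning image. At the
#' 0.57 mm pixel size of a typical planning CT, a 2-pixel deviation is
#' 1.14 mm.
#'
#' @param planned the planned [NeedleElectrode-class].
#' @param achievedEntry world point (mm) where the needle actually entered.
#' @param pixelSize planning-image pixel size (mm, > 0).
#' @return list: `error_mm`, `error_pixels`.
#' @export
placementError <- function(planned, achievedEntry, pixelSize) {
  if (pixelSize <= 0) stop("pixelSize must be > 0")
  axis <- planned@tip - planned@entry
  if (sqrt(sum(axis^2)) == 0) stop("degenerate trajectory: entry equals tip")
  mm <- .distToLine(as.numeric(achievedEntry), planned@entry, .unit(axis))
  list(error_mm = mm, error_pixels = mm / pixelSize)
}
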