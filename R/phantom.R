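## Synthetic voxel anatomy.

#' Generate a synthetic voxel phantom
#'
#' Builds a labelled voxel volume from geometric solids: tumor spheres, an
#' optional vessel cylinder and an optional bone slab, embedded in normal
#' soft tissue. Voxel membership is decided by voxel-center inclusion (a
#' voxel belongs to a solid iff its center lies inside it); no
#' partial-volume handling. Solids must be disjoint and tumor spheres (and
#' finite vessel segments) must fit inside the grid; violations raise
#' configuration errors rather than being resolved by precedence.
#'
#' @param shape integer(3), voxel counts per axis.
#' @param spacing numeric, mm per voxel (scalar or length 3).
#' @param origin numeric(3), world coordinate (mm) of the grid corner.
#' @param tumors list of spheres, each `list(center = c(x,y,z), diameter)`
#'   in mm.
#' @param vessel optional cylinder `list(point, direction, radius, length)`
#'   (mm); `length = Inf` (default) spans the grid.
#' @param bone optional slab `list(normal, offset, thickness)`: voxels whose
#'   center satisfies `offset <= <center, unit(normal)> <= offset + thickness`
#'   (mm), clipped by the grid.
#' @return a [VoxelPhantom-class].
#' @examples
#' ph <- makePhantom(c(40, 40, 40), spacing = 1,
#'                   tumors = list(list(center = c(20, 20, 20), diameter = 20)))
#' sum(tumorMask(ph)) * prod(voxelSpacing(ph)) # close to 4/3*pi*10^3
#' @export
makePhantom <- function(shape, spacing, origin = c(0, 0, 0),
                        tumors = list(), vessel = NULL, bone = NULL) {
  shape <- as.integer(shape)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(shape) == 3, all(shape > 0), all(spacing > 0))
  hi <- origin + shape * spacing

  co <- .coordArrays(shape, spacing, origin)
  masks <- list()

  tmask <- array(FALSE, shape)
  for (tu in tumors) {
    r <- tu$diameter / 2
    ctr <- tu$center
    if (any(ctr - r < origin) || any(ctr + r > hi))
      stop("configuration error: tumor sphere extends outside the grid")
    d2 <- (co$X - ctr[1])^2 + (co$Y - ctr[2])^2 + (co$Z - ctr[3])^2
    tmask <- tmask | (d2 <= r^2)
  }
  masks$tumor <- tmask

  if (!is.null(vessel)) {
    u <- .unit(vessel$direction)
    len <- if (is.null(vessel$length)) Inf else vessel$length
    if (is.finite(len)) {
      a <- vessel$point; b <- vessel$point + len * u
      if (!.insideGrid(a, shape, spacing, origin) ||
          !.insideGrid(b, shape, spacing, origin))
        stop("configuration error: vessel segment extends outside the grid")
      d2 <- .distSqToSegment(co$X, co$Y, co$Z, a, b)
    } else {
      wx <- co$X - vessel$point[1]
      wy <- co$Y - vessel$point[2]
      wz <- co$Z - vessel$point[3]
      dot <- wx * u[1] + wy * u[2] + wz * u[3]
      d2 <- pmax(0, wx^2 + wy^2 + wz^2 - dot^2)
    }
    masks$vessel <- d2 <= (vessel$radius)^2
  }

  if (!is.null(bone)) {
    n <- .unit(bone$normal)
    proj <- co$X * n[1] + co$Y * n[2] + co$Z * n[3]
    masks$bone <- proj >= bone$offset & proj <= bone$offset + bone$thickness
  }

  nm <- names(masks)
  for (i in seq_along(masks)) for (j in seq_len(i - 1L)) {
    if (any(masks[[i]] & masks[[j]]))
      stop(sprintf("configuration error: %s and %s solids overlap",
                   nm[j], nm[i]))
  }

  labels <- array(.LABELS[["normal"]], shape)
  labels[masks$tumor] <- .LABELS[["tumor"]]
  if (!is.null(masks$vessel)) labels[masks$vessel] <- .LABELS[["vessel"]]
  if (!is.null(masks$bone)) labels[masks$bone] <- .LABELS[["bone"]]
  storage.mode(labels) <- "integer"

  new("VoxelPhantom", labels = labels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Safety-margin mask around the tumor
#'
#' The safety margin is the belt of normal tissue around the tumor that the
#' plan must also cover above the reversible electroporation threshold (up
#' to 5 mm wide in the clinical workflow this models). The mask is the
#' Euclidean dilation of the tumor by `width` mm (spacing-aware distance
#' transform in world mm, so anisotropic grids are handled correctly), minus
#' the tumor itself, restricted to normal-tissue voxels (vessel and bone
#' excluded).
#'
#' @param phantom a [VoxelPhantom-class].
#' @param width margin width in mm (>= 0); `0` gives an empty mask.
#' @return logical 3-D array.
#' @export
safetyMargin <- function(phantom, width) {
  if (width < 0) stop("margin width must be >= 0")
  tm <- tumorMask(phantom)
  if (width == 0 || !any(tm)) return(array(FALSE, dim(tm)))
  d2 <- cpp_edt_sq(array(as.integer(tm), dim(tm)), voxelSpacing(phantom))
  (d2 <= width^2) & !tm & normalMask(phantom)
}
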