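## Internal world/voxel geometry helpers.
## Convention: 0-based voxel indices in formulas; the center of voxel
## (i,j,k) is origin + (index + 0.5) * spacing. R arrays are 1-based, so the
## center of labels[i,j,k] is origin + (i - 0.5) * spacing.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length direction vector")
  v / n
}

# coordinate vectors of voxel centers along each axis (mm)
.axisCenters <- function(shape, spacing, origin) {
  lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 0.5) * spacing[a])
}

# full coordinate arrays (mm); three arrays of dim = shape
.coordArrays <- function(shape, spacing, origin) {
  ax <- .axisCenters(shape, spacing, origin)
  list(
    X = array(rep(ax[[1]], times = shape[2] * shape[3]), dim = shape),
    Y = array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), dim = shape),
    Z = array(rep(ax[[3]], each = shape[1] * shape[2]), dim = shape)
  )
}

# squared distance of points (px,py,pz) to the segment [a,b]
.distSqToSegment <- function(px, py, pz, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return((px - a[1])^2 + (py - a[2])^2 + (pz - a[3])^2)
  }
  t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] + (pz - a[3]) * ab[3]) / len2
  t <- pmin(1, pmax(0, t))
  (px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2 +
    (pz - (a[3] + t * ab[3]))^2
}

# distance of a point to the infinite line through a with direction u (unit)
.distToLine <- function(p, a, u) {
  w <- p - a
  sqrt(max(0, sum(w^2) - sum(w * u)^2))
}

# world point -> 0-based voxel index (floor((world - origin)/spacing))
.worldToIndex0 <- function(p, spacing, origin) {
  floor((p - origin) / spacing)
}

.insideGrid <- function(p, shape, spacing, origin) {
  all(p >= origin) && all(p <= origin + shape * spacing)
}

# active-tip segment endpoints of a needle (distal activeTipLength mm)
.activeSegment <- function(e) {
  u <- .unit(e@tip - e@entry)
  list(a = e@tip - e@activeTipLength * u, b = e@tip)
}
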