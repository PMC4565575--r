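## TreatmentPlan construction and coarsening.

#' Construct a treatment plan
#'
#' @param phantom a [VoxelPhantom-class].
#' @param array an [ElectrodeArray-class].
#' @param schedule a [PulseSchedule-class] referencing the array's ids.
#' @param tissues a [TissueTable-class]; defaults to [tissueDefaults()].
#' @param settings solver settings, see [solverSettings()].
#' @param marginWidth safety-margin width in mm (default 5, the clinical
#'   margin this workflow models).
#' @return a [TreatmentPlan-class].
#' @export
treatmentPlan <- function(phantom, array, schedule,
                          tissues = tissueDefaults(),
                          settings = solverSettings(), marginWidth = 5) {
  new("TreatmentPlan", phantom = phantom, array = array, schedule = schedule,
      tissues = tissues, settings = settings,
      marginWidth = as.numeric(marginWidth))
}

#' Coarsen a phantom by integer subsampling
#'
#' Takes every `factor`-th voxel along each axis (stride subsampling of the
#' labels, nearest-neighbour semantics) and scales the spacing accordingly,
#' keeping retained voxel centers at their world positions. Used to score
#' candidate plans cheaply during optimization.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param factor integer >= 1.
#' @return a [VoxelPhantom-class].
#' @export
coarsenPhantom <- function(phantom, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1L) return(phantom)
  lab <- labelArray(phantom)
  d <- dim(lab)
  ii <- lapply(d, function(n) seq(1L, n, by = factor))
  lab2 <- lab[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
  sp <- voxelSpacing(phantom)
  sp2 <- sp * factor
  # keep the center of retained voxel 1 fixed: origin' + S/2 = origin + s/2
  o2 <- gridOrigin(phantom) + sp / 2 - sp2 / 2
  new("VoxelPhantom", labels = lab2, spacing = sp2, origin = o2)
}
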