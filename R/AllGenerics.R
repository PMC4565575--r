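## Generics and accessors.

#' @rdname VoxelPhantom-class
#' @param object,x an object.
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname VoxelPhantom-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname VoxelPhantom-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname VoxelPhantom-class
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))
#' @rdname VoxelPhantom-class
#' @export
setGeneric("vesselMask", function(x) standardGeneric("vesselMask"))
#' @rdname VoxelPhantom-class
#' @export
setGeneric("boneMask", function(x) standardGeneric("boneMask"))
#' @rdname VoxelPhantom-class
#' @export
setGeneric("normalMask", function(x) standardGeneric("normalMask"))

#' @rdname ElectrodeArray-class
#' @export
setGeneric("electrodes", function(x) standardGeneric("electrodes"))
#' @rdname ElectrodeArray-class
#' @export
setGeneric("insertionDirection", function(x) standardGeneric("insertionDirection"))
#' @rdname ElectrodeArray-class
#' @export
setGeneric("electrodeIds", function(x) standardGeneric("electrodeIds"))

#' @rdname PulseSchedule-class
#' @export
setGeneric("scheduleEntries", function(x) standardGeneric("scheduleEntries"))
#' @rdname PulseSchedule-class
#' @export
setGeneric("totalPulses", function(x) standardGeneric("totalPulses"))

#' @rdname TissueTable-class
#' @export
setGeneric("tissueProperties", function(x) standardGeneric("tissueProperties"))

#' @rdname FieldSolution-class
#' @export
setGeneric("fieldMagnitude", function(x) standardGeneric("fieldMagnitude"))
#' @rdname FieldSolution-class
#' @export
setGeneric("potentialGrid", function(x) standardGeneric("potentialGrid"))
#' @rdname FieldSolution-class
#' @export
setGeneric("predictedCurrent", function(x) standardGeneric("predictedCurrent"))

#' @rdname CoverageReport-class
#' @param e field strength (V/cm).
#' @export
setGeneric("tumorCoverageAt", function(x, e) standardGeneric("tumorCoverageAt"))
#' @rdname CoverageReport-class
#' @export
setGeneric("marginCoverageAt", function(x, e) standardGeneric("marginCoverageAt"))
#' @rdname CoverageReport-class
#' @export
setGeneric("cvhTable", function(x) standardGeneric("cvhTable"))

#' @rdname VoxelPhantom-class
setMethod("labelArray", "VoxelPhantom", function(x) x@labels)
#' @rdname VoxelPhantom-class
setMethod("voxelSpacing", "VoxelPhantom", function(x) x@spacing)
#' @rdname VoxelPhantom-class
setMethod("gridOrigin", "VoxelPhantom", function(x) x@origin)
#' @rdname VoxelPhantom-class
setMethod("tumorMask", "VoxelPhantom", function(x) x@labels == .LABELS[["tumor"]])
#' @rdname VoxelPhantom-class
setMethod("vesselMask", "VoxelPhantom", function(x) x@labels == .LABELS[["vessel"]])
#' @rdname VoxelPhantom-class
setMethod("boneMask", "VoxelPhantom", function(x) x@labels == .LABELS[["bone"]])
#' @rdname VoxelPhantom-class
setMethod("normalMask", "VoxelPhantom", function(x) x@labels == .LABELS[["normal"]])

#' @rdname ElectrodeArray-class
setMethod("electrodes", "ElectrodeArray", function(x) x@electrodes)
#' @rdname ElectrodeArray-class
setMethod("insertionDirection", "ElectrodeArray", function(x)
  x@insertionDirection / sqrt(sum(x@insertionDirection^2)))
#' @rdname ElectrodeArray-class
setMethod("electrodeIds", "ElectrodeArray", function(x)
  vapply(x@electrodes, function(e) e@id, integer(1)))

#' @rdname PulseSchedule-class
setMethod("scheduleEntries", "PulseSchedule", function(x) x@entries)
#' @rdname PulseSchedule-class
setMethod("totalPulses", "PulseSchedule", function(x) sum(x@entries$n_pulses))

#' @rdname TissueTable-class
setMethod("tissueProperties", "TissueTable", function(x) x@properties)

#' @rdname FieldSolution-class
setMethod("fieldMagnitude", "FieldSolution", function(x) x@fieldMagnitude)
#' @rdname FieldSolution-class
setMethod("potentialGrid", "FieldSolution", function(x) x@potential)
#' @rdname FieldSolution-class
setMethod("predictedCurrent", "FieldSolution", function(x) x@current)

#' @rdname CoverageReport-class
setMethod("cvhTable", "CoverageReport", function(x) x@cvh)
#' @rdname CoverageReport-class
setMethod("tumorCoverageAt", "CoverageReport", function(x, e)
  coverageFraction(x@cumulativeField, x@tumorMask, e))
#' @rdname CoverageReport-class
setMethod("marginCoverageAt", "CoverageReport", function(x, e)
  coverageFraction(x@cumulativeField, x@marginMask, e))

## show methods -------------------------------------------------------------

setMethod("show", "VoxelPhantom", function(object) {
  d <- dim(object@labels)
  cat(sprintf("VoxelPhantom: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  tab <- table(factor(object@labels, levels = .LABELS,
                      labels = names(.LABELS)))
  vol <- prod(object@spacing)
  for (nm in names(tab))
    cat(sprintf("  %-7s %9d voxels (%.0f mm^3)\n", nm, tab[[nm]],
                tab[[nm]] * vol))
})

setMethod("show", "ElectrodeArray", function(object) {
  cat(sprintf("ElectrodeArray: %d needle electrode(s)\n",
              length(object@electrodes)))
  for (e in object@electrodes)
    cat(sprintf("  id %d: tip (%s) mm, active %g mm, radius %g mm\n", e@id,
                paste(format(e@tip, digits = 4), collapse = ", "),
                e@activeTipLength, e@radius))
})

setMethod("show", "PulseSchedule", function(object) {
  cat(sprintf("PulseSchedule: %d pair(s), %d pulses total\n",
              nrow(object@entries), totalPulses(object)))
  print(object@entries, row.names = FALSE)
})

setMethod("show", "TissueTable", function(object) {
  cat("TissueTable:\n")
  print(object@properties, row.names = FALSE)
})

setMethod("show", "FieldSolution", function(object) {
  cat(sprintf(
    "FieldSolution: pair %d-%d at %g V, predicted current %.2f A (%s, %d iteration(s))\n",
    object@pair[1], object@pair[2], object@voltage, object@current,
    if (object@converged) "converged" else "NOT converged",
    object@iterations))
})

setMethod("show", "TreatmentPlan", function(object) {
  cat("TreatmentPlan\n")
  show(object@phantom)
  show(object@array)
  show(object@schedule)
  cat(sprintf("safety margin: %g mm\n", object@marginWidth))
})

setMethod("show", "CoverageReport", function(object) {
  cat("CoverageReport\n")
  s <- object@summary
  for (nm in names(s)) cat(sprintf("  %-28s %.4f\n", nm, s[[nm]]))
  if (length(object@robustness))
    cat(sprintf("  robustness (tumor coverage): min %.4f / mean %.4f / max %.4f over %d member(s)\n",
                object@robustness$min, object@robustness$mean,
                object@robustness$max, length(object@robustness$values)))
})

setMethod("show", "TrajectoryExport", function(object) {
  cat(sprintf("TrajectoryExport: %d marker(s) at value %g\n",
              nrow(object@markers), object@markerValue))
})
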