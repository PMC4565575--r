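## S4 classes for the planning pipeline.

#' VoxelPhantom: labelled voxel anatomy
#'
#' A 3-D integer label grid with world geometry. Label codes: 0 = background
#' / normal tissue, 1 = tumor, 2 = vessel, 3 = bone. Voxel indices are
#' 0-based in world-coordinate formulas: the center of voxel (i,j,k) lies at
#' `origin + (index + 0.5) * spacing`; axes are axis-aligned (no orientation
#' matrix).
#'
#' @slot labels integer 3-D array of label codes.
#' @slot spacing numeric(3), mm per voxel along each axis (all > 0).
#' @slot origin numeric(3), world coordinate (mm) of the corner of voxel
#'   (0,0,0).
#' @export
setClass("VoxelPhantom",
  representation(labels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must be a 3-D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (length(object@origin) != 3L)
      msg <- c(msg, "origin must have 3 components (mm)")
    if (!all(object@labels %in% .LABELS))
      msg <- c(msg, "labels must be drawn from the code set {0,1,2,3}")
    if (length(msg)) msg else TRUE
  })

#' TissueTable: electrical tissue properties
#'
#' Per-tissue baseline conductivity and electroporation parameters. For each
#' tissue code the table holds `sigma0` (baseline conductivity, S/m),
#' `sigma_factor` (multiplicative conductivity increase when fully
#' electroporated, dimensionless, >= 1), and the reversible / irreversible
#' electroporation thresholds `e_rev` < `e_irrev` (V/cm) for the pulse
#' protocol in use (8 x 100 us here).
#'
#' @slot properties data.frame with columns `code`, `tissue`, `sigma0`,
#'   `sigma_factor`, `e_rev`, `e_irrev`.
#' @export
setClass("TissueTable",
  representation(properties = "data.frame"),
  validity = function(object) {
    p <- object@properties
    need <- c("code", "tissue", "sigma0", "sigma_factor", "e_rev", "e_irrev")
    if (!all(need %in% names(p)))
      return(paste("properties must have columns:", paste(need, collapse = ", ")))
    msg <- character()
    if (anyDuplicated(p$code)) msg <- c(msg, "duplicate tissue codes")
    if (any(p$sigma0 <= 0)) msg <- c(msg, "sigma0 must be > 0")
    if (any(p$sigma_factor < 1)) msg <- c(msg, "sigma_factor must be >= 1")
    if (any(p$e_rev <= 0) || any(p$e_rev >= p$e_irrev))
      msg <- c(msg, "thresholds must satisfy 0 < e_rev < e_irrev")
    if (length(msg)) msg else TRUE
  })

#' NeedleElectrode: a single long needle electrode
#'
#' Only the distal `activeTipLength` mm of the needle (the uninsulated
#' active tip) imposes boundary potential; the insulated shaft is used for
#' collision checking only.
#'
#' @slot id integer electrode label.
#' @slot entry numeric(3), world point (mm) where the needle enters the grid.
#' @slot tip numeric(3), world point (mm) of the needle tip.
#' @slot activeTipLength numeric, mm of conductive distal segment.
#' @slot radius numeric, needle radius in mm.
#' @export
setClass("NeedleElectrode",
  representation(id = "integer", entry = "numeric", tip = "numeric",
                 activeTipLength = "numeric", radius = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@entry) != 3L || length(object@tip) != 3L)
      msg <- c(msg, "entry and tip must be 3-D world points (mm)")
    len <- sqrt(sum((object@tip - object@entry)^2))
    if (len == 0) msg <- c(msg, "entry and tip must differ")
    if (object@activeTipLength <= 0 || object@activeTipLength > len + 1e-9)
      msg <- c(msg, "activeTipLength must be positive and <= needle length")
    if (object@radius <= 0) msg <- c(msg, "radius must be > 0")
    if (length(msg)) msg else TRUE
  })

#' ElectrodeArray: a set of parallel needle electrodes
#'
#' All needles must be parallel to the shared insertion direction within an
#' angular tolerance of 1 degree, so that inter-electrode distances stay
#' constant along the active region.
#'
#' @slot electrodes list of [NeedleElectrode-class] objects.
#' @slot insertionDirection numeric(3) unit vector shared by all needles.
#' @export
setClass("ElectrodeArray",
  representation(electrodes = "list", insertionDirection = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(vapply(object@electrodes, is, logical(1), "NeedleElectrode")))
      return("electrodes must be a list of NeedleElectrode objects")
    d <- object@insertionDirection
    if (length(d) != 3L || sqrt(sum(d^2)) == 0)
      return("insertionDirection must be a nonzero 3-vector")
    d <- d / sqrt(sum(d^2))
    ids <- vapply(object@electrodes, function(e) e@id, integer(1))
    if (anyDuplicated(ids)) msg <- c(msg, "electrode ids must be unique")
    for (e in object@electrodes) {
      u <- (e@tip - e@entry)
      u <- u / sqrt(sum(u^2))
      ang <- acos(pmin(1, abs(sum(u * d)))) * 180 / pi
      if (ang > 1)
        msg <- c(msg, sprintf("electrode %d deviates %.2f deg from the insertion direction (tolerance 1 deg)", e@id, ang))
    }
    if (length(msg)) msg else TRUE
  })

#' PulseSchedule: ordered electrode-pair pulse protocol
#'
#' Each row is one pair activation: anode and cathode electrode ids, applied
#' voltage (V), number of pulses and pulse duration (us). Rows are delivered
#' in order.
#'
#' @slot entries data.frame with columns `anode`, `cathode`, `voltage`,
#'   `n_pulses`, `pulse_duration_us`.
#' @export
setClass("PulseSchedule",
  representation(entries = "data.frame"),
  validity = function(object) {
    p <- object@entries
    need <- c("anode", "cathode", "voltage", "n_pulses", "pulse_duration_us")
    if (!all(need %in% names(p)))
      return(paste("entries must have columns:", paste(need, collapse = ", ")))
    msg <- character()
    if (any(p$anode == p$cathode)) msg <- c(msg, "anode and cathode must differ")
    if (any(p$voltage < 0)) msg <- c(msg, "voltages must be >= 0")
    if (any(p$n_pulses <= 0)) msg <- c(msg, "n_pulses must be > 0")
    if (any(p$pulse_duration_us <= 0)) msg <- c(msg, "pulse_duration_us must be > 0")
    if (length(msg)) msg else TRUE
  })

#' FieldSolution: solved field for one electrode pair
#'
#' Result of the nonlinear electrostatic solve for a single pair activation:
#' the potential grid (V), the field-magnitude grid (V/cm), the converged
#' post-electroporation conductivity grid (S/m), and the predicted delivered
#' current (A).
#'
#' @slot potential numeric 3-D array, V.
#' @slot fieldMagnitude numeric 3-D array, V/cm.
#' @slot conductivity numeric 3-D array, S/m (electrode voxels carry the
#'   metal conductivity used in the solve).
#' @slot current numeric, predicted current (A), measured as the net flux
#'   out of the energized electrode.
#' @slot cathodeCurrent numeric, magnitude of the flux into the grounded
#'   electrode (A); should match `current` up to discretization error.
#' @slot pair integer(2), (anode id, cathode id).
#' @slot voltage numeric, applied voltage (V).
#' @slot spacing,origin grid geometry (mm), copied from the phantom.
#' @slot iterations integer, fixed-point iterations used.
#' @slot converged logical.
#' @slot residual numeric, final relative change of the predicted current.
#' @export
setClass("FieldSolution",
  representation(potential = "array", fieldMagnitude = "array",
                 conductivity = "array", current = "numeric",
                 cathodeCurrent = "numeric", pair = "integer",
                 voltage = "numeric", spacing = "numeric", origin = "numeric",
                 iterations = "integer", converged = "logical",
                 residual = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@fieldMagnitude < 0)) msg <- c(msg, "field magnitude must be >= 0")
    if (object@voltage > 0 && object@current <= 0)
      msg <- c(msg, "current must be > 0 for positive voltage")
    lo <- min(0, object@voltage); hi <- max(0, object@voltage)
    tol <- 1e-6 * max(1, abs(object@voltage))
    if (min(object@potential) < lo - tol || max(object@potential) > hi + tol)
      msg <- c(msg, "potential must be bounded by the applied boundary values")
    if (length(msg)) msg else TRUE
  })

#' TreatmentPlan: the serializable unit of planning work
#'
#' Bundles the anatomy, electrode array, pulse schedule, tissue properties
#' and solver settings that together define one deliverable plan.
#'
#' @slot phantom [VoxelPhantom-class].
#' @slot array [ElectrodeArray-class].
#' @slot schedule [PulseSchedule-class].
#' @slot tissues [TissueTable-class].
#' @slot settings list of solver settings (see [solverSettings()]).
#' @slot marginWidth numeric, safety-margin width in mm.
#' @export
setClass("TreatmentPlan",
  representation(phantom = "VoxelPhantom", array = "ElectrodeArray",
                 schedule = "PulseSchedule", tissues = "TissueTable",
                 settings = "list", marginWidth = "numeric"),
  validity = function(object) {
    ids <- vapply(object@array@electrodes, function(e) e@id, integer(1))
    used <- unique(c(object@schedule@entries$anode, object@schedule@entries$cathode))
    if (!all(used %in% ids))
      return("schedule references electrode ids absent from the array")
    if (object@marginWidth < 0) return("marginWidth must be >= 0")
    TRUE
  })

#' CoverageReport: cumulative coverage of a delivered plan
#'
#' @slot cumulativeField numeric 3-D array (V/cm), voxelwise maximum over
#'   the delivered pairs.
#' @slot perPair data.frame with one row per schedule entry: pair label,
#'   voltage, predicted current, and tumor coverage of the running cumulative
#'   field at the tumor reversible threshold.
#' @slot cvh data.frame (threshold, tumor fraction, margin fraction).
#' @slot tumorMask,marginMask logical 3-D arrays.
#' @slot thresholds numeric, named: `tumor_e_rev`, `normal_e_rev`,
#'   `normal_e_irrev` (V/cm) used for the summary fractions.
#' @slot summary named numeric: tumor/margin coverage at the reversible
#'   thresholds, min tumor field, overreach fraction.
#' @slot robustness list (possibly empty) as returned by
#'   [robustnessSweep()].
#' @export
setClass("CoverageReport",
  representation(cumulativeField = "array", perPair = "data.frame",
                 cvh = "data.frame", tumorMask = "array", marginMask = "array",
                 thresholds = "numeric", summary = "numeric",
                 robustness = "list"),
  validity = function(object) {
    if (nrow(object@cvh) &&
        is.unsorted(-object@cvh$tumor_fraction, strictly = FALSE))
      return("CVH tumor fractions must be nonincreasing in threshold")
    TRUE
  })

#' TrajectoryExport: navigation-ready marked volume
#'
#' @slot volume numeric/integer 3-D array: copy of the input volume with
#'   entry and tip voxels set to the marker value.
#' @slot markers data.frame: electrode id, role (entry/tip), 1-based voxel
#'   indices, world coordinates (mm).
#' @slot markerValue numeric.
#' @slot insertionLengths data.frame: electrode id, planned insertion length
#'   (mm) from entry to tip.
#' @export
setClass("TrajectoryExport",
  representation(volume = "array", markers = "data.frame",
                 markerValue = "numeric", insertionLengths = "data.frame"))
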