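## NIfTI volume I/O, plan JSON, phantom config YAML/JSON.

#' Write a phantom or grid to NIfTI
#'
#' Label volumes are written as integer data, field/potential grids as
#' floating point. The voxel spacing goes into `pixdim` and the grid
#' origin into the qform translation (NIfTI voxel coordinates address
#' voxel centers, so the translation is `origin + spacing/2`).
#'
#' @param x a [VoxelPhantom-class], or a 3-D array (then `spacing` and
#'   `origin` are required).
#' @param file output path (`.nii` or `.nii.gz`).
#' @param spacing,origin grid geometry (mm) for bare arrays.
#' @return the file path, invisibly.
#' @export
writeVolumeNifti <- function(x, file, spacing = NULL, origin = NULL) {
  if (is(x, "VoxelPhantom")) {
    spacing <- voxelSpacing(x)
    origin <- gridOrigin(x)
    x <- labelArray(x)
  }
  if (is.null(spacing) || is.null(origin))
    stop("spacing and origin are required when writing a bare array")
  im <- RNifti::asNifti(x)
  RNifti::pixdim(im) <- spacing
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin + spacing / 2
  RNifti::qform(im) <- structure(aff, code = 2L)
  dtype <- if (is.integer(x)) "int16" else "double"
  RNifti::writeNifti(im, file, datatype = dtype)
  invisible(file)
}

#' Read a label volume into a phantom
#'
#' @param file NIfTI path written by [writeVolumeNifti()] (or any integer
#'   label volume with codes 0-3).
#' @return a [VoxelPhantom-class].
#' @export
readPhantomNifti <- function(file) {
  im <- RNifti::readNifti(file)
  sp <- RNifti::pixdim(im)[1:3]
  aff <- RNifti::xform(im)
  origin <- aff[1:3, 4] - sp / 2
  lab <- as.array(im)
  storage.mode(lab) <- "integer"
  attributes(lab) <- list(dim = dim(im))
  new("VoxelPhantom", labels = lab, spacing = as.numeric(sp),
      origin = as.numeric(origin))
}

## ---- plan serialization ---------------------------------------------------

.arrayToList <- function(array) {
  list(
    insertion_direction = as.numeric(insertionDirection(array)),
    electrodes = lapply(electrodes(array), function(e) list(
      id = e@id, entry_mm = as.numeric(e@entry), tip_mm = as.numeric(e@tip),
      active_tip_length_mm = e@activeTipLength, radius_mm = e@radius)))
}

.arrayFromList <- function(x) {
  electrodeArray(
    lapply(x$electrodes, function(e)
      needleElectrode(e$id, unlist(e$entry_mm), unlist(e$tip_mm),
                      e$active_tip_length_mm, e$radius_mm)),
    unlist(x$insertion_direction))
}

#' Serialize a plan to JSON
#'
#' Writes the electrode array, schedule, tissue properties, solver
#' settings and margin width (all lengths in mm, voltages in V). The
#' phantom volume itself is written separately with [writeVolumeNifti()];
#' pass its path as `phantomFile` to record the link.
#'
#' @param plan a [TreatmentPlan-class].
#' @param file output JSON path.
#' @param phantomFile optional path string recorded in the JSON.
#' @return `file`, invisibly.
#' @export
writePlanJson <- function(plan, file, phantomFile = NULL) {
  obj <- list(
    units = list(length = "mm", voltage = "V", conductivity = "S/m",
                 field = "V/cm"),
    array = .arrayToList(plan@array),
    schedule = scheduleEntries(plan@schedule),
    tissues = tissueProperties(plan@tissues),
    settings = plan@settings,
    margin_width_mm = plan@marginWidth,
    phantom_file = phantomFile)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' Read a plan from JSON
#'
#' @param file JSON path from [writePlanJson()].
#' @param phantom a [VoxelPhantom-class]; if `NULL`, the `phantom_file`
#'   recorded in the JSON is read (relative to the JSON's directory).
#' @return a [TreatmentPlan-class].
#' @export
readPlanJson <- function(file, phantom = NULL) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE,
                           simplifyDataFrame = TRUE)
  if (is.null(phantom)) {
    if (is.null(x$phantom_file))
      stop("no phantom given and no phantom_file recorded in the plan")
    pf <- x$phantom_file
    if (!file.exists(pf)) pf <- file.path(dirname(file), pf)
    phantom <- readPhantomNifti(pf)
  }
  arr <- electrodeArray(
    lapply(seq_len(nrow(x$array$electrodes)), function(i) {
      e <- x$array$electrodes[i, ]
      needleElectrode(e$id, unlist(e$entry_mm), unlist(e$tip_mm),
                      e$active_tip_length_mm, e$radius_mm)
    }),
    unlist(x$array$insertion_direction))
  sched <- new("PulseSchedule", entries = as.data.frame(x$schedule))
  tis <- tissueTable(as.data.frame(x$tissues))
  settings <- x$settings
  settings$fpMaxit <- as.integer(settings$fpMaxit)
  settings$pcgMaxit <- as.integer(settings$pcgMaxit)
  treatmentPlan(phantom, arr, sched, tis, settings, x$margin_width_mm)
}

## ---- phantom config -------------------------------------------------------

#' Build a phantom from a YAML/JSON config
#'
#' The config mirrors [makePhantom()]'s arguments with explicit mm units:
#' `shape`, `spacing_mm`, `origin_mm`, `tumors` (list of `center_mm`,
#' `diameter_mm`), optional `vessel` (`point_mm`, `direction`,
#' `radius_mm`, optional `length_mm`) and `bone` (`normal`, `offset_mm`,
#' `thickness_mm`).
#'
#' @param config path to a `.yaml`/`.yml`/`.json` file, or an equivalent
#'   list.
#' @return a [VoxelPhantom-class].
#' @export
phantomFromConfig <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  tumors <- lapply(config$tumors, function(tu)
    list(center = num(tu$center_mm), diameter = as.numeric(tu$diameter_mm)))
  vessel <- if (!is.null(config$vessel)) list(
    point = num(config$vessel$point_mm),
    direction = num(config$vessel$direction),
    radius = as.numeric(config$vessel$radius_mm),
    length = if (is.null(config$vessel$length_mm)) Inf
             else as.numeric(config$vessel$length_mm))
  bone <- if (!is.null(config$bone)) list(
    normal = num(config$bone$normal),
    offset = as.numeric(config$bone$offset_mm),
    thickness = as.numeric(config$bone$thickness_mm))
  makePhantom(as.integer(unlist(config$shape)),
              num(config$spacing_mm),
              origin = if (is.null(config$origin_mm)) c(0, 0, 0)
                       else num(config$origin_mm),
              tumors = tumors, vessel = vessel, bone = bone)
}

#' Export a coverage report
#'
#' Writes the summary as JSON, the CVH as CSV, and optionally the
#' cumulative field grid as NIfTI.
#'
#' @param report a [CoverageReport-class].
#' @param dir output directory (created if needed).
#' @param fieldNifti also write `cumulative_field.nii.gz`.
#' @param spacing,origin grid geometry for the field volume (mm).
#' @return named list of written paths, invisibly.
#' @export
exportCoverageReport <- function(report, dir, fieldNifti = FALSE,
                                 spacing = NULL, origin = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    summary = file.path(dir, "coverage_summary.json"),
    cvh = file.path(dir, "cvh.csv"))
  jsonlite::write_json(
    c(as.list(report@summary),
      list(thresholds = as.list(report@thresholds),
           robustness = if (length(report@robustness))
             report@robustness[c("min", "mean", "max", "nominal")]
           else NULL)),
    paths$summary, auto_unbox = TRUE, digits = NA, null = "null")
  write.csv(report@cvh, paths$cvh, row.names = FALSE)
  if (fieldNifti) {
    paths$field <- file.path(dir, "cumulative_field.nii.gz")
    writeVolumeNifti(report@cumulativeField, paths$field, spacing = spacing,
                     origin = origin)
  }
  invisible(paths)
}
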