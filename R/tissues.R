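## Tissue electrical properties.

#' Default tissue property table
#'
#' Baseline conductivities and electroporation parameters for the four
#' tissue classes of the phantom. The thresholds follow the display
#' convention of field-coverage maps in ECT planning: tumor reversible
#' threshold 400 V/cm, normal soft tissue 350 V/cm (for 8 pulses of
#' 100 us); the irreversible threshold is set to 800 V/cm for all soft
#' tissues. Conductivities are representative literature-range values for
#' soft tissue, tumor, blood and cortical bone at pulse frequencies; fully
#' electroporated soft tissue is modelled as 3.5x more conductive, bone as
#' unchanged. All values are package assumptions, configurable per analysis;
#' none is a measured patient value.
#'
#' @return a [TissueTable-class] with rows for codes 0 (normal), 1 (tumor),
#'   2 (vessel/blood), 3 (bone).
#' @examples
#' tissueProperties(tissueDefaults())
#' @export
tissueDefaults <- function() {
  tissueTable(data.frame(
    code = c(0L, 1L, 2L, 3L),
    tissue = c("normal", "tumor", "vessel", "bone"),
    sigma0 = c(0.2, 0.3, 0.7, 0.02),
    sigma_factor = c(3.5, 3.5, 3.5, 1.0),
    e_rev = c(350, 400, 350, 350),
    e_irrev = c(800, 800, 800, 800)
  ))
}

#' Construct a tissue table
#'
#' @param properties data.frame with columns `code`, `tissue`, `sigma0`
#'   (S/m), `sigma_factor` (>= 1), `e_rev`, `e_irrev` (V/cm).
#' @return a validated [TissueTable-class].
#' @export
tissueTable <- function(properties) {
  properties$code <- as.integer(properties$code)
  new("TissueTable", properties = properties[order(properties$code), ,
                                             drop = FALSE])
}

#' Scale baseline conductivities
#'
#' Multiplies `sigma0` per tissue; used by the robustness sweep to model
#' uncertainty in assumed tissue conductivities.
#'
#' @param tissues a [TissueTable-class].
#' @param factors numeric: scalar, or named by tissue code.
#' @return a new [TissueTable-class].
#' @export
scaleTissueConductivity <- function(tissues, factors) {
  p <- tissueProperties(tissues)
  if (is.null(names(factors))) {
    p$sigma0 <- p$sigma0 * factors
  } else {
    idx <- match(as.integer(names(factors)), p$code)
    if (anyNA(idx)) stop("unknown tissue code in conductivity factors")
    p$sigma0[idx] <- p$sigma0[idx] * factors
  }
  tissueTable(p)
}

# per-voxel parameter grid for a given column of the tissue table
.tissueGrid <- function(phantom, tissues, column) {
  p <- tissueProperties(tissues)
  lab <- labelArray(phantom)
  idx <- match(as.vector(lab), p$code)
  if (anyNA(idx))
    stop("phantom contains label codes absent from the tissue table")
  array(p[[column]][idx], dim(lab))
}
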