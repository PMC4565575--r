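## Cumulative coverage, coverage-volume histograms, robustness.

#' Cumulative field over delivered pairs
#'
#' A voxel is considered treated at the highest field it experiences over
#' the pulse sequence, so the cumulative field is the voxelwise maximum of
#' the per-pair field magnitudes. Prefix subsets of the solution list give
#' the per-pair coverage progression.
#'
#' @param solutions list of [FieldSolution-class] sharing one grid.
#' @return numeric 3-D array (V/cm).
#' @export
cumulativeField <- function(solutions) {
  if (!length(solutions)) stop("no solutions given")
  dims <- dim(fieldMagnitude(solutions[[1]]))
  fields <- lapply(solutions, function(s) {
    f <- fieldMagnitude(s)
    if (!identical(dim(f), dims)) stop("solutions are on mismatched grids")
    f
  })
  Reduce(pmax, fields)
}

#' Fraction of a mask covered at a field threshold
#'
#' @param field numeric 3-D array (V/cm).
#' @param mask logical 3-D array (nonempty).
#' @param threshold V/cm; coverage counts voxels with field `>= threshold`
#'   (inclusive: "at least the strength indicated").
#' @return fraction in `[0, 1]`.
#' @export
coverageFraction <- function(field, mask, threshold) {
  if (!any(mask)) stop("empty mask: coverage fraction undefined")
  mean(field[mask] >= threshold)
}

#' Coverage-volume histogram
#'
#' The fraction of the masked volume that experiences at least each field
#' strength, as a function of that strength — the electroporation analogue
#' of a dose-volume histogram.
#'
#' @param field numeric 3-D array (V/cm).
#' @param mask logical 3-D array.
#' @param thresholds ascending field strengths (V/cm).
#' @return data.frame with columns `threshold`, `fraction` (nonincreasing).
#' @export
coverageVolumeHistogram <- function(field, mask, thresholds) {
  if (is.unsorted(thresholds, strictly = FALSE))
    stop("thresholds must be sorted ascending")
  data.frame(threshold = thresholds,
             fraction = vapply(thresholds, function(th)
               coverageFraction(field, mask, th), numeric(1)))
}

#' Coverage report for a solved plan
#'
#' Aggregates the per-pair solutions of a plan into the cumulative field,
#' per-pair coverage progression, summary coverage fractions at the
#' configured tissue thresholds, and the tumor/margin coverage-volume
#' histogram.
#'
#' @param plan a [TreatmentPlan-class].
#' @param solutions list of [FieldSolution-class] from [solveSchedule()].
#' @param thresholds ascending CVH thresholds (V/cm).
#' @param robustness optional list from [robustnessSweep()] to embed.
#' @return a [CoverageReport-class].
#' @export
coverageReport <- function(plan, solutions,
                           thresholds = seq(0, 1200, by = 50),
                           robustness = list()) {
  tm <- tumorMask(plan@phantom)
  mm <- safetyMargin(plan@phantom, plan@marginWidth)
  cum <- cumulativeField(solutions)
  p <- tissueProperties(plan@tissues)
  th <- c(tumor_e_rev = p$e_rev[p$code == 1L],
          normal_e_rev = p$e_rev[p$code == 0L],
          normal_e_irrev = p$e_irrev[p$code == 0L])

  entries <- scheduleEntries(plan@schedule)
  running <- NULL
  perPair <- do.call(rbind, lapply(seq_along(solutions), function(i) {
    f <- fieldMagnitude(solutions[[i]])
    running <<- if (is.null(running)) f else pmax(running, f)
    data.frame(pair = sprintf("%d-%d", entries$anode[i], entries$cathode[i]),
               voltage = entries$voltage[i],
               current_A = predictedCurrent(solutions[[i]]),
               pair_tumor_coverage = coverageFraction(f, tm, th[["tumor_e_rev"]]),
               cumulative_tumor_coverage =
                 coverageFraction(running, tm, th[["tumor_e_rev"]]))
  }))

  cvh <- data.frame(
    threshold = thresholds,
    tumor_fraction = vapply(thresholds, function(t)
      coverageFraction(cum, tm, t), numeric(1)),
    margin_fraction = if (any(mm)) vapply(thresholds, function(t)
      coverageFraction(cum, mm, t), numeric(1)) else NA_real_)

  overMask <- normalMask(plan@phantom) & !mm
  summary <- c(
    tumor_coverage_e_rev = coverageFraction(cum, tm, th[["tumor_e_rev"]]),
    margin_coverage_e_rev = if (any(mm))
      coverageFraction(cum, mm, th[["normal_e_rev"]]) else NA_real_,
    min_tumor_field = min(cum[tm]),
    normal_overreach_e_irrev = if (any(overMask))
      coverageFraction(cum, overMask, th[["normal_e_irrev"]]) else 0)

  new("CoverageReport", cumulativeField = cum, perPair = perPair, cvh = cvh,
      tumorMask = tm, marginMask = mm, thresholds = th, summary = summary,
      robustness = robustness)
}

#' Robustness of a plan to placement and conductivity uncertainty
#'
#' Re-solves the plan over a seeded ensemble of perturbed copies: each
#' electrode is translated by an independent uniform-in-sphere shift (of at
#' most `shiftRadius` mm, preserving parallelism) and each tissue's
#' baseline conductivity is scaled by an independent uniform factor in
#' `1 +/- sigmaScale`. Reports the minimum, mean and maximum tumor coverage
#' at the tumor reversible threshold over the ensemble. Members whose
#' perturbed electrodes leave the grid are flagged infeasible and excluded
#' (with a warning count).
#'
#' @param plan a [TreatmentPlan-class].
#' @param shiftRadius electrode shift radius, mm (>= 0).
#' @param sigmaScale conductivity scaling half-width (e.g. 0.2 for +/-20%).
#' @param nMembers ensemble size (default 20).
#' @param seed integer seed; the ensemble is seed-deterministic.
#' @param includeNominal include the unperturbed plan as a member.
#' @return list: `min`, `mean`, `max`, `nominal`, `values`,
#'   `n_infeasible`.
#' @export
robustnessSweep <- function(plan, shiftRadius = 1, sigmaScale = 0.2,
                            nMembers = 20, seed = 1, includeNominal = TRUE) {
  if (shiftRadius < 0 || sigmaScale < 0)
    stop("perturbation magnitudes must be >= 0")
  evalCoverage <- function(array, tissues) {
    masks <- rasterizeElectrodes(array, plan@phantom)
    p <- methods::new("TreatmentPlan", phantom = plan@phantom, array = array,
                      schedule = plan@schedule, tissues = tissues,
                      settings = plan@settings, marginWidth = plan@marginWidth)
    sols <- solveSchedule(p, masks)
    cum <- cumulativeField(sols)
    erev <- tissueProperties(tissues)$e_rev[tissueProperties(tissues)$code == 1L]
    coverageFraction(cum, tumorMask(plan@phantom), erev)
  }

  nominal <- evalCoverage(plan@array, plan@tissues)
  if (nMembers == 0)
    return(list(min = nominal, mean = nominal, max = nominal,
                nominal = nominal, values = numeric(0), n_infeasible = 0L))

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  codes <- tissueProperties(plan@tissues)$code
  values <- numeric(0)
  nInfeasible <- 0L
  for (m in seq_len(nMembers)) {
    arr <- plan@array
    if (shiftRadius > 0) {
      els <- lapply(electrodes(arr), function(e) {
        repeat { # uniform in the unit ball by rejection
          v <- runif(3, -1, 1)
          if (sum(v^2) <= 1) break
        }
        shift <- shiftRadius * v
        needleElectrode(e@id, e@entry + shift, e@tip + shift,
                        e@activeTipLength, e@radius)
      })
      arr <- electrodeArray(els, insertionDirection(arr))
    }
    tis <- if (sigmaScale > 0)
      scaleTissueConductivity(plan@tissues, setNames(
        runif(length(codes), 1 - sigmaScale, 1 + sigmaScale),
        as.character(codes)))
    else plan@tissues
    cov <- tryCatch(evalCoverage(arr, tis), error = function(e) NA_real_)
    if (is.na(cov)) nInfeasible <- nInfeasible + 1L else values <- c(values, cov)
  }
  if (nInfeasible > 0L)
    warning(sprintf("%d ensemble member(s) infeasible (electrode left the grid) and excluded",
                    nInfeasible))
  if (includeNominal) values <- c(nominal, values)
  list(min = min(values), mean = mean(values), max = max(values),
       nominal = nominal, values = values, n_infeasible = nInfeasible)
}
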