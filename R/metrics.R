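## Current-prediction QA and plan reports.

#' Signed current-prediction error
#'
#' `100 * (i_comp - i_meas) / i_meas` percent: positive when the model
#' over-predicts the measured current. Reported rounded to the nearest
#' integer percent; set `round = FALSE` for the exact value.
#'
#' @param iMeas measured current (A, > 0).
#' @param iComp computed (predicted) current (A).
#' @param round round to integer percent (reporting convention).
#' @return percent error (vectorized).
#' @examples
#' currentError(21.5, 22.6) # 5
#' @export
currentError <- function(iMeas, iComp, round = TRUE) {
  if (any(iMeas <= 0)) stop("measured current must be > 0")
  e <- 100 * (iComp - iMeas) / iMeas
  if (round) round(e) else e
}

#' Root-mean-square error of predicted currents
#'
#' `sqrt(mean((i_comp - i_meas)^2))` in amperes, reported to one decimal
#' (set `round = FALSE` for the exact value).
#'
#' @param iMeas,iComp equal-length vectors of measured and computed
#'   currents (A).
#' @param round round to one decimal (reporting convention).
#' @return RMSE in A.
#' @export
currentRMSE <- function(iMeas, iComp, round = TRUE) {
  if (!length(iMeas)) stop("empty record list")
  stopifnot(length(iMeas) == length(iComp))
  r <- sqrt(mean((iComp - iMeas)^2))
  if (round) round(r, 1) else r
}

#' Packaged measured-vs-computed current records
#'
#' The per-pair voltages, pulse-generator current readings and
#' model-predicted currents recorded for the two treated head-and-neck
#' lymph-node metastases (8 electrode pairs each) that this package's
#' validation arithmetic reproduces. Used by tests and the demo QA report.
#'
#' @return data.frame: `metastasis`, `pair`, `voltage_V`, `i_meas_A`,
#'   `i_comp_A`.
#' @export
table1Currents <- function() {
  read.csv(system.file("extdata", "table1_currents.csv",
                       package = "ectoplan"),
           colClasses = c("integer", "character", "numeric", "numeric",
                          "numeric"))
}

#' Structured plan/QA report
#'
#' Collects everything a clinician-facing plan printout needs: per-pair
#' voltage, predicted current and voltage-to-distance ratio, coverage
#' summaries at the configured thresholds, the CVH, the robustness summary
#' (if computed) and the collision-constraint check. The report is a plain
#' list, losslessly serializable to JSON.
#'
#' @param plan a [TreatmentPlan-class].
#' @param solutions list of [FieldSolution-class] from [solveSchedule()].
#' @param coverage a [CoverageReport-class] from [coverageReport()].
#' @return nested list.
#' @export
planReport <- function(plan, solutions, coverage) {
  entries <- scheduleEntries(plan@schedule)
  perPair <- lapply(seq_len(nrow(entries)), function(i) {
    list(pair = sprintf("%d-%d", entries$anode[i], entries$cathode[i]),
         voltage_V = entries$voltage[i],
         n_pulses = entries$n_pulses[i],
         predicted_current_A = predictedCurrent(solutions[[i]]),
         voltage_to_distance_V_per_cm =
           voltageToDistanceRatio(entries[i, ], plan@array))
  })
  viol <- checkCollisions(plan@array, plan@phantom)
  list(
    n_pairs = nrow(entries),
    total_pulses = totalPulses(plan@schedule),
    per_pair = perPair,
    coverage = as.list(coverage@summary),
    thresholds_V_per_cm = as.list(coverage@thresholds),
    cvh = coverage@cvh,
    robustness = if (length(coverage@robustness))
      coverage@robustness[c("min", "mean", "max", "nominal", "n_infeasible")]
    else NULL,
    constraints = list(
      collision_free = nrow(viol) == 0L,
      violations = if (nrow(viol)) viol else NULL))
}
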