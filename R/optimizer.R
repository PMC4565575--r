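## Electrode-position and voltage optimization.

#' Define an optimization problem
#'
#' Decision variables are the star-array center (within `centerRadius` mm
#' of the tumor centroid), insertion direction (within a cone around the
#' nominal direction), tip depth offset, and the two voltage levels of the
#' star schedule. Constraints: no vessel/bone collision, electrode raster
#' inside the grid, voltages within `voltageBounds`, and predicted current
#' of every pair below `currentCap` (the pulse-generator limit).
#'
#' @param phantom a [VoxelPhantom-class] (must contain a tumor).
#' @param tissues a [TissueTable-class].
#' @param insertionDirection nominal insertion direction.
#' @param centerToOuter,activeTip,radius star-array template parameters
#'   (mm).
#' @param marginWidth safety-margin width (mm).
#' @param weights numeric(3): objective weights `(w_tumor, w_margin,
#'   w_overreach)`, default `c(1, 0.5, 0.5)`.
#' @param voltageBounds numeric(2), allowed pair voltages (V), default
#'   500-1500 V.
#' @param currentCap device current limit per pulse (A), default 50 A.
#' @param settings solver settings used during scoring.
#' @return a list describing the problem, for [optimizePlan()].
#' @export
optimizationProblem <- function(phantom, tissues = tissueDefaults(),
                                insertionDirection = c(0, 0, 1),
                                centerToOuter = 10, activeTip = 30,
                                radius = 0.6, marginWidth = 5,
                                weights = c(1, 0.5, 0.5),
                                voltageBounds = c(500, 1500),
                                currentCap = 50,
                                settings = solverSettings()) {
  stopifnot(length(voltageBounds) == 2, all(is.finite(voltageBounds)),
            currentCap > 0, length(weights) == 3)
  if (!any(tumorMask(phantom))) stop("phantom contains no tumor to target")
  list(phantom = phantom, tissues = tissues,
       insertionDirection = .unit(insertionDirection),
       centerToOuter = centerToOuter, activeTip = activeTip, radius = radius,
       marginWidth = marginWidth, weights = weights,
       voltageBounds = voltageBounds, currentCap = currentCap,
       settings = settings)
}

#' Plan objective: coverage reward minus normal-tissue overreach
#'
#' `score = w1 * tumor_coverage(e_rev,tumor) + w2 * margin_coverage(e_rev,
#' normal) - w3 * overreach`, where overreach is the fraction of
#' non-margin normal tissue at or above the normal irreversible threshold.
#' Higher is better; a full-coverage plan with no overreach scores
#' `w1 + w2`. The plan must be admissible (no vessel/bone collisions);
#' inadmissible plans raise an error — filter with [checkCollisions()]
#' first.
#'
#' @param plan a [TreatmentPlan-class].
#' @param weights numeric(3) `(w_tumor, w_margin, w_overreach)`.
#' @param solutions optional precomputed [solveSchedule()] result.
#' @return list: `score`, `tumor`, `margin`, `overreach`, `currents` (A per
#'   pair), `totalVoltage`.
#' @export
planObjective <- function(plan, weights = c(1, 0.5, 0.5), solutions = NULL) {
  viol <- checkCollisions(plan@array, plan@phantom)
  if (nrow(viol))
    stop("inadmissible plan: electrode(s) ",
         paste(unique(viol$electrode), collapse = ", "),
         " intersect ", paste(unique(viol$tissue), collapse = "/"))
  if (is.null(solutions)) solutions <- solveSchedule(plan)
  cum <- cumulativeField(solutions)
  p <- tissueProperties(plan@tissues)
  eRevT <- p$e_rev[p$code == 1L]
  eRevN <- p$e_rev[p$code == 0L]
  eIrrN <- p$e_irrev[p$code == 0L]
  tm <- tumorMask(plan@phantom)
  mm <- safetyMargin(plan@phantom, plan@marginWidth)
  over <- normalMask(plan@phantom) & !mm
  tumor <- coverageFraction(cum, tm, eRevT)
  margin <- if (any(mm)) coverageFraction(cum, mm, eRevN) else 1
  overreach <- if (any(over)) coverageFraction(cum, over, eIrrN) else 0
  list(score = weights[1] * tumor + weights[2] * margin -
         weights[3] * overreach,
       tumor = tumor, margin = margin, overreach = overreach,
       currents = vapply(solutions, predictedCurrent, numeric(1)),
       totalVoltage = sum(scheduleEntries(plan@schedule)$voltage))
}

#' Optimizer settings
#'
#' @param nCenters candidate array centers: the tumor centroid plus
#'   `nCenters - 1` seeded draws within `centerRadius` mm of it.
#' @param centerRadius search radius around the tumor centroid (mm).
#' @param nDirections candidate directions: the nominal direction plus
#'   `nDirections - 1` draws in a cone of `coneHalfAngle` degrees.
#' @param coneHalfAngle direction cone half-angle (degrees).
#' @param depthOffsets candidate tip-depth offsets along the insertion
#'   direction (mm).
#' @param vCenterOuterGrid,vOuterOuterGrid candidate voltage levels (V);
#'   `NULL` means a 50 V grid across the problem's voltage bounds.
#' @param budget maximum stage-1 evaluations; if the discrete candidate
#'   space is no larger it is enumerated exhaustively (deterministically),
#'   otherwise a seeded sample of `budget` candidates (always containing
#'   the nominal) is drawn.
#' @param coarsen integer grid-coarsening factor for scoring (default 2);
#'   the returned best plan is re-scored at full resolution.
#' @param descentPasses coordinate-descent passes over (depth, vCO, vOO)
#'   after stage 1, stepping 50 V in voltage and `depthStep` mm in depth.
#' @param depthStep coordinate-descent depth step (mm).
#' @return settings list for [optimizePlan()].
#' @export
optimizerSettings <- function(nCenters = 5, centerRadius = 5,
                              nDirections = 1, coneHalfAngle = 10,
                              depthOffsets = 0, vCenterOuterGrid = NULL,
                              vOuterOuterGrid = NULL, budget = 60,
                              coarsen = 2, descentPasses = 2,
                              depthStep = 2) {
  list(nCenters = nCenters, centerRadius = centerRadius,
       nDirections = nDirections, coneHalfAngle = coneHalfAngle,
       depthOffsets = depthOffsets, vCenterOuterGrid = vCenterOuterGrid,
       vOuterOuterGrid = vOuterOuterGrid, budget = budget, coarsen = coarsen,
       descentPasses = descentPasses, depthStep = depthStep)
}

# lexicographic comparison of candidate evaluations:
# higher score, then higher tumor coverage, then lower overreach, then
# lower total voltage
.betterThan <- function(a, b) {
  if (is.null(b)) return(TRUE)
  keys <- function(x) c(x$score, x$tumor, -x$overreach, -x$totalVoltage)
  ka <- keys(a); kb <- keys(b)
  for (i in seq_along(ka)) {
    if (ka[i] > kb[i] + 1e-12) return(TRUE)
    if (ka[i] < kb[i] - 1e-12) return(FALSE)
  }
  FALSE
}

#' Optimize electrode placement and voltages
#'
#' Coarse-to-fine search: stage 1 evaluates a discrete candidate set over
#' array center, insertion direction, depth and the two star voltage
#' levels (exhaustively when small, otherwise a seeded sample); stage 2
#' runs coordinate descent on depth and the voltage levels in 50 V steps.
#' Candidates are scored with [planObjective()] on a coarsened grid;
#' inadmissible candidates (collisions, raster outside the grid, current
#' above the device cap) are skipped. The best plan is re-scored at full
#' resolution. Deterministic for fixed seed and settings.
#'
#' @param problem from [optimizationProblem()].
#' @param settings from [optimizerSettings()].
#' @param seed integer seed for candidate sampling.
#' @return list: `plan` (best [TreatmentPlan-class] at full resolution),
#'   `score` (full-resolution objective list), `coarseScore`, `trace`
#'   (data.frame of evaluations with best-so-far), `nEvaluated`,
#'   `nAdmissible`.
#' @export
optimizePlan <- function(problem, settings = optimizerSettings(), seed = 1) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  ph <- problem$phantom
  coarse <- coarsenPhantom(ph, settings$coarsen)
  tm <- tumorMask(ph)
  idx <- arrayInd(which(tm), dim(tm))
  centroid <- gridOrigin(ph) + (colMeans(idx) - 0.5) * voxelSpacing(ph)
  u0 <- problem$insertionDirection

  centers <- list(centroid)
  if (settings$nCenters > 1) {
    for (i in seq_len(settings$nCenters - 1)) {
      repeat {
        v <- runif(3, -1, 1)
        if (sum(v^2) <= 1) break
      }
      centers[[i + 1]] <- centroid + settings$centerRadius * v
    }
  }
  dirs <- list(u0)
  if (settings$nDirections > 1) {
    b <- .planeBasis(u0)
    amax <- settings$coneHalfAngle * pi / 180
    for (i in seq_len(settings$nDirections - 1)) {
      ang <- amax * sqrt(runif(1))
      az <- runif(1, 0, 2 * pi)
      dirs[[i + 1]] <- .unit(cos(ang) * u0 +
                               sin(ang) * (cos(az) * b$e1 + sin(az) * b$e2))
    }
  }
  vb <- problem$voltageBounds
  vGrid <- function(g) if (is.null(g)) seq(vb[1], vb[2], by = 50) else g
  vCO <- vGrid(settings$vCenterOuterGrid)
  vOO <- vGrid(settings$vOuterOuterGrid)

  cand <- expand.grid(center = seq_along(centers), dir = seq_along(dirs),
                      depth = settings$depthOffsets, vco = vCO, voo = vOO,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(cand) > settings$budget) {
    keep <- unique(c(1L, sample.int(nrow(cand), settings$budget)))
    cand <- cand[keep[seq_len(min(length(keep), settings$budget))], ,
                 drop = FALSE]
  }

  failures <- character()
  evalCandidate <- function(center, dir, depth, vco, voo, phantom) {
    if (vco < vb[1] || vco > vb[2] || voo < vb[1] || voo > vb[2])
      return(list(ok = FALSE, why = "voltage outside bounds"))
    arr <- starArray(center + depth * dir, dir,
                     centerToOuter = problem$centerToOuter,
                     activeTip = problem$activeTip, radius = problem$radius)
    sched <- starSchedule(arr, vCenterOuter = vco, vOuterOuter = voo)
    viol <- checkCollisions(arr, phantom)
    if (nrow(viol))
      return(list(ok = FALSE, why = paste("collision with",
                                          paste(unique(viol$tissue), collapse = "/"))))
    plan <- treatmentPlan(phantom, arr, sched, problem$tissues,
                          problem$settings, problem$marginWidth)
    res <- tryCatch(planObjective(plan, problem$weights),
                    error = function(e) NULL)
    if (is.null(res)) return(list(ok = FALSE, why = "solve failed or raster outside grid"))
    if (any(res$currents > problem$currentCap))
      return(list(ok = FALSE,
                  why = sprintf("predicted current %.1f A above cap %.1f A",
                                max(res$currents), problem$currentCap)))
    c(list(ok = TRUE, plan = plan, center = center, dir = dir,
           depth = depth, vco = vco, voo = voo), res)
  }

  best <- NULL
  trace <- data.frame(iteration = integer(), score = numeric(),
                      best_score = numeric())
  it <- 0L
  note <- function(res) {
    it <<- it + 1L
    sc <- if (isTRUE(res$ok)) res$score else NA_real_
    replaced <- isTRUE(res$ok) && .betterThan(res, best)
    if (replaced) best <<- res
    trace <<- rbind(trace, data.frame(
      iteration = it, score = sc,
      best_score = if (is.null(best)) NA_real_ else best$score))
    if (!isTRUE(res$ok)) failures <<- c(failures, res$why)
    replaced
  }

  for (r in seq_len(nrow(cand)))
    note(evalCandidate(centers[[cand$center[r]]], dirs[[cand$dir[r]]],
                       cand$depth[r], cand$vco[r], cand$voo[r], coarse))

  if (is.null(best))
    stop("no admissible candidate found; constraints violated: ",
         paste(unique(failures), collapse = "; "))

  # stage 2: coordinate descent on depth and the two voltage levels
  for (pass in seq_len(settings$descentPasses)) {
    improved <- FALSE
    for (var in c("depth", "vco", "voo")) {
      step <- if (var == "depth") settings$depthStep else 50
      for (s in c(-step, step)) {
        v <- list(depth = best$depth, vco = best$vco, voo = best$voo)
        v[[var]] <- v[[var]] + s
        if (note(evalCandidate(best$center, best$dir, v$depth, v$vco,
                               v$voo, coarse)))
          improved <- TRUE
      }
    }
    if (!improved) break
  }

  # re-score the winner at full resolution
  finalArr <- best$plan@array
  finalSched <- best$plan@schedule
  finalPlan <- treatmentPlan(ph, finalArr, finalSched, problem$tissues,
                             problem$settings, problem$marginWidth)
  finalScore <- planObjective(finalPlan, problem$weights)

  list(plan = finalPlan, score = finalScore,
       coarseScore = best[c("score", "tumor", "margin", "overreach")],
       trace = trace, nEvaluated = it,
       nAdmissible = sum(!is.na(trace$score)))
}
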