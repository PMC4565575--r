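# Shared small fixtures, built in code. Solver-based objects are cached per
# session because several tests interrogate the same solution.

fastSettings <- function(...) solverSettings(fpTol = 1e-3, ...)

# small phantom with one 20 mm tumor, 1 mm spacing
smallTumorPhantom <- function() {
  makePhantom(c(40, 40, 40), 1,
              tumors = list(list(center = c(20, 20, 20), diameter = 20)))
}

# independent voxel-center membership count for a sphere: vectorized
# enumeration over all voxel centers, written without the package's
# geometry helpers
bruteSphereCount <- function(shape, spacing, center, radius) {
  cx <- (seq_len(shape[1]) - 0.5) * spacing
  cy <- (seq_len(shape[2]) - 0.5) * spacing
  cz <- (seq_len(shape[3]) - 0.5) * spacing
  g <- expand.grid(x = cx, y = cy, z = cz)
  sum((g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2 <=
        radius^2)
}

.cache <- new.env()

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# two-needle fixture solved once at 1 mm (fast) for conservation and
# property tests
solvedTwoNeedle1mm <- function() {
  cached("tn1", {
    fx <- twoNeedleFixture(1)
    sol <- solvePair(fx$phantom, tissueDefaults(), fx$masks, c(1, 2), 1000,
                     solverSettings(epEnabled = FALSE))
    list(fx = fx, sol = sol)
  })
}

# study-like case fixture at 2 mm with solved schedule (fast, coarse)
solvedCase2mm <- function() {
  cached("case2", {
    plan <- ectCaseFixture(1, spacing = 2)
    sols <- solveSchedule(plan)
    list(plan = plan, sols = sols)
  })
}

# case plan at 2 mm with a two-entry schedule: enough structure for
# robustness-sweep semantics at a fraction of the solve cost
twoPairCasePlan <- function() {
  plan <- ectCaseFixture(1, spacing = 2)
  e <- scheduleEntries(plan@schedule)[c(1, 5), ]
  plan@schedule <- new("PulseSchedule", entries = e)
  plan
}

# two-needle validation fixture at 0.5 mm, electroporation disabled
solvedTwoNeedleHalf <- function() {
  cached("tn05", {
    fx <- twoNeedleFixture(0.5)
    sol <- solvePair(fx$phantom, tissueDefaults(), fx$masks, c(1, 2), 1000,
                     solverSettings(epEnabled = FALSE))
    list(fx = fx, sol = sol)
  })
}

# the full metastasis-1 plan at the 1 mm analysis resolution
solvedCase1mm <- function() {
  cached("case1", {
    plan <- ectCaseFixture(1, spacing = 1)
    sols <- solveSchedule(plan)
    list(plan = plan, sols = sols)
  })
}
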