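## Nonlinear electrostatic solver with electroporation-dependent
## conductivity.

#' Solver settings
#'
#' @param epEnabled model the conductivity increase of electroporated
#'   tissue (the sigma(E) fixed point); disable for a purely linear solve.
#' @param damping damping factor on the sigma update (0.5: each fixed-point
#'   step moves conductivity halfway to its target).
#' @param fpTol fixed-point convergence tolerance: relative change of the
#'   predicted current between iterations.
#' @param fpMaxit maximum fixed-point iterations; exceeding it raises a
#'   convergence error unless `allowUnconverged`.
#' @param pcgTol relative residual of the conjugate-gradient solve behind
#'   the reported solution.
#' @param pcgTolInner looser relative residual used for the intermediate
#'   solves inside the sigma(E) fixed point (inexact iteration); the final
#'   solution is always polished to `pcgTol`.
#' @param pcgMaxit CG iteration cap.
#' @param persistentSigma carry electroporated conductivity forward across
#'   schedule entries (off by default: pairs are solved independently, no
#'   pulse-history memory).
#' @param rampShape sigma(E) interpolant between the thresholds: `"cosine"`
#'   (smoothed raised-cosine ramp, default) or `"linear"`.
#' @param allowUnconverged report an unconverged fixed point instead of
#'   raising an error.
#' @return list of settings for [solvePair()].
#' @export
solverSettings <- function(epEnabled = TRUE, damping = 0.5, fpTol = 1e-3,
                           fpMaxit = 50L, pcgTol = 1e-8, pcgTolInner = 1e-4,
                           pcgMaxit = 20000L, persistentSigma = FALSE,
                           rampShape = c("cosine", "linear"),
                           allowUnconverged = FALSE) {
  list(epEnabled = epEnabled, damping = damping, fpTol = fpTol,
       fpMaxit = as.integer(fpMaxit), pcgTol = pcgTol,
       pcgTolInner = pcgTolInner, pcgMaxit = as.integer(pcgMaxit),
       persistentSigma = persistentSigma, rampShape = match.arg(rampShape),
       allowUnconverged = allowUnconverged)
}

#' Electroporation-dependent conductivity
#'
#' Conductivity as a function of local field strength: baseline `sigma0`
#' below the reversible threshold, `sigma0 * sigmaFactor` at and above the
#' irreversible threshold, joined by a smooth monotone ramp (raised cosine
#' by default, optionally linear). Vectorized over all arguments.
#'
#' @param e field magnitude, V/cm (>= 0).
#' @param sigma0 baseline conductivity, S/m.
#' @param sigmaFactor saturated multiplicative increase (>= 1).
#' @param eRev,eIrrev reversible / irreversible thresholds, V/cm.
#' @param shape `"cosine"` or `"linear"`.
#' @return conductivity, S/m.
#' @examples
#' sigmaOfE(600, 0.2, 3.5, 400, 800) # strictly between 0.2 and 0.7
#' @export
sigmaOfE <- function(e, sigma0, sigmaFactor, eRev, eIrrev,
                     shape = c("cosine", "linear")) {
  if (any(e < 0)) stop("field magnitude must be >= 0")
  shape <- match.arg(shape)
  t <- pmin(1, pmax(0, (e - eRev) / (eIrrev - eRev)))
  w <- if (shape == "cosine") 0.5 * (1 - cos(pi * t)) else t
  sigma0 * (1 + (sigmaFactor - 1) * w)
}

# |grad phi| in V/cm from a potential grid (V) on spacing (mm); central
# differences inside, one-sided at the grid faces
.fieldMagnitude <- function(phi, spacing_mm) {
  d <- dim(phi)
  slice <- function(a, rng) {
    ii <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ii[[a]] <- rng
    do.call(`[`, c(list(phi), ii, list(drop = FALSE)))
  }
  assign_slice <- function(g, a, rng, val) {
    ii <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ii[[a]] <- rng
    do.call(`[<-`, c(list(g), ii, list(val)))
  }
  g2 <- array(0, d)
  for (a in 1:3) {
    n <- d[a]
    if (n < 2) next
    grad <- array(0, d)
    if (n > 2)
      grad <- assign_slice(grad, a, 2:(n - 1),
                           (slice(a, 3:n) - slice(a, 1:(n - 2))) /
                             (2 * spacing_mm[a]))
    grad <- assign_slice(grad, a, 1,
                         (slice(a, 2) - slice(a, 1)) / spacing_mm[a])
    grad <- assign_slice(grad, a, n,
                         (slice(a, n) - slice(a, n - 1)) / spacing_mm[a])
    g2 <- g2 + grad^2
  }
  sqrt(g2) * 10 # V/mm -> V/cm
}

#' Solve the field for one electrode pair
#'
#' Solves the discretized continuity equation `div(sigma grad phi) = 0` on
#' the voxel grid (7-point finite differences, harmonic-mean face
#' conductivities) with Dirichlet values on the two active-tip voxel sets
#' (`voltage` on the anode, 0 on the cathode) and an insulating (zero
#' normal flux) outer boundary. Electrode voxels keep the local tissue
#' conductivity: the potential is imposed at the voxel centers, which
#' places the effective conductor surface at the physical needle radius
#' (validated against the two-cylinder closed form). With electroporation
#' enabled, the
#' conductivity grid is the damped fixed point of the sigma(|E|) update;
#' convergence is declared when the relative change of the predicted
#' current drops below `fpTol`. The predicted current is the net flux
#' through the faces enclosing the energized electrode.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param tissues a [TissueTable-class].
#' @param electrodeMasks named list of logical masks from
#'   [rasterizeElectrodes()].
#' @param pair integer(2): (anode id, cathode id); must name nonempty,
#'   disjoint masks.
#' @param voltage applied voltage (V, >= 0).
#' @param settings list from [solverSettings()].
#' @param sigmaBase optional conductivity grid (S/m) overriding the
#'   baseline derived from the phantom labels (used by the
#'   persistent-sigma mode).
#' @return a [FieldSolution-class].
#' @export
solvePair <- function(phantom, tissues, electrodeMasks, pair, voltage,
                      settings = solverSettings(), sigmaBase = NULL) {
  am <- electrodeMasks[[as.character(pair[1])]]
  cm <- electrodeMasks[[as.character(pair[2])]]
  if (is.null(am) || is.null(cm) || !any(am) || !any(cm))
    stop("both electrode masks of the pair must be nonempty")
  if (any(am & cm)) stop("electrode masks of the pair must be disjoint")
  if (voltage < 0) stop("voltage must be >= 0")

  shape <- dim(labelArray(phantom))
  sp_m <- voxelSpacing(phantom) / 1000
  if (is.null(sigmaBase)) sigmaBase <- .tissueGrid(phantom, tissues, "sigma0")

  sf <- .tissueGrid(phantom, tissues, "sigma_factor")
  er <- .tissueGrid(phantom, tissues, "e_rev")
  ei <- .tissueGrid(phantom, tissues, "e_irrev")
  # saturated conductivity can only grow; persistent mode passes an already
  # elevated sigmaBase, so cap targets from below by the baseline
  s0 <- .tissueGrid(phantom, tissues, "sigma0")

  U <- am | cm
  wgA <- attr(am, "wireGeom")
  wgC <- attr(cm, "wireGeom")
  if (is.null(wgA) || is.null(wgC))
    stop("electrode masks must come from rasterizeElectrodes()")
  # insulated shafts of the active pair shield the tissue they traverse
  shaft <- (attr(am, "shaft") | attr(cm, "shaft")) & !U
  excl <- U | shaft
  dmask <- array(0L, shape) # no hard Dirichlet: wire-coupled electrodes
  dvals <- array(0, shape)
  wval <- array(0, shape)
  wval[am] <- voltage

  wireCond <- function(sigma) {
    wc <- array(0, shape)
    wc[am] <- wgA * .surroundSigma(sigma, am, excl, sigmaBase[am])
    wc[cm] <- wgC * .surroundSigma(sigma, cm, excl, sigmaBase[cm])
    wc
  }
  withOverrides <- function(s) {
    s[U] <- .SIGMA_METAL
    s[shaft] <- .SIGMA_INSULATOR
    s
  }

  sigma <- withOverrides(sigmaBase)
  wc <- wireCond(sigma)
  phi <- array(0, shape)
  current <- NA_real_
  it <- 0L
  converged <- TRUE
  resid <- 0

  inner <- if (settings$epEnabled && voltage > 0)
    max(settings$pcgTolInner, settings$pcgTol) else settings$pcgTol
  repeat {
    sol <- cpp_solve_potential(sigma, dmask, dvals, sp_m, phi,
                               inner, settings$pcgMaxit, wc, wval)
    if (!sol$converged)
      stop(sprintf("linear solve failed to converge (relative residual %.2e)",
                   sol$relres))
    phi <- sol$phi
    newCurrent <- sum(wc[am] * (voltage - phi[am]))
    it <- it + 1L

    if (!settings$epEnabled || voltage == 0) { current <- newCurrent; break }

    emag <- .fieldMagnitude(phi, voxelSpacing(phantom))
    sigmaTissue <- sigma
    sigmaTissue[excl] <- sigmaBase[excl]
    target <- pmax(sigmaBase,
                   sigmaOfE(as.vector(emag), as.vector(s0), as.vector(sf),
                            as.vector(er), as.vector(ei),
                            shape = settings$rampShape))
    target <- array(target, shape)
    sigmaNext <- withOverrides(sigmaTissue +
                                 settings$damping * (target - sigmaTissue))

    if (!is.na(current)) {
      resid <- abs(newCurrent - current) / max(abs(newCurrent), 1e-300)
      if (resid < settings$fpTol) { current <- newCurrent; break }
    }
    current <- newCurrent
    if (it >= settings$fpMaxit) {
      converged <- FALSE
      if (!settings$allowUnconverged)
        stop(sprintf(
          "sigma(E) fixed point did not converge in %d iterations (last relative current change %.3e)",
          settings$fpMaxit, resid))
      break
    }
    sigma <- sigmaNext
    wc <- wireCond(sigma)
  }

  if (inner > settings$pcgTol) { # polish to the reported tolerance
    sol <- cpp_solve_potential(sigma, dmask, dvals, sp_m, phi,
                               settings$pcgTol, settings$pcgMaxit, wc, wval)
    if (!sol$converged)
      stop(sprintf("linear solve failed to converge (relative residual %.2e)",
                   sol$relres))
    phi <- sol$phi
    current <- sum(wc[am] * (voltage - phi[am]))
  }

  cathCurrent <- sum(wc[cm] * phi[cm])
  emag <- .fieldMagnitude(phi, voxelSpacing(phantom))

  new("FieldSolution", potential = phi, fieldMagnitude = emag,
      conductivity = sigma, current = current, cathodeCurrent = cathCurrent,
      pair = as.integer(pair), voltage = as.numeric(voltage),
      spacing = voxelSpacing(phantom), origin = gridOrigin(phantom),
      iterations = it, converged = converged, residual = resid)
}

#' Solve every entry of a plan's schedule
#'
#' Pairs are solved independently by default; with
#' `settings$persistentSigma` the electroporated conductivity of each pair
#' is carried forward (voxelwise maximum) as the baseline of the next,
#' modelling pulse-history memory.
#'
#' @param plan a [TreatmentPlan-class].
#' @param electrodeMasks optional precomputed [rasterizeElectrodes()]
#'   result.
#' @return list of [FieldSolution-class], one per schedule entry.
#' @export
solveSchedule <- function(plan, electrodeMasks = NULL) {
  if (is.null(electrodeMasks))
    electrodeMasks <- rasterizeElectrodes(plan@array, plan@phantom)
  entries <- scheduleEntries(plan@schedule)
  settings <- plan@settings
  sigmaBase <- NULL
  out <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    sol <- solvePair(plan@phantom, plan@tissues, electrodeMasks,
                     c(entries$anode[i], entries$cathode[i]),
                     entries$voltage[i], settings, sigmaBase = sigmaBase)
    if (isTRUE(settings$persistentSigma)) {
      s <- sol@conductivity
      # strip the electrode metal/insulator marking before carrying forward
      base0 <- .tissueGrid(plan@phantom, plan@tissues, "sigma0")
      marked <- s >= .SIGMA_METAL | s <= .SIGMA_INSULATOR
      s[marked] <- base0[marked]
      sigmaBase <- if (is.null(sigmaBase)) s else pmax(sigmaBase, s)
    }
    out[[i]] <- sol
  }
  out
}

#' Anode/cathode current mismatch
#'
#' Discrete conservation check: the current leaving the energized electrode
#' must equal the current entering the grounded one; their relative
#' mismatch quantifies solver error.
#'
#' @param solution a [FieldSolution-class].
#' @return `abs(anode - cathode) / anode` (dimensionless).
#' @export
currentBalance <- function(solution) {
  if (solution@current == 0) stop("zero anode flux: balance undefined")
  abs(solution@current - solution@cathodeCurrent) / abs(solution@current)
}
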