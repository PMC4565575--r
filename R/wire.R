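## Sub-cell electrode boundary treatment.
##
## A needle whose radius is comparable to (or smaller than) the voxel size
## cannot be represented by hard Dirichlet voxels alone: the rasterized
## voxel set behaves like a conductor of some grid-dependent effective
## radius r_eff, not the physical radius r_w. The package therefore uses
## the thin-conductor coupling familiar from well models in reservoir
## simulation: electrode voxels carry metal conductivity (the needle
## interior is equipotential) and each is tied to the applied potential
## through a radial series conductance per unit active length
##
##   g = 2 pi sigma / ln(r_eff / r_w),
##
## which exactly converts the lattice's per-unit-length conductance (to a
## far circle) into that of a true r_w cylinder. r_eff is measured once
## per electrode from a small 2-D lattice solve that mirrors the 3-D
## cross-section: same transverse spacings, same axis offset within the
## cell, same voxel-inclusion rule, metal interior. When r_eff <= r_w the
## rasterized set already resolves the needle and the coupling degenerates
## to (numerically) hard Dirichlet.

.SIGMA_METAL <- 1e6
.SIGMA_INSULATOR <- 0 # insulated needle shaft carries no current

# effective radius (mm) of the rasterized cross-section of a needle whose
# node set uses inclusion radius rIncl (mm), axis offset (f1, f2) in cell
# units, transverse spacings h1, h2 (mm). Solved on a 2-D lattice (unit
# potential on the electrode node set, far Dirichlet circle); r_eff is
# recovered by fitting the logarithmic far field phi = s ln r + c over a
# mid-range annulus, which is insensitive to the discrete outer boundary.
.effectiveRadius2D <- function(h1, h2, f1, f2, rw) {
  h <- max(h1, h2)
  W <- max(32 * h, 40 * rw) # annulus far enough that multipoles decay
  n1 <- 2L * ceiling(W / h1) + 1L
  n2 <- 2L * ceiling(W / h2) + 1L
  i0 <- (n1 - 1L) %/% 2L
  j0 <- (n2 - 1L) %/% 2L
  # axis world position; node (i,j) sits at ((i + 0.5) h1, (j + 0.5) h2),
  # 0-based
  ax <- (i0 + f1) * h1
  ay <- (j0 + f2) * h2
  xs <- (seq_len(n1) - 0.5) * h1
  ys <- (seq_len(n2) - 0.5) * h2
  dx <- matrix(xs - ax, n1, n2)
  dy <- matrix(ys - ay, n1, n2, byrow = TRUE)
  r2 <- dx^2 + dy^2
  elec <- r2 <= rw^2 + 1e-9
  elec[floor(i0 + f1) + 1L, floor(j0 + f2) + 1L] <- TRUE # containing cell
  R <- 0.9 * min(max(abs(xs - ax)), max(abs(ys - ay)))
  outer_d <- sqrt(r2) >= R

  shape <- c(n1, n2, 1L)
  sigma <- array(1, shape)
  sigma[array(elec, shape)] <- .SIGMA_METAL
  dmask <- array(0L, shape)
  dmask[array(elec | outer_d, shape)] <- 1L
  dvals <- array(0, shape)
  dvals[array(elec, shape)] <- 1
  sol <- cpp_solve_potential(sigma, dmask, dvals,
                             c(h1, h2, 1000) / 1000, # dz = 1 m
                             array(0, shape), 1e-12, 50000L)
  phi <- sol$phi
  r <- sqrt(r2)
  fit <- r >= max(6 * h, 8 * rw) & r <= 0.55 * R
  lr <- log(r[fit])
  ph <- as.vector(phi)[as.vector(fit)]
  co <- stats::coef(stats::lm(ph ~ lr))
  # phi = 1 at r_eff under phi = c + s ln r
  exp((1 - co[[1]]) / co[[2]])
}

# calibrate the node-set inclusion radius and the radial coupling for one
# electrode: grow the inclusion radius until the node set's effective
# radius is at (or above) the physical needle radius, so the series
# correction ln(r_eff / r_w) stays positive and well conditioned.
# Returns the inclusion radius (mm) and the log-radius correction.
.wireCalibrate <- function(e, phantom) {
  sp <- voxelSpacing(phantom)
  o <- gridOrigin(phantom)
  u <- abs(.unit(e@tip - e@entry))
  a <- which.max(u) # dominant axis
  tr <- setdiff(1:3, a)
  f <- ((e@tip[tr] - o[tr]) / sp[tr]) %% 1
  h <- max(sp[tr])
  rIncl <- e@radius
  for (i in 1:8) {
    reff <- .effectiveRadius2D(sp[tr[1]], sp[tr[2]], f[1], f[2], rIncl)
    if (reff >= 1.02 * e@radius) break
    rIncl <- rIncl + 0.35 * h
  }
  list(rIncl = rIncl, lnr = max(log(reff / e@radius), 0.01), reff = reff)
}

# mean conductivity of the non-electrode face neighbors of each voxel in
# mask M (U = electrode + shaft voxels of the active pair); falls back to
# the supplied per-voxel values where no outside neighbor exists
.surroundSigma <- function(sigma, M, U, fallback) {
  d <- dim(sigma)
  idx <- which(M)
  ai <- arrayInd(idx, d)
  tot <- numeric(length(idx))
  cnt <- numeric(length(idx))
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
    ni <- sweep(ai, 2, off, "+")
    ok <- ni[, 1] >= 1 & ni[, 1] <= d[1] & ni[, 2] >= 1 & ni[, 2] <= d[2] &
      ni[, 3] >= 1 & ni[, 3] <= d[3]
    lin <- ni[ok, 1] + (ni[ok, 2] - 1) * d[1] +
      (ni[ok, 3] - 1) * d[1] * d[2]
    outside <- !U[lin]
    w <- which(ok)[outside]
    tot[w] <- tot[w] + sigma[lin[outside]]
    cnt[w] <- cnt[w] + 1
  }
  ifelse(cnt > 0, tot / cnt, fallback)
}
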