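#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Core numerics for the voxel-grid electrostatic solver.
//
// Discretization: cell-centered 7-point finite differences; the conductance
// of the face between two voxels uses the harmonic mean of their
// conductivities (robust across tissue-boundary discontinuities). The outer
// grid boundary is homogeneous Neumann (insulated body): missing-neighbor
// faces simply carry no flux. Electrode active-tip voxels are Dirichlet
// nodes; they are eliminated from the unknowns and enter through the RHS.

namespace {

inline double hmean(double a, double b) {
  if (a == 0.0 || b == 0.0) return 0.0; // non-conductive voxel: no flux
  return 2.0 * a * b / (a + b);
}

struct Grid {
  int nx, ny, nz;
  double fx, fy, fz; // face conductance geometric factors area/dist (m)
  inline int id(int i, int j, int k) const { return i + nx * (j + (long)ny * k); }
};

// y = A x restricted to free voxels (dmask == 0); Dirichlet entries of x are
// ignored (their contribution was folded into the RHS).
// When no voxel is Dirichlet the stencil is applied branch-free: face
// conductances are zero past the grid edge by construction, so wrap-around
// neighbor terms vanish and only global array bounds need guarding.
void apply_A(const Grid& g, const std::vector<double>& Gx,
             const std::vector<double>& Gy, const std::vector<double>& Gz,
             const std::vector<double>& diag, const IntegerVector& dmask,
             bool anyDir, const std::vector<double>& x,
             std::vector<double>& y) {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  const long n = (long)nx * ny * nz;
  const long sxy = (long)nx * ny;
  if (!anyDir) {
    const double* X = x.data();
    const double* D = diag.data();
    const double* GX = Gx.data();
    const double* GY = Gy.data();
    const double* GZ = Gz.data();
    double* Y = y.data();
    for (long p = 0; p < sxy; ++p) {
      double acc = D[p] * X[p];
      if (p >= 1) acc -= GX[p - 1] * X[p - 1];
      if (p + 1 < n) acc -= GX[p] * X[p + 1];
      if (p >= nx) acc -= GY[p - nx] * X[p - nx];
      if (p + nx < n) acc -= GY[p] * X[p + nx];
      if (p + sxy < n) acc -= GZ[p] * X[p + sxy];
      Y[p] = acc;
    }
    for (long p = sxy; p < n - sxy; ++p) {
      Y[p] = D[p] * X[p]
        - GX[p - 1] * X[p - 1] - GX[p] * X[p + 1]
        - GY[p - nx] * X[p - nx] - GY[p] * X[p + nx]
        - GZ[p - sxy] * X[p - sxy] - GZ[p] * X[p + sxy];
    }
    for (long p = std::max(sxy, n - sxy); p < n; ++p) {
      double acc = D[p] * X[p];
      acc -= GX[p - 1] * X[p - 1];
      if (p + 1 < n) acc -= GX[p] * X[p + 1];
      acc -= GY[p - nx] * X[p - nx];
      if (p + nx < n) acc -= GY[p] * X[p + nx];
      acc -= GZ[p - sxy] * X[p - sxy];
      Y[p] = acc;
    }
    return;
  }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int p = g.id(i, j, k);
        if (dmask[p]) { y[p] = 0.0; continue; }
        double acc = diag[p] * x[p];
        if (i > 0)      { int q = p - 1;       if (!dmask[q]) acc -= Gx[g.id(i-1,j,k)] * x[q]; }
        if (i < nx - 1) { int q = p + 1;       if (!dmask[q]) acc -= Gx[p] * x[q]; }
        if (j > 0)      { int q = p - nx;      if (!dmask[q]) acc -= Gy[g.id(i,j-1,k)] * x[q]; }
        if (j < ny - 1) { int q = p + nx;      if (!dmask[q]) acc -= Gy[p] * x[q]; }
        if (k > 0)      { int q = p - nx * ny; if (!dmask[q]) acc -= Gz[g.id(i,j,k-1)] * x[q]; }
        if (k < nz - 1) { int q = p + nx * ny; if (!dmask[q]) acc -= Gz[p] * x[q]; }
        y[p] = acc;
      }
}

void face_conductances(const Grid& g, const NumericVector& sigma,
                       std::vector<double>& Gx, std::vector<double>& Gy,
                       std::vector<double>& Gz) {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int p = g.id(i, j, k);
        if (i < nx - 1) Gx[p] = hmean(sigma[p], sigma[p + 1]) * g.fx;
        if (j < ny - 1) Gy[p] = hmean(sigma[p], sigma[p + nx]) * g.fy;
        if (k < nz - 1) Gz[p] = hmean(sigma[p], sigma[p + (long)nx * ny]) * g.fz;
      }
}

} // namespace

// Solve div(sigma grad phi) = 0 with Dirichlet values on dmask voxels by
// Jacobi-preconditioned conjugate gradients on the free voxels.
// sigma: S/m, one value per voxel; spacing_m: voxel spacing in meters;
// dvals: potential (V) on Dirichlet voxels (ignored elsewhere); x0: initial
// guess (warm start across nonlinear iterations).
// wcond/wval: optional per-voxel coupling conductance (S) to a fixed
// potential wval (V) — the thin-electrode (well-index) boundary treatment;
// wcond == 0 means no coupling.
// [[Rcpp::export]]
List cpp_solve_potential(NumericVector sigma, IntegerVector dmask,
                         NumericVector dvals, NumericVector spacing_m,
                         NumericVector x0, double tol, int maxit,
                         Nullable<NumericVector> wcond = R_NilValue,
                         Nullable<NumericVector> wval = R_NilValue) {
  IntegerVector dims = sigma.attr("dim");
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  const double dx = spacing_m[0], dy = spacing_m[1], dz = spacing_m[2];
  g.fx = dy * dz / dx; g.fy = dx * dz / dy; g.fz = dx * dy / dz;
  const long n = (long)g.nx * g.ny * g.nz;

  std::vector<double> Gx(n, 0.0), Gy(n, 0.0), Gz(n, 0.0);
  face_conductances(g, sigma, Gx, Gy, Gz);

  const bool haveWire = wcond.isNotNull();
  NumericVector wc, wv;
  if (haveWire) { wc = wcond.get(); wv = wval.get(); }

  // diag and RHS from Dirichlet elimination
  std::vector<double> diag(n, 0.0), b(n, 0.0), x(n, 0.0);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        const int p = g.id(i, j, k);
        if (dmask[p]) { x[p] = dvals[p]; continue; }
        double d = 0.0, rhs = 0.0;
        auto face = [&](int q, double G) {
          d += G;
          if (dmask[q]) rhs += G * dvals[q];
        };
        if (i > 0)        face(p - 1,          Gx[g.id(i-1,j,k)]);
        if (i < g.nx - 1) face(p + 1,          Gx[p]);
        if (j > 0)        face(p - g.nx,       Gy[g.id(i,j-1,k)]);
        if (j < g.ny - 1) face(p + g.nx,       Gy[p]);
        if (k > 0)        face(p - g.nx*g.ny,  Gz[g.id(i,j,k-1)]);
        if (k < g.nz - 1) face(p + g.nx*g.ny,  Gz[p]);
        if (haveWire && wc[p] > 0.0) { d += wc[p]; rhs += wc[p] * wv[p]; }
        if (d == 0.0) { d = 1.0; rhs = 0.0; } // fully decoupled voxel
        diag[p] = d;
        b[p] = rhs;
        x[p] = x0[p];
      }

  bool anyDir = false;
  for (long p = 0; p < n; ++p) if (dmask[p]) { anyDir = true; break; }

  double bnorm = 0.0;
  for (long p = 0; p < n; ++p) if (!dmask[p]) bnorm += b[p] * b[p];
  bnorm = std::sqrt(bnorm);

  NumericVector phi(n);
  phi.attr("dim") = dims;

  if (bnorm == 0.0) { // zero applied voltage: phi = 0 is exact
    for (long p = 0; p < n; ++p) phi[p] = dmask[p] ? dvals[p] : 0.0;
    return List::create(_["phi"] = phi, _["iterations"] = 0,
                        _["relres"] = 0.0, _["converged"] = true);
  }

  std::vector<double> r(n, 0.0), z(n, 0.0), pvec(n, 0.0), Ap(n, 0.0);
  apply_A(g, Gx, Gy, Gz, diag, dmask, anyDir, x, Ap);
  for (long p = 0; p < n; ++p) r[p] = dmask[p] ? 0.0 : b[p] - Ap[p];

  double rz = 0.0;
  for (long p = 0; p < n; ++p)
    if (!dmask[p]) { z[p] = r[p] / diag[p]; rz += r[p] * z[p]; }
  pvec = z;

  double relres = 0.0;
  {
    double rn = 0.0;
    for (long p = 0; p < n; ++p) rn += r[p] * r[p];
    relres = std::sqrt(rn) / bnorm;
  }
  int it = 0;
  while (relres > tol && it < maxit) {
    apply_A(g, Gx, Gy, Gz, diag, dmask, anyDir, pvec, Ap);
    double pAp = 0.0;
    for (long p = 0; p < n; ++p) if (!dmask[p]) pAp += pvec[p] * Ap[p];
    const double alpha = rz / pAp;
    double rn = 0.0;
    for (long p = 0; p < n; ++p)
      if (!dmask[p]) {
        x[p] += alpha * pvec[p];
        r[p] -= alpha * Ap[p];
        rn += r[p] * r[p];
      }
    relres = std::sqrt(rn) / bnorm;
    double rz_new = 0.0;
    for (long p = 0; p < n; ++p)
      if (!dmask[p]) { z[p] = r[p] / diag[p]; rz_new += r[p] * z[p]; }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (long p = 0; p < n; ++p)
      if (!dmask[p]) pvec[p] = z[p] + beta * pvec[p];
    ++it;
  }

  for (long p = 0; p < n; ++p) phi[p] = dmask[p] ? dvals[p] : x[p];
  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["relres"] = relres, _["converged"] = relres <= tol);
}

// Net conduction current (A) leaving the voxel set `mask` (1 = member):
// sum over member voxels of G_face * (phi_member - phi_outside) over faces
// to non-member neighbors. Outer grid faces carry no flux (Neumann).
// [[Rcpp::export]]
double cpp_mask_flux(NumericVector sigma, NumericVector phi,
                     IntegerVector mask, NumericVector spacing_m) {
  IntegerVector dims = sigma.attr("dim");
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  const double dx = spacing_m[0], dy = spacing_m[1], dz = spacing_m[2];
  g.fx = dy * dz / dx; g.fy = dx * dz / dy; g.fz = dx * dy / dz;
  double flux = 0.0;
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        const int p = g.id(i, j, k);
        if (!mask[p]) continue;
        auto add = [&](int q, double f) {
          if (!mask[q])
            flux += hmean(sigma[p], sigma[q]) * f * (phi[p] - phi[q]);
        };
        if (i > 0)        add(p - 1,         g.fx);
        if (i < g.nx - 1) add(p + 1,         g.fx);
        if (j > 0)        add(p - g.nx,      g.fy);
        if (j < g.ny - 1) add(p + g.nx,      g.fy);
        if (k > 0)        add(p - g.nx*g.ny, g.fz);
        if (k < g.nz - 1) add(p + g.nx*g.ny, g.fz);
      }
  return flux;
}

// ---- Euclidean distance transform ------------------------------------------

namespace {

// 1-D squared-distance lower envelope (Felzenszwalb & Huttenlocher) with
// sample positions x_i = i * step, supporting anisotropic voxel spacing.
void dt1d(std::vector<double>& f, int n, double step, std::vector<double>& d,
          std::vector<int>& v, std::vector<double>& zb) {
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[q0]] == INF && q0 == 0) { v[0] = q; zb[0] = -INF; zb[1] = INF; continue; }
    double s;
    while (true) {
      const int vq = v[q0];
      const double xq = q * step, xv = vq * step;
      s = ((f[q] + xq * xq) - (f[vq] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= zb[q0] && q0 > 0) { --q0; } else break;
    }
    ++q0;
    v[q0] = q;
    zb[q0] = s;
    zb[q0 + 1] = INF;
  }
  int q1 = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * step;
    while (zb[q1 + 1] < xq) ++q1;
    const int vq = v[q1];
    if (f[vq] == INF) { d[q] = INF; continue; }
    const double dx = xq - vq * step;
    d[q] = dx * dx + f[vq];
  }
}

} // namespace

// Squared Euclidean distance (mm^2) from every voxel center to the nearest
// voxel center with mask == 1, under anisotropic spacing (mm).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, NumericVector spacing_mm) {
  IntegerVector dims = mask.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  out.attr("dim") = dims;
  std::vector<double> D(n);
  for (long p = 0; p < n; ++p) D[p] = mask[p] ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const long base = nx * (j + (long)ny * k);
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = D[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, nx, spacing_mm[0], d, v, zb);
      for (int i = 0; i < nx; ++i) D[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = D[i + nx * (j + (long)ny * k)]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, ny, spacing_mm[1], d, v, zb);
      for (int j = 0; j < ny; ++j) D[i + nx * (j + (long)ny * k)] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      bool any = false;
      for (int k = 0; k < nz; ++k) { f[k] = D[i + nx * (j + (long)ny * k)]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, nz, spacing_mm[2], d, v, zb);
      for (int k = 0; k < nz; ++k) D[i + nx * (j + (long)ny * k)] = d[k];
    }

  for (long p = 0; p < n; ++p) out[p] = D[p];
  return out;
}
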