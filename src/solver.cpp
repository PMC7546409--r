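#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cell-centred finite-volume discretization of div(sigma grad phi) = 0 on a
// uniform rectilinear grid with harmonic averaging of sigma across faces.
// Voxels with sigma == 0 are perfect insulators and drop out of the system;
// dmask != 0 marks Dirichlet voxels with potential dval. Outer box faces are
// natural zero-flux (Neumann) boundaries. Jacobi-preconditioned conjugate
// gradients; the uniform geometric face factor cancels so face weights are
// plain harmonic conductivities.

static inline double harm(double a, double b) {
  if (a <= 0.0 || b <= 0.0) return 0.0;
  return 2.0 * a * b / (a + b);
}

// [[Rcpp::export]]
List cpp_fd_solve(NumericVector sigma, IntegerVector dim, IntegerVector dmask,
                  NumericVector dval, double rtol, double atol, int maxit) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  if (sigma.size() != N || dmask.size() != N || dval.size() != N)
    stop("grid size mismatch");
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  std::vector<double> wx(N, 0.0), wy(N, 0.0), wz(N, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = i + sy * j + sz * k;
        if (i + 1 < nx) wx[id] = harm(sigma[id], sigma[id + sx]);
        if (j + 1 < ny) wy[id] = harm(sigma[id], sigma[id + sy]);
        if (k + 1 < nz) wz[id] = harm(sigma[id], sigma[id + sz]);
      }

  // free unknowns: conducting and not Dirichlet
  std::vector<char> free_(N);
  for (R_xlen_t id = 0; id < N; ++id)
    free_[id] = (sigma[id] > 0.0 && dmask[id] == 0) ? 1 : 0;

  std::vector<double> diag(N, 0.0), b(N, 0.0), phi(N, 0.0);
  for (R_xlen_t id = 0; id < N; ++id)
    if (dmask[id] != 0) phi[id] = dval[id];

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = i + sy * j + sz * k;
        if (!free_[id]) continue;
        double d = 0.0, rhs = 0.0;
        const int di[6] = {1, -1, 0, 0, 0, 0};
        const int dj[6] = {0, 0, 1, -1, 0, 0};
        const int dk[6] = {0, 0, 0, 0, 1, -1};
        for (int f = 0; f < 6; ++f) {
          int ii = i + di[f], jj = j + dj[f], kk = k + dk[f];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          R_xlen_t nb = ii + sy * jj + sz * kk;
          double w;
          if (f == 0) w = wx[id];
          else if (f == 1) w = wx[nb];
          else if (f == 2) w = wy[id];
          else if (f == 3) w = wy[nb];
          else if (f == 4) w = wz[id];
          else w = wz[nb];
          if (w <= 0.0) continue;
          d += w;
          if (dmask[nb] != 0) rhs += w * dval[nb];
        }
        diag[id] = d;
        b[id] = rhs;
      }

  // operator application on free unknowns (Dirichlet contributions in b)
  std::vector<double> r(N, 0.0), z(N, 0.0), p(N, 0.0), Ap(N, 0.0);
  std::vector<double> x(N, 0.0);

  auto applyA = [&](const std::vector<double>& v, std::vector<double>& out) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t id = i + sy * j + sz * k;
          if (!free_[id]) { out[id] = 0.0; continue; }
          double acc = diag[id] * v[id];
          if (i + 1 < nx && wx[id] > 0 && free_[id + sx]) acc -= wx[id] * v[id + sx];
          if (i > 0 && wx[id - sx] > 0 && free_[id - sx]) acc -= wx[id - sx] * v[id - sx];
          if (j + 1 < ny && wy[id] > 0 && free_[id + sy]) acc -= wy[id] * v[id + sy];
          if (j > 0 && wy[id - sy] > 0 && free_[id - sy]) acc -= wy[id - sy] * v[id - sy];
          if (k + 1 < nz && wz[id] > 0 && free_[id + sz]) acc -= wz[id] * v[id + sz];
          if (k > 0 && wz[id - sz] > 0 && free_[id - sz]) acc -= wz[id - sz] * v[id - sz];
          out[id] = acc;
        }
  };

  double bnorm = 0.0;
  for (R_xlen_t id = 0; id < N; ++id) bnorm += b[id] * b[id];
  bnorm = std::sqrt(bnorm);

  int iter = 0;
  double rnorm = bnorm;
  bool converged = (bnorm == 0.0);
  if (!converged) {
    for (R_xlen_t id = 0; id < N; ++id) r[id] = b[id];  // x = 0
    double rz = 0.0;
    for (R_xlen_t id = 0; id < N; ++id) {
      z[id] = (free_[id] && diag[id] > 0) ? r[id] / diag[id] : 0.0;
      rz += r[id] * z[id];
      p[id] = z[id];
    }
    for (iter = 1; iter <= maxit; ++iter) {
      applyA(p, Ap);
      double pAp = 0.0;
      for (R_xlen_t id = 0; id < N; ++id) pAp += p[id] * Ap[id];
      if (pAp <= 0.0) break;
      double alpha = rz / pAp;
      rnorm = 0.0;
      for (R_xlen_t id = 0; id < N; ++id) {
        x[id] += alpha * p[id];
        r[id] -= alpha * Ap[id];
        rnorm += r[id] * r[id];
      }
      rnorm = std::sqrt(rnorm);
      if (rnorm <= rtol * bnorm || rnorm <= atol) { converged = true; break; }
      double rznew = 0.0;
      for (R_xlen_t id = 0; id < N; ++id) {
        z[id] = (free_[id] && diag[id] > 0) ? r[id] / diag[id] : 0.0;
        rznew += r[id] * z[id];
      }
      double beta = rznew / rz;
      rz = rznew;
      for (R_xlen_t id = 0; id < N; ++id) p[id] = z[id] + beta * p[id];
    }
  }

  NumericVector out(N);
  for (R_xlen_t id = 0; id < N; ++id) {
    if (dmask[id] != 0) out[id] = dval[id];
    else if (free_[id]) out[id] = x[id];
    else out[id] = NA_REAL;  // excluded insulator voxel
  }
  out.attr("dim") = dim;
  return List::create(_["phi"] = out, _["iterations"] = iter,
                      _["relative_residual"] = bnorm > 0 ? rnorm / bnorm : 0.0,
                      _["converged"] = converged);
}

// Net current (amperes) leaving the Dirichlet voxels selected by group_mask,
// through faces shared with free conducting voxels. phi in volts, voxel edge
// h_mm in millimetres. Positive when the group is at higher potential than
// its surroundings (anodic).
// [[Rcpp::export]]
double cpp_dirichlet_flux(NumericVector phi, NumericVector sigma,
                          IntegerVector dim, IntegerVector dmask,
                          LogicalVector group_mask, double h_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  double total = 0.0;
  const double geo = h_mm * 1e-3;  // face area / spacing, metres
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t id = i + sy * j + sz * k;
        if (!group_mask[id]) continue;
        const int di[6] = {1, -1, 0, 0, 0, 0};
        const int dj[6] = {0, 0, 1, -1, 0, 0};
        const int dk[6] = {0, 0, 0, 0, 1, -1};
        for (int f = 0; f < 6; ++f) {
          int ii = i + di[f], jj = j + dj[f], kk = k + dk[f];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          R_xlen_t nb = ii + sy * jj + sz * kk;
          if (dmask[nb] != 0 || sigma[nb] <= 0.0) continue;
          double w = harm(sigma[id], sigma[nb]);
          if (w <= 0.0 || NumericVector::is_na(phi[nb])) continue;
          total += w * geo * (phi[id] - phi[nb]);
        }
      }
  return total;
}
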