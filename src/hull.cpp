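#include <Rcpp.h>
#include <cmath>
#include <map>
#include <utility>
#include <vector>
using namespace Rcpp;

// Quickhull in three dimensions. Input points are expected to carry a tiny
// deterministic jitter (added by the R caller) so that exact degeneracies on
// lattice-like inputs are broken; the output is the triangulated hull with
// outward unit normals and plane offsets (n . x = d, interior n . x < d).

struct Face {
  int a, b, c;
  double nx, ny, nz, d;
  bool alive;
  std::vector<int> outside;
};

static void face_plane(const std::vector<double>& X, const std::vector<double>& Y,
                       const std::vector<double>& Z, Face& f,
                       double ix, double iy, double iz) {
  double ux = X[f.b] - X[f.a], uy = Y[f.b] - Y[f.a], uz = Z[f.b] - Z[f.a];
  double vx = X[f.c] - X[f.a], vy = Y[f.c] - Y[f.a], vz = Z[f.c] - Z[f.a];
  double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz, nz = ux * vy - uy * vx;
  double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
  if (nrm <= 0) { f.nx = f.ny = f.nz = 0; f.d = 0; return; }
  nx /= nrm; ny /= nrm; nz /= nrm;
  double d = nx * X[f.a] + ny * Y[f.a] + nz * Z[f.a];
  // orient away from the interior reference point
  if (nx * ix + ny * iy + nz * iz > d) {
    nx = -nx; ny = -ny; nz = -nz; d = -d;
    std::swap(f.b, f.c);
  }
  f.nx = nx; f.ny = ny; f.nz = nz; f.d = d;
}

// [[Rcpp::export]]
List cpp_convex_hull(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4)
    return List::create(_["ok"] = false);
  std::vector<double> X(n), Y(n), Z(n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2);
    double v[3] = {X[i], Y[i], Z[i]};
    for (int k = 0; k < 3; ++k) {
      if (v[k] < lo[k]) lo[k] = v[k];
      if (v[k] > hi[k]) hi[k] = v[k];
    }
  }
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                          (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  if (diag <= 0) return List::create(_["ok"] = false);
  const double eps = 1e-10 * diag + 1e-14;

  // initial simplex: extreme pair, furthest from line, furthest from plane
  int i0 = 0, i1 = 0;
  {
    double best = -1;
    for (int a = 0; a < 3; ++a) {
      int lo_i = 0, hi_i = 0;
      for (int i = 1; i < n; ++i) {
        double v = (a == 0 ? X[i] : a == 1 ? Y[i] : Z[i]);
        double vlo = (a == 0 ? X[lo_i] : a == 1 ? Y[lo_i] : Z[lo_i]);
        double vhi = (a == 0 ? X[hi_i] : a == 1 ? Y[hi_i] : Z[hi_i]);
        if (v < vlo) lo_i = i;
        if (v > vhi) hi_i = i;
      }
      double dx = X[hi_i] - X[lo_i], dy = Y[hi_i] - Y[lo_i], dz = Z[hi_i] - Z[lo_i];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) { best = d2; i0 = lo_i; i1 = hi_i; }
    }
    if (best <= eps * eps) return List::create(_["ok"] = false);
  }
  int i2 = -1;
  {
    double best = -1;
    double ax = X[i1] - X[i0], ay = Y[i1] - Y[i0], az = Z[i1] - Z[i0];
    double a2 = ax * ax + ay * ay + az * az;
    for (int i = 0; i < n; ++i) {
      double px = X[i] - X[i0], py = Y[i] - Y[i0], pz = Z[i] - Z[i0];
      double t = (px * ax + py * ay + pz * az) / a2;
      double dx = px - t * ax, dy = py - t * ay, dz = pz - t * az;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) { best = d2; i2 = i; }
    }
    if (best <= eps * eps) return List::create(_["ok"] = false);
  }
  int i3 = -1;
  {
    double ux = X[i1] - X[i0], uy = Y[i1] - Y[i0], uz = Z[i1] - Z[i0];
    double vx = X[i2] - X[i0], vy = Y[i2] - Y[i0], vz = Z[i2] - Z[i0];
    double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz, nz = ux * vy - uy * vx;
    double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
    nx /= nn; ny /= nn; nz /= nn;
    double best = -1;
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(nx * (X[i] - X[i0]) + ny * (Y[i] - Y[i0]) +
                           nz * (Z[i] - Z[i0]));
      if (d > best) { best = d; i3 = i; }
    }
    if (best <= eps) return List::create(_["ok"] = false);  // coplanar input
  }

  double ix = (X[i0] + X[i1] + X[i2] + X[i3]) / 4.0;
  double iy = (Y[i0] + Y[i1] + Y[i2] + Y[i3]) / 4.0;
  double iz = (Z[i0] + Z[i1] + Z[i2] + Z[i3]) / 4.0;

  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c) {
    Face f; f.a = a; f.b = b; f.c = c; f.alive = true;
    face_plane(X, Y, Z, f, ix, iy, iz);
    faces.push_back(f);
    return (int)faces.size() - 1;
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  auto fdist = [&](const Face& f, int i) {
    return f.nx * X[i] + f.ny * Y[i] + f.nz * Z[i] - f.d;
  };

  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (size_t fi = 0; fi < faces.size(); ++fi)
      if (fdist(faces[fi], i) > eps) { faces[fi].outside.push_back(i); break; }
  }

  for (int guard = 0; guard < 20 * n + 100; ++guard) {
    int fsel = -1, apex = -1;
    double best = eps;
    for (size_t fi = 0; fi < faces.size(); ++fi) {
      if (!faces[fi].alive || faces[fi].outside.empty()) continue;
      for (int i : faces[fi].outside) {
        double d = fdist(faces[fi], i);
        if (d > best) { best = d; fsel = (int)fi; apex = i; }
      }
      if (fsel >= 0) break;  // furthest of the first non-empty face is enough
    }
    if (fsel < 0) break;

    // visible faces and horizon
    std::vector<int> visible;
    for (size_t fi = 0; fi < faces.size(); ++fi)
      if (faces[fi].alive && fdist(faces[fi], apex) > eps)
        visible.push_back((int)fi);
    std::map<std::pair<int, int>, int> edge_count;
    std::vector<int> orphan;
    for (int fi : visible) {
      Face& f = faces[fi];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int k = 0; k < 3; ++k) {
        int a = std::min(e[k][0], e[k][1]), b = std::max(e[k][0], e[k][1]);
        edge_count[{a, b}]++;
      }
      for (int i : f.outside) if (i != apex) orphan.push_back(i);
      f.alive = false;
      f.outside.clear();
    }
    std::vector<int> fresh;
    for (auto& kv : edge_count)
      if (kv.second == 1)
        fresh.push_back(add_face(kv.first.first, kv.first.second, apex));
    for (int i : orphan) {
      for (int fi : fresh)
        if (fdist(faces[fi], i) > eps) { faces[fi].outside.push_back(i); break; }
    }
  }

  int nf = 0;
  for (auto& f : faces) if (f.alive) ++nf;
  IntegerMatrix tri(nf, 3);
  NumericMatrix nrm(nf, 3);
  NumericVector off(nf);
  double vol = 0.0;
  int r = 0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    tri(r, 0) = f.a + 1; tri(r, 1) = f.b + 1; tri(r, 2) = f.c + 1;
    nrm(r, 0) = f.nx; nrm(r, 1) = f.ny; nrm(r, 2) = f.nz;
    off[r] = f.d;
    // signed tetra volume against the interior reference point
    double ax = X[f.a] - ix, ay = Y[f.a] - iy, az = Z[f.a] - iz;
    double bx = X[f.b] - ix, by = Y[f.b] - iy, bz = Z[f.b] - iz;
    double cx = X[f.c] - ix, cy = Y[f.c] - iy, cz = Z[f.c] - iz;
    vol += std::fabs(ax * (by * cz - bz * cy) + ay * (bz * cx - bx * cz) +
                     az * (bx * cy - by * cx)) / 6.0;
    ++r;
  }
  return List::create(_["ok"] = true, _["faces"] = tri, _["normals"] = nrm,
                      _["offsets"] = off, _["volume"] = vol);
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_hull(NumericMatrix normals, NumericVector offsets,
                                 NumericMatrix pts, double tol) {
  const int n = pts.nrow(), m = normals.nrow();
  LogicalVector inside(n);
  for (int i = 0; i < n; ++i) {
    bool in = true;
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    for (int f = 0; f < m; ++f) {
      if (normals(f, 0) * x + normals(f, 1) * y + normals(f, 2) * z >
          offsets[f] + tol) { in = false; break; }
    }
    inside[i] = in;
  }
  return inside;
}
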