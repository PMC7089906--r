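// Segment-triangle intersection core (Moller-Trumbore) with a uniform-grid
// broad phase.  All geometry is in millimetres; faces are passed 0-based.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline void sub3(const double* a, const double* b, double* r) {
  r[0] = a[0] - b[0]; r[1] = a[1] - b[1]; r[2] = a[2] - b[2];
}
static inline void cross3(const double* a, const double* b, double* r) {
  r[0] = a[1] * b[2] - a[2] * b[1];
  r[1] = a[2] * b[0] - a[0] * b[2];
  r[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// Parallel-determinant threshold: 1e-12 on the MT determinant, made
// dimensionless by the natural scale |e1| * |dir x e2|.
static const double MT_EPS = 1e-12;

// Segment p0 -> p1 against triangle (a, b, c).  On hit writes the crossing
// point to pt and returns true.  Bounds are closed: s, u, v in [0, 1].
static bool seg_tri(const double* p0, const double* p1,
                    const double* a, const double* b, const double* c,
                    double* pt) {
  double d[3], e1[3], e2[3], h[3], s0[3], q[3];
  sub3(p1, p0, d);
  sub3(b, a, e1);
  sub3(c, a, e2);
  cross3(d, e2, h);
  double det = dot3(e1, h);
  double scale = norm3(e1) * norm3(h);
  if (std::fabs(det) <= MT_EPS * (scale > 0 ? scale : 1.0)) return false;
  double f = 1.0 / det;
  sub3(p0, a, s0);
  double u = f * dot3(s0, h);
  if (u < 0.0 || u > 1.0) return false;
  cross3(s0, e1, q);
  double v = f * dot3(d, q);
  if (v < 0.0 || u + v > 1.0) return false;
  double t = f * dot3(e2, q);
  if (t < 0.0 || t > 1.0) return false;
  pt[0] = p0[0] + t * d[0];
  pt[1] = p0[1] + t * d[1];
  pt[2] = p0[2] + t * d[2];
  return true;
}

struct UniformGrid {
  double org[3];
  double cell;
  int n[3];
  std::vector<std::vector<int> > bins;

  int idx(int i, int j, int k) const { return (k * n[1] + j) * n[0] + i; }

  void build(const NumericMatrix& V, const IntegerMatrix& F) {
    int m = F.nrow();
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    double ext_sum = 0.0;
    std::vector<double> tlo(3 * m), thi(3 * m);
    for (int f = 0; f < m; ++f) {
      for (int d = 0; d < 3; ++d) {
        double a = V(F(f, 0), d), b = V(F(f, 1), d), c = V(F(f, 2), d);
        double mn = std::min(a, std::min(b, c));
        double mx = std::max(a, std::max(b, c));
        tlo[3 * f + d] = mn; thi[3 * f + d] = mx;
        if (mn < lo[d]) lo[d] = mn;
        if (mx > hi[d]) hi[d] = mx;
        ext_sum += mx - mn;
      }
    }
    // Cell size: mean triangle extent, floored to a fraction of the bbox.
    cell = ext_sum / (3.0 * m);
    double diag = 0.0;
    for (int d = 0; d < 3; ++d) diag = std::max(diag, hi[d] - lo[d]);
    if (cell <= 0 || !R_finite(cell)) cell = diag > 0 ? diag : 1.0;
    cell = std::max(cell, diag / 96.0);
    for (int d = 0; d < 3; ++d) {
      org[d] = lo[d];
      n[d] = std::max(1, std::min(96, (int)std::ceil((hi[d] - lo[d]) / cell) + 1));
    }
    bins.assign((size_t)n[0] * n[1] * n[2], std::vector<int>());
    for (int f = 0; f < m; ++f) {
      int c0[3], c1[3];
      for (int d = 0; d < 3; ++d) {
        c0[d] = std::max(0, std::min(n[d] - 1, (int)std::floor((tlo[3 * f + d] - org[d]) / cell)));
        c1[d] = std::max(0, std::min(n[d] - 1, (int)std::floor((thi[3 * f + d] - org[d]) / cell)));
      }
      for (int k = c0[2]; k <= c1[2]; ++k)
        for (int j = c0[1]; j <= c1[1]; ++j)
          for (int i = c0[0]; i <= c1[0]; ++i)
            bins[idx(i, j, k)].push_back(f);
    }
  }
};

// Test every segment (rows of P0 -> P1) against every triangle of (V, F).
// Returns 1-based segment/triangle indices of each crossing plus the points.
// use_grid = false runs the exhaustive all-pairs loop (the broad phase must
// be behaviourally identical; tests assert this).
// [[Rcpp::export]]
List edges_vs_mesh_cpp(NumericMatrix P0, NumericMatrix P1,
                       NumericMatrix V, IntegerMatrix F,
                       bool any_hit, bool use_grid) {
  int ne = P0.nrow(), m = F.nrow();
  std::vector<int> hit_e, hit_f;
  std::vector<double> pts;
  if (m == 0 || ne == 0) {
    return List::create(_["edge"] = IntegerVector(0), _["tri"] = IntegerVector(0),
                        _["points"] = NumericMatrix(0, 3));
  }
  UniformGrid grid;
  if (use_grid) grid.build(V, F);
  std::vector<int> stamp(m, -1);
  double p0[3], p1[3], a[3], b[3], c[3], pt[3];
  bool done = false;
  for (int e = 0; e < ne && !done; ++e) {
    for (int d = 0; d < 3; ++d) { p0[d] = P0(e, d); p1[d] = P1(e, d); }
    if (use_grid) {
      int c0[3], c1[3];
      bool outside = false;
      for (int d = 0; d < 3; ++d) {
        double lo = std::min(p0[d], p1[d]), hi = std::max(p0[d], p1[d]);
        if (hi < grid.org[d] || lo > grid.org[d] + grid.cell * grid.n[d]) { outside = true; break; }
        c0[d] = std::max(0, std::min(grid.n[d] - 1, (int)std::floor((lo - grid.org[d]) / grid.cell)));
        c1[d] = std::max(0, std::min(grid.n[d] - 1, (int)std::floor((hi - grid.org[d]) / grid.cell)));
      }
      if (outside) continue;
      for (int k = c0[2]; k <= c1[2] && !done; ++k)
        for (int j = c0[1]; j <= c1[1] && !done; ++j)
          for (int i = c0[0]; i <= c1[0] && !done; ++i) {
            const std::vector<int>& bin = grid.bins[grid.idx(i, j, k)];
            for (size_t q = 0; q < bin.size(); ++q) {
              int f = bin[q];
              if (stamp[f] == e) continue;
              stamp[f] = e;
              for (int d = 0; d < 3; ++d) {
                a[d] = V(F(f, 0), d); b[d] = V(F(f, 1), d); c[d] = V(F(f, 2), d);
              }
              if (seg_tri(p0, p1, a, b, c, pt)) {
                hit_e.push_back(e + 1); hit_f.push_back(f + 1);
                pts.push_back(pt[0]); pts.push_back(pt[1]); pts.push_back(pt[2]);
                if (any_hit) { done = true; break; }
              }
            }
          }
    } else {
      for (int f = 0; f < m; ++f) {
        for (int d = 0; d < 3; ++d) {
          a[d] = V(F(f, 0), d); b[d] = V(F(f, 1), d); c[d] = V(F(f, 2), d);
        }
        if (seg_tri(p0, p1, a, b, c, pt)) {
          hit_e.push_back(e + 1); hit_f.push_back(f + 1);
          pts.push_back(pt[0]); pts.push_back(pt[1]); pts.push_back(pt[2]);
          if (any_hit) { done = true; break; }
        }
      }
    }
  }
  int nh = (int)hit_e.size();
  NumericMatrix P(nh, 3);
  for (int i = 0; i < nh; ++i)
    for (int d = 0; d < 3; ++d) P(i, d) = pts[3 * i + d];
  return List::create(_["edge"] = wrap(hit_e), _["tri"] = wrap(hit_f), _["points"] = P);
}

// Any segment in (P0, P1) crossing any triangle of the grid-indexed mesh?
static bool any_crossing(const std::vector<double>& P0,
                         const std::vector<double>& P1, int ne,
                         const NumericMatrix& V, const IntegerMatrix& F,
                         const UniformGrid& grid, std::vector<int>& stamp) {
  double a[3], b[3], c[3], pt[3];
  for (int e = 0; e < ne; ++e) {
    const double* p0 = &P0[3 * e];
    const double* p1 = &P1[3 * e];
    int c0[3], c1[3];
    bool outside = false;
    for (int d = 0; d < 3; ++d) {
      double lo = std::min(p0[d], p1[d]), hi = std::max(p0[d], p1[d]);
      if (hi < grid.org[d] || lo > grid.org[d] + grid.cell * grid.n[d]) { outside = true; break; }
      c0[d] = std::max(0, std::min(grid.n[d] - 1, (int)std::floor((lo - grid.org[d]) / grid.cell)));
      c1[d] = std::max(0, std::min(grid.n[d] - 1, (int)std::floor((hi - grid.org[d]) / grid.cell)));
    }
    if (outside) continue;
    for (int k = c0[2]; k <= c1[2]; ++k)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int i = c0[0]; i <= c1[0]; ++i) {
          const std::vector<int>& bin = grid.bins[grid.idx(i, j, k)];
          for (size_t q = 0; q < bin.size(); ++q) {
            int f = bin[q];
            if (stamp[f] == e) continue;
            stamp[f] = e;
            for (int d = 0; d < 3; ++d) {
              a[d] = V(F(f, 0), d); b[d] = V(F(f, 1), d); c[d] = V(F(f, 2), d);
            }
            if (seg_tri(p0, p1, a, b, c, pt)) return true;
          }
        }
  }
  return false;
}

// First pose (1-based index) at which mesh A, rigidly posed by rotation
// R_all[3*p..3*p+2, ] and translation T[p, ], crosses mesh B; 0 if none.
// Both directions of the edge-vs-triangle test are evaluated: A's edges
// against B in world coordinates, and B's edges pulled back into A's local
// frame by the inverse pose (rigid motions preserve crossings), so the
// spatial grids of both meshes are built once for the whole sweep.
// [[Rcpp::export]]
int first_crossing_pose_cpp(NumericMatrix VA, IntegerMatrix EA,
                            IntegerMatrix FA, NumericMatrix VB,
                            IntegerMatrix EB, IntegerMatrix FB,
                            NumericMatrix R_all, NumericMatrix T) {
  int npose = T.nrow();
  int nea = EA.nrow(), neb = EB.nrow();
  if (FA.nrow() == 0 || FB.nrow() == 0) return 0;
  UniformGrid gridA, gridB;
  gridA.build(VA, FA);
  gridB.build(VB, FB);
  std::vector<int> stampA(FA.nrow(), -1), stampB(FB.nrow(), -1);
  std::vector<double> ea0(3 * nea), ea1(3 * nea), eb0(3 * neb), eb1(3 * neb);
  for (int p = 0; p < npose; ++p) {
    double R[3][3], t[3];
    for (int i = 0; i < 3; ++i) {
      t[i] = T(p, i);
      for (int j = 0; j < 3; ++j) R[i][j] = R_all(3 * p + i, j);
    }
    // A edges into world frame
    for (int e = 0; e < nea; ++e) {
      int va = EA(e, 0), vb = EA(e, 1);
      for (int i = 0; i < 3; ++i) {
        ea0[3 * e + i] = R[i][0] * VA(va, 0) + R[i][1] * VA(va, 1) + R[i][2] * VA(va, 2) + t[i];
        ea1[3 * e + i] = R[i][0] * VA(vb, 0) + R[i][1] * VA(vb, 1) + R[i][2] * VA(vb, 2) + t[i];
      }
    }
    std::fill(stampB.begin(), stampB.end(), -1);
    if (any_crossing(ea0, ea1, nea, VB, FB, gridB, stampB)) return p + 1;
    // B edges into A's local frame: x_local = R^T (x - t)
    for (int e = 0; e < neb; ++e) {
      int va = EB(e, 0), vb = EB(e, 1);
      double u[3], w[3];
      for (int i = 0; i < 3; ++i) { u[i] = VB(va, i) - t[i]; w[i] = VB(vb, i) - t[i]; }
      for (int i = 0; i < 3; ++i) {
        eb0[3 * e + i] = R[0][i] * u[0] + R[1][i] * u[1] + R[2][i] * u[2];
        eb1[3 * e + i] = R[0][i] * w[0] + R[1][i] * w[1] + R[2][i] * w[2];
      }
    }
    std::fill(stampA.begin(), stampA.end(), -1);
    if (any_crossing(eb0, eb1, neb, VA, FA, gridA, stampA)) return p + 1;
  }
  return 0;
}

// All hits of the unbounded ray origin + t*dir (t >= 0) against a mesh.
// Rows of the result: t, u, v, tri (1-based).  Used for parity containment.
// [[Rcpp::export]]
NumericMatrix ray_mesh_hits_cpp(NumericVector origin, NumericVector dir,
                                NumericMatrix V, IntegerMatrix F) {
  int m = F.nrow();
  std::vector<double> out;
  double o[3] = {origin[0], origin[1], origin[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  double a[3], b[3], c[3], e1[3], e2[3], h[3], s0[3], q[3];
  for (int f = 0; f < m; ++f) {
    for (int k = 0; k < 3; ++k) {
      a[k] = V(F(f, 0), k); b[k] = V(F(f, 1), k); c[k] = V(F(f, 2), k);
    }
    sub3(b, a, e1); sub3(c, a, e2);
    cross3(d, e2, h);
    double det = dot3(e1, h);
    double scale = norm3(e1) * norm3(h);
    if (std::fabs(det) <= MT_EPS * (scale > 0 ? scale : 1.0)) continue;
    double fct = 1.0 / det;
    sub3(o, a, s0);
    double u = fct * dot3(s0, h);
    if (u < 0.0 || u > 1.0) continue;
    cross3(s0, e1, q);
    double v = fct * dot3(d, q);
    if (v < 0.0 || u + v > 1.0) continue;
    double t = fct * dot3(e2, q);
    if (t < 0.0) continue;
    out.push_back(t); out.push_back(u); out.push_back(v); out.push_back(f + 1);
  }
  int nh = (int)out.size() / 4;
  NumericMatrix R(nh, 4);
  for (int i = 0; i < nh; ++i)
    for (int k = 0; k < 4; ++k) R(i, k) = out[4 * i + k];
  colnames(R) = CharacterVector::create("t", "u", "v", "tri");
  return R;
}
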