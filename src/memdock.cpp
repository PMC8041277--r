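#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Trilinear sampling of a regular cubic grid. Grid node (i,j,k) sits at
// origin + spacing * (i,j,k); queries outside the grid return 0.
// ---------------------------------------------------------------------------

static inline double tri_sample(const double* v, int nx, int ny, int nz,
                                const double* origin, double h,
                                double px, double py, double pz,
                                bool* outside) {
  double u = (px - origin[0]) / h;
  double w = (py - origin[1]) / h;
  double s = (pz - origin[2]) / h;
  if (u < 0 || w < 0 || s < 0 || u > nx - 1 || w > ny - 1 || s > nz - 1) {
    if (outside) *outside = true;
    return 0.0;
  }
  if (outside) *outside = false;
  int i0 = std::min((int)std::floor(u), nx - 2);
  int j0 = std::min((int)std::floor(w), ny - 2);
  int k0 = std::min((int)std::floor(s), nz - 2);
  double fx = u - i0, fy = w - j0, fz = s - k0;
  double acc = 0.0;
  for (int di = 0; di < 2; ++di)
    for (int dj = 0; dj < 2; ++dj)
      for (int dk = 0; dk < 2; ++dk) {
        double wt = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        acc += wt * v[(i0 + di) + (size_t)nx * ((j0 + dj) + (size_t)ny * (k0 + dk))];
      }
  return acc;
}

// [[Rcpp::export]]
NumericVector trilinear_cpp(NumericVector values, NumericVector origin,
                            double spacing, NumericMatrix pts) {
  IntegerVector d = values.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int n = pts.nrow();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    out[q] = tri_sample(REAL(values), nx, ny, nz, REAL(origin), spacing,
                        pts(q, 0), pts(q, 1), pts(q, 2), nullptr);
  }
  return out;
}

// Node gradient by central differences (one-sided at boundaries).
static inline double node_grad(const double* v, int nx, int ny, int nz,
                               double h, int i, int j, int k, int axis) {
  int n[3] = {nx, ny, nz};
  int idx[3] = {i, j, k};
  int lo[3] = {i, j, k}, hi[3] = {i, j, k};
  double denom = 2.0 * h;
  if (idx[axis] == 0) { hi[axis] = 1; denom = h; }
  else if (idx[axis] == n[axis] - 1) { lo[axis] = n[axis] - 2; denom = h; }
  else { lo[axis] -= 1; hi[axis] += 1; }
  size_t ilo = lo[0] + (size_t)nx * (lo[1] + (size_t)ny * lo[2]);
  size_t ihi = hi[0] + (size_t)nx * (hi[1] + (size_t)ny * hi[2]);
  return (v[ihi] - v[ilo]) / denom;
}

// [[Rcpp::export]]
NumericMatrix gradient_cpp(NumericVector values, NumericVector origin,
                           double spacing, NumericMatrix pts) {
  IntegerVector d = values.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  const double* v = REAL(values);
  const double* o = REAL(origin);
  double h = spacing;
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int q = 0; q < n; ++q) {
    double u = (pts(q, 0) - o[0]) / h;
    double w = (pts(q, 1) - o[1]) / h;
    double s = (pts(q, 2) - o[2]) / h;
    if (u < 0 || w < 0 || s < 0 || u > nx - 1 || w > ny - 1 || s > nz - 1)
      continue;  // zero gradient outside
    int i0 = std::min((int)std::floor(u), nx - 2);
    int j0 = std::min((int)std::floor(w), ny - 2);
    int k0 = std::min((int)std::floor(s), nz - 2);
    double fx = u - i0, fy = w - j0, fz = s - k0;
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj)
        for (int dk = 0; dk < 2; ++dk) {
          double wt = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          for (int ax = 0; ax < 3; ++ax)
            out(q, ax) += wt * node_grad(v, nx, ny, nz, h,
                                         i0 + di, j0 + dj, k0 + dk, ax);
        }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Isosurface extraction: marching tetrahedra on a 6-tet cube decomposition.
// Edge vertices are first placed by linear interpolation, then refined by
// bisection on the trilinear interpolant so every vertex sits on the level
// set of the continuous field, not just of its per-edge linearisation.
// Vertices are deduplicated on (sorted) global-corner edge keys.
// ---------------------------------------------------------------------------

struct VertexPool {
  std::unordered_map<uint64_t, int> index;
  std::vector<double> xyz;  // interleaved
};

static int edge_vertex(VertexPool& pool, const double* v, int nx, int ny, int nz,
                       const double* origin, double h, double iso,
                       size_t ga, size_t gb, double fa, double fb,
                       const double* pa, const double* pb) {
  uint64_t key = ga < gb ? ((uint64_t)ga << 32 | gb) : ((uint64_t)gb << 32 | ga);
  auto it = pool.index.find(key);
  if (it != pool.index.end()) return it->second;
  double t = (iso - fa) / (fb - fa);
  double lo = 0.0, hi = 1.0, flo = fa, fhi = fb;
  // bisection on the trilinear field along the segment (12 iterations keeps
  // |value - iso| far below the 5% level-set tolerance)
  double x = pa[0] + t * (pb[0] - pa[0]);
  double y = pa[1] + t * (pb[1] - pa[1]);
  double z = pa[2] + t * (pb[2] - pa[2]);
  for (int it2 = 0; it2 < 24; ++it2) {
    double fm = tri_sample(v, nx, ny, nz, origin, h, x, y, z, nullptr);
    if ((fm - iso) * (flo - iso) <= 0) { hi = t; fhi = fm; }
    else { lo = t; flo = fm; }
    t = 0.5 * (lo + hi);
    x = pa[0] + t * (pb[0] - pa[0]);
    y = pa[1] + t * (pb[1] - pa[1]);
    z = pa[2] + t * (pb[2] - pa[2]);
  }
  int id = (int)(pool.xyz.size() / 3);
  pool.xyz.push_back(x); pool.xyz.push_back(y); pool.xyz.push_back(z);
  pool.index[key] = id;
  return id;
}

// [[Rcpp::export]]
List marching_tetrahedra_cpp(NumericVector values, NumericVector origin,
                             double spacing, double iso) {
  IntegerVector d = values.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  const double* v = REAL(values);
  const double* o = REAL(origin);
  double h = spacing;

  // cube corner offsets, numbered so the 6 tetrahedra share diagonal 0-6
  static const int co[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};

  VertexPool pool;
  std::vector<int> faces;

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        size_t gidx[8];
        double f[8], pos[8][3];
        for (int c = 0; c < 8; ++c) {
          int ci = i + co[c][0], cj = j + co[c][1], ck = k + co[c][2];
          gidx[c] = ci + (size_t)nx * (cj + (size_t)ny * ck);
          f[c] = v[gidx[c]];
          pos[c][0] = o[0] + h * ci;
          pos[c][1] = o[1] + h * cj;
          pos[c][2] = o[2] + h * ck;
        }
        for (int t = 0; t < 6; ++t) {
          int tv[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (f[tv[c]] > iso) in[nin++] = tv[c]; else out[nout++] = tv[c];
          }
          if (nin == 0 || nin == 4) continue;
          auto ev = [&](int a, int b) {
            return edge_vertex(pool, v, nx, ny, nz, o, h, iso,
                               gidx[a], gidx[b], f[a], f[b], pos[a], pos[b]);
          };
          if (nin == 1) {
            faces.push_back(ev(in[0], out[0]));
            faces.push_back(ev(in[0], out[1]));
            faces.push_back(ev(in[0], out[2]));
          } else if (nin == 3) {
            faces.push_back(ev(out[0], in[0]));
            faces.push_back(ev(out[0], in[1]));
            faces.push_back(ev(out[0], in[2]));
          } else {  // 2 in, 2 out: quad -> two triangles
            int a0 = ev(in[0], out[0]), a1 = ev(in[0], out[1]);
            int b0 = ev(in[1], out[0]), b1 = ev(in[1], out[1]);
            faces.push_back(a0); faces.push_back(a1); faces.push_back(b1);
            faces.push_back(a0); faces.push_back(b1); faces.push_back(b0);
          }
        }
      }

  int nv = (int)(pool.xyz.size() / 3);
  NumericMatrix V(nv, 3);
  for (int a = 0; a < nv; ++a) {
    V(a, 0) = pool.xyz[3 * a];
    V(a, 1) = pool.xyz[3 * a + 1];
    V(a, 2) = pool.xyz[3 * a + 2];
  }
  int nf = (int)(faces.size() / 3);
  IntegerMatrix F(nf, 3);
  for (int a = 0; a < nf; ++a) {
    F(a, 0) = faces[3 * a] + 1;  // 1-based for R
    F(a, 1) = faces[3 * a + 1] + 1;
    F(a, 2) = faces[3 * a + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Exact nearest-neighbour queries via a uniform cell grid with expanding-ring
// search. Ties in distance are broken by the lowest reference index.
// ---------------------------------------------------------------------------

struct CellGrid {
  std::vector<double> pts;  // interleaved xyz
  int npts = 0;
  double lo[3], hi[3], cell = 1.0;  // lo/hi: exact point bounding box
  int nc[3];
  std::vector<int> cellStart;  // CSR offsets, size ncells+1
  std::vector<int> order;      // point ids sorted by cell
};

static void grid_build(CellGrid& g, const NumericMatrix& ref) {
  int m = ref.nrow();
  g.npts = m;
  g.pts.resize(3 * m);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int a = 0; a < m; ++a)
    for (int c = 0; c < 3; ++c) {
      double x = ref(a, c);
      g.pts[3 * a + c] = x;
      if (x < lo[c]) lo[c] = x;
      if (x > hi[c]) hi[c] = x;
    }
  for (int c = 0; c < 3; ++c) g.hi[c] = hi[c];
  double vol = 1.0;
  for (int c = 0; c < 3; ++c) vol *= std::max(hi[c] - lo[c], 1e-6);
  g.cell = std::max(std::cbrt(vol / std::max(m, 1) * 2.0), 1e-6);
  for (int c = 0; c < 3; ++c) {
    g.lo[c] = lo[c];
    g.nc[c] = std::max(1, (int)std::floor((hi[c] - lo[c]) / g.cell) + 1);
  }
  size_t ncells = (size_t)g.nc[0] * g.nc[1] * g.nc[2];
  std::vector<int> count(ncells + 1, 0);
  std::vector<int> cellOf(m);
  for (int a = 0; a < m; ++a) {
    int ci[3];
    for (int c = 0; c < 3; ++c) {
      ci[c] = std::min((int)((g.pts[3 * a + c] - g.lo[c]) / g.cell), g.nc[c] - 1);
      if (ci[c] < 0) ci[c] = 0;
    }
    cellOf[a] = ci[0] + g.nc[0] * (ci[1] + g.nc[1] * ci[2]);
    count[cellOf[a] + 1]++;
  }
  for (size_t c = 1; c <= ncells; ++c) count[c] += count[c - 1];
  g.cellStart = count;
  g.order.resize(m);
  std::vector<int> cursor(g.cellStart.begin(), g.cellStart.end() - 1);
  for (int a = 0; a < m; ++a) g.order[cursor[cellOf[a]]++] = a;  // ascending ids per cell
}

// exact nearest reference point to q; ties -> lowest index
static void grid_query(const CellGrid& g, const double* q, int* bestIdx,
                       double* bestDist) {
  int qc[3];
  double boxd2 = 0.0;
  for (int c = 0; c < 3; ++c) {
    double rel = (q[c] - g.lo[c]) / g.cell;
    qc[c] = std::min(std::max((int)std::floor(rel), 0), g.nc[c] - 1);
    double lo = g.lo[c], hi = g.lo[c] + g.cell * g.nc[c];
    double d = q[c] < lo ? lo - q[c] : (q[c] > hi ? q[c] - hi : 0.0);
    boxd2 += d * d;
  }
  int best = -1;
  double bd2 = R_PosInf;
  int maxR = g.nc[0] + g.nc[1] + g.nc[2];
  for (int r = 0; r <= maxR; ++r) {
    // lower bound on the distance from q to any cell in Chebyshev ring r:
    // the out-of-box offset and the in-grid ring offset are orthogonal in
    // the worst case
    double rr = std::max(0, r - 1) * g.cell;
    double lb2 = boxd2 + rr * rr;
    if (best >= 0 && bd2 < lb2) break;
    bool any = false;
    for (int dk = -r; dk <= r; ++dk) {
      int k = qc[2] + dk;
      if (k < 0 || k >= g.nc[2]) continue;
      for (int dj = -r; dj <= r; ++dj) {
        int j = qc[1] + dj;
        if (j < 0 || j >= g.nc[1]) continue;
        for (int di = -r; di <= r; ++di) {
          if (std::max(std::abs(di), std::max(std::abs(dj), std::abs(dk))) != r)
            continue;  // ring shell only
          int i = qc[0] + di;
          if (i < 0 || i >= g.nc[0]) continue;
          any = true;
          int cid = i + g.nc[0] * (j + g.nc[1] * k);
          for (int s = g.cellStart[cid]; s < g.cellStart[cid + 1]; ++s) {
            int a = g.order[s];
            double dx = q[0] - g.pts[3 * a];
            double dy = q[1] - g.pts[3 * a + 1];
            double dz = q[2] - g.pts[3 * a + 2];
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < bd2 || (d2 == bd2 && a < best)) { bd2 = d2; best = a; }
          }
        }
      }
    }
    if (!any && best >= 0) break;
  }
  *bestIdx = best;
  *bestDist = std::sqrt(bd2);
}

// [[Rcpp::export]]
List nearest_point_cpp(NumericMatrix ref, NumericMatrix query) {
  CellGrid g;
  grid_build(g, ref);
  int n = query.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int q = 0; q < n; ++q) {
    double p[3] = {query(q, 0), query(q, 1), query(q, 2)};
    int bi; double bd;
    grid_query(g, p, &bi, &bd);
    idx[q] = bi + 1;
    dist[q] = bd;
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Opaque handle so the receptor surface index is built once per docking run.
// [[Rcpp::export]]
SEXP nn_index_build_cpp(NumericMatrix ref) {
  XPtr<CellGrid> p(new CellGrid(), true);
  grid_build(*p, ref);
  return p;
}

// ---------------------------------------------------------------------------
// Surface-complementarity score. Ligand vertices/normals are transformed by
// the pose (x' = R (x - c) + c + t, n' = R n); each transformed vertex within
// contact_distance of its nearest receptor vertex contributes
// max(0, -n_lig . n_rec); each vertex strictly inside the receptor surface
// (signed distance (v - nn) . n_rec < -clash_depth) costs clash_penalty.
// ---------------------------------------------------------------------------

static double score_one(const CellGrid& g, const NumericMatrix& recN,
                        const NumericMatrix& ligV, const NumericMatrix& ligN,
                        const double* R9, const double* tr, const double* ce,
                        double contact, double clash_penalty,
                        double clash_depth) {
  int n = ligV.nrow();
  double s = 0.0;
  int clashes = 0;
  double c2 = contact * contact;
  for (int a = 0; a < n; ++a) {
    double p0 = ligV(a, 0) - ce[0], p1 = ligV(a, 1) - ce[1], p2 = ligV(a, 2) - ce[2];
    double q[3] = {
      R9[0] * p0 + R9[3] * p1 + R9[6] * p2 + ce[0] + tr[0],
      R9[1] * p0 + R9[4] * p1 + R9[7] * p2 + ce[1] + tr[1],
      R9[2] * p0 + R9[5] * p1 + R9[8] * p2 + ce[2] + tr[2]};
    // exact early reject: beyond contact range of the receptor point bbox a
    // vertex can neither be in contact nor inside the closed surface
    double bb2 = 0.0;
    for (int c = 0; c < 3; ++c) {
      double d = q[c] < g.lo[c] ? g.lo[c] - q[c]
                                : (q[c] > g.hi[c] ? q[c] - g.hi[c] : 0.0);
      bb2 += d * d;
    }
    if (bb2 > c2) continue;
    int bi; double bd;
    grid_query(g, q, &bi, &bd);
    if (bi < 0) continue;
    double nrx = recN(bi, 0), nry = recN(bi, 1), nrz = recN(bi, 2);
    double side = (q[0] - g.pts[3 * bi]) * nrx + (q[1] - g.pts[3 * bi + 1]) * nry +
                  (q[2] - g.pts[3 * bi + 2]) * nrz;
    if (side < -clash_depth) clashes++;
    if (bd <= contact) {
      double n0 = ligN(a, 0), n1 = ligN(a, 1), n2 = ligN(a, 2);
      double nlx = R9[0] * n0 + R9[3] * n1 + R9[6] * n2;
      double nly = R9[1] * n0 + R9[4] * n1 + R9[7] * n2;
      double nlz = R9[2] * n0 + R9[5] * n1 + R9[8] * n2;
      double dot = nlx * nrx + nly * nry + nlz * nrz;
      if (-dot > 0) s += -dot;
    }
  }
  return s - clash_penalty * clashes;
}

// [[Rcpp::export]]
double score_pose_cpp(SEXP nn_index, NumericMatrix recN, NumericMatrix ligV,
                      NumericMatrix ligN, NumericMatrix rot, NumericVector trans,
                      NumericVector center, double contact,
                      double clash_penalty, double clash_depth) {
  XPtr<CellGrid> g(nn_index);
  double R9[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) R9[r + 3 * c] = rot(r, c);
  return score_one(*g, recN, ligV, ligN, R9, REAL(trans), REAL(center),
                   contact, clash_penalty, clash_depth);
}
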