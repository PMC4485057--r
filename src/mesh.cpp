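#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Signed distance to a capped cone (frustum) between a and b with radii ra,
// rb.  Negative inside, positive outside; caps count as boundary.
static inline double sdCappedCone(double px, double py, double pz,
                                  double ax, double ay, double az,
                                  double bx, double by, double bz,
                                  double ra, double rb) {
  double bax = bx - ax, bay = by - ay, baz = bz - az;
  double pax = px - ax, pay = py - ay, paz = pz - az;
  double rba = rb - ra;
  double baba = bax * bax + bay * bay + baz * baz;
  double papa = pax * pax + pay * pay + paz * paz;
  double padotba = pax * bax + pay * bay + paz * baz;
  double paba = padotba / baba;
  double x2 = papa - paba * paba * baba;
  double x = x2 > 0.0 ? std::sqrt(x2) : 0.0;
  double cax = x - (paba < 0.5 ? ra : rb);
  if (cax < 0.0) cax = 0.0;
  double cay = std::fabs(paba - 0.5) - 0.5;
  double k = rba * rba + baba;
  double f = (rba * (x - ra) + paba * baba) / k;
  if (f < 0.0) f = 0.0;
  if (f > 1.0) f = 1.0;
  double cbx = x - ra - f * rba;
  double cby = paba - f;
  double s = (cbx < 0.0 && cay < 0.0) ? -1.0 : 1.0;
  double d2a = cax * cax + cay * cay * baba;
  double d2b = cbx * cbx + cby * cby * baba;
  return s * std::sqrt(d2a < d2b ? d2a : d2b);
}

static inline double sdSphere(double px, double py, double pz,
                              double cx, double cy, double cz, double r) {
  double dx = px - cx, dy = py - cy, dz = pz - cz;
  return std::sqrt(dx * dx + dy * dy + dz * dz) - r;
}

// Evaluate the union signed-distance field (min over primitives) at
// arbitrary points.  prims: columns x0 y0 z0 x1 y1 z1 r0 r1 sphere.
// [[Rcpp::export(name = ".cppUnionSDF")]]
NumericVector cppUnionSDF(NumericMatrix pts, NumericMatrix prims) {
  int n = pts.nrow(), m = prims.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    for (int j = 0; j < m; ++j) {
      double d;
      if (prims(j, 8) > 0.5) {
        d = sdSphere(px, py, pz, prims(j, 0), prims(j, 1), prims(j, 2),
                     prims(j, 6));
      } else {
        d = sdCappedCone(px, py, pz, prims(j, 0), prims(j, 1), prims(j, 2),
                         prims(j, 3), prims(j, 4), prims(j, 5),
                         prims(j, 6), prims(j, 7));
      }
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// Kuhn 6-tetrahedra decomposition of the unit cube around diagonal 0-6.
// Cube corner order: (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),
// (1,1,1),(0,1,1).  Face diagonals match between neighbouring cubes, so the
// extracted isosurface is closed.
static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};

struct MeshAccum {
  std::unordered_map<uint64_t, int> edgeVertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

// Tessellate the union of frusta/spheres on a regular grid of the given
// pitch via marching tetrahedra over the exact union SDF.
// [[Rcpp::export(name = ".cppMeshPrimitives")]]
List cppMeshPrimitives(NumericMatrix prims, double pitch, double pad) {
  int m = prims.nrow();
  if (m == 0) stop("no primitives to tessellate");
  if (pitch <= 0) stop("pitch must be positive");

  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int j = 0; j < m; ++j) {
    double r = std::max(prims(j, 6), prims(j, 7));
    bool sph = prims(j, 8) > 0.5;
    for (int ax = 0; ax < 3; ++ax) {
      double a = prims(j, ax), b = sph ? prims(j, ax) : prims(j, 3 + ax);
      double mn = std::min(a, b) - r, mx = std::max(a, b) + r;
      if (mn < lo[ax]) lo[ax] = mn;
      if (mx > hi[ax]) hi[ax] = mx;
    }
  }
  for (int ax = 0; ax < 3; ++ax) { lo[ax] -= pad; hi[ax] += pad; }

  // node counts (grid of values at cube corners)
  int64_t n[3];
  for (int ax = 0; ax < 3; ++ax)
    n[ax] = (int64_t)std::ceil((hi[ax] - lo[ax]) / pitch) + 2;
  int64_t nx = n[0], ny = n[1], nz = n[2];
  int64_t nNodes = nx * ny * nz;
  if (nNodes > 400000000LL)
    stop("tessellation grid too large (%lld nodes); increase spatial_step",
         (long long)nNodes);

  const float BIG = 1.0e9f;
  std::vector<float> field((size_t)nNodes, BIG);

  // banded fill: exact SDF within each primitive's padded bounding box
  double band = 2.5 * pitch;
  for (int j = 0; j < m; ++j) {
    double r = std::max(prims(j, 6), prims(j, 7));
    bool sph = prims(j, 8) > 0.5;
    int64_t i0[3], i1[3];
    for (int ax = 0; ax < 3; ++ax) {
      double a = prims(j, ax), b = sph ? prims(j, ax) : prims(j, 3 + ax);
      double mn = std::min(a, b) - r - band, mx = std::max(a, b) + r + band;
      int64_t lo_i = (int64_t)std::floor((mn - lo[ax]) / pitch);
      int64_t hi_i = (int64_t)std::ceil((mx - lo[ax]) / pitch);
      i0[ax] = lo_i < 0 ? 0 : lo_i;
      i1[ax] = hi_i > n[ax] - 1 ? n[ax] - 1 : hi_i;
    }
    double ax_ = prims(j, 0), ay_ = prims(j, 1), az_ = prims(j, 2);
    double bx_ = prims(j, 3), by_ = prims(j, 4), bz_ = prims(j, 5);
    double r0 = prims(j, 6), r1 = prims(j, 7);
    for (int64_t k = i0[2]; k <= i1[2]; ++k) {
      double pz = lo[2] + k * pitch;
      for (int64_t jy = i0[1]; jy <= i1[1]; ++jy) {
        double py = lo[1] + jy * pitch;
        size_t base = (size_t)(k * ny + jy) * nx;
        for (int64_t ix = i0[0]; ix <= i1[0]; ++ix) {
          double px = lo[0] + ix * pitch;
          double d = sph ? sdSphere(px, py, pz, ax_, ay_, az_, r0)
                         : sdCappedCone(px, py, pz, ax_, ay_, az_,
                                        bx_, by_, bz_, r0, r1);
          float fd = (float)d;
          if (fd < field[base + ix]) field[base + ix] = fd;
        }
      }
    }
  }
  // nudge exact zeros outward so no tetrahedron vertex sits on the surface
  float tiny = (float)(1e-7 * pitch);
  for (size_t i = 0; i < field.size(); ++i)
    if (field[i] == 0.0f) field[i] = tiny;

  MeshAccum acc;
  acc.edgeVertex.reserve(1 << 16);

  // corner offsets in (x,y,z)
  static const int OFF[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
  };

  // resolve (or create) the interpolated vertex on grid edge gA-gB
  struct EdgeCtx {
    MeshAccum *acc; const std::vector<float> *field;
    double lox, loy, loz, pitch; int64_t nx, ny;
  } ctx = { &acc, &field, lo[0], lo[1], lo[2], pitch, nx, ny };

  auto edgeVert = [&ctx](int64_t gA, int64_t gB) -> int {
    int64_t g0 = gA < gB ? gA : gB;
    int64_t g1 = gA < gB ? gB : gA;
    uint64_t key = (uint64_t)g0 * 0x100000001ULL ^ (uint64_t)g1;
    // use exact composite key instead: (g0, g1) packed
    key = ((uint64_t)g0 << 32) | (uint64_t)(uint32_t)(g1 - g0);
    auto it = ctx.acc->edgeVertex.find(key);
    if (it != ctx.acc->edgeVertex.end()) return it->second;
    double v0 = (*ctx.field)[(size_t)g0], v1 = (*ctx.field)[(size_t)g1];
    double t = v0 / (v0 - v1);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    int64_t k0 = g0 / (ctx.nx * ctx.ny), r0i = g0 % (ctx.nx * ctx.ny);
    int64_t j0 = r0i / ctx.nx, i0 = r0i % ctx.nx;
    int64_t k1 = g1 / (ctx.nx * ctx.ny), r1i = g1 % (ctx.nx * ctx.ny);
    int64_t j1 = r1i / ctx.nx, i1 = r1i % ctx.nx;
    double x0 = ctx.lox + i0 * ctx.pitch, y0 = ctx.loy + j0 * ctx.pitch,
           z0 = ctx.loz + k0 * ctx.pitch;
    double x1 = ctx.lox + i1 * ctx.pitch, y1 = ctx.loy + j1 * ctx.pitch,
           z1 = ctx.loz + k1 * ctx.pitch;
    ctx.acc->vx.push_back(x0 + t * (x1 - x0));
    ctx.acc->vy.push_back(y0 + t * (y1 - y0));
    ctx.acc->vz.push_back(z0 + t * (z1 - z0));
    int idx = (int)ctx.acc->vx.size() - 1;
    ctx.acc->edgeVertex.emplace(key, idx);
    return idx;
  };

  auto emitTri = [&acc](int a, int b, int c, bool flip) {
    if (flip) { int t = b; b = c; c = t; }
    acc.f0.push_back(a); acc.f1.push_back(b); acc.f2.push_back(c);
  };

  // geometric orientation sign of each Kuhn tet in its listed vertex order
  int detSign[6];
  for (int t = 0; t < 6; ++t) {
    const int *tv = TETS[t];
    double e[3][3];
    for (int c = 1; c < 4; ++c)
      for (int ax = 0; ax < 3; ++ax)
        e[c - 1][ax] = OFF[tv[c]][ax] - OFF[tv[0]][ax];
    double det = e[0][0] * (e[1][1] * e[2][2] - e[1][2] * e[2][1])
               - e[0][1] * (e[1][0] * e[2][2] - e[1][2] * e[2][0])
               + e[0][2] * (e[1][0] * e[2][1] - e[1][1] * e[2][0]);
    detSign[t] = det > 0 ? 1 : -1;
  }

  for (int64_t k = 0; k + 1 < nz; ++k) {
    for (int64_t jy = 0; jy + 1 < ny; ++jy) {
      for (int64_t ix = 0; ix + 1 < nx; ++ix) {
        int64_t g[8];
        float v[8];
        bool anyNeg = false, anyPos = false;
        for (int c = 0; c < 8; ++c) {
          g[c] = (ix + OFF[c][0]) +
                 nx * ((jy + OFF[c][1]) + ny * (k + OFF[c][2]));
          v[c] = field[(size_t)g[c]];
          if (v[c] < 0.0f) anyNeg = true; else anyPos = true;
        }
        if (!anyNeg || !anyPos) continue;
        for (int t = 0; t < 6; ++t) {
          // partition tet vertices into inside / outside, tracking the
          // parity of the permutation (insides first, original order kept
          // within each group); combined with the tet's geometric
          // orientation this fixes the outward winding combinatorially,
          // so adjacent tets always agree.
          int inn[4], outn[4], innPos[4]; int ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            int cv = TETS[t][c];
            if (v[cv] < 0.0f) { innPos[ni] = c; inn[ni++] = cv; }
            else outn[no++] = cv;
          }
          if (ni == 0 || ni == 4) continue;
          // parity: inversions created by moving insides to the front
          int inversions = 0;
          for (int c = 0; c < ni; ++c) inversions += innPos[c] - c;
          bool flip = ((inversions % 2) == 1) != (detSign[t] < 0);
          if (ni == 1) {
            int a = edgeVert(g[inn[0]], g[outn[0]]);
            int b = edgeVert(g[inn[0]], g[outn[1]]);
            int c = edgeVert(g[inn[0]], g[outn[2]]);
            emitTri(a, b, c, flip);
          } else if (ni == 3) {
            int a = edgeVert(g[inn[0]], g[outn[0]]);
            int b = edgeVert(g[inn[1]], g[outn[0]]);
            int c = edgeVert(g[inn[2]], g[outn[0]]);
            emitTri(a, b, c, flip);
          } else { // ni == 2: quad cycle
            int q0 = edgeVert(g[inn[0]], g[outn[0]]);
            int q1 = edgeVert(g[inn[0]], g[outn[1]]);
            int q2 = edgeVert(g[inn[1]], g[outn[1]]);
            int q3 = edgeVert(g[inn[1]], g[outn[0]]);
            emitTri(q0, q1, q2, flip);
            emitTri(q0, q2, q3, flip);
          }
        }
      }
    }
  }

  int nv = (int)acc.vx.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = acc.vx[i]; V(i, 1) = acc.vy[i]; V(i, 2) = acc.vz[i];
  }
  int nf = (int)acc.f0.size();
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = acc.f0[i] + 1; F(i, 1) = acc.f1[i] + 1; F(i, 2) = acc.f2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
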