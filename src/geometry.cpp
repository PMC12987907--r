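// Low-level geometry kernels: point-to-mesh (signed) distance with a uniform
// grid accelerator, ray-mesh first-hit intersection, and marching-tetrahedra
// isosurface extraction. All coordinates in millimetres; meshes are vertex
// matrices (n x 3) plus 1-based triangular face index matrices (m x 3).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
static inline Vec3 normalize(const Vec3& a) {
  double n = norm(a);
  return n > 0 ? a * (1.0 / n) : a;
}

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection).
// Also reports the barycentric coordinates of the closest point.
static Vec3 closestPointTriangle(const Vec3& p, const Vec3& a, const Vec3& b,
                                 const Vec3& c, double& u, double& v, double& w) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { u = 1; v = 0; w = 0; return a; }
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { u = 0; v = 1; w = 0; return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double t = d1 / (d1 - d3);
    u = 1 - t; v = t; w = 0;
    return a + ab * t;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { u = 0; v = 0; w = 1; return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double t = d2 / (d2 - d6);
    u = 1 - t; v = 0; w = t;
    return a + ac * t;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    u = 0; v = 1 - t; w = t;
    return b + (c - b) * t;
  }
  double denom = 1.0 / (va + vb + vc);
  double vv = vb * denom, ww = vc * denom;
  u = 1 - vv - ww; v = vv; w = ww;
  return a + ab * vv + ac * ww;
}

struct MeshAccel {
  std::vector<Vec3> V;
  std::vector<int> F;           // 3 * nF, zero-based
  int nF = 0;
  std::vector<Vec3> faceNormal; // unit
  std::vector<Vec3> vertNormal; // angle-weighted pseudonormals
  std::unordered_map<uint64_t, Vec3> edgeNormal;
  // uniform grid over triangle AABBs
  Vec3 gmin;
  double cell = 1.0;
  int nx = 1, ny = 1, nz = 1;
  std::vector<std::vector<int>> cells;
  std::vector<int> cellDist; // L-inf ring distance to the nearest occupied cell
  std::vector<int> occupied; // indices of non-empty cells

  int cellIndex(int i, int j, int k) const { return (k * ny + j) * nx + i; }

  void build(const NumericMatrix& Vm, const IntegerMatrix& Fm, bool needPseudo) {
    int nV = Vm.nrow();
    nF = Fm.nrow();
    V.resize(nV);
    for (int i = 0; i < nV; ++i) V[i] = Vec3(Vm(i, 0), Vm(i, 1), Vm(i, 2));
    F.resize(3 * nF);
    for (int f = 0; f < nF; ++f)
      for (int j = 0; j < 3; ++j) F[3 * f + j] = Fm(f, j) - 1;

    faceNormal.resize(nF);
    if (needPseudo) vertNormal.assign(nV, Vec3());
    for (int f = 0; f < nF; ++f) {
      const Vec3& a = V[F[3 * f]];
      const Vec3& b = V[F[3 * f + 1]];
      const Vec3& c = V[F[3 * f + 2]];
      Vec3 n = normalize(cross(b - a, c - a));
      faceNormal[f] = n;
      if (needPseudo) {
        for (int j = 0; j < 3; ++j) {
          int i0 = F[3 * f + j], i1 = F[3 * f + (j + 1) % 3], i2 = F[3 * f + (j + 2) % 3];
          Vec3 e1 = normalize(V[i1] - V[i0]);
          Vec3 e2 = normalize(V[i2] - V[i0]);
          double cosang = std::max(-1.0, std::min(1.0, dot(e1, e2)));
          vertNormal[i0] = vertNormal[i0] + n * std::acos(cosang);
          // accumulate edge pseudonormals on edge (i0, i1)
          uint64_t key = i0 < i1
            ? (uint64_t)i0 * (uint64_t)nV + (uint64_t)i1
            : (uint64_t)i1 * (uint64_t)nV + (uint64_t)i0;
          edgeNormal[key] = edgeNormal.count(key) ? edgeNormal[key] + n : n;
        }
      }
    }

    // grid sizing: aim for ~2 triangles per occupied cell
    Vec3 lo(R_PosInf, R_PosInf, R_PosInf), hi(R_NegInf, R_NegInf, R_NegInf);
    for (int i = 0; i < nV; ++i) {
      lo.x = std::min(lo.x, V[i].x); lo.y = std::min(lo.y, V[i].y); lo.z = std::min(lo.z, V[i].z);
      hi.x = std::max(hi.x, V[i].x); hi.y = std::max(hi.y, V[i].y); hi.z = std::max(hi.z, V[i].z);
    }
    Vec3 ext = hi - lo;
    double diag = std::max(1e-9, norm(ext));
    double target = diag / std::max(4.0, std::cbrt((double)nF));
    cell = std::max(target, 1e-6);
    gmin = lo - Vec3(1e-9, 1e-9, 1e-9);
    nx = std::max(1, (int)std::ceil((ext.x + 2e-9) / cell));
    ny = std::max(1, (int)std::ceil((ext.y + 2e-9) / cell));
    nz = std::max(1, (int)std::ceil((ext.z + 2e-9) / cell));
    // cap grid size
    while ((double)nx * ny * nz > 4e6) {
      cell *= 1.5;
      nx = std::max(1, (int)std::ceil((ext.x + 2e-9) / cell));
      ny = std::max(1, (int)std::ceil((ext.y + 2e-9) / cell));
      nz = std::max(1, (int)std::ceil((ext.z + 2e-9) / cell));
    }
    cells.assign((size_t)nx * ny * nz, std::vector<int>());
    for (int f = 0; f < nF; ++f) {
      Vec3 tlo(R_PosInf, R_PosInf, R_PosInf), thi(R_NegInf, R_NegInf, R_NegInf);
      for (int j = 0; j < 3; ++j) {
        const Vec3& p = V[F[3 * f + j]];
        tlo.x = std::min(tlo.x, p.x); tlo.y = std::min(tlo.y, p.y); tlo.z = std::min(tlo.z, p.z);
        thi.x = std::max(thi.x, p.x); thi.y = std::max(thi.y, p.y); thi.z = std::max(thi.z, p.z);
      }
      int i0 = clampi((int)((tlo.x - gmin.x) / cell), 0, nx - 1);
      int i1 = clampi((int)((thi.x - gmin.x) / cell), 0, nx - 1);
      int j0 = clampi((int)((tlo.y - gmin.y) / cell), 0, ny - 1);
      int j1 = clampi((int)((thi.y - gmin.y) / cell), 0, ny - 1);
      int k0 = clampi((int)((tlo.z - gmin.z) / cell), 0, nz - 1);
      int k1 = clampi((int)((thi.z - gmin.z) / cell), 0, nz - 1);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i)
            cells[cellIndex(i, j, k)].push_back(f);
    }
    // multi-source BFS (26-neighbourhood) so queries can start at the right ring
    size_t nc = cells.size();
    cellDist.assign(nc, -1);
    std::vector<int> frontier;
    occupied.clear();
    for (size_t c = 0; c < nc; ++c)
      if (!cells[c].empty()) { cellDist[c] = 0; frontier.push_back((int)c); }
    occupied = frontier;
    int level = 0;
    while (!frontier.empty()) {
      std::vector<int> next;
      ++level;
      for (size_t t = 0; t < frontier.size(); ++t) {
        int c = frontier[t];
        int ci = c % nx, cj = (c / nx) % ny, ck = c / (nx * ny);
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              int i = ci + di, j = cj + dj, k = ck + dk;
              if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) continue;
              int n = cellIndex(i, j, k);
              if (cellDist[n] < 0) { cellDist[n] = level; next.push_back(n); }
            }
      }
      frontier.swap(next);
    }
  }

  static int clampi(int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); }

  void testCell(int c, const Vec3& q, double& best, Vec3& cp, int& face,
                double& bu, double& bv, double& bw) const {
    const std::vector<int>& fs = cells[c];
    for (size_t t = 0; t < fs.size(); ++t) {
      int f = fs[t];
      double u, v, w;
      Vec3 cc = closestPointTriangle(q, V[F[3 * f]], V[F[3 * f + 1]], V[F[3 * f + 2]],
                                     u, v, w);
      Vec3 d = q - cc;
      double d2 = dot(d, d);
      if (d2 < best) { best = d2; cp = cc; face = f; bu = u; bv = v; bw = w; }
    }
  }

  // squared distance from q to the AABB of cell (i,j,k)
  double cellDist2(const Vec3& q, int i, int j, int k) const {
    double lx = gmin.x + i * cell, ly = gmin.y + j * cell, lz = gmin.z + k * cell;
    double dx = std::max(0.0, std::max(lx - q.x, q.x - (lx + cell)));
    double dy = std::max(0.0, std::max(ly - q.y, q.y - (ly + cell)));
    double dz = std::max(0.0, std::max(lz - q.z, q.z - (lz + cell)));
    return dx * dx + dy * dy + dz * dz;
  }

  // closest point over the whole mesh; returns squared distance, fills
  // cp/face/bary. `bound` is an optional upper bound on the true distance
  // (e.g. from a neighbouring query) used only for pruning.
  double closest(const Vec3& q, Vec3& cp, int& face, double& bu, double& bv,
                 double& bw, double bound = R_PosInf) const {
    int qi = clampi((int)((q.x - gmin.x) / cell), 0, nx - 1);
    int qj = clampi((int)((q.y - gmin.y) / cell), 0, ny - 1);
    int qk = clampi((int)((q.z - gmin.z) / cell), 0, nz - 1);
    double best = std::numeric_limits<double>::infinity();
    double bound2 = bound < R_PosInf ? bound * bound * (1 + 1e-12) : R_PosInf;
    face = -1;
    // distance from the query to the accelerator-grid bounds
    double gx = std::max(0.0, std::max(gmin.x - q.x, q.x - (gmin.x + nx * cell)));
    double gy = std::max(0.0, std::max(gmin.y - q.y, q.y - (gmin.y + ny * cell)));
    double gz = std::max(0.0, std::max(gmin.z - q.z, q.z - (gmin.z + nz * cell)));
    double distGrid = std::sqrt(gx * gx + gy * gy + gz * gz);
    if (distGrid > 2 * cell) {
      // far query: scan occupied cells with AABB pruning
      for (size_t t = 0; t < occupied.size(); ++t) {
        int c = occupied[t];
        int ci = c % nx, cj = (c / nx) % ny, ck = c / (nx * ny);
        double d2 = cellDist2(q, ci, cj, ck);
        if (d2 >= best || d2 > bound2) continue;
        testCell(c, q, best, cp, face, bu, bv, bw);
      }
      return best;
    }
    int maxRing = std::max(std::max(std::max(qi, nx - 1 - qi),
                                    std::max(qj, ny - 1 - qj)),
                           std::max(qk, nz - 1 - qk));
    int ring0 = std::max(0, cellDist[cellIndex(qi, qj, qk)] - 1);
    for (int ring = ring0; ring <= maxRing; ++ring) {
      // stop once no cell of this ring can beat the current best
      if (face >= 0) {
        double minPossible = (ring - 1) * cell - distGrid;
        if (minPossible > 0 && minPossible * minPossible > best) break;
      }
      int i0 = std::max(0, qi - ring), i1 = std::min(nx - 1, qi + ring);
      int j0 = std::max(0, qj - ring), j1 = std::min(ny - 1, qj + ring);
      int k0 = std::max(0, qk - ring), k1 = std::min(nz - 1, qk + ring);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            // shell only
            if (ring > 0 && std::abs(i - qi) != ring && std::abs(j - qj) != ring &&
                std::abs(k - qk) != ring)
              continue;
            int c = cellIndex(i, j, k);
            if (cells[c].empty()) continue;
            double d2 = cellDist2(q, i, j, k);
            if ((face >= 0 && d2 >= best) || d2 > bound2) continue;
            testCell(c, q, best, cp, face, bu, bv, bw);
          }
      if (ring == maxRing) break;
    }
    return best;
  }

  // angle-weighted pseudonormal of the closest feature
  Vec3 pseudoNormal(int face, double bu, double bv, double bw) const {
    const double eps = 1e-9;
    int i0 = F[3 * face], i1 = F[3 * face + 1], i2 = F[3 * face + 2];
    int nV = (int)V.size();
    int zeroCount = (bu < eps) + (bv < eps) + (bw < eps);
    if (zeroCount == 0) return faceNormal[face];
    if (zeroCount == 2) { // vertex
      if (bu >= eps) return vertNormal[i0];
      if (bv >= eps) return vertNormal[i1];
      return vertNormal[i2];
    }
    // edge
    int a, b;
    if (bw < eps) { a = i0; b = i1; }
    else if (bv < eps) { a = i0; b = i2; }
    else { a = i1; b = i2; }
    uint64_t key = a < b ? (uint64_t)a * (uint64_t)nV + (uint64_t)b
                         : (uint64_t)b * (uint64_t)nV + (uint64_t)a;
    std::unordered_map<uint64_t, Vec3>::const_iterator it = edgeNormal.find(key);
    return it != edgeNormal.end() ? it->second : faceNormal[face];
  }
};

// [[Rcpp::export]]
List cpp_mesh_distance(NumericMatrix V, IntegerMatrix F, NumericMatrix Q,
                       bool signed_dist) {
  MeshAccel m;
  m.build(V, F, signed_dist);
  int nQ = Q.nrow();
  NumericVector dist(nQ);
  NumericMatrix cp(nQ, 3);
  IntegerVector face(nQ);
  double lastDist = R_PosInf;
  Vec3 lastQ;
  for (int q = 0; q < nQ; ++q) {
    Vec3 p(Q(q, 0), Q(q, 1), Q(q, 2));
    // coherent queries (grid scans) give a tight upper bound via the
    // triangle inequality
    double bound = R_PosInf;
    if (q > 0 && lastDist < R_PosInf) bound = lastDist + norm(p - lastQ);
    Vec3 c; int f; double bu, bv, bw;
    double d2 = m.closest(p, c, f, bu, bv, bw, bound);
    lastDist = std::sqrt(d2);
    lastQ = p;
    double d = std::sqrt(d2);
    if (signed_dist) {
      Vec3 pn = m.pseudoNormal(f, bu, bv, bw);
      if (dot(p - c, pn) < 0) d = -d;
    }
    dist[q] = d;
    cp(q, 0) = c.x; cp(q, 1) = c.y; cp(q, 2) = c.z;
    face[q] = f + 1;
  }
  return List::create(_["distance"] = dist, _["closest"] = cp, _["face"] = face);
}

// Moeller-Trumbore; first (smallest positive t) hit per ray.
// [[Rcpp::export]]
List cpp_ray_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix origins,
                  NumericMatrix dirs) {
  int nF = F.nrow(), nR = origins.nrow();
  std::vector<Vec3> v0(nF), e1(nF), e2(nF);
  for (int f = 0; f < nF; ++f) {
    Vec3 a(V(F(f, 0) - 1, 0), V(F(f, 0) - 1, 1), V(F(f, 0) - 1, 2));
    Vec3 b(V(F(f, 1) - 1, 0), V(F(f, 1) - 1, 1), V(F(f, 1) - 1, 2));
    Vec3 c(V(F(f, 2) - 1, 0), V(F(f, 2) - 1, 1), V(F(f, 2) - 1, 2));
    v0[f] = a; e1[f] = b - a; e2[f] = c - a;
  }
  NumericVector tHit(nR, NA_REAL);
  IntegerVector fHit(nR, NA_INTEGER);
  NumericMatrix pHit(nR, 3);
  std::fill(pHit.begin(), pHit.end(), NA_REAL);
  const double eps = 1e-12;
  for (int r = 0; r < nR; ++r) {
    Vec3 o(origins(r, 0), origins(r, 1), origins(r, 2));
    Vec3 d(dirs(r, 0), dirs(r, 1), dirs(r, 2));
    double bestT = std::numeric_limits<double>::infinity();
    int bestF = -1;
    for (int f = 0; f < nF; ++f) {
      Vec3 pvec = cross(d, e2[f]);
      double det = dot(e1[f], pvec);
      if (std::fabs(det) < eps) continue;
      double invDet = 1.0 / det;
      Vec3 tvec = o - v0[f];
      double u = dot(tvec, pvec) * invDet;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      Vec3 qvec = cross(tvec, e1[f]);
      double v = dot(d, qvec) * invDet;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      double t = dot(e2[f], qvec) * invDet;
      if (t > 1e-9 && t < bestT) { bestT = t; bestF = f; }
    }
    if (bestF >= 0) {
      tHit[r] = bestT;
      fHit[r] = bestF + 1;
      pHit(r, 0) = o.x + d.x * bestT;
      pHit(r, 1) = o.y + d.y * bestT;
      pHit(r, 2) = o.z + d.z * bestT;
    }
  }
  return List::create(_["t"] = tHit, _["face"] = fHit, _["point"] = pHit);
}

// Marching tetrahedra over a regular grid (x fastest index). values < iso is
// inside; triangles are wound so normals point towards the outside.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector values, IntegerVector dims,
                       NumericVector origin, NumericVector spacing, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((double)nx * ny * nz != (double)values.size())
    stop("grid dimensions do not match value count");
  // fan of six tetrahedra around the main diagonal c0-c7
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
  };
  std::unordered_map<uint64_t, int> edgeVert;
  std::vector<double> VX, VY, VZ;
  std::vector<int> FT;
  uint64_t nNodes = (uint64_t)nx * ny * nz;

  std::vector<int64_t> nodeIdx(8);
  std::vector<double> nodeVal(8);
  std::vector<Vec3> nodePos(8);

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          int64_t idx = (int64_t)(k + dk) * ny * nx + (int64_t)(j + dj) * nx + (i + di);
          nodeIdx[c] = idx;
          nodeVal[c] = values[idx];
          nodePos[c] = Vec3(origin[0] + (i + di) * spacing[0],
                            origin[1] + (j + dj) * spacing[1],
                            origin[2] + (k + dk) * spacing[2]);
        }
        // skip cubes entirely inside/outside
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) (nodeVal[c] < iso ? anyIn : anyOut) = true;
        if (!anyIn || !anyOut) continue;

        for (int t = 0; t < 6; ++t) {
          int vIn[4], nIn = 0, vOut[4], nOut = 0;
          for (int c = 0; c < 4; ++c) {
            int node = tets[t][c];
            if (nodeVal[node] < iso) vIn[nIn++] = node; else vOut[nOut++] = node;
          }
          if (nIn == 0 || nIn == 4) continue;

          // edge-interpolated vertex, deduplicated across tets/cubes
          std::vector<int> P;
          Vec3 insideRef, outsideRef;
          int produced[4];
          int nP = 0;
          struct EdgePair { int a, b; };
          EdgePair edges[4];
          if (nIn == 1) {
            for (int c = 0; c < 3; ++c) { edges[c].a = vIn[0]; edges[c].b = vOut[c]; }
            nP = 3;
            insideRef = nodePos[vIn[0]];
            outsideRef = (nodePos[vOut[0]] + nodePos[vOut[1]] + nodePos[vOut[2]]) * (1.0 / 3);
          } else if (nIn == 3) {
            for (int c = 0; c < 3; ++c) { edges[c].a = vIn[c]; edges[c].b = vOut[0]; }
            nP = 3;
            insideRef = (nodePos[vIn[0]] + nodePos[vIn[1]] + nodePos[vIn[2]]) * (1.0 / 3);
            outsideRef = nodePos[vOut[0]];
          } else { // 2 in, 2 out; quad in order ac, ad, bd, bc
            edges[0].a = vIn[0]; edges[0].b = vOut[0];
            edges[1].a = vIn[0]; edges[1].b = vOut[1];
            edges[2].a = vIn[1]; edges[2].b = vOut[1];
            edges[3].a = vIn[1]; edges[3].b = vOut[0];
            nP = 4;
            insideRef = (nodePos[vIn[0]] + nodePos[vIn[1]]) * 0.5;
            outsideRef = (nodePos[vOut[0]] + nodePos[vOut[1]]) * 0.5;
          }
          for (int c = 0; c < nP; ++c) {
            int a = edges[c].a, b = edges[c].b;
            uint64_t ia = (uint64_t)nodeIdx[a], ib = (uint64_t)nodeIdx[b];
            uint64_t key = ia < ib ? ia * nNodes + ib : ib * nNodes + ia;
            std::unordered_map<uint64_t, int>::iterator it = edgeVert.find(key);
            int vid;
            if (it == edgeVert.end()) {
              double va = nodeVal[a], vb = nodeVal[b];
              double tt = (iso - va) / (vb - va);
              tt = std::max(1e-4, std::min(1.0 - 1e-4, tt));
              Vec3 p = nodePos[a] + (nodePos[b] - nodePos[a]) * tt;
              VX.push_back(p.x); VY.push_back(p.y); VZ.push_back(p.z);
              vid = (int)VX.size() - 1;
              edgeVert[key] = vid;
            } else vid = it->second;
            produced[c] = vid;
          }
          Vec3 outward = outsideRef - insideRef;
          int tris[2][3];
          int nTri = 1;
          tris[0][0] = produced[0]; tris[0][1] = produced[1]; tris[0][2] = produced[2];
          if (nP == 4) {
            nTri = 2;
            tris[1][0] = produced[0]; tris[1][1] = produced[2]; tris[1][2] = produced[3];
          }
          for (int tr = 0; tr < nTri; ++tr) {
            Vec3 p0(VX[tris[tr][0]], VY[tris[tr][0]], VZ[tris[tr][0]]);
            Vec3 p1(VX[tris[tr][1]], VY[tris[tr][1]], VZ[tris[tr][1]]);
            Vec3 p2(VX[tris[tr][2]], VY[tris[tr][2]], VZ[tris[tr][2]]);
            Vec3 n = cross(p1 - p0, p2 - p0);
            int a = tris[tr][0], b = tris[tr][1], c = tris[tr][2];
            if (dot(n, outward) < 0) std::swap(b, c);
            FT.push_back(a + 1); FT.push_back(b + 1); FT.push_back(c + 1);
          }
        }
      }

  int nV = (int)VX.size(), nT = (int)FT.size() / 3;
  NumericMatrix Vout(nV, 3);
  for (int i = 0; i < nV; ++i) { Vout(i, 0) = VX[i]; Vout(i, 1) = VY[i]; Vout(i, 2) = VZ[i]; }
  IntegerMatrix Fout(nT, 3);
  for (int i = 0; i < nT; ++i) {
    Fout(i, 0) = FT[3 * i]; Fout(i, 1) = FT[3 * i + 1]; Fout(i, 2) = FT[3 * i + 2];
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
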