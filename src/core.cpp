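#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Linear index into a column-major (R order) 3D array, 0-based.
static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6/18/26 connectivity), BFS, labels in
// first-encounter order scanning the array in linear order (deterministic).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(const IntegerVector& mask,
                                   int nx, int ny, int nz,
                                   int connectivity) {
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  int next = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cz = c / (nx * ny), r = c % (nx * ny), cy = r / nx, cx = r % nx;
      for (size_t k = 0; k < offx.size(); ++k) {
        int x = cx + offx[k], y = cy + offy[k], z = cz + offz[k];
        if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
        int j = lin(x, y, z, nx, ny);
        if (mask[j] && !lab[j]) { lab[j] = next; q.push(j); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Chamfer distance transform: distance (mm) from each foreground voxel to the
// nearest background voxel, two-pass 26-neighbour chamfer with anisotropic
// spacing. Background voxels get 0. Voxels on the array border count the
// outside as background.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_chamfer_dt(const IntegerVector& mask,
                             int nx, int ny, int nz,
                             double sx, double sy, double sz) {
  const int n = nx * ny * nz;
  const double INF = 1e30;
  NumericVector d(n);
  for (int i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;

  // neighbour offsets in the "backward" half (scanned before current voxel)
  std::vector<int> ox, oy, oz;
  std::vector<double> w;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0)))) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
        w.push_back(std::sqrt(dx * sx * dx * sx + dy * sy * dy * sy +
                              dz * sz * dz * sz));
      }
  double sborder = std::min(sx, std::min(sy, sz));

  // forward pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lin(x, y, z, nx, ny);
        if (d[i] == 0.0) continue;
        if (x == 0 || y == 0 || z == 0 || x == nx - 1 || y == ny - 1 ||
            z == nz - 1)
          d[i] = std::min(d[i], sborder);
        for (size_t k = 0; k < ox.size(); ++k) {
          int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          double cand = d[lin(xx, yy, zz, nx, ny)] + w[k];
          if (cand < d[i]) d[i] = cand;
        }
      }
  // backward pass
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        int i = lin(x, y, z, nx, ny);
        if (d[i] == 0.0) continue;
        for (size_t k = 0; k < ox.size(); ++k) {
          int xx = x - ox[k], yy = y - oy[k], zz = z - oz[k];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          double cand = d[lin(xx, yy, zz, nx, ny)] + w[k];
          if (cand < d[i]) d[i] = cand;
        }
      }
  return d;
}

// ---------------------------------------------------------------------------
// Bilateral filter with truncated Gaussian window; sigmas are given per axis
// in voxel units so anisotropic spacing is handled by the caller.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_bilateral(const NumericVector& vol,
                            int nx, int ny, int nz,
                            double sgx, double sgy, double sgz,
                            double sigma_range) {
  int rx = std::max(1, (int)std::ceil(2.0 * sgx));
  int ry = std::max(1, (int)std::ceil(2.0 * sgy));
  int rz = std::max(1, (int)std::ceil(2.0 * sgz));
  const int n = nx * ny * nz;
  NumericVector out(n);
  std::vector<int> ox, oy, oz;
  std::vector<double> ws;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        double e = 0.5 * (dx * dx / (sgx * sgx) + dy * dy / (sgy * sgy) +
                          dz * dz / (sgz * sgz));
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
        ws.push_back(std::exp(-e));
      }
  double inv2sr2 = 1.0 / (2.0 * sigma_range * sigma_range);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lin(x, y, z, nx, ny);
        double v0 = vol[i], sw = 0.0, sv = 0.0;
        for (size_t k = 0; k < ox.size(); ++k) {
          int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          double v = vol[lin(xx, yy, zz, nx, ny)];
          double dv = v - v0;
          double wgt = ws[k] * std::exp(-dv * dv * inv2sr2);
          sw += wgt; sv += wgt * v;
        }
        out[i] = sv / sw;
      }
  return out;
}

// ---------------------------------------------------------------------------
// 3D curve thinning: sequential deletion of simple, non-endpoint border
// points in six directional subiterations (U, D, N, S, E, W) until stable.
// Simplicity uses the standard topological characterization: exactly one
// 26-component of foreground in N26*, and exactly one 6-component of
// background within N18 touching a face neighbour. Deleting only points that
// are simple at deletion time preserves homotopy.
// ---------------------------------------------------------------------------

static bool nbhd(const std::vector<uint8_t>& m, int x, int y, int z,
                 int nx, int ny, int nz, bool nb[27]) {
  // fill the 3x3x3 neighbourhood (center excluded from "foreground count")
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[k] = (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny &&
                 zz < nz) ? (m[lin(xx, yy, zz, nx, ny)] != 0) : false;
      }
  return true;
}

// offsets within the 27-neighbourhood, index k -> (dx,dy,dz)
static inline void k2d(int k, int& dx, int& dy, int& dz) {
  dx = k % 3 - 1; dy = (k / 3) % 3 - 1; dz = k / 9 - 1;
}

// number of 26-connected components of foreground in N26 \ {center}
static int fg_comp_count(const bool nb[27]) {
  bool fg[27];
  for (int k = 0; k < 27; ++k) fg[k] = nb[k];
  fg[13] = false;
  int comp = 0;
  bool seen[27] = {false};
  for (int s = 0; s < 27; ++s) {
    if (!fg[s] || seen[s]) continue;
    ++comp;
    std::vector<int> st(1, s);
    seen[s] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cx, cy, cz; k2d(c, cx, cy, cz);
      for (int t = 0; t < 27; ++t) {
        if (!fg[t] || seen[t]) continue;
        int tx, ty, tz; k2d(t, tx, ty, tz);
        if (std::abs(tx - cx) <= 1 && std::abs(ty - cy) <= 1 &&
            std::abs(tz - cz) <= 1) { seen[t] = true; st.push_back(t); }
      }
    }
  }
  return comp;
}

static bool is_simple(const bool nb[27]) {
  if (fg_comp_count(nb) != 1) return false;  // isolated or isthmus
  // background 6-components within N18 touching a face neighbour
  bool bg[27];
  for (int k = 0; k < 27; ++k) {
    int dx, dy, dz; k2d(k, dx, dy, dz);
    int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
    bg[k] = (man >= 1 && man <= 2) && !nb[k];
  }
  const int face[6] = {4, 10, 12, 14, 16, 22};  // the 6 face neighbours
  bool anyface = false;
  for (int f = 0; f < 6; ++f) if (bg[face[f]]) anyface = true;
  if (!anyface) return false;  // interior point
  int comp = 0;
  bool seen[27] = {false};
  for (int f = 0; f < 6; ++f) {
    int s = face[f];
    if (!bg[s] || seen[s]) continue;
    ++comp;
    if (comp > 1) return false;
    std::vector<int> st(1, s);
    seen[s] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cx, cy, cz; k2d(c, cx, cy, cz);
      for (int t = 0; t < 27; ++t) {
        if (!bg[t] || seen[t]) continue;
        int tx, ty, tz; k2d(t, tx, ty, tz);
        if (std::abs(tx - cx) + std::abs(ty - cy) + std::abs(tz - cz) == 1) {
          seen[t] = true; st.push_back(t);
        }
      }
    }
  }
  return comp == 1;
}

static int n26_count(const bool nb[27]) {
  int c = 0;
  for (int k = 0; k < 27; ++k) if (k != 13 && nb[k]) ++c;
  return c;
}

// [[Rcpp::export]]
IntegerVector cpp_thin(const IntegerVector& mask, int nx, int ny, int nz) {
  const int n = nx * ny * nz;
  std::vector<uint8_t> m(n);
  for (int i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;
  // direction offsets: U(+z) D(-z) N(+y) S(-y) E(+x) W(-x)
  const int dxs[6] = {0, 0, 0, 0, 1, -1};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {1, -1, 0, 0, 0, 0};
  // Distance-ordered erosion: deletions proceed strictly from the outermost
  // distance-to-background layer inwards, so the surviving curve is anchored
  // on the medial (distance ridge) of the object rather than drifting with
  // the direction-scan order.
  NumericVector dtv = cpp_chamfer_dt(mask, nx, ny, nz, 1.0, 1.0, 1.0);
  std::vector<double> layers;
  for (int i = 0; i < n; ++i) if (m[i]) layers.push_back(dtv[i]);
  std::sort(layers.begin(), layers.end());
  layers.erase(std::unique(layers.begin(), layers.end()), layers.end());
  // Persistent curve-isthmus set: once a voxel's neighbourhood foreground
  // splits into >= 2 components (it bridges a locally 1-voxel-wide curve),
  // it is preserved for the rest of the thinning, so the emerging curve —
  // and its endpoints, once their neighbours are locked — cannot erode.
  std::vector<uint8_t> keep(n, 0);
  bool nb[27];
  for (size_t li = 0; li < layers.size(); ++li) {
    double L = layers[li];
    bool changed = true;
    while (changed) {
      changed = false;
      // mark curve isthmuses before any deletion this cycle, so a curve end
      // exposed by a deletion is already protected by its locked neighbours
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int i = lin(x, y, z, nx, ny);
            if (!m[i] || keep[i]) continue;
            nbhd(m, x, y, z, nx, ny, nz, nb);
            if (fg_comp_count(nb) >= 2) keep[i] = 1;
          }
      // 6 directional subiterations x 8 parity subfields: within one
      // (direction, subfield) pass consecutive voxels of a thin rod fall in
      // different subfields, so sequential deletion cannot cascade along
      // it; re-checking simplicity at deletion time preserves topology
      for (int dir = 0; dir < 6; ++dir) {
        for (int sf = 0; sf < 8; ++sf) {
          std::vector<int> cand;
          for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
              for (int x = 0; x < nx; ++x) {
                if (((x & 1) | ((y & 1) << 1) | ((z & 1) << 2)) != sf)
                  continue;
                int i = lin(x, y, z, nx, ny);
                if (!m[i] || dtv[i] > L) continue;
                int xx = x + dxs[dir], yy = y + dys[dir], zz = z + dzs[dir];
                bool border = (xx < 0 || yy < 0 || zz < 0 || xx >= nx ||
                               yy >= ny || zz >= nz) ||
                              !m[lin(xx, yy, zz, nx, ny)];
                if (!border) continue;
                nbhd(m, x, y, z, nx, ny, nz, nb);
                if (fg_comp_count(nb) >= 2) { keep[i] = 1; continue; }
                if (!keep[i] && is_simple(nb)) cand.push_back(i);
              }
          for (size_t k = 0; k < cand.size(); ++k) {
            int i = cand[k];
            if (keep[i]) continue;
            int z = i / (nx * ny), r = i % (nx * ny), y = r / nx,
                x = r % nx;
            nbhd(m, x, y, z, nx, ny, nz, nb);
            if (fg_comp_count(nb) >= 2) { keep[i] = 1; continue; }
            if (is_simple(nb)) { m[i] = 0; changed = true; }
          }
        }
      }
    }
  }
  // final cleanup: on the now 1-voxel-wide skeleton, locked voxels that
  // became redundant (simple, with >= 2 neighbours, e.g. triangle corners
  // of a doubled diagonal run) are removed; true curve interiors are not
  // simple and endpoints are protected, so the curve itself is untouched
  bool changed = true;
  while (changed) {
    changed = false;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = lin(x, y, z, nx, ny);
          if (!m[i]) continue;
          nbhd(m, x, y, z, nx, ny, nz, nb);
          if (n26_count(nb) <= 1) continue;
          if (is_simple(nb)) { m[i] = 0; changed = true; }
        }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = m[i];
  return out;
}

// ---------------------------------------------------------------------------
// Isosurface by marching tetrahedra: each cell is split into six tetrahedra
// around the (0,0,0)-(1,1,1) diagonal, a translation-invariant decomposition,
// so faces agree between neighbouring cells and the surface is watertight by
// construction (no ambiguous cases). Vertices are shared through an edge-key
// hash map; triangles are oriented with the outward normal pointing towards
// decreasing field values.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_march_tetra(const NumericVector& field, int nx, int ny, int nz,
                     double iso) {
  // corner offsets indexed by bits (x,y,z)
  const int cox[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  const int coy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int coz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  // six tetrahedra around diagonal 0-7
  const int tets[6][4] = {{0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
                          {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}};
  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> f1, f2, f3;
  const uint64_t NVOX = (uint64_t)nx * ny * nz;

  auto edge_vertex = [&](int ia, int ib, double fa, double fb) -> int {
    uint64_t a = (uint64_t)ia, b = (uint64_t)ib;
    if (a > b) { std::swap(a, b); std::swap(fa, fb); }
    uint64_t key = a * NVOX + b;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = (iso - fa) / (fb - fa);
    int za = (int)(a / ((uint64_t)nx * ny));
    int ra = (int)(a % ((uint64_t)nx * ny));
    int zb = (int)(b / ((uint64_t)nx * ny));
    int rb = (int)(b % ((uint64_t)nx * ny));
    double xa = ra % nx, ya = ra / nx, xb = rb % nx, yb = rb / nx;
    int id = (int)vx.size();
    vx.push_back(xa + t * (xb - xa));
    vy.push_back(ya + t * (yb - ya));
    vz.push_back(za + t * ((double)zb - za));
    vmap[key] = id;
    return id;
  };

  auto add_tri = [&](int a, int b, int c,
                     double gx, double gy, double gz,
                     double cx0, double cy0, double cz0) {
    // orient so the normal points along -gradient (outward for inside>iso)
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz,
           nzv = ux * wy - uy * wx;
    (void)cx0; (void)cy0; (void)cz0;
    if (nxv * gx + nyv * gy + nzv * gz > 0) std::swap(b, c);
    f1.push_back(a + 1); f2.push_back(b + 1); f3.push_back(c + 1);
  };

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        int ci[8];
        double cf[8];
        bool anyin = false, anyout = false;
        for (int k = 0; k < 8; ++k) {
          ci[k] = lin(x + cox[k], y + coy[k], z + coz[k], nx, ny);
          cf[k] = field[ci[k]];
          if (cf[k] > iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        // cell-level field gradient (central estimate from corner averages)
        double gx = (cf[1] + cf[3] + cf[5] + cf[7] -
                     cf[0] - cf[2] - cf[4] - cf[6]) * 0.25;
        double gy = (cf[2] + cf[3] + cf[6] + cf[7] -
                     cf[0] - cf[1] - cf[4] - cf[5]) * 0.25;
        double gz = (cf[4] + cf[5] + cf[6] + cf[7] -
                     cf[0] - cf[1] - cf[2] - cf[3]) * 0.25;
        for (int t = 0; t < 6; ++t) {
          int a = tets[t][0], b = tets[t][1], c = tets[t][2], d = tets[t][3];
          int idx[4] = {ci[a], ci[b], ci[c], ci[d]};
          double fv[4] = {cf[a], cf[b], cf[c], cf[d]};
          int code = 0;
          for (int k = 0; k < 4; ++k) if (fv[k] > iso) code |= (1 << k);
          if (code == 0 || code == 15) continue;
          // local gradient from the tetra corner values (for orientation)
          // fall back to cell gradient
          int inlist[4], outlist[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (fv[k] > iso) inlist[ni++] = k; else outlist[no++] = k;
          }
          if (ni == 1) {
            int p = inlist[0];
            int v0 = edge_vertex(idx[p], idx[outlist[0]], fv[p],
                                 fv[outlist[0]]);
            int v1 = edge_vertex(idx[p], idx[outlist[1]], fv[p],
                                 fv[outlist[1]]);
            int v2 = edge_vertex(idx[p], idx[outlist[2]], fv[p],
                                 fv[outlist[2]]);
            add_tri(v0, v1, v2, gx, gy, gz, 0, 0, 0);
          } else if (ni == 3) {
            int p = outlist[0];
            int v0 = edge_vertex(idx[p], idx[inlist[0]], fv[p], fv[inlist[0]]);
            int v1 = edge_vertex(idx[p], idx[inlist[1]], fv[p], fv[inlist[1]]);
            int v2 = edge_vertex(idx[p], idx[inlist[2]], fv[p], fv[inlist[2]]);
            add_tri(v0, v1, v2, gx, gy, gz, 0, 0, 0);
          } else {  // 2 in, 2 out -> quad
            int a0 = inlist[0], a1 = inlist[1], b0 = outlist[0],
                b1 = outlist[1];
            int v00 = edge_vertex(idx[a0], idx[b0], fv[a0], fv[b0]);
            int v01 = edge_vertex(idx[a0], idx[b1], fv[a0], fv[b1]);
            int v10 = edge_vertex(idx[a1], idx[b0], fv[a1], fv[b0]);
            int v11 = edge_vertex(idx[a1], idx[b1], fv[a1], fv[b1]);
            add_tri(v00, v01, v11, gx, gy, gz, 0, 0, 0);
            add_tri(v00, v11, v10, gx, gy, gz, 0, 0, 0);
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)f1.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i];
                                 V(i, 2) = vz[i]; }
  for (int i = 0; i < nf; ++i) { F(i, 0) = f1[i]; F(i, 1) = f2[i];
                                 F(i, 2) = f3[i]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// Trilinear interpolation at arbitrary continuous voxel coordinates
// (0-based). Points outside the grid return NA.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_trilinear(const NumericVector& vol, int nx, int ny, int nz,
                            const NumericVector& px, const NumericVector& py,
                            const NumericVector& pz) {
  int np = px.size();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double x = px[i], y = py[i], z = pz[i];
    if (ISNAN(x) || x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 ||
        z > nz - 1) { out[i] = NA_REAL; continue; }
    int x0 = std::min((int)std::floor(x), nx - 2);
    int y0 = std::min((int)std::floor(y), ny - 2);
    int z0 = std::min((int)std::floor(z), nz - 2);
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double v = 0.0;
    for (int dz = 0; dz <= 1; ++dz)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          int xx = std::min(x0 + dx, nx - 1);
          int yy = std::min(y0 + dy, ny - 1);
          int zz = std::min(z0 + dz, nz - 1);
          double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                     (dz ? fz : 1 - fz);
          v += w * vol[lin(xx, yy, zz, nx, ny)];
        }
    out[i] = v;
  }
  return out;
}
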