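// Voxel-grid morphology primitives: connected components, exact Euclidean
// distance/feature transforms, local thickness, mean-intercept-length line
// probes, topological thinning and skeleton classification.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <unordered_map>
#include <array>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---------------------------------------------------------------- components

// Label connected components of a binary volume. connectivity: 6 or 26.
// Returns integer labels (0 = background, 1..k), labelled in decreasing
// component size so label 1 is always the largest component.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(IntegerVector vol, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  IntegerVector lab(n, 0);
  std::vector<int> sizes;
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!vol[i] || lab[i]) continue;
    ++next;
    int sz = 0;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      ++sz;
      int z = cur / (nx * ny), rem = cur % (nx * ny);
      int y = rem / nx, x = rem % nx;
      for (auto &o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        int j = idx3(xx, yy, zz, nx, ny);
        if (vol[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
    sizes.push_back(sz);
  }
  // relabel so components come in decreasing size order
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> remap(next + 1, 0);
  for (int r = 0; r < next; ++r) remap[order[r] + 1] = r + 1;
  std::vector<int> szsorted(next);
  for (int r = 0; r < next; ++r) szsorted[r] = sizes[order[r]];
  for (int i = 0; i < n; ++i) if (lab[i]) lab[i] = remap[lab[i]];
  lab.attr("sizes") = wrap(szsorted);
  return lab;
}

// ------------------------------------------------- distance/feature transform

// 1D lower-envelope-of-parabolas pass (squared Euclidean distance), carrying
// the feature (nearest-seed) index along.
static void dt1d(const std::vector<double> &f, const std::vector<int> &feat,
                 std::vector<double> &d, std::vector<int> &dfeat) {
  const int n = (int)f.size();
  static const double INF = 1e30;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] >= INF) continue;
    double s;
    while (true) {
      if (f[v[k]] >= INF) { // previous vertex was at infinity: replace
        v[k] = q; z[k + 1] = INF; break;
      }
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; continue; }
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF; break;
    }
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = (q - v[kk]) * (double)(q - v[kk]) + f[v[kk]];
    d[q] = dq;
    dfeat[q] = (f[v[kk]] >= INF) ? -1 : feat[v[kk]];
  }
}

// Exact squared EDT + feature transform. seeds: binary array marking seed
// voxels (distance 0). Returns list(dist2, feature) where feature is the
// 0-based linear index of the nearest seed (-1 if no seed exists).
// [[Rcpp::export(name = ".edt_feature")]]
List edt_feature(IntegerVector seeds, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  const double INF = 1e30;
  NumericVector d2(n);
  IntegerVector feat(n);
  for (int i = 0; i < n; ++i) {
    d2[i] = seeds[i] ? 0.0 : INF;
    feat[i] = seeds[i] ? i : -1;
  }
  // pass along x
  {
    std::vector<double> f(nx), dd(nx);
    std::vector<int> ff(nx), dfeat(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) { int i = idx3(x,y,z,nx,ny); f[x] = d2[i]; ff[x] = feat[i]; }
        dt1d(f, ff, dd, dfeat);
        for (int x = 0; x < nx; ++x) { int i = idx3(x,y,z,nx,ny); d2[i] = dd[x]; feat[i] = dfeat[x]; }
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), dd(ny);
    std::vector<int> ff(ny), dfeat(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) { int i = idx3(x,y,z,nx,ny); f[y] = d2[i]; ff[y] = feat[i]; }
        dt1d(f, ff, dd, dfeat);
        for (int y = 0; y < ny; ++y) { int i = idx3(x,y,z,nx,ny); d2[i] = dd[y]; feat[i] = dfeat[y]; }
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), dd(nz);
    std::vector<int> ff(nz), dfeat(nz);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        for (int z = 0; z < nz; ++z) { int i = idx3(x,y,z,nx,ny); f[z] = d2[i]; ff[z] = feat[i]; }
        dt1d(f, ff, dd, dfeat);
        for (int z = 0; z < nz; ++z) { int i = idx3(x,y,z,nx,ny); d2[i] = dd[z]; feat[i] = dfeat[z]; }
      }
  }
  return List::create(_["dist2"] = d2, _["feature"] = feat);
}

// ------------------------------------------------------------ local thickness

// Hildebrand-Ruegsegger local thickness in voxel units (diameter of the
// largest inscribed sphere covering each foreground voxel). Sphere radius at
// a centre c is dist(c, nearest background centre) - 1/2; redundant centres
// (spheres fully contained in a neighbour's sphere) are pruned exactly.
// [[Rcpp::export(name = ".local_thickness")]]
List local_thickness(IntegerVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  IntegerVector bg(n);
  for (int i = 0; i < n; ++i) bg[i] = vol[i] ? 0 : 1;
  bool any_bg = false, any_fg = false;
  for (int i = 0; i < n; ++i) { if (bg[i]) any_bg = true; else any_fg = true; }
  NumericVector th(n, 0.0);
  IntegerVector owner(n, -1);  // centre of the covering maximal sphere
  if (!any_fg) return List::create(_["thickness"] = th, _["owner"] = owner);
  std::vector<double> r(n, 0.0);
  if (!any_bg) {
    // no background anywhere: thickness is bounded by the grid, use distance
    // to the virtual background outside the grid
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int b = std::min(std::min(x, nx - 1 - x), std::min(std::min(y, ny - 1 - y), std::min(z, nz - 1 - z)));
          r[idx3(x,y,z,nx,ny)] = b + 1.0;
        }
  } else {
    List ed = edt_feature(bg, dim);
    NumericVector d2 = ed["dist2"];
    // r is the painting radius (distance to the nearest background centre,
    // which covers every bone voxel); the recorded thickness is
    // 2 * (r - 1/2), the sphere touching the material boundary
    for (int i = 0; i < n; ++i) if (vol[i]) r[i] = std::sqrt(d2[i]);
  }
  // collect candidate centres; prune centres whose sphere is contained in a
  // 26-neighbour's sphere: r[n] >= r[c] + |c - n|
  std::vector<int> cand;
  cand.reserve(n / 4);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x,y,z,nx,ny);
        if (!vol[i]) continue;
        bool redundant = false;
        for (int dz = -1; dz <= 1 && !redundant; ++dz)
          for (int dy = -1; dy <= 1 && !redundant; ++dy)
            for (int dx = -1; dx <= 1 && !redundant; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
              int j = idx3(xx,yy,zz,nx,ny);
              if (!vol[j]) continue;
              double dist = std::sqrt((double)(dx*dx + dy*dy + dz*dz));
              if (r[j] >= r[i] + dist - 1e-12) redundant = true;
            }
        if (!redundant) cand.push_back(i);
      }
  std::sort(cand.begin(), cand.end(), [&](int a, int b) { return r[a] > r[b]; });
  for (int c : cand) {
    double rc = r[c];
    double val = 2.0 * (rc - 0.5);
    if (val <= 0) continue;
    int z = c / (nx * ny), rem = c % (nx * ny);
    int y = rem / nx, x = rem % nx;
    int ri = (int)std::floor(rc);
    double rc2 = rc * rc + 1e-12;
    for (int dz = -ri; dz <= ri; ++dz) {
      int zz = z + dz; if (zz < 0 || zz >= nz) continue;
      for (int dy = -ri; dy <= ri; ++dy) {
        int yy = y + dy; if (yy < 0 || yy >= ny) continue;
        for (int dx = -ri; dx <= ri; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          if (dx*dx + dy*dy + dz*dz > rc2) continue;
          int j = idx3(xx,yy,zz,nx,ny);
          if (th[j] < val) { th[j] = val; owner[j] = c; }
        }
      }
    }
  }
  for (int i = 0; i < n; ++i) if (!vol[i]) { th[i] = 0.0; owner[i] = -1; }
  return List::create(_["thickness"] = th, _["owner"] = owner);
}

// ------------------------------------------------- plate/rod classification

// Classify each bone voxel as plate (1) or rod (2) from local geometry:
// the thickness direction u is taken at the centre of the voxel's covering
// maximal sphere (so plate rims inherit the plate normal); the structure's
// bilateral extent is probed along 8 directions spanning the plane
// perpendicular to u. A voxel is plate-like when most in-plane directions
// extend beyond ext_factor times the local thickness. Classes are then
// smoothed by majority vote over the 26-neighbourhood.
// smallest-eigenvalue eigenvector of a symmetric 3x3 (cyclic Jacobi)
static void min_eigvec3(double A[3][3], double out[3]) {
  double V[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
  for (int sweep = 0; sweep < 30; ++sweep) {
    double off = std::fabs(A[0][1]) + std::fabs(A[0][2]) + std::fabs(A[1][2]);
    if (off < 1e-12) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(A[p][q]) < 1e-15) continue;
        double theta = 0.5 * std::atan2(2.0 * A[p][q], A[q][q] - A[p][p]);
        double c = std::cos(theta), s = std::sin(theta);
        for (int k = 0; k < 3; ++k) {
          double akp = A[k][p], akq = A[k][q];
          A[k][p] = c * akp - s * akq;
          A[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 3; ++k) {
          double apk = A[p][k], aqk = A[q][k];
          A[p][k] = c * apk - s * aqk;
          A[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 3; ++k) {
          double vkp = V[k][p], vkq = V[k][q];
          V[k][p] = c * vkp - s * vkq;
          V[k][q] = s * vkp + c * vkq;
        }
      }
  }
  int best = 0;
  if (A[1][1] < A[best][best]) best = 1;
  if (A[2][2] < A[best][best]) best = 2;
  out[0] = V[0][best]; out[1] = V[1][best]; out[2] = V[2][best];
}

// [[Rcpp::export(name = ".classify_platerod")]]
IntegerVector classify_platerod(IntegerVector vol, IntegerVector dim,
                                IntegerVector owner, NumericVector th,
                                double ext_factor, int min_votes,
                                int smooth_passes) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  IntegerVector cls(n, 0);
  const double step = 0.6;
  // thickness direction per covering-sphere centre: smallest-variance
  // principal axis of the bone occupancy in a local box scaled to the
  // local thickness (robust where the nearest-background direction is
  // ambiguous, e.g. at plate edges)
  std::unordered_map<int, std::array<double,3>> udir;
  auto owner_dir = [&](int c) -> std::array<double,3> {
    auto it = udir.find(c);
    if (it != udir.end()) return it->second;
    int cz = c / (nx * ny), crem = c % (nx * ny);
    int cy = crem / nx, cx = crem % nx;
    int R = (int)std::min(12.0, std::max(3.0, std::round(0.75 * th[c] + 1.0)));
    // mirror at the grid boundary: the cut structure continues symmetrically
    auto foldi = [](int p, int nmax) {
      while (p < 0 || p >= nmax) {
        if (p < 0) p = -1 - p;
        if (p >= nmax) p = 2 * nmax - 1 - p;
      }
      return p;
    };
    double sw = 0, mx = 0, my = 0, mz = 0;
    for (int dz = -R; dz <= R; ++dz)
      for (int dy = -R; dy <= R; ++dy)
        for (int dx = -R; dx <= R; ++dx) {
          int xx = foldi(cx + dx, nx), yy = foldi(cy + dy, ny), zz = foldi(cz + dz, nz);
          if (!vol[idx3(xx,yy,zz,nx,ny)]) continue;
          sw += 1; mx += dx; my += dy; mz += dz;
        }
    mx /= sw; my /= sw; mz /= sw;
    double C[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
    for (int dz = -R; dz <= R; ++dz)
      for (int dy = -R; dy <= R; ++dy)
        for (int dx = -R; dx <= R; ++dx) {
          int xx = foldi(cx + dx, nx), yy = foldi(cy + dy, ny), zz = foldi(cz + dz, nz);
          if (!vol[idx3(xx,yy,zz,nx,ny)]) continue;
          double ex = dx - mx, ey = dy - my, ez = dz - mz;
          C[0][0] += ex*ex; C[0][1] += ex*ey; C[0][2] += ex*ez;
          C[1][1] += ey*ey; C[1][2] += ey*ez; C[2][2] += ez*ez;
        }
    C[1][0] = C[0][1]; C[2][0] = C[0][2]; C[2][1] = C[1][2];
    double u[3];
    min_eigvec3(C, u);
    std::array<double,3> res = {u[0], u[1], u[2]};
    udir[c] = res;
    return res;
  };
  for (int i = 0; i < n; ++i) {
    if (!vol[i]) continue;
    int z = i / (nx * ny), rem = i % (nx * ny);
    int y = rem / nx, x = rem % nx;
    int c = owner[i] >= 0 ? owner[i] : i;
    auto u = owner_dir(c);
    double ux = u[0], uy = u[1], uz = u[2];
    // orthonormal basis of the plane perpendicular to u
    double ax = 1, ay = 0, az = 0;
    if (std::fabs(ux) > 0.9) { ax = 0; ay = 1; }
    double p1x = ay * uz - az * uy, p1y = az * ux - ax * uz, p1z = ax * uy - ay * ux;
    double pn = std::sqrt(p1x*p1x + p1y*p1y + p1z*p1z);
    p1x /= pn; p1y /= pn; p1z /= pn;
    double p2x = uy * p1z - uz * p1y, p2y = uz * p1x - ux * p1z, p2z = ux * p1y - uy * p1x;
    double tv = std::max(th[i], 1.0);
    double cap = std::max(3.0 * tv, 6.0);
    int extended = 0;
    for (int j = 0; j < 8; ++j) {
      double angle = M_PI * j / 8.0;
      double dxj = std::cos(angle) * p1x + std::sin(angle) * p2x;
      double dyj = std::cos(angle) * p1y + std::sin(angle) * p2y;
      double dzj = std::cos(angle) * p1z + std::sin(angle) * p2z;
      double total = 0;
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        double s = step;
        for (; s <= cap; s += step) {
          double px = x + sgn * s * dxj, py = y + sgn * s * dyj, pz = z + sgn * s * dzj;
          // mirror at the grid boundary: the cut structure is assumed to
          // continue symmetrically beyond the RVE faces
          auto fold = [](double p, int nmax) {
            while (p < -0.5 || p > nmax - 0.5) {
              if (p < -0.5) p = -1.0 - p;
              if (p > nmax - 0.5) p = 2.0 * nmax - 1.0 - p;
            }
            return p;
          };
          int xi = (int)std::lround(fold(px, nx));
          int yi = (int)std::lround(fold(py, ny));
          int zi = (int)std::lround(fold(pz, nz));
          if (!vol[idx3(xi,yi,zi,nx,ny)]) break;
        }
        total += std::min(s, cap);
      }
      if (total >= ext_factor * tv) ++extended;
    }
    cls[i] = (extended >= min_votes) ? 1 : 2;
  }
  // majority smoothing over bone neighbours
  for (int pass = 0; pass < smooth_passes; ++pass) {
    bool changed = false;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x,y,z,nx,ny);
          if (!vol[i]) continue;
          int same = 0, other = 0;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int xx = x + dx, yy = y + dy, zz = z + dz;
                if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
                int j = idx3(xx,yy,zz,nx,ny);
                if (!vol[j]) continue;
                if (cls[j] == cls[i]) ++same; else ++other;
              }
          if (other > same) { cls[i] = 3 - cls[i]; changed = true; }
        }
    if (!changed) break;
  }
  return cls;
}

// ------------------------------------------------------- mean intercept length

// Probe lines through the volume for each direction; returns per-direction
// total bone length (voxel units) and intercept (bone entry) counts.
// origins: matrix n_origins x 3 of points in [0,1)^3 (scaled to the grid).
// [[Rcpp::export(name = ".mil_probe")]]
List mil_probe(IntegerVector vol, IntegerVector dim, NumericMatrix dirs,
               NumericMatrix origins, double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nd = dirs.nrow(), no = origins.nrow();
  NumericVector bone_len(nd);
  IntegerVector intercepts(nd);
  const double ext = std::sqrt((double)(nx*nx + ny*ny + nz*nz));
  for (int d = 0; d < nd; ++d) {
    double ux = dirs(d,0), uy = dirs(d,1), uz = dirs(d,2);
    double blen = 0; int icpt = 0;
    for (int o = 0; o < no; ++o) {
      double px = origins(o,0) * nx, py = origins(o,1) * ny, pz = origins(o,2) * nz;
      bool prev_bone = false;
      int nstep = (int)(2.0 * ext / step);
      double t0 = -ext;
      for (int s = 0; s <= nstep; ++s) {
        double t = t0 + s * step;
        double x = px + t * ux, y = py + t * uy, z = pz + t * uz;
        int xi = (int)std::floor(x), yi = (int)std::floor(y), zi = (int)std::floor(z);
        bool bone = false;
        if (xi >= 0 && yi >= 0 && zi >= 0 && xi < nx && yi < ny && zi < nz)
          bone = vol[idx3(xi,yi,zi,nx,ny)] != 0;
        if (bone) {
          blen += step;
          if (!prev_bone) ++icpt;
        }
        prev_bone = bone;
      }
    }
    bone_len[d] = blen;
    intercepts[d] = icpt;
  }
  return List::create(_["bone_length"] = bone_len, _["intercepts"] = intercepts);
}

// ---------------------------------------------------------------- thinning

// Neighbourhood helpers operate on a 3x3x3 window flattened as
// w[dx+1 + 3*(dy+1) + 9*(dz+1)], centre at index 13.
static void get_window(const std::vector<uint8_t> &v, int x, int y, int z,
                       int nx, int ny, int nz, uint8_t w[27]) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        w[k] = (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
               ? 0 : v[idx3(xx,yy,zz,nx,ny)];
      }
}

// number of 26-connected components of foreground within the 26-neighbourhood
static int fg_components26(const uint8_t w[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !w[i] || seen[i]) continue;
    ++comps;
    std::vector<int> st{ i };
    seen[i] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cz = c / 9, cy = (c % 9) / 3, cx = c % 3;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = cx + dx, yy = cy + dy, zz = cz + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
            int j = xx + 3 * yy + 9 * zz;
            if (j == 13 || seen[j] || !w[j]) continue;
            seen[j] = true;
            st.push_back(j);
          }
    }
  }
  return comps;
}

// number of 6-connected components of background restricted to the
// 18-neighbourhood that touch a face neighbour of the centre
static int bg_components6(const uint8_t w[27]) {
  auto in18 = [](int i) {
    int cz = i / 9 - 1, cy = (i % 9) / 3 - 1, cx = i % 3 - 1;
    int man = std::abs(cx) + std::abs(cy) + std::abs(cz);
    return man >= 1 && man <= 2;
  };
  static const int face[6] = {13 - 1, 13 + 1, 13 - 3, 13 + 3, 13 - 9, 13 + 9};
  bool seen[27] = {false};
  int comps = 0;
  for (int f = 0; f < 6; ++f) {
    int i = face[f];
    if (w[i] || seen[i]) continue;
    ++comps;
    std::vector<int> st{ i };
    seen[i] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cz = c / 9, cy = (c % 9) / 3, cx = c % 3;
      const int dxs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (auto &dd : dxs) {
        int xx = cx + dd[0], yy = cy + dd[1], zz = cz + dd[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
        int j = xx + 3 * yy + 9 * zz;
        if (j == 13 || seen[j] || w[j] || !in18(j)) continue;
        seen[j] = true;
        st.push_back(j);
      }
    }
  }
  return comps;
}

static inline bool is_simple_w(const uint8_t w[27]) {
  return fg_components26(w) == 1 && bg_components6(w) == 1;
}

static inline int count_fg_neighbours(const uint8_t w[27]) {
  int c = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && w[i]) ++c;
  return c;
}

// surface point: some axis has background on both sides of the voxel
static inline bool is_surface_point(const uint8_t w[27]) {
  if (!w[13 - 1] && !w[13 + 1]) return true;
  if (!w[13 - 3] && !w[13 + 3]) return true;
  if (!w[13 - 9] && !w[13 + 9]) return true;
  return false;
}

// Topology-preserving thinning to a one-voxel skeleton that retains plate
// sheets and rod curves. Border voxels are eroded in increasing
// distance-transform order (distance-ordered homotopic thinning). A voxel
// is frozen when it is a medial surface point: background on both sides of
// one axis AND locally maximal EDT along its thickness direction. To stop
// transient one-voxel walls (which are locally genuine surfaces and could
// never be removed afterwards) from forming inside thick rods, a deletion
// is reverted when it would turn a neighbour into a NON-medial surface
// point; erosion then proceeds from wall ends instead.
// [[Rcpp::export(name = ".skeletonize")]]
IntegerVector skeletonize(IntegerVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<uint8_t> v(n);
  for (int i = 0; i < n; ++i) v[i] = vol[i] ? 1 : 0;
  // squared EDT of the foreground + nearest-background feature
  IntegerVector bg(n);
  for (int i = 0; i < n; ++i) bg[i] = v[i] ? 0 : 1;
  List ed = edt_feature(bg, dim);
  NumericVector d2 = ed["dist2"];
  IntegerVector feat = ed["feature"];
  auto edt2_at = [&](int x, int y, int z) -> double {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0.0;
    return vol[idx3(x,y,z,nx,ny)] ? (double)d2[idx3(x,y,z,nx,ny)] : 0.0;
  };
  // medial along the (rounded) thickness direction: EDT >= both neighbours
  // along the direction from the nearest background voxel
  auto is_medial = [&](int i) -> bool {
    int z = i / (nx * ny), rem = i % (nx * ny);
    int y = rem / nx, x = rem % nx;
    int q = feat[i];
    if (q < 0) return true;
    int qz = q / (nx * ny), qrem = q % (nx * ny);
    int qy = qrem / nx, qx = qrem % nx;
    double dx = x - qx, dy = y - qy, dz = z - qz;
    double m = std::max(std::fabs(dx), std::max(std::fabs(dy), std::fabs(dz)));
    if (m <= 0) return true;
    int ux = (std::fabs(dx) >= 0.5 * m) ? (dx > 0 ? 1 : -1) : 0;
    int uy = (std::fabs(dy) >= 0.5 * m) ? (dy > 0 ? 1 : -1) : 0;
    int uz = (std::fabs(dz) >= 0.5 * m) ? (dz > 0 ? 1 : -1) : 0;
    double here = d2[i];
    return here >= edt2_at(x + ux, y + uy, z + uz) - 1e-9 &&
           here >= edt2_at(x - ux, y - uy, z - uz) - 1e-9;
  };
  uint8_t w[27];
  auto surface_at = [&](int x, int y, int z) {
    get_window(v, x, y, z, nx, ny, nz, w);
    return is_surface_point(w);
  };
  auto is_border = [&](int x, int y, int z) {
    const int dxs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (auto &dd : dxs) {
      int xx = x + dd[0], yy = y + dd[1], zz = z + dd[2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        return true;
      if (!v[idx3(xx,yy,zz,nx,ny)]) return true;
    }
    return false;
  };
  std::vector<int> cands;
  bool changed = true;
  int guard = 0;
  while (changed && ++guard < 1000) {
    changed = false;
    cands.clear();
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x,y,z,nx,ny);
          if (v[i] && is_border(x, y, z)) cands.push_back(i);
        }
    std::stable_sort(cands.begin(), cands.end(),
                     [&](int a, int b) { return d2[a] < d2[b]; });
    bool inner = true;
    int inner_guard = 0;
    while (inner && ++inner_guard < 500) {
      inner = false;
      for (int i : cands) {
        if (!v[i]) continue;
        int z = i / (nx * ny), rem = i % (nx * ny);
        int y = rem / nx, x = rem % nx;
        get_window(v, x, y, z, nx, ny, nz, w);
        if (count_fg_neighbours(w) <= 1) continue;           // curve endpoint
        if (is_surface_point(w) && is_medial(i)) continue;   // medial sheet
        if (!is_simple_w(w)) continue;
        // tentative deletion: must not create a non-medial wall voxel
        v[i] = 0;
        bool ok = true;
        for (int dz = -1; dz <= 1 && ok; ++dz)
          for (int dy = -1; dy <= 1 && ok; ++dy)
            for (int dx = -1; dx <= 1 && ok; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                continue;
              int j = idx3(xx,yy,zz,nx,ny);
              if (!v[j]) continue;
              if (surface_at(xx, yy, zz) && !is_medial(j)) {
                // was it a surface point already before the deletion?
                v[i] = 1;
                bool before = surface_at(xx, yy, zz);
                v[i] = 0;
                if (!before) ok = false;
              }
            }
        if (!ok) { v[i] = 1; continue; }
        changed = true;
        inner = true;
      }
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = v[i];
  return out;
}

// Classify skeleton voxels by the local topological number of the
// 26-neighbourhood: >= 2 background 6-components across the voxel means a
// surface (plate) point, otherwise a curve (rod) point.
// 1 = plate, 2 = rod.
// [[Rcpp::export(name = ".classify_skeleton")]]
IntegerVector classify_skeleton(IntegerVector skel, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<uint8_t> v(n);
  for (int i = 0; i < n; ++i) v[i] = skel[i] ? 1 : 0;
  IntegerVector cls(n, 0);
  uint8_t w[27];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x,y,z,nx,ny);
        if (!v[i]) continue;
        get_window(v, x, y, z, nx, ny, nz, w);
        cls[i] = (bg_components6(w) >= 2) ? 1 : 2;
      }
  // majority-vote relaxation: isolated misclassifications (sheet rims read
  // as curves, zigzag curve voxels read as surfaces) adopt the dominant
  // class of their skeleton neighbourhood
  for (int pass = 0; pass < 5; ++pass) {
    bool changed = false;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = idx3(x,y,z,nx,ny);
          if (!v[i]) continue;
          int same = 0, other = 0;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int xx = x + dx, yy = y + dy, zz = z + dz;
                if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
                int j = idx3(xx,yy,zz,nx,ny);
                if (!v[j]) continue;
                if (cls[j] == cls[i]) ++same; else ++other;
              }
          if (other > same) { cls[i] = 3 - cls[i]; changed = true; }
        }
    if (!changed) break;
  }
  return cls;
}

// Total Euclidean MST length of a small 3D point cloud (Prim, O(n^2)).
// Used for skeleton-segment arc length.
// [[Rcpp::export(name = ".mst_length")]]
double mst_length(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n <= 1) return 0.0;
  std::vector<double> mind(n, 1e30);
  std::vector<bool> used(n, false);
  mind[0] = 0.0;
  double total = 0.0;
  for (int it = 0; it < n; ++it) {
    int best = -1; double bd = 1e30;
    for (int i = 0; i < n; ++i) if (!used[i] && mind[i] < bd) { bd = mind[i]; best = i; }
    used[best] = true;
    total += std::sqrt(bd);
    for (int i = 0; i < n; ++i) {
      if (used[i]) continue;
      double dx = pts(i,0) - pts(best,0), dy = pts(i,1) - pts(best,1), dz = pts(i,2) - pts(best,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < mind[i]) mind[i] = d2;
    }
  }
  return total;
}

// ------------------------------------------------------------- smoothing

// Separable Gaussian smoothing with per-axis sigma (voxel units), reflected
// boundary. sigma component <= 0 leaves that axis untouched.
// [[Rcpp::export(name = ".gaussian_smooth3d")]]
NumericVector gaussian_smooth3d(NumericVector vol, IntegerVector dim,
                                NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  NumericVector cur(clone(vol));
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * rad + 1);
    double sum = 0;
    for (int k = -rad; k <= rad; ++k) { ker[k + rad] = std::exp(-0.5 * k * k / (s * s)); sum += ker[k + rad]; }
    for (auto &kv : ker) kv /= sum;
    NumericVector out(n);
    int len = (ax == 0) ? nx : (ax == 1) ? ny : nz;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int pos = (ax == 0) ? x : (ax == 1) ? y : z;
          double acc = 0;
          for (int k = -rad; k <= rad; ++k) {
            int p = pos + k;
            if (p < 0) p = -p - 1;
            if (p >= len) p = 2 * len - p - 1;
            int xx = x, yy = y, zz = z;
            if (ax == 0) xx = p; else if (ax == 1) yy = p; else zz = p;
            acc += ker[k + rad] * cur[idx3(xx,yy,zz,nx,ny)];
          }
          out[idx3(x,y,z,nx,ny)] = acc;
        }
    cur = out;
  }
  return cur;
}
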