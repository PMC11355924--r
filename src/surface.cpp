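// Isosurface extraction (marching tetrahedra on the voxel-centre sample
// grid), mesh statistics, and per-vertex principal curvature estimation by
// finite differences of vertex normals along edges (least-squares fit of the
// second fundamental form per face, corner-angle-weighted vertex averaging).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};
static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline Vec3 vadd(const Vec3 &a, const Vec3 &b) { return {a.x+b.x, a.y+b.y, a.z+b.z}; }
static inline Vec3 vscale(const Vec3 &a, double s) { return {a.x*s, a.y*s, a.z*s}; }
static inline double vdot(const Vec3 &a, const Vec3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
static inline double vnorm(const Vec3 &a) { return std::sqrt(vdot(a, a)); }
static inline Vec3 vunit(const Vec3 &a) {
  double n = vnorm(a);
  return (n > 0) ? vscale(a, 1.0 / n) : Vec3{0, 0, 0};
}

// ------------------------------------------------------------ marching tets

// Extract the iso-level surface of a scalar field sampled on a regular grid.
// field: nx*ny*nz values (R array layout); sample (i,j,k) sits at physical
// position offset + (i,j,k)*spacing. Bone/solid phase is field > iso; emitted
// triangles are oriented with outward normals (pointing into field < iso).
// [[Rcpp::export(name = ".marching_tetrahedra")]]
List marching_tetrahedra(NumericVector field, IntegerVector dim,
                         NumericVector spacing, NumericVector offset,
                         double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t nxy = (int64_t)nx * ny;
  // cube corner offsets (x,y,z bits)
  static const int cx[8] = {0,1,1,0,0,1,1,0};
  static const int cy[8] = {0,0,1,1,0,0,1,1};
  static const int cz[8] = {0,0,0,0,1,1,1,1};
  // six tetrahedra around the main diagonal corner0 - corner6
  static const int tets[6][4] = {
    {0,1,2,6}, {0,2,3,6}, {0,3,7,6}, {0,7,4,6}, {0,4,5,6}, {0,5,1,6}
  };
  std::unordered_map<int64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;

  auto sample_pos = [&](int64_t gi) -> Vec3 {
    int zi = (int)(gi / nxy);
    int64_t rem = gi % nxy;
    int yi = (int)(rem / nx), xi = (int)(rem % nx);
    return {offset[0] + xi * spacing[0], offset[1] + yi * spacing[1],
            offset[2] + zi * spacing[2]};
  };
  auto cut_vertex = [&](int64_t ga, int64_t gb, double fa, double fb) -> int {
    int64_t a = ga, b = gb;
    double va = fa, vb = fb;
    if (a > b) { std::swap(a, b); std::swap(va, vb); }
    int64_t key = a * (int64_t)(nxy * nz) + b;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - va) / (vb - va);
    Vec3 pa = sample_pos(a), pb = sample_pos(b);
    Vec3 p = vadd(pa, vscale(vsub(pb, pa), t));
    int id = (int)vx.size();
    vx.push_back(p.x); vy.push_back(p.y); vz.push_back(p.z);
    edge_vertex[key] = id;
    return id;
  };
  auto emit = [&](int a, int b, int c, const Vec3 &ref) {
    Vec3 pa{vx[a], vy[a], vz[a]}, pb{vx[b], vy[b], vz[b]}, pc{vx[c], vy[c], vz[c]};
    Vec3 nrm = vcross(vsub(pb, pa), vsub(pc, pa));
    if (vdot(nrm, ref) < 0) std::swap(b, c);
    f0.push_back(a); f1.push_back(b); f2.push_back(c);
  };

  std::vector<int64_t> gidx(8);
  std::vector<double> fv(8);
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int64_t gi = (x + cx[c]) + (int64_t)nx * ((y + cy[c]) + (int64_t)ny * (z + cz[c]));
          gidx[c] = gi;
          double v = field[gi];
          if (std::fabs(v - iso) < 1e-12) v = iso + 1e-9;  // avoid degenerate cuts
          fv[c] = v;
          if (v > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (auto &tet : tets) {
          int in[4], out[4];
          int ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (fv[tet[c]] > iso) in[ni++] = tet[c]; else out[no++] = tet[c];
          }
          if (ni == 0 || ni == 4) continue;
          // outward reference: from inside centroid toward outside centroid
          Vec3 ci{0,0,0}, co{0,0,0};
          for (int c = 0; c < ni; ++c) ci = vadd(ci, sample_pos(gidx[in[c]]));
          for (int c = 0; c < no; ++c) co = vadd(co, sample_pos(gidx[out[c]]));
          Vec3 ref = vsub(vscale(co, 1.0 / no), vscale(ci, 1.0 / ni));
          if (ni == 1) {
            int a = cut_vertex(gidx[in[0]], gidx[out[0]], fv[in[0]], fv[out[0]]);
            int b = cut_vertex(gidx[in[0]], gidx[out[1]], fv[in[0]], fv[out[1]]);
            int c = cut_vertex(gidx[in[0]], gidx[out[2]], fv[in[0]], fv[out[2]]);
            emit(a, b, c, ref);
          } else if (ni == 3) {
            int a = cut_vertex(gidx[in[0]], gidx[out[0]], fv[in[0]], fv[out[0]]);
            int b = cut_vertex(gidx[in[1]], gidx[out[0]], fv[in[1]], fv[out[0]]);
            int c = cut_vertex(gidx[in[2]], gidx[out[0]], fv[in[2]], fv[out[0]]);
            emit(a, b, c, ref);
          } else { // ni == 2: quad split into two triangles
            int q0 = cut_vertex(gidx[in[0]], gidx[out[0]], fv[in[0]], fv[out[0]]);
            int q1 = cut_vertex(gidx[in[0]], gidx[out[1]], fv[in[0]], fv[out[1]]);
            int q2 = cut_vertex(gidx[in[1]], gidx[out[1]], fv[in[1]], fv[out[1]]);
            int q3 = cut_vertex(gidx[in[1]], gidx[out[0]], fv[in[1]], fv[out[0]]);
            emit(q0, q1, q2, ref);
            emit(q0, q2, q3, ref);
          }
        }
      }
  const int nv = (int)vx.size(), nf = (int)f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) { V(i,0) = vx[i]; V(i,1) = vy[i]; V(i,2) = vz[i]; }
  for (int i = 0; i < nf; ++i) { F(i,0) = f0[i] + 1; F(i,1) = f1[i] + 1; F(i,2) = f2[i] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ------------------------------------------------------------- mesh helpers

// Area-weighted vertex normals (unit length).
// [[Rcpp::export(name = ".vertex_normals")]]
NumericMatrix vertex_normals_cpp(NumericMatrix V, IntegerMatrix F) {
  const int nv = V.nrow(), nf = F.nrow();
  NumericMatrix N(nv, 3);
  for (int f = 0; f < nf; ++f) {
    int a = F(f,0) - 1, b = F(f,1) - 1, c = F(f,2) - 1;
    Vec3 pa{V(a,0),V(a,1),V(a,2)}, pb{V(b,0),V(b,1),V(b,2)}, pc{V(c,0),V(c,1),V(c,2)};
    Vec3 n = vcross(vsub(pb, pa), vsub(pc, pa));  // magnitude = 2 * area
    for (int k = 0; k < 3; ++k) {
      double nk = (k == 0) ? n.x : (k == 1) ? n.y : n.z;
      N(a,k) += nk; N(b,k) += nk; N(c,k) += nk;
    }
  }
  for (int i = 0; i < nv; ++i) {
    double nn = std::sqrt(N(i,0)*N(i,0) + N(i,1)*N(i,1) + N(i,2)*N(i,2));
    if (nn > 0) { N(i,0) /= nn; N(i,1) /= nn; N(i,2) /= nn; }
  }
  return N;
}

// Edge statistics used for manifold/closedness checks:
// n_edges, max face incidence per edge, number of boundary edges.
// [[Rcpp::export(name = ".mesh_edge_stats")]]
List mesh_edge_stats(IntegerMatrix F, int n_vertices) {
  std::unordered_map<int64_t, int> inc;
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    for (int e = 0; e < 3; ++e) {
      int a = F(f,e) - 1, b = F(f,(e+1)%3) - 1;
      if (a > b) std::swap(a, b);
      inc[(int64_t)a * n_vertices + b]++;
    }
  }
  int maxinc = 0, nbound = 0;
  for (auto &kv : inc) {
    if (kv.second > maxinc) maxinc = kv.second;
    if (kv.second == 1) ++nbound;
  }
  return List::create(_["n_edges"] = (int)inc.size(),
                      _["max_incidence"] = maxinc,
                      _["n_boundary_edges"] = nbound);
}

// --------------------------------------------------------------- curvature

// rotate vector x from the plane normal to `from` into the plane normal to
// `to` (minimal rotation between unit normals)
static Vec3 rotate_between(const Vec3 &x, const Vec3 &from, const Vec3 &to) {
  double c = vdot(from, to);
  if (c < -0.9999) return vscale(x, -1.0);  // antipodal: flip
  Vec3 ab = vadd(from, to);
  double s = vdot(ab, x) / (1.0 + c);
  // double-reflection formula mapping `from` to `to`
  return vadd(vsub(x, vscale(ab, s)), vscale(to, 2.0 * vdot(from, x)));
}

// Per-vertex second fundamental form by per-face finite differences of
// vertex normals along edges, corner-angle-weighted averaging in each
// vertex's tangent frame. Returns k1 >= k2 (units 1/length of V).
// [[Rcpp::export(name = ".principal_curvatures")]]
List principal_curvatures_cpp(NumericMatrix V, IntegerMatrix F, NumericMatrix N) {
  const int nv = V.nrow(), nf = F.nrow();
  std::vector<double> ee(nv, 0.0), ff(nv, 0.0), gg(nv, 0.0), wsum(nv, 0.0);
  // vertex tangent frames
  std::vector<Vec3> vu(nv), vv(nv), vn(nv);
  for (int i = 0; i < nv; ++i) {
    Vec3 n{N(i,0), N(i,1), N(i,2)};
    vn[i] = n;
    Vec3 a = (std::fabs(n.x) < 0.9) ? Vec3{1,0,0} : Vec3{0,1,0};
    Vec3 u = vunit(vcross(a, n));
    vu[i] = u;
    vv[i] = vcross(n, u);
  }
  for (int f = 0; f < nf; ++f) {
    int vi[3] = {F(f,0) - 1, F(f,1) - 1, F(f,2) - 1};
    Vec3 p[3], nrm[3];
    for (int c = 0; c < 3; ++c) {
      p[c] = {V(vi[c],0), V(vi[c],1), V(vi[c],2)};
      nrm[c] = {N(vi[c],0), N(vi[c],1), N(vi[c],2)};
    }
    Vec3 fn = vcross(vsub(p[1], p[0]), vsub(p[2], p[0]));
    double a2 = vnorm(fn);
    if (a2 <= 0) continue;
    fn = vscale(fn, 1.0 / a2);
    Vec3 u = vunit(vsub(p[1], p[0]));
    Vec3 w = vcross(fn, u);
    // least squares for face II = [[e f],[f g]] from the three edges
    double A[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
    double b[3] = {0, 0, 0};
    for (int e = 0; e < 3; ++e) {
      int i = e, j = (e + 1) % 3;
      Vec3 dp = vsub(p[j], p[i]);
      Vec3 dn = vsub(nrm[j], nrm[i]);
      double du = vdot(dp, u), dw = vdot(dp, w);
      double nu = vdot(dn, u), nw = vdot(dn, w);
      // eq1: e*du + f*dw = nu  -> row (du, dw, 0)
      // eq2: f*du + g*dw = nw  -> row (0, du, dw)
      double r1[3] = {du, dw, 0}, r2[3] = {0, du, dw};
      for (int q = 0; q < 3; ++q) {
        for (int r = 0; r < 3; ++r) A[q][r] += r1[q]*r1[r] + r2[q]*r2[r];
        b[q] += r1[q]*nu + r2[q]*nw;
      }
    }
    // solve 3x3 (Cramer)
    double det = A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
               - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
               + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
    if (std::fabs(det) < 1e-30) continue;
    auto solve3 = [&](int col) {
      double M[3][3];
      for (int q = 0; q < 3; ++q)
        for (int r = 0; r < 3; ++r) M[q][r] = (r == col) ? b[q] : A[q][r];
      return (M[0][0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1])
            - M[0][1]*(M[1][0]*M[2][2]-M[1][2]*M[2][0])
            + M[0][2]*(M[1][0]*M[2][1]-M[1][1]*M[2][0])) / det;
    };
    double fe = solve3(0), fff = solve3(1), fg = solve3(2);
    // distribute to vertices with corner-angle weights
    for (int c = 0; c < 3; ++c) {
      int vid = vi[c];
      Vec3 ea = vunit(vsub(p[(c+1)%3], p[c]));
      Vec3 eb = vunit(vsub(p[(c+2)%3], p[c]));
      double cosang = std::max(-1.0, std::min(1.0, vdot(ea, eb)));
      double wgt = std::acos(cosang);
      // express vertex frame in the face plane
      Vec3 upf = rotate_between(vu[vid], vn[vid], fn);
      Vec3 vpf = rotate_between(vv[vid], vn[vid], fn);
      double a1 = vdot(upf, u), b1 = vdot(upf, w);
      double a2_ = vdot(vpf, u), b2 = vdot(vpf, w);
      double evv = fe*a1*a1 + 2.0*fff*a1*b1 + fg*b1*b1;
      double fvv = fe*a1*a2_ + fff*(a1*b2 + a2_*b1) + fg*b1*b2;
      double gvv = fe*a2_*a2_ + 2.0*fff*a2_*b2 + fg*b2*b2;
      ee[vid] += wgt * evv;
      ff[vid] += wgt * fvv;
      gg[vid] += wgt * gvv;
      wsum[vid] += wgt;
    }
  }
  NumericVector k1(nv), k2(nv);
  for (int i = 0; i < nv; ++i) {
    if (wsum[i] <= 0) { k1[i] = NA_REAL; k2[i] = NA_REAL; continue; }
    double e = ee[i] / wsum[i], f = ff[i] / wsum[i], g = gg[i] / wsum[i];
    double h = 0.5 * (e + g);
    double d = std::sqrt(0.25 * (e - g) * (e - g) + f * f);
    k1[i] = h + d;
    k2[i] = h - d;
  }
  return List::create(_["k1"] = k1, _["k2"] = k2);
}

// Outward unit normals at arbitrary points as the exact analytic gradient
// of the Gaussian-smoothed occupancy field: n(x) = -grad sum_i b_i G_sigma(x - c_i),
// evaluated by direct convolution over the kernel support (no grid
// interpolation, so the normal field is smooth in x).
// verts_grid: continuous 0-based voxel-centre coordinates of the points.
// [[Rcpp::export(name = ".field_normals_conv")]]
NumericMatrix field_normals_conv(IntegerVector vol, IntegerVector dim,
                                 NumericMatrix verts_grid, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nv = verts_grid.nrow();
  const int R = std::max(2, (int)std::ceil(4.0 * sigma));
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  NumericMatrix N(nv, 3);
  std::vector<double> kx(2 * R + 2), ky(2 * R + 2), kz(2 * R + 2);
  std::vector<double> dx_(2 * R + 2), dy_(2 * R + 2), dz_(2 * R + 2);
  for (int v = 0; v < nv; ++v) {
    double ux = verts_grid(v, 0), uy = verts_grid(v, 1), uz = verts_grid(v, 2);
    int ix0 = (int)std::floor(ux) - R, ix1 = (int)std::floor(ux) + R + 1;
    int iy0 = (int)std::floor(uy) - R, iy1 = (int)std::floor(uy) + R + 1;
    int iz0 = (int)std::floor(uz) - R, iz1 = (int)std::floor(uz) + R + 1;
    for (int i = ix0; i <= ix1; ++i) {
      double d = i - ux;
      kx[i - ix0] = std::exp(-d * d * inv2s2);
      dx_[i - ix0] = d;
    }
    for (int i = iy0; i <= iy1; ++i) {
      double d = i - uy;
      ky[i - iy0] = std::exp(-d * d * inv2s2);
      dy_[i - iy0] = d;
    }
    for (int i = iz0; i <= iz1; ++i) {
      double d = i - uz;
      kz[i - iz0] = std::exp(-d * d * inv2s2);
      dz_[i - iz0] = d;
    }
    double gx = 0, gy = 0, gz = 0;
    for (int z = std::max(0, iz0); z <= std::min(nz - 1, iz1); ++z) {
      double wz = kz[z - iz0], dz = dz_[z - iz0];
      for (int y = std::max(0, iy0); y <= std::min(ny - 1, iy1); ++y) {
        double wyz = ky[y - iy0] * wz, dy = dy_[y - iy0];
        const int *col = &vol[0] + (size_t)nx * (y + (size_t)ny * z);
        for (int x = std::max(0, ix0); x <= std::min(nx - 1, ix1); ++x) {
          if (!col[x]) continue;
          double w = kx[x - ix0] * wyz;
          gx += w * dx_[x - ix0];
          gy += w * dy;
          gz += w * dz;
        }
      }
    }
    // grad(field) is along the +d-weighted sum; outward normal = -grad(field)
    double nn = std::sqrt(gx * gx + gy * gy + gz * gz);
    if (nn > 0) { N(v, 0) = -gx / nn; N(v, 1) = -gy / nn; N(v, 2) = -gz / nn; }
  }
  return N;
}
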