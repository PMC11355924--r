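// Voxel-based linear elastic homogenization under kinematic uniform boundary
// conditions. Each bone voxel becomes either six first-order tetrahedra
// (split along the voxel main diagonal) or one trilinear hexahedron; all
// voxels share one element stiffness, so the stiffness operator is applied
// matrix-free. The reduced system on interior DOFs is solved by
// Jacobi-preconditioned conjugate gradients.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// cube corner bit pattern, shared with the mesh/tet code
static const int CX[8] = {0,1,1,0,0,1,1,0};
static const int CY[8] = {0,0,1,1,0,0,1,1};
static const int CZ[8] = {0,0,0,0,1,1,1,1};
static const int TETS[6][4] = {
  {0,1,2,6}, {0,2,3,6}, {0,3,7,6}, {0,7,4,6}, {0,4,5,6}, {0,5,1,6}
};

// isotropic elasticity matrix, Voigt order (11,22,33,23,13,12), engineering
// shear strains
static void dmatrix(double E, double nu, double D[6][6]) {
  double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  double mu = E / (2.0 * (1.0 + nu));
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) D[i][j] = 0.0;
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) D[i][j] = lam;
    D[i][i] = lam + 2.0 * mu;
    D[i + 3][i + 3] = mu;
  }
}

static void inv3(const double M[3][3], double Mi[3][3]) {
  double det = M[0][0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1])
             - M[0][1]*(M[1][0]*M[2][2]-M[1][2]*M[2][0])
             + M[0][2]*(M[1][0]*M[2][1]-M[1][1]*M[2][0]);
  double id = 1.0 / det;
  Mi[0][0] =  (M[1][1]*M[2][2]-M[1][2]*M[2][1]) * id;
  Mi[0][1] = -(M[0][1]*M[2][2]-M[0][2]*M[2][1]) * id;
  Mi[0][2] =  (M[0][1]*M[1][2]-M[0][2]*M[1][1]) * id;
  Mi[1][0] = -(M[1][0]*M[2][2]-M[1][2]*M[2][0]) * id;
  Mi[1][1] =  (M[0][0]*M[2][2]-M[0][2]*M[2][0]) * id;
  Mi[1][2] = -(M[0][0]*M[1][2]-M[0][2]*M[1][0]) * id;
  Mi[2][0] =  (M[1][0]*M[2][1]-M[1][1]*M[2][0]) * id;
  Mi[2][1] = -(M[0][0]*M[2][1]-M[0][1]*M[2][0]) * id;
  Mi[2][2] =  (M[0][0]*M[1][1]-M[0][1]*M[1][0]) * id;
}

// per-tet constant B (6 x 12) and volume for a tet on the h-cube
static double tet_b_matrix(const int tet[4], double h, double B[6][12]) {
  double p[4][3];
  for (int c = 0; c < 4; ++c) {
    p[c][0] = CX[tet[c]] * h; p[c][1] = CY[tet[c]] * h; p[c][2] = CZ[tet[c]] * h;
  }
  double M[3][3];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) M[r][c] = p[r + 1][c] - p[0][c];
  double det = M[0][0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1])
             - M[0][1]*(M[1][0]*M[2][2]-M[1][2]*M[2][0])
             + M[0][2]*(M[1][0]*M[2][1]-M[1][1]*M[2][0]);
  double V = std::fabs(det) / 6.0;
  double Mi[3][3];
  inv3(M, Mi);
  // x - p0 = A lambda with A columns p_i - p0, i.e. A = M^T, so
  // grad(lambda_i) = rows of A^{-1} = columns of inv(M); lambda_0 = -sum
  double g[4][3];
  for (int c = 0; c < 3; ++c) {
    g[1][c] = Mi[c][0]; g[2][c] = Mi[c][1]; g[3][c] = Mi[c][2];
    g[0][c] = -(g[1][c] + g[2][c] + g[3][c]);
  }
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 12; ++c) B[r][c] = 0.0;
  for (int nd = 0; nd < 4; ++nd) {
    int cx_ = 3 * nd;
    double gx = g[nd][0], gy = g[nd][1], gz = g[nd][2];
    B[0][cx_ + 0] = gx;
    B[1][cx_ + 1] = gy;
    B[2][cx_ + 2] = gz;
    B[3][cx_ + 1] = gz; B[3][cx_ + 2] = gy;   // gamma_yz
    B[4][cx_ + 0] = gz; B[4][cx_ + 2] = gx;   // gamma_xz
    B[5][cx_ + 0] = gy; B[5][cx_ + 1] = gx;   // gamma_xy
  }
  return V;
}

// hex trilinear B at a quadrature point (xi in [-1,1]^3), plus |J|
static double hex_b_matrix(double h, double xi, double eta, double zeta,
                           double B[6][24]) {
  double g[8][3];
  for (int nd = 0; nd < 8; ++nd) {
    double sx = 2.0 * CX[nd] - 1.0, sy = 2.0 * CY[nd] - 1.0, sz = 2.0 * CZ[nd] - 1.0;
    // dN/dxi etc. on the reference cube, then scale by (2/h)
    g[nd][0] = 0.125 * sx * (1 + sy * eta) * (1 + sz * zeta) * (2.0 / h);
    g[nd][1] = 0.125 * (1 + sx * xi) * sy * (1 + sz * zeta) * (2.0 / h);
    g[nd][2] = 0.125 * (1 + sx * xi) * (1 + sy * eta) * sz * (2.0 / h);
  }
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 24; ++c) B[r][c] = 0.0;
  for (int nd = 0; nd < 8; ++nd) {
    int cx_ = 3 * nd;
    double gx = g[nd][0], gy = g[nd][1], gz = g[nd][2];
    B[0][cx_ + 0] = gx;
    B[1][cx_ + 1] = gy;
    B[2][cx_ + 2] = gz;
    B[3][cx_ + 1] = gz; B[3][cx_ + 2] = gy;
    B[4][cx_ + 0] = gz; B[4][cx_ + 2] = gx;
    B[5][cx_ + 0] = gy; B[5][cx_ + 1] = gx;
  }
  return (h / 2.0) * (h / 2.0) * (h / 2.0);  // |J|
}

// 24x24 voxel stiffness and the 6x24 matrix taking element displacements to
// the element's volume-integrated stress (D * int B dV)
struct VoxelElement {
  double Ke[24][24];
  double SInt[6][24];  // integral of D*B over the voxel
  double vol;
};

static void build_element(double E, double nu, double h, bool hex,
                          VoxelElement &el) {
  double D[6][6];
  dmatrix(E, nu, D);
  for (int i = 0; i < 24; ++i)
    for (int j = 0; j < 24; ++j) el.Ke[i][j] = 0.0;
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 24; ++j) el.SInt[i][j] = 0.0;
  el.vol = h * h * h;
  if (!hex) {
    double B[6][12];
    for (auto &tet : TETS) {
      double V = tet_b_matrix(tet, h, B);
      double DB[6][12];
      for (int r = 0; r < 6; ++r)
        for (int c = 0; c < 12; ++c) {
          double s = 0;
          for (int k = 0; k < 6; ++k) s += D[r][k] * B[k][c];
          DB[r][c] = s;
        }
      int dofmap[12];
      for (int nd = 0; nd < 4; ++nd)
        for (int c = 0; c < 3; ++c) dofmap[3 * nd + c] = 3 * tet[nd] + c;
      for (int r = 0; r < 12; ++r)
        for (int c = 0; c < 12; ++c) {
          double s = 0;
          for (int k = 0; k < 6; ++k) s += B[k][r] * DB[k][c];
          el.Ke[dofmap[r]][dofmap[c]] += V * s;
        }
      for (int r = 0; r < 6; ++r)
        for (int c = 0; c < 12; ++c) el.SInt[r][dofmap[c]] += V * DB[r][c];
    }
  } else {
    double B[6][24];
    const double gp = 1.0 / std::sqrt(3.0);
    for (int ix = 0; ix < 2; ++ix)
      for (int iy = 0; iy < 2; ++iy)
        for (int iz = 0; iz < 2; ++iz) {
          double xi = (2 * ix - 1) * gp, eta = (2 * iy - 1) * gp, zeta = (2 * iz - 1) * gp;
          double w = hex_b_matrix(h, xi, eta, zeta, B);
          double DB[6][24];
          for (int r = 0; r < 6; ++r)
            for (int c = 0; c < 24; ++c) {
              double s = 0;
              for (int k = 0; k < 6; ++k) s += D[r][k] * B[k][c];
              DB[r][c] = s;
            }
          for (int r = 0; r < 24; ++r)
            for (int c = 0; c < 24; ++c) {
              double s = 0;
              for (int k = 0; k < 6; ++k) s += B[k][r] * DB[k][c];
              el.Ke[r][c] += w * s;
            }
          for (int r = 0; r < 6; ++r)
            for (int c = 0; c < 24; ++c) el.SInt[r][c] += w * DB[r][c];
        }
  }
}

// [[Rcpp::export(name = ".fe_element_stiffness")]]
NumericMatrix fe_element_stiffness(double E, double nu, double h, bool hex) {
  VoxelElement el;
  build_element(E, nu, h, hex, el);
  NumericMatrix K(24, 24);
  for (int i = 0; i < 24; ++i)
    for (int j = 0; j < 24; ++j) K(i, j) = el.Ke[i][j];
  return K;
}

// Solve one kinematic-uniform load case on the voxel structure.
// vol: binary occupancy; strain: applied macroscopic strain, Voigt
// (e11,e22,e33,g23,g13,g12) with engineering shears. Returns the RVE
// volume-average stress in the same Voigt order, plus solver diagnostics.
// [[Rcpp::export(name = ".fe_solve_case")]]
List fe_solve_case(IntegerVector vol, IntegerVector dim, double h,
                   double E, double nu, NumericVector strain, bool hex,
                   double tol, int max_iter) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = nx + 1, my = ny + 1, mz = nz + 1;
  const int nvox_total = nx * ny * nz;
  VoxelElement el;
  build_element(E, nu, h, hex, el);

  // collect bone voxels and active nodes
  std::vector<int> voxels;
  voxels.reserve(nvox_total / 2);
  for (int i = 0; i < nvox_total; ++i) if (vol[i]) voxels.push_back(i);
  if (voxels.empty()) stop("empty volume: no elements to mesh");
  std::vector<int> nodemap((size_t)mx * my * mz, -1);
  auto nodeid = [&](int x, int y, int z) { return x + mx * (y + my * z); };
  int nactive = 0;
  for (int v : voxels) {
    int z = v / (nx * ny), rem = v % (nx * ny), y = rem / nx, x = rem % nx;
    for (int c = 0; c < 8; ++c) {
      int gid = nodeid(x + CX[c], y + CY[c], z + CZ[c]);
      if (nodemap[gid] < 0) nodemap[gid] = nactive++;
    }
  }
  // per-voxel compact node ids
  std::vector<int> enodes((size_t)voxels.size() * 8);
  std::vector<uint8_t> fixed(nactive, 0);
  std::vector<double> px(nactive), py(nactive), pz(nactive);
  for (size_t e = 0; e < voxels.size(); ++e) {
    int v = voxels[e];
    int z = v / (nx * ny), rem = v % (nx * ny), y = rem / nx, x = rem % nx;
    for (int c = 0; c < 8; ++c) {
      int gx = x + CX[c], gy = y + CY[c], gz = z + CZ[c];
      int nid = nodemap[nodeid(gx, gy, gz)];
      enodes[8 * e + c] = nid;
      px[nid] = gx * h; py[nid] = gy * h; pz[nid] = gz * h;
      if (gx == 0 || gy == 0 || gz == 0 || gx == nx || gy == ny || gz == nz)
        fixed[nid] = 1;
    }
  }
  int nfixed = 0;
  for (int i = 0; i < nactive; ++i) nfixed += fixed[i];
  if (nfixed < 3) stop("structure does not reach the RVE boundary: KUBC underconstrained");

  const int ndof = 3 * nactive;
  std::vector<double> u(ndof, 0.0);
  // prescribed affine displacement u = eps0 * x on boundary nodes
  double e11 = strain[0], e22 = strain[1], e33 = strain[2];
  double e23 = 0.5 * strain[3], e13 = 0.5 * strain[4], e12 = 0.5 * strain[5];
  for (int i = 0; i < nactive; ++i) {
    if (!fixed[i]) continue;
    u[3*i + 0] = e11 * px[i] + e12 * py[i] + e13 * pz[i];
    u[3*i + 1] = e12 * px[i] + e22 * py[i] + e23 * pz[i];
    u[3*i + 2] = e13 * px[i] + e23 * py[i] + e33 * pz[i];
  }

  auto applyK = [&](const std::vector<double> &x, std::vector<double> &y) {
    std::fill(y.begin(), y.end(), 0.0);
    double ue[24], ye[24];
    for (size_t e = 0; e < voxels.size(); ++e) {
      const int *nd = &enodes[8 * e];
      for (int c = 0; c < 8; ++c) {
        ue[3*c+0] = x[3*nd[c]+0]; ue[3*c+1] = x[3*nd[c]+1]; ue[3*c+2] = x[3*nd[c]+2];
      }
      for (int r = 0; r < 24; ++r) {
        double s = 0;
        const double *kr = el.Ke[r];
        for (int c = 0; c < 24; ++c) s += kr[c] * ue[c];
        ye[r] = s;
      }
      for (int c = 0; c < 8; ++c) {
        y[3*nd[c]+0] += ye[3*c+0]; y[3*nd[c]+1] += ye[3*c+1]; y[3*nd[c]+2] += ye[3*c+2];
      }
    }
  };

  // rhs on free dofs: b = -K u_bc (u currently holds bc values, zeros free)
  std::vector<double> b(ndof), r(ndof), zv(ndof), p(ndof), Ap(ndof);
  applyK(u, b);
  for (int i = 0; i < ndof; ++i) b[i] = -b[i];
  // Jacobi diagonal
  std::vector<double> diag(ndof, 0.0);
  for (size_t e = 0; e < voxels.size(); ++e) {
    const int *nd = &enodes[8 * e];
    for (int c = 0; c < 8; ++c)
      for (int k = 0; k < 3; ++k)
        diag[3*nd[c]+k] += el.Ke[3*c+k][3*c+k];
  }
  auto zero_fixed = [&](std::vector<double> &x) {
    for (int i = 0; i < nactive; ++i)
      if (fixed[i]) { x[3*i] = 0; x[3*i+1] = 0; x[3*i+2] = 0; }
  };
  zero_fixed(b);
  double bnorm = 0;
  for (int i = 0; i < ndof; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  double relres = 0.0;
  int iter = 0;
  if (bnorm > 0) {
    // PCG on free dofs; free part of u starts at zero
    r = b;
    for (int i = 0; i < ndof; ++i) zv[i] = r[i] / diag[i];
    zero_fixed(zv);
    p = zv;
    double rz = 0;
    for (int i = 0; i < ndof; ++i) rz += r[i] * zv[i];
    std::vector<double> ufree(ndof, 0.0);
    for (iter = 1; iter <= max_iter; ++iter) {
      applyK(p, Ap);
      zero_fixed(Ap);
      double pAp = 0;
      for (int i = 0; i < ndof; ++i) pAp += p[i] * Ap[i];
      double alpha = rz / pAp;
      for (int i = 0; i < ndof; ++i) { ufree[i] += alpha * p[i]; r[i] -= alpha * Ap[i]; }
      double rnorm = 0;
      for (int i = 0; i < ndof; ++i) rnorm += r[i] * r[i];
      relres = std::sqrt(rnorm) / bnorm;
      if (relres <= tol) break;
      for (int i = 0; i < ndof; ++i) zv[i] = r[i] / diag[i];
      zero_fixed(zv);
      double rznew = 0;
      for (int i = 0; i < ndof; ++i) rznew += r[i] * zv[i];
      double beta = rznew / rz;
      rz = rznew;
      for (int i = 0; i < ndof; ++i) p[i] = zv[i] + beta * p[i];
    }
    if (relres > tol)
      stop("PCG did not converge: relative residual %g after %d iterations",
           relres, max_iter);
    for (int i = 0; i < nactive; ++i) {
      if (fixed[i]) continue;
      u[3*i] = ufree[3*i]; u[3*i+1] = ufree[3*i+1]; u[3*i+2] = ufree[3*i+2];
    }
  }

  // RVE volume-average stress: sum over elements of int(sigma) / V_RVE
  double sint[6] = {0,0,0,0,0,0};
  double ue[24];
  for (size_t e = 0; e < voxels.size(); ++e) {
    const int *nd = &enodes[8 * e];
    for (int c = 0; c < 8; ++c) {
      ue[3*c+0] = u[3*nd[c]+0]; ue[3*c+1] = u[3*nd[c]+1]; ue[3*c+2] = u[3*nd[c]+2];
    }
    for (int r6 = 0; r6 < 6; ++r6) {
      double s = 0;
      for (int c = 0; c < 24; ++c) s += el.SInt[r6][c] * ue[c];
      sint[r6] += s;
    }
  }
  double vrve = (double)nvox_total * h * h * h;
  NumericVector sigma(6);
  for (int i = 0; i < 6; ++i) sigma[i] = sint[i] / vrve;
  return List::create(_["avg_stress"] = sigma,
                      _["iterations"] = iter,
                      _["relres"] = relres,
                      _["n_elements"] = (int)voxels.size() * (hex ? 1 : 6),
                      _["n_nodes"] = nactive,
                      _["n_fixed_nodes"] = nfixed);
}
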