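// Hot numerical kernels: mass-conserving forward convection (splat) and its
// adjoints, real-space projection (rotate-then-sum) and backprojection,
// volume rotation, SVD local-rigidity energy, and a separable Euclidean
// distance transform.  All grids are cubic N^3, R column-major
// (index = ix + N*(iy + N*iz)), coordinates in voxel units with the
// rotation/projection origin at index N/2 on each axis.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int cube_dim(const NumericVector& v) {
  IntegerVector d = v.attr("dim");
  if (d.size() != 3 || d[0] != d[1] || d[0] != d[2])
    stop("expected a cubic N x N x N grid");
  return d[0];
}

// Keys cubic interpolation kernel, a = -0.5 (support 2).
static inline double keys_w(double t) {
  t = std::fabs(t);
  if (t < 1.0)  return ((1.5 * t - 2.5) * t) * t + 1.0;
  if (t < 2.0)  return (((-0.5 * t) + 2.5) * t - 4.0) * t + 2.0;
  return 0.0;
}
static inline double keys_dw(double t) {
  double s = t < 0 ? -1.0 : 1.0;
  t = std::fabs(t);
  if (t < 1.0)  return s * ((4.5 * t - 5.0) * t);
  if (t < 2.0)  return s * ((-1.5 * t + 5.0) * t - 4.0);
  return 0.0;
}

// ---------------------------------------------------------------------------
// Forward convection: W(x) = sum_y V(y) k(x - u(y)),  u(y) = y + d(y).
// kernel: 0 = trilinear, 1 = tricubic (Keys a=-0.5).
// [[Rcpp::export]]
NumericVector cpp_convect(NumericVector V, NumericVector dx, NumericVector dy,
                          NumericVector dz, int kernel) {
  const int N = cube_dim(V);
  NumericVector W(V.size());
  W.attr("dim") = V.attr("dim");
  const double* v = V.begin();
  const double* px = dx.begin(); const double* py = dy.begin();
  const double* pz = dz.begin();
  double* w = W.begin();
  long idx = 0;
  for (int iz = 0; iz < N; ++iz)
  for (int iy = 0; iy < N; ++iy)
  for (int ix = 0; ix < N; ++ix, ++idx) {
    const double val = v[idx];
    if (val == 0.0) continue;
    const double ux = ix + px[idx], uy = iy + py[idx], uz = iz + pz[idx];
    if (kernel == 0) {
      const int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy),
                z0 = (int)std::floor(uz);
      const double fx = ux - x0, fy = uy - y0, fz = uz - z0;
      const double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy},
                   wz[2] = {1.0 - fz, fz};
      for (int c = 0; c < 2; ++c) { int zc = z0 + c;
        if (zc < 0 || zc >= N) continue;
        for (int b = 0; b < 2; ++b) { int yb = y0 + b;
          if (yb < 0 || yb >= N) continue;
          const double wyz = wy[b] * wz[c] * val;
          for (int a = 0; a < 2; ++a) { int xa = x0 + a;
            if (xa < 0 || xa >= N || wx[a] == 0.0) continue;
            w[xa + (long)N * (yb + (long)N * zc)] += wx[a] * wyz;
          }
        }
      }
    } else {
      const int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy),
                z0 = (int)std::floor(uz);
      double wx[4], wy[4], wz[4];
      for (int a = 0; a < 4; ++a) {
        wx[a] = keys_w(ux - (x0 - 1 + a));
        wy[a] = keys_w(uy - (y0 - 1 + a));
        wz[a] = keys_w(uz - (z0 - 1 + a));
      }
      for (int c = 0; c < 4; ++c) { int zc = z0 - 1 + c;
        if (zc < 0 || zc >= N) continue;
        for (int b = 0; b < 4; ++b) { int yb = y0 - 1 + b;
          if (yb < 0 || yb >= N) continue;
          const double wyz = wy[b] * wz[c] * val;
          for (int a = 0; a < 4; ++a) { int xa = x0 - 1 + a;
            if (xa < 0 || xa >= N) continue;
            w[xa + (long)N * (yb + (long)N * zc)] += wx[a] * wyz;
          }
        }
      }
    }
  }
  return W;
}

// Adjoint of convection.  Given gW = dE/dW, returns
//   gV(y)  = sum_x gW(x) k(x - u(y))                (gather at u(y))
//   gd(y)  = V(y) * d/du [ gather of gW at u(y) ]   (per component)
// [[Rcpp::export]]
List cpp_convect_adjoint(NumericVector gW, NumericVector dx, NumericVector dy,
                         NumericVector dz, NumericVector V, bool need_gv,
                         bool need_gd, int kernel) {
  const int N = cube_dim(gW);
  const double* g = gW.begin();
  const double* v = V.begin();
  const double* px = dx.begin(); const double* py = dy.begin();
  const double* pz = dz.begin();
  NumericVector gV, gdx, gdy, gdz;
  if (need_gv) { gV = NumericVector(gW.size()); gV.attr("dim") = gW.attr("dim"); }
  if (need_gd) {
    gdx = NumericVector(gW.size()); gdy = NumericVector(gW.size());
    gdz = NumericVector(gW.size());
  }
  long idx = 0;
  for (int iz = 0; iz < N; ++iz)
  for (int iy = 0; iy < N; ++iy)
  for (int ix = 0; ix < N; ++ix, ++idx) {
    const double val = v[idx];
    if (!need_gv && val == 0.0) continue;
    const double ux = ix + px[idx], uy = iy + py[idx], uz = iz + pz[idx];
    double acc = 0.0, accx = 0.0, accy = 0.0, accz = 0.0;
    if (kernel == 0) {
      const int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy),
                z0 = (int)std::floor(uz);
      const double fx = ux - x0, fy = uy - y0, fz = uz - z0;
      const double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy},
                   wz[2] = {1.0 - fz, fz};
      const double dwx[2] = {-1.0, 1.0};
      for (int c = 0; c < 2; ++c) { int zc = z0 + c;
        if (zc < 0 || zc >= N) continue;
        for (int b = 0; b < 2; ++b) { int yb = y0 + b;
          if (yb < 0 || yb >= N) continue;
          for (int a = 0; a < 2; ++a) { int xa = x0 + a;
            if (xa < 0 || xa >= N) continue;
            const double gv = g[xa + (long)N * (yb + (long)N * zc)];
            acc  += wx[a] * wy[b] * wz[c] * gv;
            if (need_gd) {
              accx += dwx[a] * wy[b] * wz[c] * gv;
              accy += wx[a] * dwx[b] * wz[c] * gv;
              accz += wx[a] * wy[b] * dwx[c] * gv;
            }
          }
        }
      }
    } else {
      const int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy),
                z0 = (int)std::floor(uz);
      double wx[4], wy[4], wz[4], dwx_[4], dwy_[4], dwz_[4];
      for (int a = 0; a < 4; ++a) {
        const double tx = ux - (x0 - 1 + a), ty = uy - (y0 - 1 + a),
                     tz = uz - (z0 - 1 + a);
        wx[a] = keys_w(tx); wy[a] = keys_w(ty); wz[a] = keys_w(tz);
        dwx_[a] = keys_dw(tx); dwy_[a] = keys_dw(ty); dwz_[a] = keys_dw(tz);
      }
      for (int c = 0; c < 4; ++c) { int zc = z0 - 1 + c;
        if (zc < 0 || zc >= N) continue;
        for (int b = 0; b < 4; ++b) { int yb = y0 - 1 + b;
          if (yb < 0 || yb >= N) continue;
          for (int a = 0; a < 4; ++a) { int xa = x0 - 1 + a;
            if (xa < 0 || xa >= N) continue;
            const double gv = g[xa + (long)N * (yb + (long)N * zc)];
            acc  += wx[a] * wy[b] * wz[c] * gv;
            if (need_gd) {
              accx += dwx_[a] * wy[b] * wz[c] * gv;
              accy += wx[a] * dwy_[b] * wz[c] * gv;
              accz += wx[a] * wy[b] * dwz_[c] * gv;
            }
          }
        }
      }
    }
    if (need_gv) gV[idx] = acc;
    if (need_gd) {
      gdx[idx] = val * accx; gdy[idx] = val * accy; gdz[idx] = val * accz;
    }
  }
  List out;
  if (need_gv) out["gV"] = gV;
  if (need_gd) { out["gdx"] = gdx; out["gdy"] = gdy; out["gdz"] = gdz; }
  return out;
}

// Trilinear gather from a cubic grid with zero outside; core of projection.
static inline double tri_read(const double* w, int N, double x, double y,
                              double z) {
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
  if (x0 >= 0 && x0 < N - 1 && y0 >= 0 && y0 < N - 1 && z0 >= 0 &&
      z0 < N - 1) {  // interior fast path: all 8 taps in bounds
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const double* p = w + x0 + (long)N * (y0 + (long)N * z0);
    const long sy = N, sz = (long)N * N;
    const double c00 = p[0] + fx * (p[1] - p[0]);
    const double c10 = p[sy] + fx * (p[sy + 1] - p[sy]);
    const double c01 = p[sz] + fx * (p[sz + 1] - p[sz]);
    const double c11 = p[sz + sy] + fx * (p[sz + sy + 1] - p[sz + sy]);
    const double c0 = c00 + fy * (c10 - c00);
    const double c1 = c01 + fy * (c11 - c01);
    return c0 + fz * (c1 - c0);
  }
  if (x0 < -1 || x0 >= N || y0 < -1 || y0 >= N || z0 < -1 || z0 >= N)
    return 0.0;
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  const double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy},
               wz[2] = {1.0 - fz, fz};
  for (int c = 0; c < 2; ++c) { int zc = z0 + c;
    if (zc < 0 || zc >= N || wz[c] == 0.0) continue;
    for (int b = 0; b < 2; ++b) { int yb = y0 + b;
      if (yb < 0 || yb >= N || wy[b] == 0.0) continue;
      const double wyz = wy[b] * wz[c];
      for (int a = 0; a < 2; ++a) { int xa = x0 + a;
        if (xa < 0 || xa >= N || wx[a] == 0.0) continue;
        acc += wx[a] * wyz * w[xa + (long)N * (yb + (long)N * zc)];
      }
    }
  }
  return acc;
}

// Projection: image(ix,iy) = sum_iz W( R^T (m - c) + c ),
// m = (ix - sx, iy - sy, iz); R maps canonical -> microscope frame,
// (sx, sy) the in-plane shift in pixels; out-of-grid samples read 0.
// [[Rcpp::export]]
NumericMatrix cpp_project(NumericVector W, NumericMatrix R, double sx,
                          double sy) {
  const int N = cube_dim(W);
  const double c = N / 2;
  NumericMatrix img(N, N);
  const double* w = W.begin();
  // canonical-frame step per unit microscope z: R^T e_z = row 3 of R
  const double ezx = R(2, 0), ezy = R(2, 1), ezz = R(2, 2);
  for (int iy = 0; iy < N; ++iy) {
    const double my = iy - sy - c;
    for (int ix = 0; ix < N; ++ix) {
      const double mx = ix - sx - c;
      // canonical coords at iz = 0: R^T (mx, my, -c) + c
      double px = R(0, 0) * mx + R(1, 0) * my + R(2, 0) * (-c) + c;
      double py = R(0, 1) * mx + R(1, 1) * my + R(2, 1) * (-c) + c;
      double pz = R(0, 2) * mx + R(1, 2) * my + R(2, 2) * (-c) + c;
      double acc = 0.0;
      for (int iz = 0; iz < N; ++iz) {
        acc += tri_read(w, N, px, py, pz);
        px += ezx; py += ezy; pz += ezz;
      }
      img(ix, iy) = acc;
    }
  }
  return img;
}

// Adjoint of cpp_project: splat g(ix,iy) along the same sample points.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericMatrix g, NumericMatrix R, double sx,
                              double sy, int N) {
  const double c = N / 2;
  NumericVector W((long)N * N * N);
  W.attr("dim") = IntegerVector::create(N, N, N);
  double* w = W.begin();
  const double ezx = R(2, 0), ezy = R(2, 1), ezz = R(2, 2);
  for (int iy = 0; iy < N; ++iy) {
    const double my = iy - sy - c;
    for (int ix = 0; ix < N; ++ix) {
      const double val = g(ix, iy);
      if (val == 0.0) continue;
      const double mx = ix - sx - c;
      double px = R(0, 0) * mx + R(1, 0) * my + R(2, 0) * (-c) + c;
      double py = R(0, 1) * mx + R(1, 1) * my + R(2, 1) * (-c) + c;
      double pz = R(0, 2) * mx + R(1, 2) * my + R(2, 2) * (-c) + c;
      for (int iz = 0; iz < N; ++iz) {
        const int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
                  z0 = (int)std::floor(pz);
        if (x0 >= 0 && x0 < N - 1 && y0 >= 0 && y0 < N - 1 && z0 >= 0 &&
            z0 < N - 1) {  // interior fast path
          const double fx = px - x0, fy = py - y0, fz = pz - z0;
          double* p = w + x0 + (long)N * (y0 + (long)N * z0);
          const long sy = N, sz = (long)N * N;
          const double wz0 = val * (1.0 - fz), wz1 = val * fz;
          const double a00 = wz0 * (1.0 - fy), a10 = wz0 * fy;
          const double a01 = wz1 * (1.0 - fy), a11 = wz1 * fy;
          p[0]          += a00 * (1.0 - fx); p[1]          += a00 * fx;
          p[sy]         += a10 * (1.0 - fx); p[sy + 1]     += a10 * fx;
          p[sz]         += a01 * (1.0 - fx); p[sz + 1]     += a01 * fx;
          p[sz + sy]    += a11 * (1.0 - fx); p[sz + sy + 1] += a11 * fx;
        } else if (x0 >= -1 && x0 < N && y0 >= -1 && y0 < N && z0 >= -1 && z0 < N) {
          const double fx = px - x0, fy = py - y0, fz = pz - z0;
          const double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy},
                       wz[2] = {1.0 - fz, fz};
          for (int cc = 0; cc < 2; ++cc) { int zc = z0 + cc;
            if (zc < 0 || zc >= N || wz[cc] == 0.0) continue;
            for (int b = 0; b < 2; ++b) { int yb = y0 + b;
              if (yb < 0 || yb >= N || wy[b] == 0.0) continue;
              const double wyz = wy[b] * wz[cc] * val;
              for (int a = 0; a < 2; ++a) { int xa = x0 + a;
                if (xa < 0 || xa >= N || wx[a] == 0.0) continue;
                w[xa + (long)N * (yb + (long)N * zc)] += wx[a] * wyz;
              }
            }
          }
        }
        px += ezx; py += ezy; pz += ezz;
      }
    }
  }
  return W;
}

// Fused convect-then-project: never returns the convected map W_i.
// [[Rcpp::export]]
NumericMatrix cpp_convect_project(NumericVector V, NumericVector dx,
                                  NumericVector dy, NumericVector dz,
                                  NumericMatrix R, double sx, double sy,
                                  int kernel) {
  NumericVector W = cpp_convect(V, dx, dy, dz, kernel);
  return cpp_project(W, R, sx, sy);
}

// Rotated resample (gather): out(x) = V( R^T (x - c) + c ).
// [[Rcpp::export]]
NumericVector cpp_rotate_volume(NumericVector V, NumericMatrix R) {
  const int N = cube_dim(V);
  const double c = N / 2;
  NumericVector out(V.size());
  out.attr("dim") = V.attr("dim");
  const double* v = V.begin();
  long idx = 0;
  for (int iz = 0; iz < N; ++iz)
  for (int iy = 0; iy < N; ++iy)
  for (int ix = 0; ix < N; ++ix, ++idx) {
    const double mx = ix - c, my = iy - c, mz = iz - c;
    const double px = R(0, 0) * mx + R(1, 0) * my + R(2, 0) * mz + c;
    const double py = R(0, 1) * mx + R(1, 1) * my + R(2, 1) * mz + c;
    const double pz = R(0, 2) * mx + R(1, 2) * my + R(2, 2) * mz + c;
    out[idx] = tri_read(v, N, px, py, pz);
  }
  return out;
}

// Fast symmetric 3x3 eigendecomposition (Jacobi sweeps) for the SVD of the
// small, well-conditioned deformation gradients (A close to a rotation).
// Falls back to Armadillo's LAPACK SVD when A is nearly singular.
static inline bool svd3(const arma::mat33& A, arma::mat33& U, arma::vec3& s,
                        arma::mat33& V) {
  arma::mat33 B = A.t() * A;        // symmetric positive semi-definite
  arma::mat33 Q; Q.eye();
  for (int sweep = 0; sweep < 12; ++sweep) {
    double off = std::fabs(B(0, 1)) + std::fabs(B(0, 2)) +
                 std::fabs(B(1, 2));
    if (off < 1e-14 * (std::fabs(B(0, 0)) + std::fabs(B(1, 1)) +
                       std::fabs(B(2, 2)) + 1e-300)) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(B(p, q)) < 1e-300) continue;
        const double tau = (B(q, q) - B(p, p)) / (2.0 * B(p, q));
        const double t = (tau >= 0 ? 1.0 : -1.0) /
          (std::fabs(tau) + std::sqrt(1.0 + tau * tau));
        const double c = 1.0 / std::sqrt(1.0 + t * t), sn = t * c;
        arma::mat33 J; J.eye();
        J(p, p) = c; J(q, q) = c; J(p, q) = sn; J(q, p) = -sn;
        B = J.t() * B * J;
        Q = Q * J;
      }
  }
  arma::vec3 ev = {B(0, 0), B(1, 1), B(2, 2)};
  // sort descending
  arma::uvec ord = arma::sort_index(ev, "descend");
  for (int k = 0; k < 3; ++k) {
    s(k) = std::sqrt(std::max(ev(ord(k)), 0.0));
    V.col(k) = Q.col(ord(k));
  }
  if (s(2) < 1e-6) return false;    // nearly singular: caller falls back
  for (int k = 0; k < 3; ++k) U.col(k) = A * V.col(k) / s(k);
  return true;
}

// ---------------------------------------------------------------------------
// Local-rigidity energy over a batch of per-vertex displacement fields.
// For cell j with rest vertices X0..X3 and displacements D0..D3, the affine
// deformation u(x) = A x + b is solved from the 4 vertex correspondences:
// A = I + Ed * Er^{-1} with edge matrices Er (rest) and Ed (displacement).
// E = sum_b sum_j w_j sum_l (s_l(A) - 1)^2.
// disp: cube n_v x 3 x B;  cells: n_c x 4, 0-based;  returns E, per-cell
// nonrigidity (summed over batch) and optionally dE/ddisp.
// [[Rcpp::export]]
List cpp_rigidity(arma::mat verts, arma::imat cells, arma::vec weights,
                  arma::cube disp, bool need_grad) {
  const unsigned n_c = cells.n_rows, B = disp.n_slices;
  arma::cube grad;
  if (need_grad) grad = arma::zeros<arma::cube>(disp.n_rows, 3, B);
  // precompute inverse rest edge matrices
  std::vector<arma::mat33> erinv(n_c);
  for (unsigned j = 0; j < n_c; ++j) {
    arma::mat33 Er;
    for (int k = 0; k < 3; ++k)
      Er.col(k) = (verts.row(cells(j, k + 1)) - verts.row(cells(j, 0))).t();
    if (std::fabs(arma::det(Er)) < 1e-12)
      stop("degenerate mesh cell (zero volume)");
    erinv[j] = arma::inv(Er);
  }
  double E = 0.0;
  arma::vec cell_nr = arma::zeros<arma::vec>(n_c);
  for (unsigned b = 0; b < B; ++b) {
    for (unsigned j = 0; j < n_c; ++j) {
      arma::mat33 Ed;
      for (int k = 0; k < 3; ++k)
        Ed.col(k) = (disp.slice(b).row(cells(j, k + 1)) -
                     disp.slice(b).row(cells(j, 0))).t();
      arma::mat33 A = arma::eye(3, 3) + Ed * erinv[j];
      arma::mat33 U, Vm;
      arma::vec3 s;
      if (!svd3(A, U, s, Vm)) {
        arma::mat Uf, Vf; arma::vec sf;
        if (!arma::svd(Uf, sf, Vf, arma::mat(A)))
          stop("SVD failed in rigidity energy");
        U = Uf; s = sf; Vm = Vf;
      }
      double nr = 0.0;
      for (int l = 0; l < 3; ++l) nr += (s(l) - 1.0) * (s(l) - 1.0);
      cell_nr(j) += nr;
      E += weights(j) * nr;
      if (need_grad) {
        // dE/dA = 2 w U diag(s-1) V^T ; chain through A = I + Ed Er^-1
        arma::vec3 sm = 2.0 * weights(j) * (s - 1.0);
        arma::mat33 dA = U * arma::diagmat(sm) * Vm.t();
        arma::mat33 dEd = dA * erinv[j].t();
        for (int k = 0; k < 3; ++k) {
          for (int d = 0; d < 3; ++d) {
            grad(cells(j, k + 1), d, b) += dEd(d, k);
            grad(cells(j, 0), d, b)     -= dEd(d, k);
          }
        }
      }
    }
  }
  List out = List::create(Named("energy") = E,
                          Named("cell_nonrigidity") = cell_nr);
  if (need_grad) out["grad"] = grad;
  return out;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// separable 1-D passes; input: 0/1 grid, output: squared distance in voxels
// to the nearest nonzero voxel (Inf if none).
static void edt_1d(std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(NumericVector mask) {
  IntegerVector dm = mask.attr("dim");
  if (dm.size() != 3) stop("expected a 3-D array");
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  NumericVector D(mask.size());
  D.attr("dim") = mask.attr("dim");
  const double BIG = 1e30;
  for (long i = 0; i < mask.size(); ++i) D[i] = mask[i] > 0.5 ? 0.0 : BIG;
  std::vector<double> f(std::max(nx, std::max(ny, nz))),
                      d(std::max(nx, std::max(ny, nz)));
  // pass along x
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) f[ix] = D[ix + (long)nx * (iy + (long)ny * iz)];
      edt_1d(f, d, nx);
      for (int ix = 0; ix < nx; ++ix) D[ix + (long)nx * (iy + (long)ny * iz)] = d[ix];
    }
  // pass along y
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy) f[iy] = D[ix + (long)nx * (iy + (long)ny * iz)];
      edt_1d(f, d, ny);
      for (int iy = 0; iy < ny; ++iy) D[ix + (long)nx * (iy + (long)ny * iz)] = d[iy];
    }
  // pass along z
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iz = 0; iz < nz; ++iz) f[iz] = D[ix + (long)nx * (iy + (long)ny * iz)];
      edt_1d(f, d, nz);
      for (int iz = 0; iz < nz; ++iz) D[ix + (long)nx * (iy + (long)ny * iz)] = d[iz];
    }
  return D;
}

// ---------------------------------------------------------------------------
// Sparse-displacement variants: only voxels listed in idx (0-based linear
// indices) carry a displacement; all others contribute identically (splat at
// their own center, which is exact for both kernels).  This is the training
// fast path, since the mesh covers only part of the grid.

// [[Rcpp::export]]
NumericVector cpp_convect_sparse(NumericVector V, IntegerVector idx,
                                 NumericMatrix d, int kernel) {
  const int N = cube_dim(V);
  NumericVector W = clone(V);
  double* w = W.begin();
  const double* v = V.begin();
  const int n = idx.size();
  for (int t = 0; t < n; ++t) {
    const long id = idx[t];
    const double val = v[id];
    if (val == 0.0) continue;
    w[id] -= val;
    const int ix = id % N, iy = (id / N) % N, iz = id / ((long)N * N);
    const double ux = ix + d(t, 0), uy = iy + d(t, 1), uz = iz + d(t, 2);
    if (kernel == 0) {
      const int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy),
                z0 = (int)std::floor(uz);
      const double fx = ux - x0, fy = uy - y0, fz = uz - z0;
      const double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy},
                   wz[2] = {1.0 - fz, fz};
      for (int c = 0; c < 2; ++c) { int zc = z0 + c;
        if (zc < 0 || zc >= N) continue;
        for (int b = 0; b < 2; ++b) { int yb = y0 + b;
          if (yb < 0 || yb >= N) continue;
          const double wyz = wy[b] * wz[c] * val;
          for (int a = 0; a < 2; ++a) { int xa = x0 + a;
            if (xa < 0 || xa >= N || wx[a] == 0.0) continue;
            w[xa + (long)N * (yb + (long)N * zc)] += wx[a] * wyz;
          }
        }
      }
    } else {
      const int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy),
                z0 = (int)std::floor(uz);
      double wx[4], wy[4], wz[4];
      for (int a = 0; a < 4; ++a) {
        wx[a] = keys_w(ux - (x0 - 1 + a));
        wy[a] = keys_w(uy - (y0 - 1 + a));
        wz[a] = keys_w(uz - (z0 - 1 + a));
      }
      for (int c = 0; c < 4; ++c) { int zc = z0 - 1 + c;
        if (zc < 0 || zc >= N) continue;
        for (int b = 0; b < 4; ++b) { int yb = y0 - 1 + b;
          if (yb < 0 || yb >= N) continue;
          const double wyz = wy[b] * wz[c] * val;
          for (int a = 0; a < 4; ++a) { int xa = x0 - 1 + a;
            if (xa < 0 || xa >= N) continue;
            w[xa + (long)N * (yb + (long)N * zc)] += wx[a] * wyz;
          }
        }
      }
    }
  }
  return W;
}

// Adjoint for the sparse path: gV (optional, full grid) and gd (n x 3).
// [[Rcpp::export]]
List cpp_convect_adjoint_sparse(NumericVector gW, IntegerVector idx,
                                NumericMatrix d, NumericVector V,
                                bool need_gv, bool need_gd, int kernel) {
  const int N = cube_dim(gW);
  const double* g = gW.begin();
  const double* v = V.begin();
  const int n = idx.size();
  NumericVector gV;
  NumericMatrix gd;
  if (need_gv) gV = clone(gW);          // unlisted voxels: gather at center
  if (need_gd) gd = NumericMatrix(n, 3);
  for (int t = 0; t < n; ++t) {
    const long id = idx[t];
    const double val = v[id];
    if (!need_gv && val == 0.0) continue;
    const int ix = id % N, iy = (id / N) % N, iz = id / ((long)N * N);
    const double ux = ix + d(t, 0), uy = iy + d(t, 1), uz = iz + d(t, 2);
    double acc = 0.0, accx = 0.0, accy = 0.0, accz = 0.0;
    if (kernel == 0) {
      const int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy),
                z0 = (int)std::floor(uz);
      const double fx = ux - x0, fy = uy - y0, fz = uz - z0;
      const double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy},
                   wz[2] = {1.0 - fz, fz};
      const double dwx[2] = {-1.0, 1.0};
      for (int c = 0; c < 2; ++c) { int zc = z0 + c;
        if (zc < 0 || zc >= N) continue;
        for (int b = 0; b < 2; ++b) { int yb = y0 + b;
          if (yb < 0 || yb >= N) continue;
          for (int a = 0; a < 2; ++a) { int xa = x0 + a;
            if (xa < 0 || xa >= N) continue;
            const double gv = g[xa + (long)N * (yb + (long)N * zc)];
            acc  += wx[a] * wy[b] * wz[c] * gv;
            if (need_gd) {
              accx += dwx[a] * wy[b] * wz[c] * gv;
              accy += wx[a] * dwx[b] * wz[c] * gv;
              accz += wx[a] * wy[b] * dwx[c] * gv;
            }
          }
        }
      }
    } else {
      const int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy),
                z0 = (int)std::floor(uz);
      double wx[4], wy[4], wz[4], dwxa[4], dwya[4], dwza[4];
      for (int a = 0; a < 4; ++a) {
        const double tx = ux - (x0 - 1 + a), ty = uy - (y0 - 1 + a),
                     tz = uz - (z0 - 1 + a);
        wx[a] = keys_w(tx); wy[a] = keys_w(ty); wz[a] = keys_w(tz);
        dwxa[a] = keys_dw(tx); dwya[a] = keys_dw(ty); dwza[a] = keys_dw(tz);
      }
      for (int c = 0; c < 4; ++c) { int zc = z0 - 1 + c;
        if (zc < 0 || zc >= N) continue;
        for (int b = 0; b < 4; ++b) { int yb = y0 - 1 + b;
          if (yb < 0 || yb >= N) continue;
          for (int a = 0; a < 4; ++a) { int xa = x0 - 1 + a;
            if (xa < 0 || xa >= N) continue;
            const double gv = g[xa + (long)N * (yb + (long)N * zc)];
            acc  += wx[a] * wy[b] * wz[c] * gv;
            if (need_gd) {
              accx += dwxa[a] * wy[b] * wz[c] * gv;
              accy += wx[a] * dwya[b] * wz[c] * gv;
              accz += wx[a] * wy[b] * dwza[c] * gv;
            }
          }
        }
      }
    }
    if (need_gv) gV[id] = acc;
    if (need_gd) {
      gd(t, 0) = val * accx; gd(t, 1) = val * accy; gd(t, 2) = val * accz;
    }
  }
  List out;
  if (need_gv) out["gV"] = gV;
  if (need_gd) out["gd"] = gd;
  return out;
}

// Fused sparse convect + project (training fast path; W never leaves C++).
// [[Rcpp::export]]
NumericMatrix cpp_predict_sparse(NumericVector V, IntegerVector idx,
                                 NumericMatrix d, NumericMatrix R, double sx,
                                 double sy, int kernel) {
  NumericVector W = cpp_convect_sparse(V, idx, d, kernel);
  return cpp_project(W, R, sx, sy);
}

// Keys tricubic gather (zero outside); high-fidelity projection variant.
static inline double cubic_read(const double* w, int N, double x, double y,
                                double z) {
  const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
  if (x0 < -2 || x0 > N || y0 < -2 || y0 > N || z0 < -2 || z0 > N)
    return 0.0;
  double wx[4], wy[4], wz[4];
  for (int a = 0; a < 4; ++a) {
    wx[a] = keys_w(x - (x0 - 1 + a));
    wy[a] = keys_w(y - (y0 - 1 + a));
    wz[a] = keys_w(z - (z0 - 1 + a));
  }
  double acc = 0.0;
  for (int c = 0; c < 4; ++c) { int zc = z0 - 1 + c;
    if (zc < 0 || zc >= N) continue;
    for (int b = 0; b < 4; ++b) { int yb = y0 - 1 + b;
      if (yb < 0 || yb >= N) continue;
      const double wyz = wy[b] * wz[c];
      if (wyz == 0.0) continue;
      for (int a = 0; a < 4; ++a) { int xa = x0 - 1 + a;
        if (xa < 0 || xa >= N) continue;
        acc += wx[a] * wyz * w[xa + (long)N * (yb + (long)N * zc)];
      }
    }
  }
  return acc;
}

// Projection with a tricubic (Keys) volume interpolant; used where spectral
// fidelity matters more than speed or adjoint pairing.
// [[Rcpp::export]]
NumericMatrix cpp_project_cubic(NumericVector W, NumericMatrix R, double sx,
                                double sy) {
  const int N = cube_dim(W);
  const double c = N / 2;
  NumericMatrix img(N, N);
  const double* w = W.begin();
  const double ezx = R(2, 0), ezy = R(2, 1), ezz = R(2, 2);
  for (int iy = 0; iy < N; ++iy) {
    const double my = iy - sy - c;
    for (int ix = 0; ix < N; ++ix) {
      const double mx = ix - sx - c;
      double px = R(0, 0) * mx + R(1, 0) * my + R(2, 0) * (-c) + c;
      double py = R(0, 1) * mx + R(1, 1) * my + R(2, 1) * (-c) + c;
      double pz = R(0, 2) * mx + R(1, 2) * my + R(2, 2) * (-c) + c;
      double acc = 0.0;
      for (int iz = 0; iz < N; ++iz) {
        acc += cubic_read(w, N, px, py, pz);
        px += ezx; py += ezy; pz += ezz;
      }
      img(ix, iy) = acc;
    }
  }
  return img;
}

// Convection correction only: Delta(x) such that W = V + Delta.  Splats the
// listed voxels and subtracts their resting contribution; all other voxels
// cancel exactly.  Lets callers cache the projection of V across many flow
// evaluations (projection is linear).
// [[Rcpp::export]]
NumericVector cpp_delta_splat(NumericVector V, IntegerVector idx,
                              NumericMatrix d, int kernel) {
  const int N = cube_dim(V);
  NumericVector D((long)N * N * N);
  D.attr("dim") = V.attr("dim");
  double* w = D.begin();
  const double* v = V.begin();
  const int n = idx.size();
  for (int t = 0; t < n; ++t) {
    const long id = idx[t];
    const double val = v[id];
    if (val == 0.0) continue;
    w[id] -= val;
    const int ix = id % N, iy = (id / N) % N, iz = id / ((long)N * N);
    const double ux = ix + d(t, 0), uy = iy + d(t, 1), uz = iz + d(t, 2);
    if (kernel == 0) {
      const int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy),
                z0 = (int)std::floor(uz);
      const double fx = ux - x0, fy = uy - y0, fz = uz - z0;
      const double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy},
                   wz[2] = {1.0 - fz, fz};
      for (int c = 0; c < 2; ++c) { int zc = z0 + c;
        if (zc < 0 || zc >= N) continue;
        for (int b = 0; b < 2; ++b) { int yb = y0 + b;
          if (yb < 0 || yb >= N) continue;
          const double wyz = wy[b] * wz[c] * val;
          for (int a = 0; a < 2; ++a) { int xa = x0 + a;
            if (xa < 0 || xa >= N || wx[a] == 0.0) continue;
            w[xa + (long)N * (yb + (long)N * zc)] += wx[a] * wyz;
          }
        }
      }
    } else {
      const int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy),
                z0 = (int)std::floor(uz);
      double wx[4], wy[4], wz[4];
      for (int a = 0; a < 4; ++a) {
        wx[a] = keys_w(ux - (x0 - 1 + a));
        wy[a] = keys_w(uy - (y0 - 1 + a));
        wz[a] = keys_w(uz - (z0 - 1 + a));
      }
      for (int c = 0; c < 4; ++c) { int zc = z0 - 1 + c;
        if (zc < 0 || zc >= N) continue;
        for (int b = 0; b < 4; ++b) { int yb = y0 - 1 + b;
          if (yb < 0 || yb >= N) continue;
          const double wyz = wy[b] * wz[c] * val;
          for (int a = 0; a < 4; ++a) { int xa = x0 - 1 + a;
            if (xa < 0 || xa >= N) continue;
            w[xa + (long)N * (yb + (long)N * zc)] += wx[a] * wyz;
          }
        }
      }
    }
  }
  return D;
}

// Projection of a volume supported inside the box [lo, hi] (inclusive,
// 0-based): samples whose canonical coordinates fall outside are skipped
// before the interpolation read.  Exact for such volumes; used to project
// sparse convection corrections cheaply.
// [[Rcpp::export]]
NumericMatrix cpp_project_box(NumericVector W, NumericMatrix R, double sx,
                              double sy, NumericVector lo, NumericVector hi) {
  const int N = cube_dim(W);
  const double c = N / 2;
  NumericMatrix img(N, N);
  const double* w = W.begin();
  const double ezx = R(2, 0), ezy = R(2, 1), ezz = R(2, 2);
  const double lx = lo[0], ly = lo[1], lz = lo[2];
  const double hx = hi[0], hy = hi[1], hz = hi[2];
  for (int iy = 0; iy < N; ++iy) {
    const double my = iy - sy - c;
    for (int ix = 0; ix < N; ++ix) {
      const double mx = ix - sx - c;
      double px = R(0, 0) * mx + R(1, 0) * my + R(2, 0) * (-c) + c;
      double py = R(0, 1) * mx + R(1, 1) * my + R(2, 1) * (-c) + c;
      double pz = R(0, 2) * mx + R(1, 2) * my + R(2, 2) * (-c) + c;
      double acc = 0.0;
      for (int iz = 0; iz < N; ++iz) {
        if (px >= lx && px <= hx && py >= ly && py <= hy && pz >= lz &&
            pz <= hz)
          acc += tri_read(w, N, px, py, pz);
        px += ezx; py += ezy; pz += ezz;
      }
      img(ix, iy) = acc;
    }
  }
  return img;
}

// Backprojection restricted to canonical coordinates inside [lo, hi]:
// samples splatting outside the box are skipped.  Exact whenever the caller
// only reads the result within the box (e.g. the convection adjoint of a
// mesh-supported flow).
// [[Rcpp::export]]
NumericVector cpp_backproject_box(NumericMatrix g, NumericMatrix R, double sx,
                                  double sy, int N, NumericVector lo,
                                  NumericVector hi) {
  const double c = N / 2;
  NumericVector W((long)N * N * N);
  W.attr("dim") = IntegerVector::create(N, N, N);
  double* w = W.begin();
  const double ezx = R(2, 0), ezy = R(2, 1), ezz = R(2, 2);
  const double lx = lo[0], ly = lo[1], lz = lo[2];
  const double hx = hi[0], hy = hi[1], hz = hi[2];
  for (int iy = 0; iy < N; ++iy) {
    const double my = iy - sy - c;
    for (int ix = 0; ix < N; ++ix) {
      const double val = g(ix, iy);
      if (val == 0.0) continue;
      const double mx = ix - sx - c;
      double px = R(0, 0) * mx + R(1, 0) * my + R(2, 0) * (-c) + c;
      double py = R(0, 1) * mx + R(1, 1) * my + R(2, 1) * (-c) + c;
      double pz = R(0, 2) * mx + R(1, 2) * my + R(2, 2) * (-c) + c;
      for (int iz = 0; iz < N; ++iz) {
        if (px >= lx && px <= hx && py >= ly && py <= hy && pz >= lz &&
            pz <= hz) {
          const int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
                    z0 = (int)std::floor(pz);
          if (x0 >= 0 && x0 < N - 1 && y0 >= 0 && y0 < N - 1 && z0 >= 0 &&
              z0 < N - 1) {
            const double fx = px - x0, fy = py - y0, fz = pz - z0;
            double* p = w + x0 + (long)N * (y0 + (long)N * z0);
            const long sy_ = N, sz_ = (long)N * N;
            const double wz0 = val * (1.0 - fz), wz1 = val * fz;
            const double a00 = wz0 * (1.0 - fy), a10 = wz0 * fy;
            const double a01 = wz1 * (1.0 - fy), a11 = wz1 * fy;
            p[0]           += a00 * (1.0 - fx); p[1]            += a00 * fx;
            p[sy_]         += a10 * (1.0 - fx); p[sy_ + 1]      += a10 * fx;
            p[sz_]         += a01 * (1.0 - fx); p[sz_ + 1]      += a01 * fx;
            p[sz_ + sy_]   += a11 * (1.0 - fx); p[sz_ + sy_ + 1] += a11 * fx;
          } else if (x0 >= -1 && x0 < N && y0 >= -1 && y0 < N && z0 >= -1 &&
                     z0 < N) {
            const double fx = px - x0, fy = py - y0, fz = pz - z0;
            const double wx[2] = {1.0 - fx, fx}, wy[2] = {1.0 - fy, fy},
                         wz[2] = {1.0 - fz, fz};
            for (int cc = 0; cc < 2; ++cc) { int zc = z0 + cc;
              if (zc < 0 || zc >= N || wz[cc] == 0.0) continue;
              for (int b = 0; b < 2; ++b) { int yb = y0 + b;
                if (yb < 0 || yb >= N || wy[b] == 0.0) continue;
                const double wyz = wy[b] * wz[cc] * val;
                for (int a = 0; a < 2; ++a) { int xa = x0 + a;
                  if (xa < 0 || xa >= N || wx[a] == 0.0) continue;
                  w[xa + (long)N * (yb + (long)N * zc)] += wx[a] * wyz;
                }
              }
            }
          }
        }
        px += ezx; py += ezy; pz += ezz;
      }
    }
  }
  return W;
}
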