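#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Greedy coincidence grouping: an event opens at the first unassigned hit
// and absorbs every hit within `window` of the opener.
// [[Rcpp::export]]
IntegerVector cpp_group_coincidences(NumericVector t, double window) {
  int n = t.size();
  IntegerVector id(n);
  double opener = 0;
  int cur = 0;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && t[i] < t[i - 1]) stop("hits must be sorted by time");
    if (cur == 0 || t[i] - opener > window) {
      ++cur;
      opener = t[i];
    }
    id[i] = cur;
  }
  return id;
}

static inline double cone_t(double dx, double dy, double dz,
                            double ax, double ay, double az,
                            double theta, double a, double sigma,
                            double nsig, bool &inside) {
  double d2 = dx * dx + dy * dy + dz * dz;
  inside = false;
  double solid, Theta;
  if (d2 <= 0.0) {
    solid = 2.0 * M_PI;     // voxel coincident with scatter pixel: cap
    Theta = theta;          // treat as on-cone
  } else {
    double d = std::sqrt(d2);
    double c = (dx * ax + dy * ay + dz * az) / d;
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    Theta = std::acos(c);
    if (std::fabs(Theta - theta) > nsig * sigma) return 0.0;
    solid = 2.0 * M_PI * (1.0 - d / std::sqrt(d2 + a * a));
  }
  inside = true;
  double z = (Theta - theta) / sigma;
  return solid * std::exp(-0.5 * z * z) / std::sin(theta);
}

// Sparse cone system matrix rows t_kj (triplets, 1-based indices).
// axis points from the absorption position through the scatter position
// (the cone of possible incidence directions opens around it).
// [[Rcpp::export]]
List cpp_cone_tkj(NumericMatrix scatter, NumericMatrix axis,
                  NumericVector theta, NumericMatrix vox,
                  double a, double sigma, double nsig) {
  int K = scatter.nrow(), J = vox.nrow();
  std::vector<int> ii, jj;
  std::vector<double> xx;
  for (int k = 0; k < K; ++k) {
    double sx = scatter(k, 0), sy = scatter(k, 1), sz = scatter(k, 2);
    double ax = axis(k, 0), ay = axis(k, 1), az = axis(k, 2);
    for (int j = 0; j < J; ++j) {
      bool inside;
      double t = cone_t(vox(j, 0) - sx, vox(j, 1) - sy, vox(j, 2) - sz,
                        ax, ay, az, theta[k], a, sigma, nsig, inside);
      if (inside && t > 0) {
        ii.push_back(k + 1);
        jj.push_back(j + 1);
        xx.push_back(t);
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["x"] = wrap(xx));
}

// List-mode MLEM with the cone system matrix built once (CSR) and the
// per-angle sensitivity applied inside the event sum:
//   lambda_j <- lambda_j * sum_k t_kj / (s_j^{l_k} * sum_j' t_kj' lambda_j')
// Events whose system-matrix row is empty are dropped (reported in `kept`).
// Returns lambda and the log-likelihood trace
//   LL(lambda^{n-1}) = sum_k log(denom_k) - sum_j sbar_j lambda_j
// (sbar = mean sensitivity over event angles), evaluated at the image the
// iteration starts from.
// [[Rcpp::export]]
List cpp_compton_mlem(NumericMatrix scatter, NumericMatrix axis,
                      NumericVector theta, IntegerVector angle,
                      NumericMatrix vox, double a, double sigma,
                      NumericMatrix sens, int n_iter, double nsig) {
  int K = scatter.nrow(), J = vox.nrow();
  if (n_iter < 1) stop("n_iter must be >= 1");
  if (sens.nrow() != J) stop("sensitivity rows must match voxel count");
  int L = sens.ncol();
  for (int k = 0; k < K; ++k)
    if (angle[k] < 0 || angle[k] >= L) stop("event angle without sensitivity layer");

  // column-contiguous voxel copies for the hot loop
  std::vector<double> vx(J), vy(J), vz(J);
  for (int j = 0; j < J; ++j) {
    vx[j] = vox(j, 0); vy[j] = vox(j, 1); vz[j] = vox(j, 2);
  }
  std::vector<size_t> rowptr(K + 1, 0);
  std::vector<int> colind;
  std::vector<double> val;
  colind.reserve((size_t)K * 64);
  val.reserve((size_t)K * 64);
  for (int k = 0; k < K; ++k) {
    double sx = scatter(k, 0), sy = scatter(k, 1), sz = scatter(k, 2);
    double ax = axis(k, 0), ay = axis(k, 1), az = axis(k, 2);
    double th = theta[k];
    double th_lo = th - nsig * sigma, th_hi = th + nsig * sigma;
    double c_hi = std::cos(th_lo < 0 ? 0 : th_lo);       // upper cos bound
    double c_lo = std::cos(th_hi > M_PI ? M_PI : th_hi); // lower cos bound
    double inv_sin = 1.0 / std::sin(th);
    for (int j = 0; j < J; ++j) {
      double dx = vx[j] - sx, dy = vy[j] - sy, dz = vz[j] - sz;
      double d2 = dx * dx + dy * dy + dz * dz;
      double t;
      if (d2 <= 0.0) {
        t = 2.0 * M_PI * inv_sin;   // solid angle capped, on-cone Gaussian
      } else {
        double d = std::sqrt(d2);
        double c = (dx * ax + dy * ay + dz * az) / d;
        if (c < c_lo || c > c_hi) continue;   // outside the nsig shell
        if (c > 1.0) c = 1.0;
        if (c < -1.0) c = -1.0;
        double z = (std::acos(c) - th) / sigma;
        t = 2.0 * M_PI * (1.0 - d / std::sqrt(d2 + a * a)) *
          std::exp(-0.5 * z * z) * inv_sin;
      }
      if (t > 0) { colind.push_back(j); val.push_back(t); }
    }
    rowptr[k + 1] = colind.size();
  }
  size_t nnz = rowptr[K];

  LogicalVector kept(K);
  for (int k = 0; k < K; ++k) kept[k] = rowptr[k + 1] > rowptr[k];

  std::vector<double> lambda(J, 1.0), acc(J), sbar(J, 0.0);
  // mean total sensitivity weight for the log-likelihood trace
  {
    std::vector<double> w(L, 0.0);
    int kc = 0;
    for (int k = 0; k < K; ++k) if (kept[k]) { w[angle[k]] += 1.0; ++kc; }
    if (kc > 0)
      for (int j = 0; j < J; ++j) {
        double s = 0;
        for (int l = 0; l < L; ++l) s += w[l] * sens(j, l);
        sbar[j] = s / kc;
      }
  }

  NumericVector loglik(n_iter);
  for (int it = 0; it < n_iter; ++it) {
    std::fill(acc.begin(), acc.end(), 0.0);
    double ll = 0.0, pen = 0.0;
    for (int j = 0; j < J; ++j) pen += sbar[j] * lambda[j];
    for (int k = 0; k < K; ++k) {
      if (!kept[k]) continue;
      double denom = 0.0;
      for (size_t p = rowptr[k]; p < rowptr[k + 1]; ++p)
        denom += val[p] * lambda[colind[p]];
      if (denom <= 0.0) continue;
      ll += std::log(denom);
      int l = angle[k];
      for (size_t p = rowptr[k]; p < rowptr[k + 1]; ++p) {
        int j = colind[p];
        acc[j] += val[p] / (denom * sens(j, l));
      }
    }
    for (int j = 0; j < J; ++j) lambda[j] *= acc[j];
    loglik[it] = ll - pen;
  }
  return List::create(_["lambda"] = wrap(lambda), _["loglik"] = loglik,
                      _["kept"] = kept, _["nnz"] = (double)nnz);
}

// Pinhole system matrix c_ij = Omega_ij * p_int, gated by the aperture.
// One pose per (angle, camera); detector bins are flattened as
// bin = pose * npix^2 + iy * npix + ix (+1 for R).  For every voxel the
// aperture is projected onto the rear plane so that only the handful of
// candidate pixels behind the hole are tested.
// [[Rcpp::export]]
List cpp_pinhole_cij(NumericMatrix fc, NumericMatrix ex, NumericMatrix ey,
                     NumericMatrix nout, NumericMatrix vox,
                     int npix, double pitch, double hole_hw, double sep,
                     double slab_cm, double mu_lin) {
  int P = fc.nrow(), J = vox.nrow();
  double half = (npix - 1) / 2.0;
  std::vector<int> ii, jj;
  std::vector<double> xx;
  double area = pitch * pitch;
  for (int p = 0; p < P; ++p) {
    double cx = fc(p, 0), cy = fc(p, 1), cz = fc(p, 2);
    double exx = ex(p, 0), exy = ex(p, 1), exz = ex(p, 2);
    double eyx = ey(p, 0), eyy = ey(p, 1), eyz = ey(p, 2);
    double nx = nout(p, 0), ny = nout(p, 1), nz = nout(p, 2);
    for (int j = 0; j < J; ++j) {
      double rx = vox(j, 0) - cx, ry = vox(j, 1) - cy, rz = vox(j, 2) - cz;
      double wV = rx * nx + ry * ny + rz * nz;       // along n_out, < 0 in FOV
      if (wV >= -1e-9) continue;                     // behind or inside camera
      double uV = rx * exx + ry * exy + rz * exz;
      double vV = rx * eyx + ry * eyy + rz * eyz;
      double f = -wV / (sep - wV);                   // front-plane fraction
      // rear-pixel window whose rays pass the hole
      double u_lo = (-hole_hw - uV * (1.0 - f)) / f;
      double u_hi = ( hole_hw - uV * (1.0 - f)) / f;
      double v_lo = (-hole_hw - vV * (1.0 - f)) / f;
      double v_hi = ( hole_hw - vV * (1.0 - f)) / f;
      int ix0 = (int)std::floor(u_lo / pitch + half);
      int ix1 = (int)std::ceil(u_hi / pitch + half);
      int iy0 = (int)std::floor(v_lo / pitch + half);
      int iy1 = (int)std::ceil(v_hi / pitch + half);
      if (ix0 < 0) ix0 = 0;
      if (iy0 < 0) iy0 = 0;
      if (ix1 > npix - 1) ix1 = npix - 1;
      if (iy1 > npix - 1) iy1 = npix - 1;
      for (int iy = iy0; iy <= iy1; ++iy) {
        double vp = (iy - half) * pitch;
        double v0 = vV + f * (vp - vV);
        if (std::fabs(v0) > hole_hw) continue;
        for (int ix = ix0; ix <= ix1; ++ix) {
          double up = (ix - half) * pitch;
          double u0 = uV + f * (up - uV);
          if (std::fabs(u0) > hole_hw) continue;
          // rear pixel center in world
          double qx = cx + sep * nx + up * exx + vp * eyx;
          double qy = cy + sep * ny + up * exy + vp * eyy;
          double qz = cz + sep * nz + up * exz + vp * eyz;
          double dx = qx - vox(j, 0), dy = qy - vox(j, 1), dz = qz - vox(j, 2);
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 <= 0.0) stop("voxel coincident with a detector pixel");
          double r = std::sqrt(r2);
          double cosa = (sep - wV) / r;
          if (cosa > 1.0) cosa = 1.0;
          double omega = area * cosa / r2;
          double pint = 1.0 - std::exp(-mu_lin * slab_cm / cosa);
          ii.push_back(p * npix * npix + iy * npix + ix + 1);
          jj.push_back(j + 1);
          xx.push_back(omega * pint);
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["x"] = wrap(xx));
}

// Exact ray traversal (Siddon-style): each LOR adds to every voxel it
// crosses the intersection length (mm).  Returns the image and the chord
// length of each LOR inside the grid.
// [[Rcpp::export]]
List cpp_siddon_backproject(NumericMatrix p0, NumericMatrix p1,
                            NumericVector origin, double pitch,
                            IntegerVector dims) {
  int M = p0.nrow();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector img((R_xlen_t)nx * ny * nz);
  NumericVector chord(M);
  for (int m = 0; m < M; ++m) {
    double ax = p0(m, 0), ay = p0(m, 1), az = p0(m, 2);
    double dx = p1(m, 0) - ax, dy = p1(m, 1) - ay, dz = p1(m, 2) - az;
    double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (len <= 0) continue;
    double tmin = 0.0, tmax = 1.0;
    double lo[3] = {origin[0], origin[1], origin[2]};
    double hi[3] = {origin[0] + nx * pitch, origin[1] + ny * pitch,
                    origin[2] + nz * pitch};
    double pa[3] = {ax, ay, az}, dd[3] = {dx, dy, dz};
    bool miss = false;
    for (int c = 0; c < 3; ++c) {
      if (std::fabs(dd[c]) < 1e-14) {
        if (pa[c] < lo[c] || pa[c] >= hi[c]) { miss = true; break; }
      } else {
        double t1 = (lo[c] - pa[c]) / dd[c];
        double t2 = (hi[c] - pa[c]) / dd[c];
        if (t1 > t2) std::swap(t1, t2);
        if (t1 > tmin) tmin = t1;
        if (t2 < tmax) tmax = t2;
      }
    }
    if (miss || tmax <= tmin) continue;
    chord[m] = (tmax - tmin) * len;
    // crossing parameters of all grid planes inside [tmin, tmax]
    std::vector<double> ts;
    ts.push_back(tmin);
    for (int c = 0; c < 3; ++c) {
      if (std::fabs(dd[c]) < 1e-14) continue;
      int n = (c == 0) ? nx : (c == 1) ? ny : nz;
      for (int i = 0; i <= n; ++i) {
        double t = (lo[c] + i * pitch - pa[c]) / dd[c];
        if (t > tmin && t < tmax) ts.push_back(t);
      }
    }
    ts.push_back(tmax);
    std::sort(ts.begin(), ts.end());
    for (size_t s = 0; s + 1 < ts.size(); ++s) {
      double t0 = ts[s], t1s = ts[s + 1];
      if (t1s - t0 < 1e-14) continue;
      double tm = 0.5 * (t0 + t1s);
      double mx = (ax + tm * dx - lo[0]) / pitch;
      double my = (ay + tm * dy - lo[1]) / pitch;
      double mz = (az + tm * dz - lo[2]) / pitch;
      int ix = (int)std::floor(mx), iy = (int)std::floor(my),
          iz = (int)std::floor(mz);
      // boundary-grazing segment: assign to the lower-index voxel
      if (mx == std::floor(mx) && ix > 0) --ix;
      if (my == std::floor(my) && iy > 0) --iy;
      if (mz == std::floor(mz) && iz > 0) --iz;
      if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
        continue;
      img[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] +=
        (t1s - t0) * len;
    }
  }
  return List::create(_["img"] = img, _["chord"] = chord);
}
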