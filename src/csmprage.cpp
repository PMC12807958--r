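// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;
using arma::cx_mat;
using arma::cx_cube;

// ---------------------------------------------------------------------------
// Sampling-mask support: snap real-valued spiral targets to the nearest
// unsampled footprint grid point, searching outward ring by ring on collision.
// targets: m x 2 (1-based real coords), footprint: logical matrix.
// Returns m x 2 integer matrix of 0-based grid indices.
// [[Rcpp::export]]
IntegerMatrix snap_points_cpp(NumericMatrix targets, LogicalMatrix footprint) {
  const int ny = footprint.nrow(), nz = footprint.ncol(), m = targets.nrow();
  std::vector<char> occ((size_t)ny * nz, 0);
  IntegerMatrix out(m, 2);
  const int rmaxlim = std::max(ny, nz);
  for (int i = 0; i < m; i++) {
    const double ty = targets(i, 0) - 1.0, tz = targets(i, 1) - 1.0;
    int cy = (int)std::lround(ty), cz = (int)std::lround(tz);
    if (cy < 0) cy = 0; if (cy >= ny) cy = ny - 1;
    if (cz < 0) cz = 0; if (cz >= nz) cz = nz - 1;
    int besty = -1, bestz = -1;
    double bestd = 1e300;
    for (int ring = 0; ring <= rmaxlim; ring++) {
      // scan the Chebyshev ring of radius `ring` around (cy, cz)
      for (int dy = -ring; dy <= ring; dy++) {
        int ylo = cy + dy;
        if (ylo < 0 || ylo >= ny) continue;
        int dzlo = -ring, dzhi = ring, step = 1;
        bool edge = (std::abs(dy) == ring);
        for (int dz = dzlo; dz <= dzhi; dz += step) {
          if (!edge && std::abs(dz) != ring) continue;
          int z = cz + dz;
          if (z < 0 || z >= nz) continue;
          size_t id = (size_t)ylo + (size_t)z * ny;
          if (!footprint(ylo, z) || occ[id]) continue;
          double d = (ylo - ty) * (ylo - ty) + (z - tz) * (z - tz);
          if (d < bestd) { bestd = d; besty = ylo; bestz = z; }
        }
      }
      // a candidate at Euclidean distance d can only be beaten inside
      // Chebyshev radius d, so search on until the ring exceeds it
      if (besty >= 0 && ring >= (int)std::ceil(std::sqrt(bestd))) break;
    }
    if (besty < 0) stop("snap_points_cpp: footprint exhausted");
    occ[(size_t)besty + (size_t)bestz * ny] = 1;
    out(i, 0) = besty;
    out(i, 1) = bestz;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Mixed-radix complex FFT (radices 2/3/5, recursive decimation in time) with
// a precomputed twiddle table. Grid sizes used by the reconstruction factor
// into {2,3,5}; other sizes fall back to a direct DFT radix. Forward is the
// unnormalized DFT; inverse carries the 1/n factor.
typedef std::complex<double> cpx;

struct FFTPlan {
  int n;
  std::vector<cpx> W;      // W[j] = exp(-2 pi i j / n)
  std::vector<cpx> Wc;     // conjugate table for the inverse
  std::vector<cpx> buf;    // scratch for strided transforms
  explicit FFTPlan(int n_) : n(n_), W(n_), Wc(n_), buf(n_) {
    for (int j = 0; j < n_; j++) {
      double a = -2.0 * M_PI * j / n_;
      W[j] = cpx(std::cos(a), std::sin(a));
      Wc[j] = std::conj(W[j]);
    }
  }
};

static int pick_radix(int n) {
  if (n % 4 == 0) return 4;
  if (n % 2 == 0) return 2;
  if (n % 3 == 0) return 3;
  if (n % 5 == 0) return 5;
  return n;  // prime: direct DFT
}

static void fft_rec(const cpx* x, cpx* y, int n, int s, const cpx* W,
                    int Wn) {
  if (n == 1) { y[0] = x[0]; return; }
  if (n == 2) {
    const cpx a = x[0], b = x[s];
    y[0] = a + b; y[1] = a - b;
    return;
  }
  if (n == 4) {
    const cpx a = x[0], b = x[s], c = x[2 * s], d = x[3 * s];
    const cpx t0 = a + c, t1 = a - c, t2 = b + d;
    const cpx t3 = (b - d) * W[Wn / 4];  // -i forward, +i inverse
    y[0] = t0 + t2; y[1] = t1 + t3; y[2] = t0 - t2; y[3] = t1 - t3;
    return;
  }
  if (n == 3) {
    const cpx a = x[0], b = x[s], c = x[2 * s];
    const cpx w1 = W[Wn / 3], w2 = W[2 * (Wn / 3)];
    y[0] = a + b + c;
    y[1] = a + b * w1 + c * w2;
    y[2] = a + b * w2 + c * w1;
    return;
  }
  if (n == 5) {
    const int st = Wn / 5;
    for (int j = 0; j < 5; j++) {
      cpx acc = x[0];
      for (int q = 1; q < 5; q++) acc += x[q * s] * W[(size_t)(j * q) % 5 * st];
      y[j] = acc;
    }
    return;
  }
  const int r = pick_radix(n), m = n / r;
  if (r == n) {                        // direct DFT for prime length
    const int step = Wn / n;
    for (int j = 0; j < n; j++) {
      cpx acc(0.0);
      for (int q = 0; q < n; q++) acc += x[q * s] * W[(size_t)(j * q) % n * step];
      y[j] = acc;
    }
    return;
  }
  for (int q = 0; q < r; q++) fft_rec(x + q * s, y + q * m, m, s * r, W, Wn);
  const int tw = Wn / n;
  if (r == 4) {                        // radix-4 butterfly, twiddles fused
    const cpx i4 = W[Wn / 4];
    for (int k = 0; k < m; k++) {
      const cpx a = y[k];
      const cpx b = y[m + k] * W[(size_t)k * tw];
      const cpx c = y[2 * m + k] * W[(size_t)(2 * k) * tw];
      const cpx d = y[3 * m + k] * W[(size_t)(3 * k) * tw];
      const cpx t0 = a + c, t1 = a - c, t2 = b + d, t3 = (b - d) * i4;
      y[k] = t0 + t2; y[m + k] = t1 + t3;
      y[2 * m + k] = t0 - t2; y[3 * m + k] = t1 - t3;
    }
    return;
  }
  if (r == 2) {
    for (int k = 0; k < m; k++) {
      const cpx a = y[k], b = y[m + k] * W[(size_t)k * tw];
      y[k] = a + b; y[m + k] = a - b;
    }
    return;
  }
  const int twr = Wn / r;
  cpx t[5], o[5];
  for (int k = 0; k < m; k++) {
    for (int q = 0; q < r; q++)
      t[q] = y[q * m + k] * W[(size_t)(q * k) * tw % Wn];
    for (int j = 0; j < r; j++) {
      cpx acc = t[0];
      for (int q = 1; q < r; q++) acc += t[q] * W[(size_t)((q * j) % r) * twr];
      o[j] = acc;
    }
    for (int j = 0; j < r; j++) y[j * m + k] = o[j];
  }
}

// 2D transform of a column-major ny x nz complex matrix, in place; the
// result is multiplied by `scale` during the row pass (no extra sweep).
static void fft2_inplace_s(cx_mat& x, FFTPlan& py, FFTPlan& pz, bool inverse,
                           double scale) {
  const int ny = x.n_rows, nz = x.n_cols;
  const cpx* Wy = inverse ? py.Wc.data() : py.W.data();
  const cpx* Wz = inverse ? pz.Wc.data() : pz.W.data();
  cpx* d = reinterpret_cast<cpx*>(x.memptr());
  // columns (contiguous)
  for (int c = 0; c < nz; c++) {
    fft_rec(d + (size_t)c * ny, py.buf.data(), ny, 1, Wy, ny);
    std::copy(py.buf.begin(), py.buf.end(), d + (size_t)c * ny);
  }
  // rows (stride ny)
  for (int r = 0; r < ny; r++) {
    fft_rec(d + r, pz.buf.data(), nz, ny, Wz, nz);
    cpx* row = d + r;
    if (scale == 1.0) {
      for (int c = 0; c < nz; c++) row[(size_t)c * ny] = pz.buf[c];
    } else {
      for (int c = 0; c < nz; c++) row[(size_t)c * ny] = pz.buf[c] * scale;
    }
  }
}

static void fft2_inplace(cx_mat& x, FFTPlan& py, FFTPlan& pz, bool inverse) {
  fft2_inplace_s(x, py, pz, inverse,
                 inverse ? 1.0 / ((double)x.n_rows * x.n_cols) : 1.0);
}

// [[Rcpp::export]]
arma::cx_mat fft2_mr_cpp(arma::cx_mat x, bool inverse = false) {
  FFTPlan py(x.n_rows), pz(x.n_cols);
  fft2_inplace(x, py, pz, inverse);
  return x;
}

// ---------------------------------------------------------------------------
// Periodic orthogonal tensor (separable) DWT via lifting-free filter banks.
// Convention matches the package's transform matrices: analysis low-pass
// a_k = sum_j h_j x_{(2k+j) mod m}, high-pass with g_j = h_{L-1-j} (-1)^j;
// each dimension is transformed through all its levels independently.
static void dwt1d_step(std::complex<double>* v, int stride, int m,
                       const std::vector<double>& h,
                       const std::vector<double>& g,
                       std::vector<std::complex<double>>& buf, bool inverse) {
  const int half = m / 2, L = (int)h.size();
  if (!inverse) {
    for (int k = 0; k < half; k++) {
      std::complex<double> a(0.0), d(0.0);
      for (int j = 0; j < L; j++) {
        const std::complex<double> x = v[((2 * k + j) % m) * stride];
        a += h[j] * x; d += g[j] * x;
      }
      buf[k] = a; buf[half + k] = d;
    }
  } else {
    for (int i = 0; i < m; i++) buf[i] = 0.0;
    for (int k = 0; k < half; k++) {
      const std::complex<double> a = v[k * stride], d = v[(half + k) * stride];
      for (int j = 0; j < L; j++)
        buf[(2 * k + j) % m] += h[j] * a + g[j] * d;
    }
  }
  for (int i = 0; i < m; i++) v[i * stride] = buf[i];
}

static void dwt2_inplace(cx_mat& x, const std::vector<double>& h,
                         const std::vector<double>& g, int ly, int lz,
                         bool inverse) {
  const int ny = x.n_rows, nz = x.n_cols;
  std::vector<std::complex<double>> buf(std::max(ny, nz));
  if (!inverse) {
    for (int l = 0; l < ly; l++) {
      const int m = ny >> l;
      for (int c = 0; c < nz; c++) dwt1d_step(x.colptr(c), 1, m, h, g, buf, false);
    }
    for (int l = 0; l < lz; l++) {
      const int m = nz >> l;
      for (int r = 0; r < ny; r++) dwt1d_step(x.memptr() + r, ny, m, h, g, buf, false);
    }
  } else {
    for (int l = lz - 1; l >= 0; l--) {
      const int m = nz >> l;
      for (int r = 0; r < ny; r++) dwt1d_step(x.memptr() + r, ny, m, h, g, buf, true);
    }
    for (int l = ly - 1; l >= 0; l--) {
      const int m = ny >> l;
      for (int c = 0; c < nz; c++) dwt1d_step(x.colptr(c), 1, m, h, g, buf, true);
    }
  }
}

static std::vector<double> qmf_highpass(const std::vector<double>& h) {
  const int L = (int)h.size();
  std::vector<double> g(L);
  for (int j = 0; j < L; j++) g[j] = h[L - 1 - j] * ((j % 2) ? -1.0 : 1.0);
  return g;
}

// [[Rcpp::export]]
arma::cx_mat dwt2_fb_cpp(arma::cx_mat x, arma::vec filt, int levels_y,
                         int levels_z, bool inverse = false) {
  std::vector<double> h(filt.begin(), filt.end());
  std::vector<double> g = qmf_highpass(h);
  dwt2_inplace(x, h, g, levels_y, levels_z, inverse);
  return x;
}

// ---------------------------------------------------------------------------
// FISTA reconstruction of all readout slices of a volume.
//
// Data layout: y and S are lists of complex cubes of size (ny, nz, nx) --
// slice s of each cube is one readout position. y is already masked, scaled
// to the unitary 2D DFT convention, and intensity-normalized. mask: ny x nz
// (0/1). Wy (ny x ny) and Wz (nz x nz) are orthogonal DWT matrices.
//
// Per slice: FISTA with fixed step 1/L, L from power iteration on the normal
// operator of the mid slice (deterministic all-ones start), soft-threshold
// prox with threshold lambda/L, stop on relative objective change < tol.
// [[Rcpp::export]]
List cs_fista_cpp(List y_coils, List s_coils, arma::mat mask_, double lambda,
                  int max_iter, double tol, arma::vec filt, int levels_y,
                  int levels_z, int power_iters = 12) {
  const std::vector<double> h(filt.begin(), filt.end());
  const std::vector<double> g = qmf_highpass(h);
  const int nc = y_coils.size();
  std::vector<cx_cube> Y(nc), S(nc);
  for (int c = 0; c < nc; c++) {
    Y[c] = as<cx_cube>(y_coils[c]);
    S[c] = as<cx_cube>(s_coils[c]);
  }
  const int ny = Y[0].n_rows, nz = Y[0].n_cols, nx = Y[0].n_slices;
  const double s2 = std::sqrt((double)ny * nz);
  arma::cx_mat M = arma::conv_to<arma::cx_mat>::from(mask_);
  FFTPlan py(ny), pz(nz);
  const double nyz = (double)ny * nz;
  // unitary 2D DFT pair built on the mixed-radix kernels (scale fused into
  // the final transform pass)
  auto fwd_u = [&](cx_mat& m) { fft2_inplace_s(m, py, pz, false, 1.0 / s2); };
  auto inv_u = [&](cx_mat& m) { fft2_inplace_s(m, py, pz, true, s2 / nyz); };

  // --- Lipschitz bound by power iteration on the mid-slice normal operator
  int smid = nx / 2;
  cx_mat v(ny, nz, arma::fill::ones);
  double L = 1.0;
  for (int it = 0; it < power_iters; it++) {
    cx_mat b(ny, nz, arma::fill::zeros);
    for (int c = 0; c < nc; c++) {
      cx_mat f = S[c].slice(smid) % v;
      fwd_u(f);
      f %= M;
      inv_u(f);
      b += arma::conj(S[c].slice(smid)) % f;
    }
    double nb = arma::norm(arma::vectorise(b), 2);
    double nv = arma::norm(arma::vectorise(v), 2);
    if (nv < 1e-30 || nb < 1e-30) { L = 1.0; break; }
    L = nb / nv;
    v = b / nb;
  }
  L = std::max(L * 1.02, 1e-12);
  const double step = 1.0 / L, tau = lambda / L;

  cx_cube X(ny, nz, nx, arma::fill::zeros);
  arma::vec total_trace(max_iter + 1, arma::fill::zeros);
  arma::ivec iters(nx);

  std::vector<cx_mat> xF(nc), xFprev(nc), yv(nc), sv(nc), csv(nc);
  for (int s = 0; s < nx; s++) {
    for (int c = 0; c < nc; c++) {
      yv[c] = Y[c].slice(s); sv[c] = S[c].slice(s);
      csv[c] = arma::conj(sv[c]);
    }
    // init: coil-combined zero-filled (adjoint) image
    cx_mat x(ny, nz, arma::fill::zeros);
    for (int c = 0; c < nc; c++) {
      cx_mat tmp = yv[c];
      inv_u(tmp);
      x += csv[c] % tmp;
    }
    for (int c = 0; c < nc; c++) { xF[c] = sv[c] % x; fwd_u(xF[c]); }
    cx_mat w0 = x;
    dwt2_inplace(w0, h, g, levels_y, levels_z, false);
    double obj = 0.0;
    for (int c = 0; c < nc; c++)
      obj += 0.5 * std::pow(arma::norm(arma::vectorise(M % xF[c] - yv[c]), 2), 2);
    obj += lambda * arma::accu(arma::abs(w0));
    arma::vec trace(max_iter + 1);
    trace(0) = obj;
    cx_mat xprev = x;
    for (int c = 0; c < nc; c++) xFprev[c] = xF[c];
    double t = 1.0;
    int k = 0;
    const size_t nel = (size_t)ny * nz;
    cx_mat resid(ny, nz), grad(ny, nz), w(ny, nz);
    for (k = 1; k <= max_iter; k++) {
      double tn = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t * t));
      double beta = (t - 1.0) / tn;
      // gradient at the extrapolated point, via tracked transforms
      grad.zeros();
      const cpx* mm = M.memptr();
      for (int c = 0; c < nc; c++) {
        cpx* rp = resid.memptr();
        const cpx* f1 = xF[c].memptr();
        const cpx* f0 = xFprev[c].memptr();
        const cpx* yy = yv[c].memptr();
        for (size_t i = 0; i < nel; i++)
          rp[i] = mm[i] * ((1.0 + beta) * f1[i] - beta * f0[i]) - yy[i];
        inv_u(resid);
        const cpx* cs = csv[c].memptr();
        cpx* gp = grad.memptr();
        for (size_t i = 0; i < nel; i++) gp[i] += cs[i] * rp[i];
      }
      {
        cpx* wp = w.memptr();
        const cpx* xp = x.memptr();
        const cpx* xq = xprev.memptr();
        const cpx* gp = grad.memptr();
        for (size_t i = 0; i < nel; i++)
          wp[i] = (1.0 + beta) * xp[i] - beta * xq[i] - step * gp[i];
      }
      dwt2_inplace(w, h, g, levels_y, levels_z, false);
      double l1 = 0.0;
      if (tau > 0) {
        cpx* wp = w.memptr();
        for (size_t i = 0; i < nel; i++) {
          double m = std::abs(wp[i]);
          if (m <= tau) { wp[i] = 0.0; }
          else { double f = (m - tau) / m; wp[i] *= f; l1 += m - tau; }
        }
      } else if (lambda > 0) {
        l1 = arma::accu(arma::abs(w));
      }
      cx_mat xn = w;
      dwt2_inplace(xn, h, g, levels_y, levels_z, true);
      double objn = lambda * l1;
      for (int c = 0; c < nc; c++) {
        xFprev[c] = std::move(xF[c]);
        xF[c] = sv[c] % xn;
        fwd_u(xF[c]);
        const cpx* a = xF[c].memptr();
        const cpx* yy = yv[c].memptr();
        double acc = 0.0;
        for (size_t i = 0; i < nel; i++) {
          cpx r = mm[i] * a[i] - yy[i];
          acc += std::norm(r);
        }
        objn += 0.5 * acc;
      }
      xprev = std::move(x); x = std::move(xn); t = tn;
      trace(k) = objn;
      double rel = std::fabs(objn - obj) / std::max(obj, 1e-30);
      obj = objn;
      if (rel < tol) break;
    }
    int kdone = std::min(k, max_iter);
    iters(s) = kdone;
    // pad trace with the final value so volume totals stay defined
    for (int j = kdone + 1; j <= max_iter; j++) trace(j) = trace(kdone);
    total_trace += trace;
    X.slice(s) = x;
  }
  int kmax = (int)iters.max();
  return List::create(_["x"] = X,
                      _["trace"] = total_trace.head(kmax + 1),
                      _["iters"] = iters, _["L"] = L);
}

// ---------------------------------------------------------------------------
// Separable 3D convolution with a symmetric 1D kernel, zero padding.
// Used for Gaussian-window local statistics (SSIM); callers renormalize by
// the convolution of a ones-array to get weighted means near edges.
// [[Rcpp::export]]
arma::cube sepconv3_cpp(arma::cube vol, arma::vec kernel) {
  const int r = (kernel.n_elem - 1) / 2;
  const int nx = vol.n_rows, ny = vol.n_cols, nz = vol.n_slices;
  arma::cube a = vol, b(nx, ny, nz);
  // axis 1 (rows)
  b.zeros();
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        double acc = 0;
        int jlo = std::max(0, x - r), jhi = std::min(nx - 1, x + r);
        for (int j = jlo; j <= jhi; j++) acc += kernel(j - x + r) * a(j, y, z);
        b(x, y, z) = acc;
      }
  // axis 2 (cols)
  a.zeros();
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++)
      for (int y = 0; y < ny; y++) {
        double acc = 0;
        int jlo = std::max(0, y - r), jhi = std::min(ny - 1, y + r);
        for (int j = jlo; j <= jhi; j++) acc += kernel(j - y + r) * b(x, j, z);
        a(x, y, z) = acc;
      }
  // axis 3 (slices)
  b.zeros();
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++)
      for (int z = 0; z < nz; z++) {
        double acc = 0;
        int jlo = std::max(0, z - r), jhi = std::min(nz - 1, z + r);
        for (int j = jlo; j <= jhi; j++) acc += kernel(j - z + r) * a(x, y, j);
        b(x, y, z) = acc;
      }
  return b;
}

// ---------------------------------------------------------------------------
// Exact 3D Euclidean distance transform (Felzenszwalb & Huttenlocher):
// distance from every voxel to the nearest feature voxel, anisotropic
// spacing supported. feature: 0/1 cube; spacing: length-3 (mm per voxel).
static void edt1d(std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& zb, double w2) {
  const int n = f.size();
  int k = 0;
  v[0] = 0; zb[0] = -1e300; zb[1] = 1e300;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= zb[k]) k--; else break;
    }
    k++;
    v[k] = q; zb[k] = s; zb[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (zb[k + 1] < q) k++;
    d[q] = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
arma::cube edt3_cpp(arma::cube feature, arma::vec spacing) {
  const int nx = feature.n_rows, ny = feature.n_cols, nz = feature.n_slices;
  const double INF = 1e300;
  arma::cube D(nx, ny, nz);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++)
        D(x, y, z) = feature(x, y, z) > 0.5 ? 0.0 : INF;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // axis 1
  double w2 = spacing(0) * spacing(0);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      f.resize(nx); d.resize(nx);
      for (int x = 0; x < nx; x++) f[x] = D(x, y, z);
      edt1d(f, d, v, zb, w2);
      for (int x = 0; x < nx; x++) D(x, y, z) = d[x];
    }
  // axis 2
  w2 = spacing(1) * spacing(1);
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      f.resize(ny); d.resize(ny);
      for (int y = 0; y < ny; y++) f[y] = D(x, y, z);
      edt1d(f, d, v, zb, w2);
      for (int y = 0; y < ny; y++) D(x, y, z) = d[y];
    }
  // axis 3
  w2 = spacing(2) * spacing(2);
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      f.resize(nz); d.resize(nz);
      for (int z = 0; z < nz; z++) f[z] = D(x, y, z);
      edt1d(f, d, v, zb, w2);
      for (int z = 0; z < nz; z++) D(x, y, z) = d[z];
    }
  return arma::sqrt(D);
}

// ---------------------------------------------------------------------------
// 6-connected region growing from a seed voxel over an intensity band,
// capped at max_vox voxels. Returns a logical cube of the grown region.
// [[Rcpp::export]]
arma::ucube region_grow_cpp(arma::cube img, arma::ivec seed, double lo,
                            double hi, int max_vox) {
  const int nx = img.n_rows, ny = img.n_cols, nz = img.n_slices;
  arma::ucube out(nx, ny, nz, arma::fill::zeros);
  int sx = seed(0) - 1, sy = seed(1) - 1, sz = seed(2) - 1;
  if (sx < 0 || sx >= nx || sy < 0 || sy >= ny || sz < 0 || sz >= nz)
    stop("seed outside volume");
  double v = img(sx, sy, sz);
  if (v < lo || v > hi) return out;
  std::queue<std::array<int, 3>> q;
  q.push({sx, sy, sz});
  out(sx, sy, sz) = 1;
  int count = 1;
  const int d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty() && count < max_vox) {
    auto p = q.front(); q.pop();
    for (int i = 0; i < 6; i++) {
      int x = p[0] + d[i][0], y = p[1] + d[i][1], z = p[2] + d[i][2];
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
      if (out(x, y, z)) continue;
      double w = img(x, y, z);
      if (w < lo || w > hi) continue;
      out(x, y, z) = 1;
      if (++count >= max_vox) break;
      q.push({x, y, z});
    }
  }
  return out;
}
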