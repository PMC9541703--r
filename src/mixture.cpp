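// Numerical core for the causal Gaussian mixture likelihood.
//
// The marginal density of a z-score is the convolution implied by the
// characteristic function
//   phi_j(t) = exp(-sigma0^2 t^2 / 2) *
//              prod_{i in nbr(j)} [ 1 - pi1 + pi1 * exp(-N sb^2 r_ij^2 t^2 / 2) ]
// (and its four-component bivariate analogue).  Densities are recovered by
// FFT on a symmetric grid.  Variants sharing the same multiset of neighbor
// r^2 values share a density, so work is organised around "LD profiles":
// a counts matrix (profile x r^2 value) plus one profile index per variant.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double DENS_FLOOR = 1e-300;

// Inverse-Fourier a real, even characteristic function sampled on the half
// grid t = 0, dt, ..., (n/2) dt into a density sampled at z = (k - n/2) dz.
static arma::vec density_from_half_logcf(const arma::rowvec& logcf, int n,
                                         double dt) {
  int H = n / 2;
  arma::cx_vec psi(n);
  for (int m = 0; m < n; ++m) {
    int idx = (m <= H) ? m : (n - m);
    double val = std::exp(logcf(idx));
    psi(m) = ((m % 2) == 0) ? val : -val;  // phase shift centres z at 0
  }
  arma::cx_vec F = arma::fft(psi);
  return arma::real(F) * (dt / (2.0 * M_PI));
}

// Catmull-Rom cubic interpolation at fractional grid index u.
static double interp_cubic(const arma::vec& f, double u) {
  int n = f.n_elem;
  int i = (int)std::floor(u);
  if (i < 1) i = 1;
  if (i > n - 3) i = n - 3;
  double x = u - i;
  double fm1 = f(i - 1), f0 = f(i), f1 = f(i + 1), f2 = f(i + 2);
  double a0 = -0.5 * fm1 + 1.5 * f0 - 1.5 * f1 + 0.5 * f2;
  double a1 = fm1 - 2.5 * f0 + 2.0 * f1 - 0.5 * f2;
  double a2 = -0.5 * fm1 + 0.5 * f1;
  return ((a0 * x + a1) * x + a2) * x + f0;
}

// [[Rcpp::export]]
arma::mat cpp_uni_densgrid(const arma::mat& counts, const arma::vec& r2,
                           double pi1, double sb2N, double sig0, int n,
                           double zmax) {
  int P = counts.n_rows, R = counts.n_cols, H = n / 2;
  double dz = 2.0 * zmax / n;
  double dt = 2.0 * M_PI / (n * dz);

  arma::mat g(R, H + 1);
  for (int r = 0; r < R; ++r) {
    for (int m = 0; m <= H; ++m) {
      double t = m * dt;
      double e = std::exp(-0.5 * sb2N * r2(r) * t * t);
      g(r, m) = std::log(std::max(1.0 - pi1 + pi1 * e, DENS_FLOOR));
    }
  }
  arma::mat logcf = counts * g;  // P x (H+1)
  arma::rowvec noise(H + 1);
  for (int m = 0; m <= H; ++m) {
    double t = m * dt;
    noise(m) = -0.5 * sig0 * sig0 * t * t;
  }
  logcf.each_row() += noise;

  arma::mat dens(n, P);
  for (int p = 0; p < P; ++p)
    dens.col(p) = density_from_half_logcf(logcf.row(p), n, dt);
  return dens;  // row k is z = (k - n/2) * dz
}

// [[Rcpp::export]]
double cpp_uni_loglik(const arma::vec& z, const arma::uvec& prof,
                      const arma::mat& counts, const arma::vec& r2,
                      double pi1, double sb2N, double sig0, int n,
                      double zmax) {
  arma::mat dens = cpp_uni_densgrid(counts, r2, pi1, sb2N, sig0, n, zmax);
  double dz = 2.0 * zmax / n;
  double ll = 0.0;
  for (arma::uword i = 0; i < z.n_elem; ++i) {
    double u = z(i) / dz + n / 2.0;
    double f = interp_cubic(dens.col(prof(i)), u);
    ll += std::log(std::max(f, DENS_FLOOR));
  }
  return ll;
}

// [[Rcpp::export]]
arma::cube cpp_biv_densgrid(const arma::mat& counts, const arma::vec& r2,
                            double pi1, double pi2, double pi12, double s1,
                            double s2, double rho12, double s01, double s02,
                            double rho0, int n, double zmax) {
  int P = counts.n_rows, R = counts.n_cols;
  double pi0 = 1.0 - pi1 - pi2 - pi12;
  double dz = 2.0 * zmax / n;
  double dt = 2.0 * M_PI / (n * dz);
  int H = n / 2;

  arma::vec tv(n);
  for (int m = 0; m < n; ++m) tv(m) = ((m <= H) ? m : m - n) * dt;

  // log of the per-neighbor four-component mixture factor, one row per r2
  arma::mat A(R, n * n);
  double cross = 2.0 * rho12 * std::sqrt(s1 * s2);
  for (int r = 0; r < R; ++r) {
    arma::vec e1 = arma::exp(-0.5 * s1 * r2(r) * arma::square(tv));
    arma::vec e2 = arma::exp(-0.5 * s2 * r2(r) * arma::square(tv));
    double* Aptr = A.memptr();  // column-major: A(r, m2*n + m1)
    for (int m2 = 0; m2 < n; ++m2) {
      double t2 = tv(m2), e2v = e2(m2);
      for (int m1 = 0; m1 < n; ++m1) {
        double t1 = tv(m1);
        // shared-component quadratic form is positive semi-definite for
        // |rho12| <= 1, so the exponent never overflows
        double q = r2(r) * (s1 * t1 * t1 + cross * t1 * t2 + s2 * t2 * t2);
        double val = pi0 + pi1 * e1(m1) + pi2 * e2v +
                     pi12 * std::exp(-0.5 * q);
        Aptr[r + (size_t)R * (m2 * (size_t)n + m1)] =
            std::log(std::max(val, DENS_FLOOR));
      }
    }
  }

  arma::mat logcf = counts * A;  // P x n^2
  arma::rowvec noise(n * n);
  for (int m2 = 0; m2 < n; ++m2)
    for (int m1 = 0; m1 < n; ++m1)
      noise(m2 * n + m1) =
          -0.5 * (s01 * s01 * tv(m1) * tv(m1) +
                  2.0 * rho0 * s01 * s02 * tv(m1) * tv(m2) +
                  s02 * s02 * tv(m2) * tv(m2));
  logcf.each_row() += noise;

  arma::cube dens(n, n, P);
  double scale = dt * dt / (4.0 * M_PI * M_PI);
  for (int p = 0; p < P; ++p) {
    arma::cx_mat psi(n, n);
    for (int m2 = 0; m2 < n; ++m2)
      for (int m1 = 0; m1 < n; ++m1) {
        double val = std::exp(logcf(p, m2 * n + m1));
        psi(m1, m2) = (((m1 + m2) % 2) == 0) ? val : -val;
      }
    dens.slice(p) = arma::real(arma::fft2(psi)) * scale;
  }
  return dens;  // (k1, k2) is z1 = (k1 - n/2) dz, z2 = (k2 - n/2) dz
}

// [[Rcpp::export]]
double cpp_biv_loglik(const arma::vec& z1, const arma::vec& z2,
                      const arma::uvec& prof, const arma::mat& counts,
                      const arma::vec& r2, double pi1, double pi2,
                      double pi12, double s1, double s2, double rho12,
                      double s01, double s02, double rho0, int n,
                      double zmax) {
  arma::cube dens = cpp_biv_densgrid(counts, r2, pi1, pi2, pi12, s1, s2,
                                     rho12, s01, s02, rho0, n, zmax);
  double dz = 2.0 * zmax / n;
  double ll = 0.0;
  arma::vec col(n);
  for (arma::uword i = 0; i < z1.n_elem; ++i) {
    double u1 = z1(i) / dz + n / 2.0;
    double u2 = z2(i) / dz + n / 2.0;
    int j = (int)std::floor(u2);
    if (j < 1) j = 1;
    if (j > n - 3) j = n - 3;
    const arma::mat& D = dens.slice(prof(i));
    // bicubic: cubic along z1 within four z2 columns, then cubic across z2
    arma::vec vals(4);
    for (int k = 0; k < 4; ++k)
      vals(k) = interp_cubic(D.col(j - 1 + k), u1);
    double x = u2 - j;
    double a0 = -0.5 * vals(0) + 1.5 * vals(1) - 1.5 * vals(2) + 0.5 * vals(3);
    double a1 = vals(0) - 2.5 * vals(1) + 2.0 * vals(2) - 0.5 * vals(3);
    double a2 = -0.5 * vals(0) + 0.5 * vals(2);
    double f = ((a0 * x + a1) * x + a2) * x + vals(1);
    ll += std::log(std::max(f, DENS_FLOOR));
  }
  return ll;
}

// Greedy sequential pruning: visit nodes in `order` (0-based); keep a node
// iff none of its neighbors has already been kept.  Adjacency in CSR form.
// [[Rcpp::export]]
LogicalVector cpp_greedy_keep(const IntegerVector& order,
                              const IntegerVector& adj_ptr,
                              const IntegerVector& adj_idx) {
  int n = order.size();
  std::vector<char> kept(n, 0), decided(n, 0);
  for (int o = 0; o < n; ++o) {
    int v = order[o];
    bool ok = true;
    for (int e = adj_ptr[v]; e < adj_ptr[v + 1]; ++e) {
      if (kept[adj_idx[e]]) { ok = false; break; }
    }
    kept[v] = ok ? 1 : 0;
    decided[v] = 1;
  }
  LogicalVector out(n);
  for (int v = 0; v < n; ++v) out[v] = kept[v] == 1;
  return out;
}
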