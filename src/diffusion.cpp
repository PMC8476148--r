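#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Finite-difference solver for the forward diffusion equation of allele
// frequency density phi(x) under drift, selection with dominance, and
// migration, in the conventions used throughout the package: time in units
// of 2*Na generations, population sizes relative to Na, gamma = 2*Na*s with
// genotype fitnesses 1 : 1+2hs : 1+2s, migration rates as 2*Na*m.
//
// The scheme is a conservative flux discretisation on a non-uniform grid
// with Chang-Cooper exponential-fitting interface weights (reduces to
// centred delj = 1/2 for weak drift, exact for locally constant M/V), and
// fully implicit (backward Euler) time stepping. 2D integration uses
// operator splitting, alternating implicit sweeps along each axis.

static inline double sel_M(double x, double gamma, double h) {
  // mean change in allele frequency per unit time from selection
  return 2.0 * gamma * x * (1.0 - x) * (h + (1.0 - 2.0 * h) * x);
}

static inline double cc_delta(double w) {
  // Chang-Cooper interface weight for Peclet number w = 2*M*dx/V
  if (std::fabs(w) < 1e-8) return 0.5 - w / 12.0;
  if (w > 500.0) return 1.0 - 1.0 / w;
  if (w < -500.0) return -1.0 / w;
  return 1.0 / (-std::expm1(-w)) - 1.0 / w;
}

// Thomas algorithm: solves (sub, diag, sup) tri-diagonal system in place.
static void thomas(std::vector<double> &sub, std::vector<double> &diag,
                   std::vector<double> &sup, std::vector<double> &rhs,
                   std::vector<double> &out) {
  const int n = diag.size();
  std::vector<double> cp(n), dp(n);
  cp[0] = sup[0] / diag[0];
  dp[0] = rhs[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    double m = diag[i] - sub[i] * cp[i - 1];
    cp[i] = sup[i] / m;
    dp[i] = (rhs[i] - sub[i] * dp[i - 1]) / m;
  }
  out[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) out[i] = dp[i] - cp[i] * out[i + 1];
}

// Build the tridiagonal action d(phi)/dt = -(a*phi[i-1] + b*phi[i] + c*phi[i+1])
// for one axis. Mnode: drift coefficient at the grid nodes (selection +
// migration); nu: relative size of this population (diffusion V = x(1-x)/nu).
static void build_coefs(const std::vector<double> &xx,
                        const std::vector<double> &Mnode,
                        const std::vector<double> &Mint, double nu,
                        std::vector<double> &a, std::vector<double> &b,
                        std::vector<double> &c, bool absorb) {
  const int L = xx.size();
  std::vector<double> dx(L - 1), dfactor(L), V(L), VInt(L - 1), delj(L - 1);
  for (int j = 0; j < L - 1; ++j) dx[j] = xx[j + 1] - xx[j];
  dfactor[0] = 2.0 / dx[0];
  dfactor[L - 1] = 2.0 / dx[L - 2];
  for (int i = 1; i < L - 1; ++i) dfactor[i] = 2.0 / (xx[i + 1] - xx[i - 1]);
  for (int i = 0; i < L; ++i) V[i] = xx[i] * (1.0 - xx[i]) / nu;
  std::fill(a.begin(), a.end(), 0.0);
  std::fill(b.begin(), b.end(), 0.0);
  std::fill(c.begin(), c.end(), 0.0);
  // Flux at interface j (between nodes j and j+1):
  //   F_j = Mint[j]*(delj*phi[j] + (1-delj)*phi[j+1])
  //         - (V[j+1]*phi[j+1] - V[j]*phi[j]) / (2*dx[j])
  // The (V phi)' difference is exact for the neutral equilibrium profile.
  // delj is the Chang-Cooper exponential-fitting weight; at the two
  // boundary-adjacent interfaces the advective part is purely upwinded so
  // that density accumulated at a boundary node (V = 0 there) can never
  // leak back into the interior unless drift genuinely points inward.
  // d(phi[i])/dt = dfactor[i] * (F_{i-1} - F_i), domain-end fluxes zero.
  for (int j = 0; j < L - 1; ++j) {
    double xm = 0.5 * (xx[j] + xx[j + 1]);
    VInt[j] = xm * (1.0 - xm) / nu;
    double w = 2.0 * Mint[j] * dx[j] / VInt[j];
    delj[j] = cc_delta(w);
    if (j == 0 || j == L - 2) delj[j] = (Mint[j] > 0) ? 1.0 : 0.0;
    double fl_j = Mint[j] * delj[j] + V[j] / (2.0 * dx[j]);        // * phi[j]
    double fl_jp = Mint[j] * (1.0 - delj[j]) - V[j + 1] / (2.0 * dx[j]); // * phi[j+1]
    // node j: -F_j contributes
    b[j] += dfactor[j] * fl_j;
    c[j] += dfactor[j] * fl_jp;
    // node j+1: +F_j contributes
    a[j + 1] -= dfactor[j + 1] * fl_j;
    b[j + 1] -= dfactor[j + 1] * fl_jp;
  }
  // Boundary handling. In a single-population integration, density
  // reaching a boundary is removed (the variant is no longer segregating
  // anywhere): an absorption term unless drift pushes inward. In the 2D
  // sweeps absorption is wrong -- a variant lost or fixed in one
  // population may still segregate in the other -- so the boundary nodes
  // conservatively accumulate the incoming flux and keep evolving along
  // the transverse axis.
  if (absorb) {
    if (Mnode[0] <= 0) b[0] += (0.5 / nu - Mnode[0]) * 2.0 / dx[0];
    if (Mnode[L - 1] >= 0) b[L - 1] += (0.5 / nu + Mnode[L - 1]) * 2.0 / dx[L - 2];
  }
}

// One implicit step of length dt along a vector phi given prebuilt coefs.
static void implicit_step(const std::vector<double> &a,
                          const std::vector<double> &b,
                          const std::vector<double> &c, double dt,
                          std::vector<double> &phi) {
  const int L = phi.size();
  std::vector<double> sub(L), diag(L), sup(L), rhs(L), out(L);
  for (int i = 0; i < L; ++i) {
    sub[i] = dt * a[i];
    diag[i] = 1.0 + dt * b[i];
    sup[i] = dt * c[i];
    rhs[i] = phi[i];
  }
  thomas(sub, diag, sup, rhs, out);
  phi = out;
}

// [[Rcpp::export]]
NumericVector phi1d_equilibrium_cpp(NumericVector xx_, double nu, double gamma,
                                    double h, double theta0) {
  const int L = xx_.size();
  std::vector<double> xx(xx_.begin(), xx_.end());
  std::vector<double> Mnode(L), Mint(L - 1), a(L), b(L), c(L);
  for (int i = 0; i < L; ++i) Mnode[i] = sel_M(xx[i], gamma, h);
  for (int j = 0; j < L - 1; ++j)
    Mint[j] = sel_M(0.5 * (xx[j] + xx[j + 1]), gamma, h);
  build_coefs(xx, Mnode, Mint, nu, a, b, c, true);
  // steady state of d(phi)/dt = -(A phi) + inj  =>  A phi = inj
  std::vector<double> inj(L, 0.0), out(L);
  inj[1] = theta0 / (xx[1] * (xx[2] - xx[0]));
  thomas(a, b, c, inj, out);
  NumericVector res(L);
  for (int i = 0; i < L; ++i) res[i] = out[i];
  return res;
}

// [[Rcpp::export]]
NumericVector phi1d_integrate_cpp(NumericVector phi_, NumericVector xx_,
                                  NumericVector nu_t, double gamma, double h,
                                  double theta0, double dt) {
  const int L = xx_.size();
  const int nsteps = nu_t.size();
  std::vector<double> xx(xx_.begin(), xx_.end());
  std::vector<double> phi(phi_.begin(), phi_.end());
  std::vector<double> Mnode(L), Mint(L - 1), a(L), b(L), c(L);
  for (int i = 0; i < L; ++i) Mnode[i] = sel_M(xx[i], gamma, h);
  for (int j = 0; j < L - 1; ++j)
    Mint[j] = sel_M(0.5 * (xx[j] + xx[j + 1]), gamma, h);
  double inj = theta0 / (xx[1] * (xx[2] - xx[0]));
  double nu_prev = -1.0;
  for (int s = 0; s < nsteps; ++s) {
    if (nu_t[s] != nu_prev) {
      build_coefs(xx, Mnode, Mint, nu_t[s], a, b, c, true);
      nu_prev = nu_t[s];
    }
    phi[1] += dt * inj;
    implicit_step(a, b, c, dt, phi);
  }
  NumericVector res(L);
  for (int i = 0; i < L; ++i) res[i] = phi[i];
  return res;
}

// [[Rcpp::export]]
NumericMatrix phi2d_integrate_cpp(NumericMatrix phi_, NumericVector xx_,
                                  NumericVector nu1_t, NumericVector nu2_t,
                                  double m12, double m21, double gamma1,
                                  double gamma2, double h, double theta0,
                                  double dt) {
  const int L = xx_.size();
  const int nsteps = nu1_t.size();
  std::vector<double> xx(xx_.begin(), xx_.end());
  NumericMatrix phi(clone(phi_));
  std::vector<double> selx(L), selx_int(L - 1);
  std::vector<double> sely(L), sely_int(L - 1);
  for (int i = 0; i < L; ++i) {
    selx[i] = sel_M(xx[i], gamma1, h);
    sely[i] = sel_M(xx[i], gamma2, h);
  }
  for (int j = 0; j < L - 1; ++j) {
    double xm = 0.5 * (xx[j] + xx[j + 1]);
    selx_int[j] = sel_M(xm, gamma1, h);
    sely_int[j] = sel_M(xm, gamma2, h);
  }
  double inj_amp = theta0 / (xx[1] * (xx[2] - xx[0])) * 2.0 / xx[1];
  std::vector<double> Mnode(L), Mint(L - 1), a(L), b(L), c(L), col(L);
  for (int s = 0; s < nsteps; ++s) {
    // mutation influx: new variants private to each population
    phi(1, 0) += dt * inj_amp;
    phi(0, 1) += dt * inj_amp;
    // implicit sweep along x (first index), one tridiag per y node
    for (int j = 0; j < L; ++j) {
      double y = xx[j];
      for (int i = 0; i < L; ++i) Mnode[i] = selx[i] + m12 * (y - xx[i]);
      for (int k = 0; k < L - 1; ++k) {
        double xm = 0.5 * (xx[k] + xx[k + 1]);
        Mint[k] = selx_int[k] + m12 * (y - xm);
      }
      build_coefs(xx, Mnode, Mint, nu1_t[s], a, b, c, false);
      for (int i = 0; i < L; ++i) col[i] = phi(i, j);
      implicit_step(a, b, c, dt, col);
      for (int i = 0; i < L; ++i) phi(i, j) = col[i];
    }
    // implicit sweep along y (second index), one tridiag per x node
    for (int i = 0; i < L; ++i) {
      double x = xx[i];
      for (int j = 0; j < L; ++j) Mnode[j] = sely[j] + m21 * (x - xx[j]);
      for (int k = 0; k < L - 1; ++k) {
        double ym = 0.5 * (xx[k] + xx[k + 1]);
        Mint[k] = sely_int[k] + m21 * (x - ym);
      }
      build_coefs(xx, Mnode, Mint, nu2_t[s], a, b, c, false);
      for (int j = 0; j < L; ++j) col[j] = phi(i, j);
      implicit_step(a, b, c, dt, col);
      for (int j = 0; j < L; ++j) phi(i, j) = col[j];
    }
  }
  return phi;
}
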