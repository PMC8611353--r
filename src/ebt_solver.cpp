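// EBT mass-ODE integrator for the radially reduced non-local proliferation
// model.  Particle locations are fixed at x_i = i*R0/N; only the masses m_i
// evolve:  dm_i/dt = (4*pi*x_i^2*R0/N - m_i) * sum_j L(x_i, x_j) m_j.
// The interaction kernel L vanishes for |R - r| >= sigma_k, so L is banded
// with half-bandwidth ceil(sigma_k*N/R0); both construction and the matvec
// are O(N*b).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// exact case analysis (matches interaction_L in R): avoids the cancellation
// (R+r)^2 - (R-r)^2 and never divides by R*r outside the clamped regime
static inline double L_eval(double R, double r, double alpha, double sigma_k) {
  const double s2 = sigma_k * sigma_k;
  const double a = R + r, b = R - r;
  const double pref = 3.0 * alpha / (16.0 * M_PI * sigma_k * s2);
  if (a * a <= s2) return 4.0 * pref;
  if (b * b < s2) return pref * (s2 - b * b) / (R * r);
  return 0.0;
}

// Banded storage: column j of `band` holds L(x_{j-b+k}, x_j) at row k,
// k = 0..2b; out-of-range rows are zero.
struct BandedL {
  arma::mat band;  // (2b+1) x N
  int b;
};

static BandedL build_band(int N, double R0, double alpha, double sigma_k) {
  const double h = R0 / N;
  int b = (int)std::ceil(sigma_k / h) + 1;  // +1 guard row for the boundary
  if (b > N - 1) b = N - 1;
  BandedL L;
  L.b = b;
  L.band.zeros(2 * b + 1, N);
  for (int j = 0; j < N; ++j) {
    double xj = (j + 1) * h;
    int i0 = std::max(0, j - b), i1 = std::min(N - 1, j + b);
    for (int i = i0; i <= i1; ++i) {
      double xi = (i + 1) * h;
      L.band(i - j + b, j) = L_eval(xi, xj, alpha, sigma_k);
    }
  }
  return L;
}

// dm = (cap - m) .* (L m)
static void rhs(const BandedL& L, const arma::vec& cap, const arma::vec& m,
                arma::vec& out) {
  const int N = (int)m.n_elem, b = L.b;
  out.zeros();
  for (int j = 0; j < N; ++j) {
    double mj = m[j];
    if (mj == 0.0) continue;
    int i0 = std::max(0, j - b), i1 = std::min(N - 1, j + b);
    for (int i = i0; i <= i1; ++i) out[i] += L.band(i - j + b, j) * mj;
  }
  out %= (cap - m);
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

//' @noRd
// [[Rcpp::export(name = ".ebt_solve_cpp")]]
arma::mat ebt_solve_cpp(const arma::vec& m0, double R0, double alpha,
                        double sigma_k, const arma::vec& times, double rtol,
                        double atol, int max_steps, double fixed_dt) {
  const int N = (int)m0.n_elem;
  const double h = R0 / N;
  BandedL L = build_band(N, R0, alpha, sigma_k);
  arma::vec cap(N);
  for (int i = 0; i < N; ++i) {
    double xi = (i + 1) * h;
    cap[i] = 4.0 * M_PI * xi * xi * h;
  }

  const int nt = (int)times.n_elem;
  arma::mat out(nt, N);
  arma::vec m = m0;
  double t = times[0];
  out.row(0) = m.t();

  arma::vec k1(N), k2(N), k3(N), k4(N), k5(N), k6(N), k7(N), y(N), mnew(N),
      err(N);
  double dt_carry = -1.0;  // adaptive step persists across output intervals

  for (int iout = 1; iout < nt; ++iout) {
    double tend = times[iout];
    if (fixed_dt > 0.0) {
      // classical RK4, fixed step (bit-reproducible path)
      long nstep = (long)std::ceil((tend - t) / fixed_dt - 1e-12);
      if (nstep < 1) nstep = 1;
      double dt = (tend - t) / nstep;
      for (long s = 0; s < nstep; ++s) {
        rhs(L, cap, m, k1);
        y = m + 0.5 * dt * k1; rhs(L, cap, y, k2);
        y = m + 0.5 * dt * k2; rhs(L, cap, y, k3);
        y = m + dt * k3;       rhs(L, cap, y, k4);
        m += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      }
      t = tend;
    } else {
      double dt = (dt_carry > 0.0) ? std::min(dt_carry, tend - t)
                                   : std::min(1e-2, tend - t);
      long steps = 0;
      rhs(L, cap, m, k1);  // FSAL
      while (t < tend - 1e-14 * (1.0 + std::abs(tend))) {
        if (++steps > max_steps)
          stop("EBT integrator exceeded max_steps=%d at t=%g (alpha=%g, sigma_k=%g)",
               max_steps, t, alpha, sigma_k);
        bool clipped = false;
        if (t + dt >= tend) { dt = tend - t; clipped = true; }
        y = m + dt * (a21 * k1);                                   rhs(L, cap, y, k2);
        y = m + dt * (a31 * k1 + a32 * k2);                        rhs(L, cap, y, k3);
        y = m + dt * (a41 * k1 + a42 * k2 + a43 * k3);             rhs(L, cap, y, k4);
        y = m + dt * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4);  rhs(L, cap, y, k5);
        y = m + dt * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5);
        rhs(L, cap, y, k6);
        mnew = m + dt * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
        rhs(L, cap, mnew, k7);
        err = dt * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7);
        double enorm = 0.0;
        for (int i = 0; i < N; ++i) {
          double sc = atol + rtol * std::max(std::abs(m[i]), std::abs(mnew[i]));
          double q = err[i] / sc;
          enorm += q * q;
        }
        enorm = std::sqrt(enorm / N);
        if (enorm <= 1.0) {
          t += dt;
          m = mnew;
          k1 = k7;
        }
        double fac = (enorm > 0.0) ? 0.9 * std::pow(enorm, -0.2) : 5.0;
        fac = std::min(5.0, std::max(0.2, fac));
        dt *= fac;
        if (!std::isfinite(dt) || dt < 1e-14)
          stop("EBT integrator step-size underflow at t=%g (alpha=%g, sigma_k=%g)",
               t, alpha, sigma_k);
        if (!clipped || dt_carry < 0.0) dt_carry = dt;
      }
      t = tend;
    }
    out.row(iout) = m.t();
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".interaction_band_cpp")]]
List interaction_band_cpp(int N, double R0, double alpha, double sigma_k) {
  BandedL L = build_band(N, R0, alpha, sigma_k);
  return List::create(_["band"] = L.band, _["halfwidth"] = L.b);
}
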