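#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Radial Schroedinger solver on a logarithmic grid x = log(r).
// With P(r) = sqrt(r) y(x), the radial equation becomes
//   y'' = W(x) y,  W = (l + 1/2)^2 + 2 r^2 (V(r) - E)
// which is integrated with the Numerov scheme (uniform step h in x).
// Atomic (Hartree) units throughout.

static inline double Wval(double r, double V, double E, double lph2) {
  return lph2 + 2.0 * r * r * (V - E);
}

// Outward Numerov integration. Counts nodes up to the outer classical
// turning point and returns the sign of y at i_end (a point far enough
// into the forbidden region that the diverging solution dominates).
struct ShootResult {
  int nodes;
  double sign_end;
  double sign_last_lobe;
  int i_turn;
  int i_end;
};

static ShootResult shoot(const NumericVector& r, const NumericVector& V,
                         double E, int l, double h) {
  int n = r.size();
  double lph2 = (l + 0.5) * (l + 0.5);
  std::vector<double> W(n);
  for (int i = 0; i < n; ++i) W[i] = Wval(r[i], V[i], E, lph2);

  int i_turn = 0;
  for (int i = n - 1; i >= 0; --i) { if (W[i] < 0) { i_turn = i; break; } }
  if (i_turn > n - 4) i_turn = n - 4;
  ShootResult res{0, 0.0, 1.0, i_turn, n - 2};

  // end point: accumulate WKB phase sqrt(W) * h beyond the turning point
  double acc = 0.0; int i_end = n - 2;
  for (int i = i_turn + 1; i < n - 1; ++i) {
    if (W[i] > 0) acc += std::sqrt(W[i]) * h;
    if (acc > 18.0) { i_end = i; break; }
  }
  if (i_end < i_turn + 3) i_end = std::min(i_turn + 3, n - 2);
  res.i_end = i_end;

  double fac = h * h / 12.0;
  double y0 = std::pow(r[0], l + 0.5);
  double y1 = std::pow(r[1], l + 0.5);
  int nodes = 0;
  double prev = y0, cur = y1;
  double last_allowed = cur;
  for (int i = 1; i < i_end; ++i) {
    double ynext = ((2.0 + 10.0 * fac * W[i]) * cur -
                    (1.0 - fac * W[i - 1]) * prev) /
                   (1.0 - fac * W[i + 1]);
    prev = cur; cur = ynext;
    if (std::fabs(cur) > 1e250) { prev *= 1e-250; cur *= 1e-250; }
    if (i + 1 <= i_turn) {
      if ((cur > 0 && prev < 0) || (cur < 0 && prev > 0)) ++nodes;
      last_allowed = cur;
    }
  }
  res.nodes = nodes;
  res.sign_end = (cur > 0) ? 1.0 : ((cur < 0) ? -1.0 : 0.0);
  res.sign_last_lobe = (last_allowed > 0) ? 1.0 : -1.0;
  return res;
}

// Assemble the eigenfunction at energy E: outward to the turning point,
// inward from i_end, matched and normalised to int P^2 dr = 1.
static void assemble(const NumericVector& r, const NumericVector& V,
                     double E, int l, double h,
                     NumericVector& P, double& resid) {
  int n = r.size();
  double lph2 = (l + 0.5) * (l + 0.5);
  std::vector<double> W(n);
  for (int i = 0; i < n; ++i) W[i] = Wval(r[i], V[i], E, lph2);
  int i_turn = 1;
  for (int i = n - 1; i >= 0; --i) { if (W[i] < 0) { i_turn = i; break; } }
  if (i_turn > n - 4) i_turn = n - 4;
  if (i_turn < 1) i_turn = 1;
  double acc = 0.0; int i_end = n - 2;
  for (int i = i_turn + 1; i < n - 1; ++i) {
    if (W[i] > 0) acc += std::sqrt(W[i]) * h;
    if (acc > 30.0) { i_end = i; break; }
  }
  if (i_end < i_turn + 3) i_end = std::min(i_turn + 3, n - 2);
  double fac = h * h / 12.0;
  std::vector<double> yo(n, 0.0), yi(n, 0.0);
  yo[0] = std::pow(r[0], l + 0.5);
  yo[1] = std::pow(r[1], l + 0.5);
  for (int i = 1; i <= i_turn; ++i) {
    yo[i + 1] = ((2.0 + 10.0 * fac * W[i]) * yo[i] -
                 (1.0 - fac * W[i - 1]) * yo[i - 1]) /
                (1.0 - fac * W[i + 1]);
    if (std::fabs(yo[i + 1]) > 1e250)
      for (int j = 0; j <= i + 1; ++j) yo[j] *= 1e-250;
  }
  yi[i_end] = 1e-25;
  yi[i_end - 1] = yi[i_end] * std::exp(std::sqrt(std::max(W[i_end], 0.0)) * h);
  for (int i = i_end - 1; i > i_turn; --i) {
    yi[i - 1] = ((2.0 + 10.0 * fac * W[i]) * yi[i] -
                 (1.0 - fac * W[i + 1]) * yi[i + 1]) /
                (1.0 - fac * W[i - 1]);
    if (std::fabs(yi[i - 1]) > 1e250)
      for (int j = i - 1; j <= i_end; ++j) yi[j] *= 1e-250;
  }
  double scale = yo[i_turn + 1] / yi[i_turn + 1];
  for (int i = i_turn + 1; i <= i_end; ++i) yo[i] = yi[i] * scale;
  // derivative mismatch at the matching point (relative)
  double dout = yo[i_turn + 1] - yo[i_turn - 1];
  double dmid = yo[i_turn];
  // recompute outward one-step beyond match for the residual
  double ynext = ((2.0 + 10.0 * fac * W[i_turn]) * yo[i_turn] -
                  (1.0 - fac * W[i_turn - 1]) * yo[i_turn - 1]) /
                 (1.0 - fac * W[i_turn + 1]);
  resid = std::fabs(ynext - yo[i_turn + 1]) /
          (std::fabs(dmid) + std::fabs(dout) + 1e-300);
  double norm = 0.0;
  for (int i = 0; i < n; ++i) {
    double Pv = (i <= i_end) ? yo[i] * std::sqrt(r[i]) : 0.0;
    P[i] = Pv;
    norm += Pv * Pv * r[i] * h; // dr = r h on the log grid
  }
  norm = std::sqrt(norm);
  double sgn = 0.0;
  for (int i = 0; i < n; ++i) { if (std::fabs(P[i]) > 1e-12) { sgn = (P[i] > 0) ? 1 : -1; break; } }
  if (sgn == 0) sgn = 1;
  for (int i = 0; i < n; ++i) P[i] *= sgn / norm;
}

// [[Rcpp::export]]
List cpp_bound_state(NumericVector r, NumericVector V, int l,
                     int nodes_target, double guess = NA_REAL) {
  int n = r.size();
  double h = std::log(r[1] / r[0]);
  double Emin = R_PosInf;
  for (int i = 0; i < n; ++i) {
    double veff = V[i] + 0.5 * l * (l + 1) / (r[i] * r[i]);
    if (veff < Emin) Emin = veff;
  }
  if (!R_finite(Emin)) stop("invalid potential");
  Emin = Emin * 1.0000001 + 1e-12;
  double Emax = -1e-10;
  // warm start: try a narrow window around a previous eigenvalue first
  if (R_finite(guess) && guess < 0) {
    double wlo = std::max(Emin, guess * 1.35);
    double whi = std::min(Emax, guess * 0.65);
    if (wlo < whi) {
      ShootResult slo_w = shoot(r, V, wlo, l, h);
      ShootResult shi_w = shoot(r, V, whi, l, h);
      if (slo_w.nodes <= nodes_target && shi_w.nodes >= nodes_target) {
        Emin = wlo; Emax = whi;
      }
    }
  }

  // number of eigenvalues below E: node count, plus one if the diverging
  // tail has already flipped sign against the last lobe
  auto count_below = [&](double E) {
    ShootResult s = shoot(r, V, E, l, h);
    int c = s.nodes;
    if (s.sign_end * s.sign_last_lobe < 0) ++c;
    return c;
  };
  if (count_below(Emin) > nodes_target || count_below(Emax) <= nodes_target)
    return List::create(_["ok"] = false,
                        _["message"] = "requested state not inside bracket");
  // bisect on the count: it jumps from nodes_target to nodes_target + 1
  // exactly at the eigenvalue with nodes_target radial nodes
  double elo = Emin, ehi = Emax, E = 0.5 * (Emin + Emax);
  for (int k = 0; k < 110; ++k) {
    E = 0.5 * (elo + ehi);
    if (count_below(E) <= nodes_target) elo = E; else ehi = E;
    if (ehi - elo < 1e-13 * std::max(1.0, std::fabs(E))) break;
  }
  NumericVector P(n);
  double resid = 0.0;
  assemble(r, V, E, l, h, P, resid);
  return List::create(_["ok"] = true, _["energy"] = E, _["P"] = P,
                      _["residual"] = resid);
}

// Energy-normalised continuum wave P_{e l}(r): outward Numerov, WKB
// amplitude matching at i_norm (0-based), normalised per unit energy
// (Hartree), i.e. P ~ sqrt(2/(pi k)) sin(...) asymptotically.
// [[Rcpp::export]]
NumericVector cpp_continuum_wave(NumericVector r, NumericVector V, int l,
                                 double energy, int i_norm) {
  int n = r.size();
  double h = std::log(r[1] / r[0]);
  double lph2 = (l + 0.5) * (l + 0.5);
  std::vector<double> W(n), y(n);
  for (int i = 0; i < n; ++i) W[i] = Wval(r[i], V[i], energy, lph2);
  double fac = h * h / 12.0;
  y[0] = std::pow(r[0], l + 0.5);
  y[1] = std::pow(r[1], l + 0.5);
  // integrate only slightly beyond the normalisation point: at high
  // energies the coarse outer grid cannot carry the oscillation further
  int i_stop = std::min(n - 1, i_norm + 8);
  for (int i = 1; i < i_stop; ++i) {
    y[i + 1] = ((2.0 + 10.0 * fac * W[i]) * y[i] -
                (1.0 - fac * W[i - 1]) * y[i - 1]) /
               (1.0 - fac * W[i + 1]);
    if (std::fabs(y[i + 1]) > 1e200) {
      for (int j = 0; j <= i + 1; ++j) y[j] *= 1e-200;
    }
  }
  for (int i = i_stop + 1; i < n; ++i) y[i] = 0.0;
  // local amplitude A^2 = P^2 + (P'/k)^2 averaged over several points
  int i0 = std::max(2, i_norm - 6), i1 = std::min(n - 3, i_norm + 6);
  double A2sum = 0.0; int cnt = 0;
  for (int i = i0; i <= i1; ++i) {
    double k2 = 2.0 * (energy - V[i]) - l * (l + 1) / (r[i] * r[i]);
    if (k2 <= 0) continue;
    double k = std::sqrt(k2);
    double P = y[i] * std::sqrt(r[i]);
    double dydx = (y[i + 1] - y[i - 1]) / (2.0 * h);
    double dPdr = std::sqrt(r[i]) * (dydx + 0.5 * y[i]) / r[i];
    A2sum += P * P + (dPdr / k) * (dPdr / k);
    ++cnt;
  }
  if (cnt == 0) stop("continuum normalisation failed: classically forbidden at i_norm");
  double A2 = A2sum / cnt;
  double k2n = 2.0 * (energy - V[i_norm]) - l * (l + 1) / (r[i_norm] * r[i_norm]);
  double kn = std::sqrt(std::max(k2n, 1e-300));
  double target = std::sqrt(2.0 / (M_PI * kn));
  double scale = target / std::sqrt(A2);
  NumericVector P(n);
  for (int i = 0; i < n; ++i) P[i] = y[i] * std::sqrt(r[i]) * scale;
  return P;
}
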