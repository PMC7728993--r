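// Fixed-step RK4 integration of the full neuronal + hemodynamic cascade on
// the microtime grid. Inputs are zero-order-held over each micro step.
// Hemodynamic states f, v, q are propagated in log coordinates (the exact
// transform of the balloon equations), which keeps them positive under the
// extreme parameter proposals that occur during inversion.
//
// State layout: [neuronal block | s (l) | log f (l) | log v (l) | log q (l)]
// where the neuronal block is z (l) for single-state models or
// [zE (l), zI (l)] for two-state models. Hemodynamics are driven by z
// (single-state) or zE (two-state).
//
// Boxcar inputs are piecewise constant, so the input-dependent quantities
// (effective coupling matrices, driving term C u) are re-assembled only
// when the input vector actually changes between steps.

#include <RcppArmadillo.h>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct NeuroModel {
  int variant;     // 0 bilinear, 1 wilson_cowan
  int states;      // 1 or 2
  int l, m;
  // single-state
  mat A;
  std::vector<mat> B;
  mat C;
  vec alpha;
  // two-state
  mat wEE;
  std::vector<mat> bEE;
  vec wSE, wSI, wIE, wEI;
  std::vector<vec> bIE;
  vec alphaE, alphaI;
  // caches, refreshed when u changes
  mat Aeff;        // single-state effective coupling
  mat wEEeff;      // two-state effective extrinsic coupling
  vec wIEeff;
  vec Cu;

  void refresh(const double* u) {
    Cu.zeros(l);
    for (int j = 0; j < m; ++j)
      if (u[j] != 0.0) Cu += u[j] * C.col(j);
    if (states == 1) {
      Aeff = A;
      for (int j = 0; j < m; ++j)
        if (u[j] != 0.0) Aeff += u[j] * B[j];
    } else {
      mat bsum(l, l, fill::zeros);
      vec esum(l, fill::zeros);
      bool mod = false;
      for (int j = 0; j < m; ++j) {
        if (u[j] != 0.0) {
          bsum += u[j] * bEE[j];
          esum += u[j] * bIE[j];
          mod = true;
        }
      }
      wEEeff = mod ? mat(wEE % exp(bsum)) : wEE;
      wEEeff.diag().zeros();
      wIEeff = mod ? vec(wIE % exp(esum)) : wIE;
    }
  }
};

struct HemoModel {
  vec kappa, gamma, tauH;
  double alphaG, rho, V0, k1, k2, k3;
  double log1mrho;
};

// full-state drift with cached input terms; x and dx of length nz + 4l
inline void fullDrift(const NeuroModel& nm, const HemoModel& hm,
                      const double* x, double* dx) {
  const int l = nm.l;
  const int nz = (nm.states == 1) ? l : 2 * l;
  if (nm.states == 1) {
    for (int i = 0; i < l; ++i) {
      double xi = nm.Cu[i];
      for (int j = 0; j < l; ++j) xi += nm.Aeff(i, j) * x[j];
      if (nm.variant == 0) dx[i] = xi;
      else dx[i] = -x[i] + 0.5 * std::tanh(0.5 * nm.alpha[i] * xi);
    }
  } else {
    const double* zE = x;
    const double* zI = x + l;
    for (int i = 0; i < l; ++i) {
      double ext = nm.Cu[i];
      for (int j = 0; j < l; ++j) ext += nm.wEEeff(i, j) * zE[j];
      if (nm.variant == 0) {
        dx[i] = ext - nm.wSE[i] * zE[i] - nm.wIEeff[i] * zI[i];
        dx[l + i] = nm.wEI[i] * zE[i] - nm.wSI[i] * zI[i];
      } else {
        double xE = ext + nm.wSE[i] * zE[i] - nm.wIEeff[i] * zI[i];
        double xI = nm.wEI[i] * zE[i] - nm.wSI[i] * zI[i];
        dx[i] = -zE[i] + 0.5 * std::tanh(0.5 * nm.alphaE[i] * xE);
        dx[l + i] = -zI[i] + 0.5 * std::tanh(0.5 * nm.alphaI[i] * xI);
      }
    }
  }
  // The balloon equations are singular as f -> 0 (sustained strongly
  // negative drive); log-states are clamped to +/- 5 inside the drift,
  // far outside the physiological range, so ordinary trajectories are
  // untouched while pathological parameter proposals stay integrable.
  const double CLAMP = 5.0;
  for (int i = 0; i < l; ++i) {
    double zi = x[i];  // z or zE of region i
    double s = x[nz + i];
    double lf = std::clamp(x[nz + l + i], -CLAMP, CLAMP);
    double lv = std::clamp(x[nz + 2 * l + i], -CLAMP, CLAMP);
    double lq = std::clamp(x[nz + 3 * l + i], -CLAMP, CLAMP);
    double f = std::exp(lf);
    double v = std::exp(lv);
    double q = std::exp(lq);
    double E = 1.0 - std::exp(hm.log1mrho / f);
    double fout = std::exp(lv / hm.alphaG);
    dx[nz + i] = zi - hm.kappa[i] * s - hm.gamma[i] * (f - 1.0);
    dx[nz + l + i] = s / f;
    dx[nz + 2 * l + i] = (f - fout) / (hm.tauH[i] * v);
    dx[nz + 3 * l + i] = (f * E / hm.rho - fout * q / v) / (hm.tauH[i] * q);
  }
}

}  // namespace

// [[Rcpp::export(name = ".dcmIntegrateCpp")]]
Rcpp::List dcmIntegrateCpp(Rcpp::List neuro, Rcpp::List hemo,
                           const arma::mat& U, double dt, int nSteps,
                           const arma::ivec& sampleSteps, bool keepLatent) {
  NeuroModel nm;
  nm.variant = Rcpp::as<int>(neuro["variant"]);
  nm.states = Rcpp::as<int>(neuro["states"]);
  nm.l = Rcpp::as<int>(neuro["l"]);
  nm.m = Rcpp::as<int>(neuro["m"]);
  if (nm.states == 1) {
    nm.A = Rcpp::as<mat>(neuro["A"]);
    Rcpp::List Bl = neuro["B"];
    for (int j = 0; j < nm.m; ++j) nm.B.push_back(Rcpp::as<mat>(Bl[j]));
    nm.C = Rcpp::as<mat>(neuro["C"]);
    nm.alpha = Rcpp::as<vec>(neuro["alpha"]);
  } else {
    nm.wEE = Rcpp::as<mat>(neuro["wEE"]);
    Rcpp::List bl = neuro["bEE"];
    for (int j = 0; j < nm.m; ++j) nm.bEE.push_back(Rcpp::as<mat>(bl[j]));
    nm.wSE = Rcpp::as<vec>(neuro["wSE"]);
    nm.wSI = Rcpp::as<vec>(neuro["wSI"]);
    nm.wIE = Rcpp::as<vec>(neuro["wIE"]);
    nm.wEI = Rcpp::as<vec>(neuro["wEI"]);
    Rcpp::List il = neuro["bIE"];
    for (int j = 0; j < nm.m; ++j) nm.bIE.push_back(Rcpp::as<vec>(il[j]));
    nm.C = Rcpp::as<mat>(neuro["C"]);
    nm.alphaE = Rcpp::as<vec>(neuro["alphaE"]);
    nm.alphaI = Rcpp::as<vec>(neuro["alphaI"]);
  }
  HemoModel hm;
  hm.kappa = Rcpp::as<vec>(hemo["kappa"]);
  hm.gamma = Rcpp::as<vec>(hemo["gamma"]);
  hm.tauH = Rcpp::as<vec>(hemo["tauH"]);
  hm.alphaG = Rcpp::as<double>(hemo["alphaG"]);
  hm.rho = Rcpp::as<double>(hemo["rho"]);
  hm.V0 = Rcpp::as<double>(hemo["V0"]);
  hm.k1 = Rcpp::as<double>(hemo["k1"]);
  hm.k2 = Rcpp::as<double>(hemo["k2"]);
  hm.k3 = Rcpp::as<double>(hemo["k3"]);
  hm.log1mrho = std::log(1.0 - hm.rho);

  const int l = nm.l;
  const int m = nm.m;
  const int nz = (nm.states == 1) ? l : 2 * l;
  const int nx = nz + 4 * l;
  std::vector<double> x(nx, 0.0);  // rest: neuronal 0, s = 0, logs 0
  std::vector<double> k1(nx), k2(nx), k3(nx), k4(nx), xt(nx);
  std::vector<double> uPrev(m, std::numeric_limits<double>::quiet_NaN());

  const int nSamp = sampleSteps.n_elem;
  mat y(nSamp, l, fill::zeros);
  mat zlat;
  if (keepLatent) zlat.zeros(nSamp, nz);

  int sIdx = 0;
  bool diverged = false;
  int badStep = -1;

  for (int step = 0; step < nSteps; ++step) {
    int ucol = std::min(step, (int)U.n_cols - 1);
    const double* u = U.colptr(ucol);
    bool changed = false;
    for (int j = 0; j < m; ++j)
      if (u[j] != uPrev[j]) { changed = true; break; }
    if (changed) {
      nm.refresh(u);
      std::copy(u, u + m, uPrev.begin());
    }
    fullDrift(nm, hm, x.data(), k1.data());
    for (int i = 0; i < nx; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
    fullDrift(nm, hm, xt.data(), k2.data());
    for (int i = 0; i < nx; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
    fullDrift(nm, hm, xt.data(), k3.data());
    for (int i = 0; i < nx; ++i) xt[i] = x[i] + dt * k3[i];
    fullDrift(nm, hm, xt.data(), k4.data());
    bool bad = false;
    for (int i = 0; i < nx; ++i) {
      x[i] += (dt / 6.0) * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e6) bad = true;
    }
    // keep the hemodynamic log-states in a recoverable band (inactive for
    // ordinary trajectories, |log state| < 1)
    for (int i = nz + l; i < nx; ++i) x[i] = std::clamp(x[i], -6.0, 6.0);
    if (bad) { diverged = true; badStep = step + 1; break; }
    if (sIdx < nSamp && step + 1 == sampleSteps[sIdx]) {
      for (int i = 0; i < l; ++i) {
        double v = std::exp(x[nz + 2 * l + i]);
        double q = std::exp(x[nz + 3 * l + i]);
        y(sIdx, i) = 100.0 * hm.V0 *
          (hm.k1 * (1.0 - q) + hm.k2 * (1.0 - q / v) + hm.k3 * (1.0 - v));
      }
      if (keepLatent)
        for (int i = 0; i < nz; ++i) zlat(sIdx, i) = x[i];
      ++sIdx;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("y") = y,
    Rcpp::Named("latent") = zlat,
    Rcpp::Named("diverged") = diverged,
    Rcpp::Named("badStep") = badStep);
}
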