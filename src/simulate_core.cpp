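#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coupled torsional-pendulum chains with an energy-threshold bond rule.
// This mirrors the R-level rhs()/rk4_step()/update_bonds() exactly; the R
// test suite checks the two paths agree to machine precision.

struct Model {
  int n;
  const double *I1, *I2, *R1, *R2, *K1, *K2, *k12, *b1, *b2, *Ecr;
  double F0, omega;
  bool conservative, delta_both;

  // backbone torque for one chain; conservative mode uses segment springs
  // K_seg(i) = K[i] (force = -grad of the segment potential), literal mode
  // the printed second-difference form. Identical for uniform K.
  void backbone(const std::vector<double>& phi, const double* K,
                std::vector<double>& out) const {
    if (conservative) {
      out[0] = K[0] * (phi[1] - phi[0]);
      out[n - 1] = -K[n - 2] * (phi[n - 1] - phi[n - 2]);
      for (int i = 1; i < n - 1; ++i)
        out[i] = K[i - 1] * (phi[i - 1] - phi[i]) + K[i] * (phi[i + 1] - phi[i]);
    } else {
      out[0] = K[0] * (phi[1] - phi[0]);
      out[n - 1] = K[n - 1] * (phi[n - 2] - phi[n - 1]);
      for (int i = 1; i < n - 1; ++i)
        out[i] = K[i] * (phi[i - 1] - 2.0 * phi[i] + phi[i + 1]);
    }
  }

  void accel(const std::vector<double>& phi1, const std::vector<double>& phi2,
             const std::vector<double>& v1, const std::vector<double>& v2,
             const std::vector<int>& delta, double t,
             std::vector<double>& a1, std::vector<double>& a2,
             std::vector<double>& bb1, std::vector<double>& bb2) const {
    backbone(phi1, K1, bb1);
    backbone(phi2, K2, bb2);
    const double drive = F0 * std::cos(omega * t);
    for (int i = 0; i < n; ++i) {
      const double d = (double)delta[i];
      const double dg = delta_both ? d : 1.0;
      const double kRR = k12[i] * R1[i] * R2[i];
      const double srel = std::sin(phi1[i] - phi2[i]);
      double tq1 = bb1[i] - d * k12[i] * R1[i] * (R1[i] + R2[i]) * std::sin(phi1[i]) +
                   dg * kRR * srel - b1[i] * v1[i] + drive;
      double rel2 = conservative ? -dg * kRR * srel : dg * kRR * srel;
      double tq2 = bb2[i] + d * k12[i] * R2[i] * (R1[i] + R2[i]) * std::sin(phi2[i]) +
                   rel2 - b2[i] * v2[i] + drive;
      a1[i] = tq1 / I1[i];
      a2[i] = tq2 / I2[i];
    }
  }
};

// [[Rcpp::export]]
List simulate_core(NumericVector phi1_, NumericVector phi2_,
                   NumericVector v1_, NumericVector v2_, IntegerVector delta_,
                   NumericVector I1, NumericVector I2,
                   NumericVector R1, NumericVector R2,
                   NumericVector K1, NumericVector K2,
                   NumericVector k12, NumericVector beta1, NumericVector beta2,
                   NumericVector Ecr,
                   double F0, double omega, double t0, double tau,
                   int m, int stride,
                   bool conservative, bool delta_both,
                   IntegerVector group_lo, IntegerVector group_hi,
                   bool record_mask, bool record_energy) {
  const int n = phi1_.size();
  const int ngrp = group_lo.size();
  Model mod{n, REAL(I1), REAL(I2), REAL(R1), REAL(R2), REAL(K1), REAL(K2),
            REAL(k12), REAL(beta1), REAL(beta2), REAL(Ecr),
            F0, omega, conservative, delta_both};

  std::vector<double> phi1(phi1_.begin(), phi1_.end());
  std::vector<double> phi2(phi2_.begin(), phi2_.end());
  std::vector<double> v1(v1_.begin(), v1_.end());
  std::vector<double> v2(v2_.begin(), v2_.end());
  std::vector<int> delta(delta_.begin(), delta_.end());

  const int nsamp = m / stride;
  NumericMatrix q(nsamp, ngrp);
  LogicalMatrix mask(record_mask ? nsamp : 0, record_mask ? n : 0);
  NumericMatrix energy(record_energy ? nsamp : 0, record_energy ? n : 0);
  NumericVector times(nsamp);

  // RK4 work arrays
  std::vector<double> a1(n), a2(n), bb1(n), bb2(n);
  std::vector<double> p1(n), p2(n), w1(n), w2(n);
  std::vector<double> dphi1(n), dphi2(n), dv1(n), dv2(n);

  double t = t0;
  int isamp = 0;
  for (int step = 1; step <= m; ++step) {
    // stage 1
    mod.accel(phi1, phi2, v1, v2, delta, t, a1, a2, bb1, bb2);
    for (int i = 0; i < n; ++i) {
      dphi1[i] = v1[i]; dphi2[i] = v2[i]; dv1[i] = a1[i]; dv2[i] = a2[i];
      p1[i] = phi1[i] + 0.5 * tau * v1[i];
      p2[i] = phi2[i] + 0.5 * tau * v2[i];
      w1[i] = v1[i] + 0.5 * tau * a1[i];
      w2[i] = v2[i] + 0.5 * tau * a2[i];
    }
    // stage 2
    mod.accel(p1, p2, w1, w2, delta, t + 0.5 * tau, a1, a2, bb1, bb2);
    for (int i = 0; i < n; ++i) {
      dphi1[i] += 2.0 * w1[i]; dphi2[i] += 2.0 * w2[i];
      dv1[i] += 2.0 * a1[i];  dv2[i] += 2.0 * a2[i];
      double np1 = phi1[i] + 0.5 * tau * w1[i];
      double np2 = phi2[i] + 0.5 * tau * w2[i];
      double nw1 = v1[i] + 0.5 * tau * a1[i];
      double nw2 = v2[i] + 0.5 * tau * a2[i];
      p1[i] = np1; p2[i] = np2; w1[i] = nw1; w2[i] = nw2;
    }
    // stage 3
    mod.accel(p1, p2, w1, w2, delta, t + 0.5 * tau, a1, a2, bb1, bb2);
    for (int i = 0; i < n; ++i) {
      dphi1[i] += 2.0 * w1[i]; dphi2[i] += 2.0 * w2[i];
      dv1[i] += 2.0 * a1[i];  dv2[i] += 2.0 * a2[i];
      double np1 = phi1[i] + tau * w1[i];
      double np2 = phi2[i] + tau * w2[i];
      double nw1 = v1[i] + tau * a1[i];
      double nw2 = v2[i] + tau * a2[i];
      p1[i] = np1; p2[i] = np2; w1[i] = nw1; w2[i] = nw2;
    }
    // stage 4
    mod.accel(p1, p2, w1, w2, delta, t + tau, a1, a2, bb1, bb2);
    for (int i = 0; i < n; ++i) {
      phi1[i] += tau / 6.0 * (dphi1[i] + w1[i]);
      phi2[i] += tau / 6.0 * (dphi2[i] + w2[i]);
      v1[i] += tau / 6.0 * (dv1[i] + a1[i]);
      v2[i] += tau / 6.0 * (dv2[i] + a2[i]);
    }
    t = t0 + step * tau;
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(phi1[i]) || !std::isfinite(phi2[i]) ||
          !std::isfinite(v1[i]) || !std::isfinite(v2[i]))
        stop("integration diverged at t = %g s, position %d", t, i + 1);
    }

    // bond break/restore (strict inequalities; ties leave delta unchanged)
    for (int i = 0; i < n; ++i) {
      double e = k12[i] * R1[i] * R2[i] * (1.0 + std::cos(phi1[i] - phi2[i]));
      if (e > Ecr[i]) delta[i] = 0;
      else if (delta[i] == 0 && e < Ecr[i]) delta[i] = 1;
    }

    if (step % stride == 0 && isamp < nsamp) {
      times[isamp] = t;
      int run = 0;
      // per-group occupancy from maximal broken runs
      std::vector<int> grp_broken(ngrp, 0);
      for (int i = 0; i <= n; ++i) {
        bool broken = (i < n) && (delta[i] == 0);
        if (broken) {
          ++run;
        } else if (run > 0) {
          for (int g = 0; g < ngrp; ++g)
            if (run >= group_lo[g] && run <= group_hi[g]) grp_broken[g] += run;
          run = 0;
        }
      }
      for (int g = 0; g < ngrp; ++g)
        q(isamp, g) = (double)grp_broken[g] / (double)n;
      if (record_mask)
        for (int i = 0; i < n; ++i) mask(isamp, i) = (delta[i] == 0);
      if (record_energy)
        for (int i = 0; i < n; ++i)
          energy(isamp, i) = k12[i] * R1[i] * R2[i] * (1.0 + std::cos(phi1[i] - phi2[i]));
      ++isamp;
    }
  }

  List out = List::create(
    _["times"] = times, _["q"] = q,
    _["phi1"] = NumericVector(phi1.begin(), phi1.end()),
    _["phi2"] = NumericVector(phi2.begin(), phi2.end()),
    _["v1"] = NumericVector(v1.begin(), v1.end()),
    _["v2"] = NumericVector(v2.begin(), v2.end()),
    _["delta"] = IntegerVector(delta.begin(), delta.end()),
    _["t"] = t);
  if (record_mask) out["mask"] = mask;
  if (record_energy) out["energy"] = energy;
  return out;
}
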