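#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-region, four-population conductance-based canonical microcircuit.
// Population order (region-major): ss, sp, ii, dp for region 1, then region 2.
// State layout: V[0..7], gAMPA[8..15], gGABA[16..23], gNMDA[24..31].

static const int NPOP = 8;
static const int NSTATE = 32;

struct CmmPars {
  const double *SA, *SG, *SN;       // 8x8 column-major coupling (target row, source col)
  const double *alpha;              // exp(blk) per population (shared within region)
  const double *tauA, *tauG, *tauN; // ms, per population
  const double *Cm, *gL;            // capacitance, leak conductance per population
  double VL, VA, VG, VN;            // reversal potentials (mV)
  double mg_num;                    // numerator of the magnesium switch
  double sig_slope, sig_thresh;     // firing sigmoid
  const double *u_w;                // input weight per population (dV/dt)
  int u_into_g;                     // deliver u to conductance equations too
};

static inline double mg_switch_c(double V, double alpha, double num) {
  return num / (1.0 + 0.33 * std::exp(-0.06 * alpha * V));
}

static inline double firing_c(double V, double slope, double thresh) {
  return 1.0 / (1.0 + std::exp(-slope * (V - thresh)));
}

static void cmm_drift(const double *x, double u, const CmmPars &p, double *dx) {
  double sig[NPOP];
  for (int k = 0; k < NPOP; ++k)
    sig[k] = firing_c(x[k], p.sig_slope, p.sig_thresh);

  for (int i = 0; i < NPOP; ++i) {
    double V  = x[i];
    double gA = x[8 + i], gG = x[16 + i], gN = x[24 + i];
    double m  = mg_switch_c(V, p.alpha[i], p.mg_num);
    double ui = u * p.u_w[i];

    dx[i] = (p.gL[i] * (p.VL - V) + gA * (p.VA - V) + gG * (p.VG - V) +
             gN * m * (p.VN - V)) / p.Cm[i] + ui;

    double dA = 0.0, dG = 0.0, dN = 0.0;
    for (int k = 0; k < NPOP; ++k) {
      double s = sig[k];
      dA += p.SA[i + NPOP * k] * s;
      dG += p.SG[i + NPOP * k] * s;
      dN += p.SN[i + NPOP * k] * s;
    }
    double ug = p.u_into_g ? ui : 0.0;
    dx[8 + i]  = (dA - gA) / p.tauA[i] + ug;
    dx[16 + i] = (dG - gG) / p.tauG[i] + ug;
    dx[24 + i] = (dN - gN) / p.tauN[i] + ug;
  }
}

static CmmPars unpack(const NumericMatrix &SA, const NumericMatrix &SG,
                      const NumericMatrix &SN, const NumericVector &alpha,
                      const NumericVector &tauA, const NumericVector &tauG,
                      const NumericVector &tauN, const NumericVector &Cm,
                      const NumericVector &gL, const NumericVector &Vrev,
                      double mg_num, double sig_slope, double sig_thresh,
                      const NumericVector &u_w, int u_into_g) {
  CmmPars p;
  p.SA = SA.begin(); p.SG = SG.begin(); p.SN = SN.begin();
  p.alpha = alpha.begin();
  p.tauA = tauA.begin(); p.tauG = tauG.begin(); p.tauN = tauN.begin();
  p.Cm = Cm.begin(); p.gL = gL.begin();
  p.VL = Vrev[0]; p.VA = Vrev[1]; p.VG = Vrev[2]; p.VN = Vrev[3];
  p.mg_num = mg_num; p.sig_slope = sig_slope; p.sig_thresh = sig_thresh;
  p.u_w = u_w.begin(); p.u_into_g = u_into_g;
  return p;
}

// [[Rcpp::export]]
NumericVector cmm_drift_cpp(NumericVector state, double u,
                            NumericMatrix SA, NumericMatrix SG, NumericMatrix SN,
                            NumericVector alpha, NumericVector tauA,
                            NumericVector tauG, NumericVector tauN,
                            NumericVector Cm, NumericVector gL,
                            NumericVector Vrev, double mg_num,
                            double sig_slope, double sig_thresh,
                            NumericVector u_w, int u_into_g) {
  if (state.size() != NSTATE) stop("state must have length 32");
  CmmPars p = unpack(SA, SG, SN, alpha, tauA, tauG, tauN, Cm, gL, Vrev,
                     mg_num, sig_slope, sig_thresh, u_w, u_into_g);
  NumericVector dx(NSTATE);
  cmm_drift(state.begin(), u, p, dx.begin());
  return dx;
}

// Fixed-step RK4 over t = 0, dt, ..., (nt-1)*dt with a Gaussian-bump input
// u(t) = u_amp * exp(-((t - u_onset)^2) / (2 u_width^2)).
// Returns the membrane-potential trajectory (nt x 8) with attribute
// "diverged" set if any |V| exceeds v_bound.
// [[Rcpp::export]]
NumericMatrix cmm_integrate_cpp(NumericVector state0, double dt, int nt,
                                double u_onset, double u_width, double u_amp,
                                NumericMatrix SA, NumericMatrix SG, NumericMatrix SN,
                                NumericVector alpha, NumericVector tauA,
                                NumericVector tauG, NumericVector tauN,
                                NumericVector Cm, NumericVector gL,
                                NumericVector Vrev, double mg_num,
                                double sig_slope, double sig_thresh,
                                NumericVector u_w, int u_into_g,
                                double v_bound) {
  if (state0.size() != NSTATE) stop("state0 must have length 32");
  CmmPars p = unpack(SA, SG, SN, alpha, tauA, tauG, tauN, Cm, gL, Vrev,
                     mg_num, sig_slope, sig_thresh, u_w, u_into_g);

  NumericMatrix out(nt, NPOP);
  double x[NSTATE], k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], tmp[NSTATE];
  for (int i = 0; i < NSTATE; ++i) x[i] = state0[i];
  bool diverged = false;

  for (int s = 0; s < nt; ++s) {
    for (int i = 0; i < NPOP; ++i) out(s, i) = x[i];
    for (int i = 0; i < NPOP; ++i)
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > v_bound) diverged = true;
    if (diverged) {
      for (int r = s; r < nt; ++r)
        for (int i = 0; i < NPOP; ++i) out(r, i) = NA_REAL;
      break;
    }
    if (s == nt - 1) break;

    double t = s * dt;
    double zh = (t + 0.5 * dt - u_onset) / u_width;
    double zf = (t + dt - u_onset) / u_width;
    double z0 = (t - u_onset) / u_width;
    double u0 = u_amp * std::exp(-0.5 * z0 * z0);
    double uh = u_amp * std::exp(-0.5 * zh * zh);
    double uf = u_amp * std::exp(-0.5 * zf * zf);

    cmm_drift(x, u0, p, k1);
    for (int i = 0; i < NSTATE; ++i) tmp[i] = x[i] + 0.5 * dt * k1[i];
    cmm_drift(tmp, uh, p, k2);
    for (int i = 0; i < NSTATE; ++i) tmp[i] = x[i] + 0.5 * dt * k2[i];
    cmm_drift(tmp, uh, p, k3);
    for (int i = 0; i < NSTATE; ++i) tmp[i] = x[i] + dt * k3[i];
    cmm_drift(tmp, uf, p, k4);
    for (int i = 0; i < NSTATE; ++i)
      x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  }

  out.attr("diverged") = diverged;
  return out;
}
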