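// Coupled two-neuron / one-astrocyte model: right-hand side and fixed-step
// RK4 integrator.  All dynamics are integrated in milliseconds; astrocyte
// rate constants quoted per second in the parameter table are converted by
// the R-side parameter constructor before they reach this file.
//
// State layout (13 components):
//   0 v1  1 m1  2 h1  3 n1   4 v2  5 m2  6 h2  7 n2
//   8 s1 (excitatory gate, driven by N1)   9 s2 (inhibitory gate, driven by N2)
//  10 C (uM) 11 q 12 P (uM)

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 13;

struct Params {
  double Cm, gNa, gK, gL, vNa, vK, vL;
  double thetaS, sigmaS, alphaS, betaS;
  double gse, gsi, Eexc, Einh;
  double c0, c1, va, vb, vc, d1, d2, d3, d5, a2, k3;   // per-ms rates
  double P0, tauP, rP;                                  // per-ms rates
  double lambda, Ie1, Ie2, kAstro, Ctheta, vg;
  int trigger;       // 0: Heaviside(v1 - vg); 1: sigmoid T(v1)
  int freezeAstro;   // 1: hold C, q, P fixed
};

static Params unpackParams(const NumericVector& p) {
  Params q;
  q.Cm = p["Cm"];   q.gNa = p["gNa"]; q.gK = p["gK"]; q.gL = p["gL"];
  q.vNa = p["vNa"]; q.vK = p["vK"];   q.vL = p["vL"];
  q.thetaS = p["thetaS"]; q.sigmaS = p["sigmaS"];
  q.alphaS = p["alphaS"]; q.betaS = p["betaS"];
  q.gse = p["gse"]; q.gsi = p["gsi"]; q.Eexc = p["Eexc"]; q.Einh = p["Einh"];
  q.c0 = p["c0"]; q.c1 = p["c1"]; q.va = p["va"]; q.vb = p["vb"]; q.vc = p["vc"];
  q.d1 = p["d1"]; q.d2 = p["d2"]; q.d3 = p["d3"]; q.d5 = p["d5"];
  q.a2 = p["a2"]; q.k3 = p["k3"];
  q.P0 = p["P0"]; q.tauP = p["tauP"]; q.rP = p["rP"];
  q.lambda = p["lambda"]; q.Ie1 = p["Ie1"]; q.Ie2 = p["Ie2"];
  q.kAstro = p["kAstro"]; q.Ctheta = p["Ctheta"]; q.vg = p["vg"];
  q.trigger = (int) p["trigger"];
  q.freezeAstro = (int) p["freezeAstro"];
  return q;
}

// Shifted-frame squid-axon gate rates (1/ms); removable singularities at
// v = 25 (alpha_m) and v = 10 (alpha_n) replaced by their limits.
static inline void gateRates(double v, double* r) {
  double um = 25.0 - v;
  r[0] = (std::fabs(um) < 1e-7) ? 1.0 : 0.1 * um / (std::exp(um / 10.0) - 1.0);
  r[1] = 4.0 * std::exp(-v / 18.0);
  r[2] = 0.07 * std::exp(-v / 20.0);
  r[3] = 1.0 / (std::exp((30.0 - v) / 10.0) + 1.0);
  double un = 10.0 - v;
  r[4] = (std::fabs(un) < 1e-7) ? 0.1 : 0.01 * un / (std::exp(un / 10.0) - 1.0);
  r[5] = 0.125 * std::exp(-v / 80.0);
}

static inline double transmitter(double v, const Params& p) {
  return 1.0 / (1.0 + std::exp(-(v - p.thetaS) / p.sigmaS));
}

static inline double astroCurrent(double C, const Params& p) {
  double y = C * 1000.0 - p.Ctheta;   // nM above threshold
  return (y > 1.0) ? p.kAstro * std::log(y) : 0.0;
}

struct Currents {
  double Is1, Is2, Iastro, Ia1, Ia2, Itot1;
};

static void deriv(const double* s, const Params& p, double* ds, Currents* cur) {
  double v1 = s[0], m1 = s[1], h1 = s[2], n1 = s[3];
  double v2 = s[4], m2 = s[5], h2 = s[6], n2 = s[7];
  double s1 = s[8], s2 = s[9];
  double C = s[10], q = s[11], P = s[12];

  double Iastro = astroCurrent(C, p);
  double Ia1 = -p.lambda * Iastro;     // inhibits the pyramidal cell
  double Ia2 =  p.lambda * Iastro;     // excites the interneuron
  double Is1 = p.gsi * s2 * (p.Einh - v1);
  double Is2 = p.gse * s1 * (p.Eexc - v2);

  double r[6];
  // neuron 1
  gateRates(v1, r);
  double Iion1 = -p.gNa * m1 * m1 * m1 * h1 * (v1 - p.vNa)
                 - p.gK * n1 * n1 * n1 * n1 * (v1 - p.vK)
                 - p.gL * (v1 - p.vL);
  ds[0] = (Iion1 + p.Ie1 + Ia1 + Is1) / p.Cm;
  ds[1] = r[0] * (1.0 - m1) - r[1] * m1;
  ds[2] = r[2] * (1.0 - h1) - r[3] * h1;
  ds[3] = r[4] * (1.0 - n1) - r[5] * n1;
  // neuron 2
  gateRates(v2, r);
  double Iion2 = -p.gNa * m2 * m2 * m2 * h2 * (v2 - p.vNa)
                 - p.gK * n2 * n2 * n2 * n2 * (v2 - p.vK)
                 - p.gL * (v2 - p.vL);
  ds[4] = (Iion2 + p.Ie2 + Ia2 + Is2) / p.Cm;
  ds[5] = r[0] * (1.0 - m2) - r[1] * m2;
  ds[6] = r[2] * (1.0 - h2) - r[3] * h2;
  ds[7] = r[4] * (1.0 - n2) - r[5] * n2;
  // synaptic gates
  ds[8] = p.alphaS * transmitter(v1, p) * (1.0 - s1) - p.betaS * s1;
  ds[9] = p.alphaS * transmitter(v2, p) * (1.0 - s2) - p.betaS * s2;
  // astrocyte (Li-Rinzel + IP3 production)
  if (p.freezeAstro) {
    ds[10] = ds[11] = ds[12] = 0.0;
  } else {
    double Cer = (p.c0 - C) / p.c1;
    double minf = P / (P + p.d1);
    double ninf = C / (C + p.d5);
    double gate = minf * ninf * q;
    double Jchan = p.c1 * p.va * gate * gate * gate * (Cer - C);
    double Jleak = p.c1 * p.vb * (Cer - C);
    double Jpump = p.vc * C * C / (p.k3 * p.k3 + C * C);
    ds[10] = Jchan + Jleak - Jpump;
    double alphaQ = p.a2 * p.d2 * (P + p.d1) / (P + p.d3);
    ds[11] = alphaQ * (1.0 - q) - p.a2 * C * q;
    double drive = (p.trigger == 1) ? transmitter(v1, p)
                                    : (v1 > p.vg ? 1.0 : 0.0);
    ds[12] = p.tauP * (p.P0 - P) + p.rP * drive;
  }

  if (cur) {
    cur->Is1 = Is1; cur->Is2 = Is2; cur->Iastro = Iastro;
    cur->Ia1 = Ia1; cur->Ia2 = Ia2;
    cur->Itot1 = p.Ie1 + Ia1 + Is1;
  }
}

// Gate / fraction variables: clip tiny numerical overshoot, error otherwise.
static const int GATE_IDX[8] = {1, 2, 3, 5, 6, 7, 8, 9};

static void enforceBounds(double* s, double t) {
  for (int k = 0; k < 8; ++k) {
    int i = GATE_IDX[k];
    if (s[i] < 0.0) {
      if (s[i] > -1e-9) s[i] = 0.0;
      else stop("gate variable %d fell to %g at t = %g ms", i + 1, s[i], t);
    } else if (s[i] > 1.0) {
      if (s[i] < 1.0 + 1e-9) s[i] = 1.0;
      else stop("gate variable %d rose to %g at t = %g ms", i + 1, s[i], t);
    }
  }
  // q of the astrocyte shares the fraction invariant
  if (s[11] < 0.0 && s[11] > -1e-9) s[11] = 0.0;
  if (s[11] > 1.0 && s[11] < 1.0 + 1e-9) s[11] = 1.0;
  for (int i = 0; i < NSTATE; ++i) {
    if (!std::isfinite(s[i]))
      stop("integration blow-up: state component %d non-finite at t = %g ms",
           i + 1, t);
  }
}

static void rk4(double* s, double dt, const Params& p) {
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], tmp[NSTATE];
  deriv(s, p, k1, nullptr);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
  deriv(tmp, p, k2, nullptr);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
  deriv(tmp, p, k3, nullptr);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = s[i] + dt * k3[i];
  deriv(tmp, p, k4, nullptr);
  for (int i = 0; i < NSTATE; ++i)
    s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// [[Rcpp::export]]
List systemDerivCpp(NumericVector state, NumericVector params) {
  if (state.size() != NSTATE) stop("state must have %d components", NSTATE);
  Params p = unpackParams(params);
  double ds[NSTATE];
  Currents cur;
  deriv(REAL(state), p, ds, &cur);
  NumericVector out(NSTATE);
  for (int i = 0; i < NSTATE; ++i) out[i] = ds[i];
  out.attr("names") = state.attr("names");
  return List::create(
    _["deriv"] = out,
    _["currents"] = NumericVector::create(
      _["Is1"] = cur.Is1, _["Is2"] = cur.Is2, _["Iastro"] = cur.Iastro,
      _["Ia1"] = cur.Ia1, _["Ia2"] = cur.Ia2, _["Itot1"] = cur.Itot1));
}

// [[Rcpp::export]]
NumericVector rk4StepCpp(NumericVector state, NumericVector params, double dt) {
  if (state.size() != NSTATE) stop("state must have %d components", NSTATE);
  Params p = unpackParams(params);
  NumericVector out = clone(state);
  rk4(REAL(out), dt, p);
  enforceBounds(REAL(out), dt);
  return out;
}

// Integrate for `nsteps` steps of size dt, recording every `stride`-th step
// (always including step 0 and the final step).  Returns a matrix with one
// row per record: t + 13 state components + 6 current diagnostics.
// [[Rcpp::export]]
NumericMatrix simulateCpp(NumericVector state, NumericVector params,
                          double dt, int nsteps, int stride, double t0) {
  if (state.size() != NSTATE) stop("state must have %d components", NSTATE);
  if (nsteps < 1) stop("nsteps must be positive");
  if (stride < 1) stop("stride must be >= 1");
  Params p = unpackParams(params);

  int nrec = nsteps / stride + 1 + (nsteps % stride != 0 ? 1 : 0);
  NumericMatrix out(nrec, 1 + NSTATE + 6);
  double s[NSTATE];
  for (int i = 0; i < NSTATE; ++i) s[i] = state[i];

  int row = 0;
  double ds[NSTATE];
  Currents cur;
  auto record = [&](double t) {
    deriv(s, p, ds, &cur);
    out(row, 0) = t;
    for (int i = 0; i < NSTATE; ++i) out(row, 1 + i) = s[i];
    out(row, 14) = cur.Is1;  out(row, 15) = cur.Is2;
    out(row, 16) = cur.Iastro;
    out(row, 17) = cur.Ia1;  out(row, 18) = cur.Ia2;
    out(row, 19) = cur.Itot1;
    ++row;
  };

  record(t0);
  for (int step = 1; step <= nsteps; ++step) {
    rk4(s, dt, p);
    double t = t0 + step * dt;
    enforceBounds(s, t);
    if (step % stride == 0 || step == nsteps) record(t);
    if (step % 200000 == 0) Rcpp::checkUserInterrupt();
  }
  return out(Range(0, row - 1), _);
}
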