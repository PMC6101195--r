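// Compiled inner loop for the single-compartment stellate cell model.
//
// Unit conventions (documented in ?stellate_model):
//   V mV, t ms, conductance densities mS/cm2, currents uA/cm2 internally
//   (mS/cm2 * mV = uA/cm2), Cm uF/cm2, [Ca] mM, injected current pA
//   (converted to uA/cm2 via inj_scale = 1e-6 / area_cm2).
//
// State layout (length 22):
//   [0]     V
//   [1:14]  gates: NaF m,h; KDR n; HCN mf,ms; NaP m,h; KA m,h; HVA m,h;
//           LVA m,h; KM m
//   [15:20] SK occupancies C1,C2,C3,C4,O1,O2
//   [21]    [Ca]_c (mM)
//
// Parameter vector: the 55 model parameters in the canonical order of
// inst/extdata/parameters.yaml (conductances in their table units; converted
// to mS/cm2 here).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double E_NA = 50.0, E_K = -90.0, E_H = -20.0, E_LEAK = -77.0;
static const double CA_OUT = 2.0;      // mM
static const double CA_INF = 1e-4;     // mM (100 nM)
static const double CA_DEPTH = 0.1;    // um
static const double FARADAY = 96485.33212;
static const double GAS_R = 8.314462618;
static const double TEMP_K = 307.15;   // 34 C
// RT/2F in mV for a divalent ion
static const double GHK_F = 1000.0 * GAS_R * TEMP_K / (2.0 * FARADAY);
// SK transition rates, ms^-1 (alpha = 10 per-uM per-s => 10 * [Ca]_mM ms^-1)
static const double SK_KON_PER_MM = 10.0;
static const double SK_KOFF = 0.5e-3, SK_GAMMA = 600e-3, SK_DELTA = 400e-3;

// x / (1 - exp(-x)) with its removable singularity at x = 0
static inline double vtrap(double x) {
  if (std::fabs(x) < 1e-7) return 1.0 + 0.5 * x;
  return x / (1.0 - std::exp(-x));
}

// z / (exp(z) - 1) with its removable singularity at z = 0
static inline double efun(double z) {
  if (std::fabs(z) < 1e-7) return 1.0 - 0.5 * z;
  return z / (std::exp(z) - 1.0);
}

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(x)); }

// GHK driving-force term for Ca2+ (mV); multiply by a conductance-scale in
// mS/cm2 to obtain a current density in uA/cm2. Negative below the calcium
// Nernst potential (inward current).
static inline double ghk_df(double v, double cai, double cao) {
  double nu = v / GHK_F;
  return -GHK_F * (1.0 - (cai / cao) * std::exp(nu)) * efun(nu);
}

struct Pars {
  // conductances, mS/cm2
  double gNaF, gKDR, gHCN, hcn_ratio, gNaP, gKA, gHVA, gLVA, gKM, gSK, gLeak;
  double Cm, tauCa;
  // gate parameters
  double VmNaF, kmNaF, FmNaF, VhNaF, khNaF, FhNaF;
  double VnKDR, knKDR, FnKDR;
  double VmfH, VmsH, kmfH, kmsH, FmfH, FmsH;
  double VmNaP, kmNaP, FmNaP, VhNaP, khNaP, FhNaP;
  double VmKA, kmKA, FmKA, VhKA, khKA, FhKA;
  double VmHVA, kmHVA, FmHVA, VhHVA, khHVA, FhHVA;
  double VmLVA, kmLVA, FmLVA, VhLVA, khLVA, FhLVA;
  double VmKM, kmKM, FmKM;
  bool ka_betah_printed;
};

static Pars unpack(const NumericVector& p, bool ka_betah_printed) {
  if (p.size() != 55) stop("parameter vector must have length 55");
  Pars q;
  q.gNaF = p[0];  q.VmNaF = p[1];  q.kmNaF = p[2];  q.FmNaF = p[3];
  q.VhNaF = p[4]; q.khNaF = p[5];  q.FhNaF = p[6];
  q.gKDR = p[7];  q.VnKDR = p[8];  q.knKDR = p[9];  q.FnKDR = p[10];
  q.gHCN = p[11] * 1e-3;  q.hcn_ratio = p[12];
  q.VmfH = p[13]; q.VmsH = p[14];  q.kmfH = p[15];  q.kmsH = p[16];
  q.FmfH = p[17]; q.FmsH = p[18];
  q.gNaP = p[19] * 1e-3;  q.VmNaP = p[20]; q.kmNaP = p[21]; q.FmNaP = p[22];
  q.VhNaP = p[23]; q.khNaP = p[24]; q.FhNaP = p[25];
  q.gKA = p[26] * 1e-3;   q.VmKA = p[27];  q.kmKA = p[28];  q.FmKA = p[29];
  q.VhKA = p[30]; q.khKA = p[31];  q.FhKA = p[32];
  q.gHVA = p[33]; q.VmHVA = p[34]; q.kmHVA = p[35]; q.FmHVA = p[36];
  q.VhHVA = p[37]; q.khHVA = p[38]; q.FhHVA = p[39];
  q.gLVA = p[40] * 1e-3;  q.VmLVA = p[41]; q.kmLVA = p[42]; q.FmLVA = p[43];
  q.VhLVA = p[44]; q.khLVA = p[45]; q.FhLVA = p[46];
  q.gKM = p[47];  q.VmKM = p[48];  q.kmKM = p[49];  q.FmKM = p[50];
  q.gSK = p[51] * 1e-3;
  q.gLeak = 1.0 / p[52];  // 1/(kOhm.cm2) = mS/cm2
  q.tauCa = p[53];
  q.Cm = p[54];
  q.ka_betah_printed = ka_betah_printed;
  return q;
}

// Steady states and time constants of the 14 voltage-gated particles at V.
static void gate_rates(const Pars& q, double V, double* xinf, double* tau) {
  // NaF m
  xinf[0] = sigm((q.VmNaF - V) / q.kmNaF);
  {
    double a = 4.0 * vtrap((V + 33.0) / 9.0);
    double b = 27.6 * vtrap(-(V + 58.0) / 12.0);
    tau[0] = q.FmNaF / (a + b);
  }
  // NaF h
  xinf[1] = 1.0 - sigm((q.VhNaF - V) / q.khNaF);
  {
    double a = 0.36 * vtrap(-(V + 48.0) / 12.0);
    double b = 0.4 * vtrap((V + 11.0) / 6.0);
    tau[1] = q.FhNaF / (a + b);
  }
  // KDR n
  xinf[2] = sigm((q.VnKDR - V) / q.knKDR);
  {
    double a = 0.2 * vtrap((V + 38.0) / 10.0);
    double b = 0.6294 * vtrap(-(V + 47.0) / 35.0);
    tau[2] = q.FnKDR / (a + b);
  }
  // HCN fast / slow: fractional powers applied to the whole sigmoid bracket
  xinf[3] = std::pow(1.0 + std::exp((V + q.VmfH) / q.kmfH), -1.36);
  tau[3] = q.FmfH * 0.51 /
    (std::exp((V - 1.7) / 10.0) + std::exp(-(V + 340.0) / 52.0));
  xinf[4] = std::pow(1.0 + std::exp((V + q.VmsH) / q.kmsH), -58.5);
  tau[4] = q.FmsH * 5.6 /
    (std::exp((V - 17.0) / 14.0) + std::exp(-(V + 260.0) / 43.0));
  // NaP m (rate constants in s^-1; tau converted to ms)
  xinf[5] = sigm(-(V + q.VmNaP) / q.kmNaP);
  {
    double a = 455.0 * vtrap((V + 38.0) / 5.0);
    double b = 310.0 * vtrap(-(V + 38.0) / 5.0);
    tau[5] = 1000.0 * q.FmNaP / (a + b);
  }
  // NaP h (rate constants in s^-1; tau converted to ms)
  xinf[6] = sigm((V + q.VhNaP) / q.khNaP);
  {
    double d1 = 1.0 - std::exp((V - 49.1) / 4.63);
    if (std::fabs(d1) < 1e-9) d1 = (d1 < 0) ? -1e-9 : 1e-9;
    double a = -0.00288 * (V + 17.049) / d1;
    double d2 = 1.0 - std::exp(-(V + 447.0) / 2.63);
    if (std::fabs(d2) < 1e-9) d2 = (d2 < 0) ? -1e-9 : 1e-9;
    double b = 0.00694 * (V + 64.409) / d2;
    // the fitted rate sum turns negative below ~-99 mV (outside the fit
    // range of the source data); clamp so tau stays positive (very slow)
    double r = a + b;
    if (r < 1e-4) r = 1e-4;
    tau[6] = 1000.0 * q.FhNaP / r;
  }
  // KA m
  xinf[7] = sigm((q.VmKA - V) / q.kmKA);
  {
    double a = 0.15 * vtrap((V + 18.3) / 15.0);
    double b = 0.15 * vtrap(-(V + 18.3) / 15.0);
    tau[7] = q.FmKA / (a + b);
  }
  // KA h (beta_h uses (V+58); the literal printed (V+8.2) is available
  // behind the ka_betah_as_printed option)
  xinf[8] = 1.0 - sigm((q.VhKA - V) / q.khKA);
  {
    double a = 0.082 * vtrap(-(V + 58.0) / 8.2);
    double shift = q.ka_betah_printed ? 8.2 : 58.0;
    double b = 0.082 * vtrap((V + shift) / 8.2);
    tau[8] = q.FhKA / (a + b);
  }
  // HVA m, h (voltage-independent time constants)
  xinf[9] = sigm(-(q.VmHVA + V) / q.kmHVA);
  tau[9] = 0.92 * q.FmHVA;
  xinf[10] = sigm((q.VhHVA + V) / q.khHVA);
  tau[10] = 250.0 * q.FhHVA;
  // LVA m
  xinf[11] = sigm((q.VmLVA - V) / q.kmLVA);
  tau[11] = q.FmLVA /
    (8.967 * vtrap((V + 7.88) / 10.0) + 0.046 * std::exp(-V / 22.73));
  // LVA h
  xinf[12] = 1.0 - sigm((q.VhLVA - V) / q.khLVA);
  tau[12] = 1.2 * q.FhLVA /
    (1.6e-4 * std::exp(-(V + 79.5) / 20.0) + sigm(-(V + 5.0) / 10.0));
  // KM m (slope negative as defined: activation with depolarization)
  xinf[13] = sigm((V - q.VmKM) / q.kmKM);
  tau[13] = q.FmKM * (60.0 + std::exp(0.10584 * (V + 42.0)) /
    (0.009 * (1.0 + std::exp(0.2646 * (V + 42.0)))));
}

// [[Rcpp::export(name = ".gate_rates_cpp")]]
List gate_rates_cpp(NumericVector params, double V,
                    bool ka_betah_as_printed = false) {
  Pars q = unpack(params, ka_betah_as_printed);
  NumericVector xinf(14), tau(14);
  gate_rates(q, V, xinf.begin(), tau.begin());
  CharacterVector nm = CharacterVector::create(
    "NaF_m", "NaF_h", "KDR_n", "HCN_mf", "HCN_ms", "NaP_m", "NaP_h",
    "KA_m", "KA_h", "HVA_m", "HVA_h", "LVA_m", "LVA_h", "KM_m");
  xinf.names() = nm;
  tau.names() = nm;
  return List::create(_["inf"] = xinf, _["tau"] = tau);
}

// [[Rcpp::export(name = ".ghk_df_cpp")]]
double ghk_df_cpp(double V, double cai, double cao) {
  return ghk_df(V, cai, cao);
}

static void sk_derivs(const double* s, double kon, double* ds) {
  // C1 -[kon]-> C2 -[kon]-> C3 -[kon]-> C4 (backward SK_KOFF);
  // C3 <-> O1 and C4 <-> O2 with SK_GAMMA / SK_DELTA.
  ds[0] = SK_KOFF * s[1] - kon * s[0];
  ds[1] = kon * s[0] + SK_KOFF * s[2] - (SK_KOFF + kon) * s[1];
  ds[2] = kon * s[1] + SK_KOFF * s[3] + SK_DELTA * s[4] -
          (SK_KOFF + kon + SK_GAMMA) * s[2];
  ds[3] = kon * s[2] + SK_DELTA * s[5] - (SK_KOFF + SK_GAMMA) * s[3];
  ds[4] = SK_GAMMA * s[2] - SK_DELTA * s[4];
  ds[5] = SK_GAMMA * s[3] - SK_DELTA * s[5];
}

// Per-channel current densities (uA/cm2) at a given state.
static void channel_currents(const Pars& q, const double* st, double* I) {
  double V = st[0], Ca = st[21];
  const double* g = st + 1;
  double m3h = g[0] * g[0] * g[0] * g[1];
  double n4 = g[2] * g[2]; n4 *= n4;
  double sCa = 0.001 / (0.001 + Ca);
  double df = ghk_df(V, Ca, CA_OUT);
  I[0] = q.gNaF * m3h * (V - E_NA);
  I[1] = q.gKDR * n4 * (V - E_K);
  I[2] = q.gHCN * (g[4] + q.hcn_ratio * g[3]) * (V - E_H);
  I[3] = q.gNaP * g[5] * g[6] * (V - E_NA);
  I[4] = q.gKA * g[7] * g[8] * (V - E_K);
  I[5] = q.gHVA * g[9] * g[9] * g[9] * g[10] * df;
  I[6] = q.gLVA * g[11] * g[11] * g[12] * sCa * df;
  I[7] = q.gKM * g[13] * (V - E_K);
  I[8] = q.gSK * (st[19] + st[20]) * (V - E_K);
  I[9] = q.gLeak * (V - E_LEAK);
}

// [[Rcpp::export(name = ".channel_currents_cpp")]]
NumericVector channel_currents_cpp(NumericVector params, NumericVector state,
                                   bool ka_betah_as_printed = false) {
  Pars q = unpack(params, ka_betah_as_printed);
  if (state.size() != 22) stop("state must have length 22");
  NumericVector I(10);
  channel_currents(q, state.begin(), I.begin());
  I.names() = CharacterVector::create(
    "NaF", "KDR", "HCN", "NaP", "KA", "HVA", "LVA", "KM", "SK", "leak");
  return I;
}

// Fixed-step integration: exponential Euler for the gating particles (exact
// for the per-step linear gate ODE), forward Euler for V, [Ca] and the SK
// occupancies.
//
// I_pA[j] is the injected current held over step j (t in [j dt, (j+1) dt)).
// Recorded samples are the state at times j*dt for j = 0, stride, 2*stride,
// ..., aligned with the stimulus samples.
// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(NumericVector params, NumericVector state0,
                  NumericVector I_pA, double dt, double inj_scale,
                  int stride = 1, bool record_ca = false,
                  bool record_currents = false,
                  bool ka_betah_as_printed = false) {
  Pars q = unpack(params, ka_betah_as_printed);
  if (state0.size() != 22) stop("state0 must have length 22");
  if (dt <= 0) stop("dt must be positive");
  if (stride < 1) stop("stride must be >= 1");
  R_xlen_t n = I_pA.size();
  R_xlen_t nrec = (n + stride - 1) / stride;

  NumericVector Vrec(nrec);
  NumericVector Carec(record_ca ? nrec : 0);
  NumericMatrix Irec(record_currents ? nrec : 0, record_currents ? 10 : 0);

  double st[22];
  for (int i = 0; i < 22; ++i) st[i] = state0[i];

  double xinf[14], tau[14], Ich[10], ds[6];
  bool diverged = false;
  double t_div = NA_REAL;
  R_xlen_t k = 0;

  for (R_xlen_t j = 0; j < n; ++j) {
    if (j % stride == 0) {
      Vrec[k] = st[0];
      if (record_ca) Carec[k] = st[21];
      if (record_currents) {
        channel_currents(q, st, Ich);
        for (int c = 0; c < 10; ++c) Irec(k, c) = Ich[c];
      }
      ++k;
    }
    double V = st[0], Ca = st[21];

    channel_currents(q, st, Ich);
    double Itot = 0.0;
    for (int c = 0; c < 10; ++c) Itot += Ich[c];
    double dV = dt * (I_pA[j] * inj_scale - Itot) / q.Cm;

    // gates: exponential Euler at the pre-step voltage
    gate_rates(q, V, xinf, tau);
    for (int g = 0; g < 14; ++g) {
      double e = std::exp(-dt / tau[g]);
      st[1 + g] = xinf[g] + (st[1 + g] - xinf[g]) * e;
    }

    // SK occupancies: forward Euler + renormalization (conservation)
    double kon = SK_KON_PER_MM * Ca;
    sk_derivs(st + 15, kon, ds);
    double tot = 0.0;
    for (int i = 0; i < 6; ++i) {
      st[15 + i] += dt * ds[i];
      if (st[15 + i] < 0) st[15 + i] = 0;
      tot += st[15 + i];
    }
    for (int i = 0; i < 6; ++i) st[15 + i] /= tot;

    // calcium: influx from I_Ca (mA/cm2) plus first-order decay
    double Ica_mA = (Ich[5] + Ich[6]) * 1e-3;
    double dCa = dt * (-10000.0 * Ica_mA / (36.0 * CA_DEPTH * FARADAY) +
                       (CA_INF - Ca) / q.tauCa);
    st[21] = Ca + dCa;
    st[0] = V + dV;

    if (!std::isfinite(st[0]) || std::fabs(st[0]) > 200.0 || st[21] <= 0.0) {
      diverged = true;
      t_div = (j + 1) * dt;
      break;
    }
  }

  NumericVector fin(22);
  for (int i = 0; i < 22; ++i) fin[i] = st[i];
  return List::create(
    _["V"] = Vrec, _["Ca"] = Carec, _["currents"] = Irec,
    _["state"] = fin, _["diverged"] = diverged, _["t_diverged"] = t_div,
    _["n_recorded"] = (double)(diverged ? k : nrec));
}
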