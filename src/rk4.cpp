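#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 for the admissible in-degree coupled neuron models.
// model: 1 = gap, 2 = chem type I, 3 = chem type II.
// pars: alpha_leak, alpha_gap, alpha_chem, alpha_ext, V_rest, gamma, a_r, a_d.
// A(j, i) is the multiplicity of edge j -> i; coupling sums over column i.
// The smooth stimulus (constant drive Id per node plus per-channel
// sinusoids) is evaluated at the RK stage times; the random-walk noise path
// (noise, n x nsteps) advances once per step and is held constant within it.

static inline double phi(double v, double vthr, double gamma) {
  return 1.0 / (1.0 + std::exp(-gamma * (v - vthr)));
}

struct Stim {
  const double* Id;        // per-node constant drive
  const int* ch_node;      // per-channel 0-based node index
  const double* ch_amp;    // per-channel oscillation amplitude
  const double* ch_freq;   // per-channel frequency (Hz)
  int nchan;
  const double* noise;     // n x nsteps column-major, or NULL
  int n;
};

static void fill_current(const Stim& st, double t, int step,
                         std::vector<double>& I) {
  for (int i = 0; i < st.n; ++i) {
    I[i] = st.Id[i];
    if (st.noise) I[i] += st.noise[(size_t)step * st.n + i];
  }
  for (int c = 0; c < st.nchan; ++c) {
    I[st.ch_node[c]] += st.ch_amp[c] * std::sin(2.0 * M_PI * st.ch_freq[c] * t);
  }
}

static void deriv(const NumericMatrix& A, int model, const double* p,
                  const NumericVector& Vs, const NumericVector& Vthr,
                  const std::vector<double>& I, const std::vector<double>& V,
                  const std::vector<double>& s, std::vector<double>& dV,
                  std::vector<double>& ds) {
  const int n = A.nrow();
  const double al = p[0], ag = p[1], ac = p[2], ax = p[3], Vr = p[4],
               gm = p[5], ar = p[6], ad = p[7];
  for (int i = 0; i < n; ++i) {
    double coup = 0.0;
    if (model == 1) {
      for (int j = 0; j < n; ++j) {
        double a = A(j, i);
        if (a != 0.0) coup += a * (V[i] - V[j]);
      }
      coup *= ag;
    } else if (model == 2) {
      for (int j = 0; j < n; ++j) {
        double a = A(j, i);
        if (a != 0.0) coup += a * phi(V[j], Vthr[j], gm) * (V[i] - Vs[j]);
      }
      coup *= ac;
    } else {
      for (int j = 0; j < n; ++j) {
        double a = A(j, i);
        if (a != 0.0) coup += a * s[j] * (V[i] - Vs[j]);
      }
      coup *= ac;
    }
    dV[i] = -al * (V[i] - Vr) - coup + ax * I[i];
  }
  if (model == 3) {
    for (int i = 0; i < n; ++i) {
      ds[i] = ar * phi(V[i], Vthr[i], gm) * (1.0 - s[i]) - ad * s[i];
    }
  }
}

// [[Rcpp::export]]
List rk4_core(NumericMatrix A, int model, NumericVector pars,
              NumericVector Vs, NumericVector Vthr,
              NumericVector Id, IntegerVector ch_node, NumericVector ch_amp,
              NumericVector ch_freq, NumericMatrix noise,
              NumericVector V0, NumericVector s0, double dt, int nsteps) {
  const int n = A.nrow();
  const bool syn = (model == 3);
  NumericMatrix Vout(n, nsteps + 1);
  NumericMatrix Sout(syn ? n : 0, syn ? (nsteps + 1) : 0);
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> s(syn ? n : 0);
  if (syn) std::copy(s0.begin(), s0.end(), s.begin());
  for (int i = 0; i < n; ++i) Vout(i, 0) = V[i];
  if (syn) for (int i = 0; i < n; ++i) Sout(i, 0) = s[i];

  Stim st;
  st.Id = REAL(Id);
  st.ch_node = ch_node.size() ? INTEGER(ch_node) : nullptr;
  st.ch_amp = ch_amp.size() ? REAL(ch_amp) : nullptr;
  st.ch_freq = ch_freq.size() ? REAL(ch_freq) : nullptr;
  st.nchan = ch_node.size();
  st.noise = noise.ncol() > 0 ? REAL(noise) : nullptr;
  st.n = n;

  std::vector<double> k1V(n), k2V(n), k3V(n), k4V(n), tmpV(n), Icur(n);
  std::vector<double> k1s, k2s, k3s, k4s, tmps;
  if (syn) {
    k1s.resize(n); k2s.resize(n); k3s.resize(n); k4s.resize(n); tmps.resize(n);
  }
  int status = 0, bad_step = -1;
  const double* p = REAL(pars);

  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    fill_current(st, t, step, Icur);
    deriv(A, model, p, Vs, Vthr, Icur, V, s, k1V, k1s);
    for (int i = 0; i < n; ++i) tmpV[i] = V[i] + 0.5 * dt * k1V[i];
    if (syn) for (int i = 0; i < n; ++i) tmps[i] = s[i] + 0.5 * dt * k1s[i];
    fill_current(st, t + 0.5 * dt, step, Icur);
    deriv(A, model, p, Vs, Vthr, Icur, tmpV, tmps, k2V, k2s);
    for (int i = 0; i < n; ++i) tmpV[i] = V[i] + 0.5 * dt * k2V[i];
    if (syn) for (int i = 0; i < n; ++i) tmps[i] = s[i] + 0.5 * dt * k2s[i];
    deriv(A, model, p, Vs, Vthr, Icur, tmpV, tmps, k3V, k3s);
    for (int i = 0; i < n; ++i) tmpV[i] = V[i] + dt * k3V[i];
    if (syn) for (int i = 0; i < n; ++i) tmps[i] = s[i] + dt * k3s[i];
    fill_current(st, t + dt, step, Icur);
    deriv(A, model, p, Vs, Vthr, Icur, tmpV, tmps, k4V, k4s);
    bool finite = true;
    for (int i = 0; i < n; ++i) {
      V[i] += dt / 6.0 * (k1V[i] + 2.0 * k2V[i] + 2.0 * k3V[i] + k4V[i]);
      if (!std::isfinite(V[i])) finite = false;
      Vout(i, step + 1) = V[i];
    }
    if (syn) {
      for (int i = 0; i < n; ++i) {
        s[i] += dt / 6.0 * (k1s[i] + 2.0 * k2s[i] + 2.0 * k3s[i] + k4s[i]);
        if (!std::isfinite(s[i])) finite = false;
        Sout(i, step + 1) = s[i];
      }
    }
    if (!finite) {
      status = 1;
      bad_step = step + 1;
      break;
    }
  }
  return List::create(_["V"] = Vout, _["S"] = Sout, _["status"] = status,
                      _["bad_step"] = bad_step);
}
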