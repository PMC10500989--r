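// Simulation core: BAOAB Langevin dynamics on the built-in model potentials,
// OPES Explore kernel biases, the expanded-ensemble (MultiThermal) bias on U,
// and the replica-exchange loop with Metropolis-Hastings coordinate swaps.
//
// All physical parameters (gamma, epsilon, kBT, beta grids, sigma0) are
// resolved on the R side and passed in as plain numbers, so the R functions
// remain the single source of those definitions.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

static const double SQRT2PI = 2.5066282746310002;

// ---------------------------------------------------------------- RNG ------
// Deterministic, compiler-independent streams: mt19937_64 raw draws mapped to
// doubles by hand (std::*_distribution is implementation-defined), Gaussians
// via Box-Muller. Stream seeds derive from the root seed by splitmix-style
// mixing of (seed, stream id).
static inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct RngStream {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  void seed_stream(uint64_t root, uint64_t id) {
    eng.seed(mix64(root * 0x9E3779B97F4A7C15ULL + (id + 1) * 0xD1B54A32D192ED03ULL));
    has_spare = false;
  }
  double unif() { return (eng() >> 11) * (1.0 / 9007199254740992.0); }
  double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = 0.0, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// ------------------------------------------------------- model systems -----
// ids: 1 double_well_1d (h, d); 2 hidden_barrier_2d (hx, hy, kc, d);
//      3 mueller_brown (scale); 4 harmonic_2d (k)
static double sys_energy(int id, const double* p, const double* x, double* g) {
  switch (id) {
  case 1: {
    double h = p[0], d = p[1], xx = x[0];
    double q = xx * xx - 1.0;
    if (g) g[0] = 4.0 * h * xx * q + d;
    return h * q * q + d * xx;
  }
  case 2: {
    double hx = p[0], hy = p[1], kc = p[2], d = p[3];
    double qx = x[0] * x[0] - 1.0, qy = x[1] * x[1] - 1.0;
    if (g) {
      g[0] = 4.0 * hx * x[0] * qx + kc * x[1] + d;
      g[1] = 4.0 * hy * x[1] * qy + kc * x[0];
    }
    return hx * qx * qx + hy * qy * qy + kc * x[0] * x[1] + d * x[0];
  }
  case 3: {
    static const double A[4]  = {-200.0, -100.0, -170.0, 15.0};
    static const double aa[4] = {-1.0, -1.0, -6.5, 0.7};
    static const double bb[4] = {0.0, 0.0, 11.0, 0.6};
    static const double cc[4] = {-10.0, -10.0, -6.5, 0.7};
    static const double X0[4] = {1.0, 0.0, -0.5, -1.0};
    static const double Y0[4] = {0.0, 0.5, 1.5, 1.0};
    double s = p[0], u = 0.0, gx = 0.0, gy = 0.0;
    for (int i = 0; i < 4; ++i) {
      double dx = x[0] - X0[i], dy = x[1] - Y0[i];
      double e = A[i] * std::exp(aa[i] * dx * dx + bb[i] * dx * dy + cc[i] * dy * dy);
      u += e;
      gx += e * (2.0 * aa[i] * dx + bb[i] * dy);
      gy += e * (bb[i] * dx + 2.0 * cc[i] * dy);
    }
    if (g) { g[0] = s * gx; g[1] = s * gy; }
    return s * u;
  }
  case 4: {
    double k = p[0];
    if (g) { g[0] = k * x[0]; g[1] = k * x[1]; }
    return 0.5 * k * (x[0] * x[0] + x[1] * x[1]);
  }
  }
  return NA_REAL;
}

// [[Rcpp::export(name = ".sys_eval_cpp")]]
List sys_eval_cpp(int sys_id, NumericVector params, NumericMatrix X) {
  int n = X.nrow(), d = X.ncol();
  NumericVector U(n);
  NumericMatrix G(n, d);
  std::vector<double> x(d), g(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) x[j] = X(i, j);
    U[i] = sys_energy(sys_id, params.begin(), x.data(), g.data());
    for (int j = 0; j < d; ++j) G(i, j) = g[j];
  }
  return List::create(_["U"] = U, _["grad"] = G);
}

// --------------------------------------------------------- OPES Explore ----
// One-dimensional kernel estimator of the sampled CV distribution with
// on-deposition compression (merge within one sigma0), discrete Z estimate
// (mean density over kernel centers), and the Explore bias
//   V(s) = kBT (gamma - 1) log(phat(s)/Z + eps).
struct ExploreBias {
  int cv = 0;      // coordinate index the bias acts on
  int slot = 0;    // output column slot (0 = main, 1.. = auxiliary)
  long pace = 0;
  double kbt = 0.0, gamma = 0.0, eps = 0.0, sigma0 = 0.0;
  std::vector<double> c, sig, h;
  double Z = 1.0, H = 0.0;
  long ndep = 0;

  double dens(double s, double* dd) const {
    if (c.empty()) { if (dd) *dd = 0.0; return 0.0; }
    double p = 0.0, dp = 0.0;
    for (size_t k = 0; k < c.size(); ++k) {
      double z = (s - c[k]) / sig[k];
      double g = h[k] * std::exp(-0.5 * z * z) / (sig[k] * SQRT2PI);
      p += g;
      dp += -z / sig[k] * g;
    }
    if (dd) *dd = dp / H;
    return p / H;
  }
  double bias(double s, double* dVds) const {
    if (c.empty()) { if (dVds) *dVds = 0.0; return 0.0; }
    double dp = 0.0;
    double p = dens(s, dVds ? &dp : (double*)nullptr);
    double arg = p / Z + eps;
    if (dVds) *dVds = kbt * (gamma - 1.0) * (dp / Z) / arg;
    return kbt * (gamma - 1.0) * std::log(arg);
  }
  void deposit(double s) {
    ndep++;
    int best = -1;
    double bd = HUGE_VAL;
    for (size_t k = 0; k < c.size(); ++k) {
      double d = std::fabs(s - c[k]) / sigma0;
      if (d < bd) { bd = d; best = (int)k; }
    }
    if (best >= 0 && bd < 1.0) {
      double h1 = h[best], c1 = c[best], s1 = sig[best];
      double hn = h1 + 1.0;
      double cn = (h1 * c1 + s) / hn;
      double vn = (h1 * (s1 * s1 + c1 * c1) + (sigma0 * sigma0 + s * s)) / hn - cn * cn;
      h[best] = hn;
      c[best] = cn;
      sig[best] = std::sqrt(vn);
    } else {
      c.push_back(s);
      sig.push_back(sigma0);
      h.push_back(1.0);
    }
    H = 0.0;
    for (double hh : h) H += hh;
    double zz = 0.0;
    for (size_t k = 0; k < c.size(); ++k) zz += dens(c[k], nullptr);
    Z = zz / (double)c.size();
  }
};

// [[Rcpp::export(name = ".explore_eval_cpp")]]
List explore_eval_cpp(NumericVector centers, NumericVector sigmas,
                      NumericVector heights, double Z, double eps,
                      double gamma, double kbt, NumericVector s) {
  ExploreBias b;
  b.kbt = kbt; b.gamma = gamma; b.eps = eps; b.Z = Z;
  b.c.assign(centers.begin(), centers.end());
  b.sig.assign(sigmas.begin(), sigmas.end());
  b.h.assign(heights.begin(), heights.end());
  b.H = 0.0;
  for (double hh : b.h) b.H += hh;
  int n = s.size();
  NumericVector V(n), dV(n);
  for (int i = 0; i < n; ++i) {
    double d;
    V[i] = b.bias(s[i], &d);
    dV[i] = d;
  }
  return List::create(_["value"] = V, _["deriv"] = dV);
}

// [[Rcpp::export(name = ".explore_deposit_seq_cpp")]]
List explore_deposit_seq_cpp(NumericVector s, double sigma0) {
  ExploreBias b;
  b.sigma0 = sigma0;
  for (int i = 0; i < s.size(); ++i) b.deposit(s[i]);
  int K = b.c.size();
  NumericMatrix kern(K, 3);
  for (int k = 0; k < K; ++k) {
    kern(k, 0) = b.c[k];
    kern(k, 1) = b.sig[k];
    kern(k, 2) = b.h[k];
  }
  colnames(kern) = CharacterVector::create("center", "sigma", "height");
  return List::create(_["kernels"] = kern, _["Z"] = b.Z, _["n_deposited"] = (double)b.ndep);
}

// ------------------------------------------------------ OPES MultiThermal --
// Expanded-ensemble bias over a fixed beta grid acting on the potential
// energy, with the free-energy shifts DeltaF(T_j) learned on the fly from
// the full weighted history via streaming log-sum-exp accumulators.
static inline double logadd(double a, double b) {
  if (a == -HUGE_VAL) return b;
  if (b == -HUGE_VAL) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

struct MtBias {
  long stride = 0;
  double kbt = 0.0, beta0 = 0.0;
  std::vector<double> beta, dF, acc;  // acc_j = logsumexp(logw - (b_j-b0) U)
  double accw = -HUGE_VAL;            // logsumexp(logw)
  long nsamp = 0;

  void init(const std::vector<double>& betas, double b0, double kbt_) {
    beta = betas;
    beta0 = b0;
    kbt = kbt_;
    dF.assign(beta.size(), 0.0);
    acc.assign(beta.size(), -HUGE_VAL);
    accw = -HUGE_VAL;
    nsamp = 0;
  }
  double bias(double U, double* dVdU) const {
    size_t N = beta.size();
    double m = -HUGE_VAL;
    std::vector<double> a(N);
    for (size_t j = 0; j < N; ++j) {
      a[j] = -(beta[j] - beta0) * U + beta[j] * dF[j];
      if (a[j] > m) m = a[j];
    }
    double S = 0.0, Sg = 0.0;
    for (size_t j = 0; j < N; ++j) {
      double e = std::exp(a[j] - m);
      S += e;
      Sg += e * (beta[j] - beta0);
    }
    if (dVdU) *dVdU = kbt * Sg / S;
    return -kbt * (m + std::log(S / (double)N));
  }
  void add_sample(double U, double logw) {
    for (size_t j = 0; j < beta.size(); ++j)
      acc[j] = logadd(acc[j], logw - (beta[j] - beta0) * U);
    accw = logadd(accw, logw);
    for (size_t j = 0; j < beta.size(); ++j)
      dF[j] = -(acc[j] - accw) / beta[j];
    nsamp++;
  }
};

// ------------------------------------------------------------ replicas -----
struct Replica {
  std::vector<double> x, v, f;
  double U = 0.0;
  bool has_main = false;
  ExploreBias main;
  std::vector<ExploreBias> aux;
  bool has_mt = false;
  MtBias mt;
  RngStream rng;
};

struct Engine {
  int sys_id = 0, dim = 1, n_rep = 1, n_aux_slots = 0;
  std::vector<double> pars;
  double kbt = 0.0, beta0 = 0.0, dt = 0.0, friction = 0.0, mass = 1.0;
  double c1 = 1.0, c2 = 0.0;
  std::vector<Replica> reps;
  RngStream xrng;

  void forces(Replica& r) {
    std::vector<double> g(dim);
    r.U = sys_energy(sys_id, pars.data(), r.x.data(), g.data());
    double escale = 1.0;
    if (r.has_mt) {
      double dVdU;
      r.mt.bias(r.U, &dVdU);
      escale += dVdU;
    }
    for (int d = 0; d < dim; ++d) r.f[d] = -escale * g[d];
    if (r.has_main) {
      double dVds;
      r.main.bias(r.x[r.main.cv], &dVds);
      r.f[r.main.cv] -= dVds;
    }
    for (auto& b : r.aux) {
      double dVds;
      b.bias(r.x[b.cv], &dVds);
      r.f[b.cv] -= dVds;
    }
  }

  // total bias of replica r's stacks evaluated at arbitrary coords/energy
  double total_bias_at(const Replica& r, const double* x, double U,
                       double* v_main = nullptr, double* v_aux = nullptr,
                       double* v_mt = nullptr) const {
    double tot = 0.0;
    if (v_main) *v_main = 0.0;
    if (v_mt) *v_mt = 0.0;
    if (v_aux)
      for (int m = 0; m < n_aux_slots; ++m) v_aux[m] = 0.0;
    if (r.has_main) {
      double v = r.main.bias(x[r.main.cv], nullptr);
      if (v_main) *v_main = v;
      tot += v;
    }
    for (auto& b : r.aux) {
      double v = b.bias(x[b.cv], nullptr);
      if (v_aux) v_aux[b.slot - 1] = v;
      tot += v;
    }
    if (r.has_mt) {
      double v = r.mt.bias(U, nullptr);
      if (v_mt) *v_mt = v;
      tot += v;
    }
    return tot;
  }

  void baoab(Replica& r) {
    double hdt = 0.5 * dt, sqm = std::sqrt(kbt / mass);
    for (int d = 0; d < dim; ++d) {
      r.v[d] += hdt * r.f[d] / mass;
      r.x[d] += hdt * r.v[d];
      r.v[d] = c1 * r.v[d] + c2 * sqm * r.rng.gauss();
      r.x[d] += hdt * r.v[d];
    }
    forces(r);  // also refreshes r.U
    for (int d = 0; d < dim; ++d) r.v[d] += hdt * r.f[d] / mass;
  }
};

// [[Rcpp::export(name = ".run_core_cpp")]]
List run_core_cpp(int sys_id, NumericVector sys_params, int dim,
                  NumericVector x0, double temperature, double dt,
                  double friction, double mass, double n_steps_d,
                  int exchange_stride, int record_stride, List replicas,
                  int n_aux_slots, int seed) {
  const double KB = 0.0083144621;
  long n_steps = (long)n_steps_d;
  Engine E;
  E.sys_id = sys_id;
  E.dim = dim;
  E.pars.assign(sys_params.begin(), sys_params.end());
  E.kbt = KB * temperature;
  E.beta0 = 1.0 / E.kbt;
  E.dt = dt;
  E.friction = friction;
  E.mass = mass;
  E.n_aux_slots = n_aux_slots;
  E.c1 = std::exp(-friction * dt);
  E.c2 = std::sqrt(std::max(0.0, 1.0 - E.c1 * E.c1));
  if (friction == 0.0) { E.c1 = 1.0; E.c2 = 0.0; }
  E.n_rep = replicas.size();
  E.reps.resize(E.n_rep);
  E.xrng.seed_stream((uint64_t)seed, 1000u);

  for (int i = 0; i < E.n_rep; ++i) {
    Replica& r = E.reps[i];
    r.x.assign(x0.begin(), x0.end());
    r.v.assign(dim, 0.0);
    r.f.assign(dim, 0.0);
    r.rng.seed_stream((uint64_t)seed, (uint64_t)i);
    for (int d = 0; d < dim; ++d) r.v[d] = std::sqrt(E.kbt / mass) * r.rng.gauss();
    List spec = replicas[i];
    if (spec.containsElementNamed("main") && !Rf_isNull(spec["main"])) {
      List m = spec["main"];
      r.has_main = true;
      r.main.cv = as<int>(m["cv"]);
      r.main.slot = 0;
      r.main.pace = (long)as<double>(m["pace"]);
      r.main.kbt = E.kbt;
      r.main.gamma = as<double>(m["gamma"]);
      r.main.eps = as<double>(m["epsilon"]);
      r.main.sigma0 = as<double>(m["sigma0"]);
    }
    if (spec.containsElementNamed("aux") && !Rf_isNull(spec["aux"])) {
      List ax = spec["aux"];
      for (int a = 0; a < ax.size(); ++a) {
        List m = ax[a];
        ExploreBias b;
        b.cv = as<int>(m["cv"]);
        b.slot = as<int>(m["slot"]);
        b.pace = (long)as<double>(m["pace"]);
        b.kbt = E.kbt;
        b.gamma = as<double>(m["gamma"]);
        b.eps = as<double>(m["epsilon"]);
        b.sigma0 = as<double>(m["sigma0"]);
        r.aux.push_back(b);
      }
    }
    if (spec.containsElementNamed("mt") && !Rf_isNull(spec["mt"])) {
      List m = spec["mt"];
      r.has_mt = true;
      NumericVector bv = m["betas"];
      std::vector<double> betas(bv.begin(), bv.end());
      r.mt.init(betas, E.beta0, E.kbt);
      r.mt.stride = (long)as<double>(m["stride"]);
    }
    E.forces(r);
  }

  long n_rec = record_stride > 0 ? n_steps / record_stride : 0;
  int ncol = 1 + dim + 1 + 1 + n_aux_slots + 1 + 1;
  std::vector<NumericMatrix> rec;
  for (int i = 0; i < E.n_rep; ++i) rec.push_back(NumericMatrix(n_rec, ncol));
  std::vector<double> xlog;  // time, i, j, delta, accepted, draw
  long attempt_parity = 0;
  std::vector<double> vaux(std::max(1, n_aux_slots));

  long irec = 0;
  for (long step = 1; step <= n_steps; ++step) {
    for (auto& r : E.reps) E.baoab(r);
    for (int i = 0; i < E.n_rep; ++i) {
      Replica& r = E.reps[i];
      for (int d = 0; d < dim; ++d)
        if (!std::isfinite(r.x[d]))
          stop("numerical blow-up: non-finite coordinate in replica %d at step %ld", i, step);
    }
    bool dirty = false;
    // expanded-ensemble update (fastest stride)
    for (auto& r : E.reps) {
      if (r.has_mt && step % r.mt.stride == 0) {
        double vtot = E.total_bias_at(r, r.x.data(), r.U);
        r.mt.add_sample(r.U, E.beta0 * vtot);
        dirty = true;
      }
    }
    // kernel depositions (main PACE, auxiliary 2x slower)
    for (auto& r : E.reps) {
      if (r.has_main && step % r.main.pace == 0) {
        r.main.deposit(r.x[r.main.cv]);
        dirty = true;
      }
      for (auto& b : r.aux) {
        if (step % b.pace == 0) {
          b.deposit(r.x[b.cv]);
          dirty = true;
        }
      }
    }
    // exchange attempts on alternating even/odd neighbour pairs
    if (E.n_rep > 1 && exchange_stride > 0 && step % exchange_stride == 0) {
      int parity = (int)(attempt_parity % 2);
      attempt_parity++;
      for (int i = parity; i + 1 < E.n_rep; i += 2) {
        Replica& a = E.reps[i];
        Replica& b = E.reps[i + 1];
        double va_a = E.total_bias_at(a, a.x.data(), a.U);
        double vb_b = E.total_bias_at(b, b.x.data(), b.U);
        double va_b = E.total_bias_at(a, b.x.data(), b.U);
        double vb_a = E.total_bias_at(b, a.x.data(), a.U);
        // Ubar_i(x_j) + Ubar_j(x_i) - Ubar_i(x_i) - Ubar_j(x_j); the bare U
        // terms cancel identically (same Hamiltonian and thermostat), so the
        // exponent reduces to the bias cross-terms
        double delta = (va_b + vb_a) - (va_a + vb_b);
        double alpha = delta <= 0.0 ? 1.0 : std::exp(-E.beta0 * delta);
        double u = E.xrng.unif();
        int acc = (u < alpha) ? 1 : 0;
        if (acc) {
          std::swap(a.x, b.x);
          std::swap(a.v, b.v);
          E.forces(a);
          E.forces(b);
        }
        double row[6] = {step * E.dt, (double)i, (double)(i + 1), delta, (double)acc, u};
        xlog.insert(xlog.end(), row, row + 6);
      }
    }
    if (dirty)
      for (auto& r : E.reps) E.forces(r);
    // record after all updates at this step
    if (record_stride > 0 && step % record_stride == 0) {
      for (int i = 0; i < E.n_rep; ++i) {
        Replica& r = E.reps[i];
        double vm, vmt;
        double vtot = E.total_bias_at(r, r.x.data(), r.U, &vm, vaux.data(), &vmt);
        int col = 0;
        rec[i](irec, col++) = step * E.dt;
        for (int d = 0; d < dim; ++d) rec[i](irec, col++) = r.x[d];
        rec[i](irec, col++) = r.U;
        rec[i](irec, col++) = vm;
        for (int m = 0; m < n_aux_slots; ++m) rec[i](irec, col++) = vaux[m];
        rec[i](irec, col++) = vmt;
        rec[i](irec, col++) = vtot;
      }
      irec++;
    }
  }

  // assemble outputs
  List tables(E.n_rep), states(E.n_rep);
  for (int i = 0; i < E.n_rep; ++i) {
    tables[i] = rec[i];
    Replica& r = E.reps[i];
    List st;
    if (r.has_main) {
      int K = r.main.c.size();
      NumericMatrix kern(K, 3);
      for (int k = 0; k < K; ++k) {
        kern(k, 0) = r.main.c[k];
        kern(k, 1) = r.main.sig[k];
        kern(k, 2) = r.main.h[k];
      }
      colnames(kern) = CharacterVector::create("center", "sigma", "height");
      st["main"] = List::create(_["kernels"] = kern, _["Z"] = r.main.Z,
                                _["n_deposited"] = (double)r.main.ndep);
    }
    if (!r.aux.empty()) {
      List axl(r.aux.size());
      for (size_t a = 0; a < r.aux.size(); ++a) {
        ExploreBias& b = r.aux[a];
        int K = b.c.size();
        NumericMatrix kern(K, 3);
        for (int k = 0; k < K; ++k) {
          kern(k, 0) = b.c[k];
          kern(k, 1) = b.sig[k];
          kern(k, 2) = b.h[k];
        }
        colnames(kern) = CharacterVector::create("center", "sigma", "height");
        axl[a] = List::create(_["kernels"] = kern, _["Z"] = b.Z,
                              _["n_deposited"] = (double)b.ndep, _["slot"] = b.slot);
      }
      st["aux"] = axl;
    }
    if (r.has_mt) {
      st["mt"] = List::create(_["betas"] = NumericVector(r.mt.beta.begin(), r.mt.beta.end()),
                              _["deltaF"] = NumericVector(r.mt.dF.begin(), r.mt.dF.end()),
                              _["n_samples"] = (double)r.mt.nsamp);
    }
    states[i] = st;
  }
  long n_ev = xlog.size() / 6;
  NumericMatrix xmat(n_ev, 6);
  for (long e = 0; e < n_ev; ++e)
    for (int c = 0; c < 6; ++c) xmat(e, c) = xlog[e * 6 + c];
  colnames(xmat) = CharacterVector::create("time", "i", "j", "delta", "accepted", "draw");
  return List::create(_["tables"] = tables, _["exchange"] = xmat, _["states"] = states);
}
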