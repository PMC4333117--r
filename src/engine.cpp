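// Lattice Monte Carlo engine.
//
// Periodic triangular lattice in axial (rhombic) coordinates: site (u,v)
// has neighbors (u,v+-1), (u+-1,v), (u-1,v+1), (u+1,v-1), all modulo the
// lattice dimensions. Species move by Gillespie-sampled neighbor swaps with
// rate r(i,k) = exp(beta*(w_i + w_k)); per-site ordering states relax by
// Metropolis proposals on the ordering energy J between swap phases.
//
// Conventions used throughout this file:
//   species: 0 = CH, 1 = PC, 2 = SM
//   state:   0 = ho (spin -1), 1 = lo (spin +1)
// R passes species as 1..3 and states as spins (+1 lo / -1 ho); conversion
// happens at the interface functions only.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

// ---------------------------------------------------------------- RNG ----
// xoshiro256++ seeded through splitmix64; self-contained so that runs are
// bit-reproducible from the recorded integer seed alone.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  inline double unif_pos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
  inline int below(int n) { return (int)(unif() * n); }
};

// Axial offsets (du, dv) of the six neighbor directions.
const int OFFU[6] = {0, 0, -1, 1, -1, 1};
const int OFFV[6] = {-1, 1, 0, 0, 1, -1};

struct Tables {
  double pairE[3][2][3][2];  // [spA][stA][spB][stB] interaction energy
  double jt[3][2][3];        // [spA][stA][spB] ordering coupling
  double jdiff[3][2][3];     // jt[a][s][b] - jt[a][1-s][b] (flip deltas)
  double beta;
  // Ordering-energy formulation: the default "state-field" form
  // J = -sum_i sum_k j(X_i^s_i, X_k) couples each lipid's own state to its
  // neighbors' species; spin_product switches to the literal
  // J = -sum j(X_i^s_i, X_k) * sigma_i * sigma_k.
  bool spin_product;
  // Metropolis acceptance lookup for coupling tables on a 0.05 grid.
  bool gridded;
  double egrid_inv;
  std::vector<double> etab;

  void build(const double* pe, const double* j18, double beta_,
             bool spin_product_ = false) {
    beta = beta_;
    spin_product = spin_product_;
    for (int a = 0; a < 3; ++a)
      for (int sa = 0; sa < 2; ++sa)
        for (int b = 0; b < 3; ++b)
          for (int sb = 0; sb < 2; ++sb)
            pairE[a][sa][b][sb] = pe[((a * 2 + sa) * 3 + b) * 2 + sb];
    double jmax = 0.0;
    gridded = true;
    for (int a = 0; a < 3; ++a)
      for (int sa = 0; sa < 2; ++sa)
        for (int b = 0; b < 3; ++b) {
          double val = j18[(a * 2 + sa) * 3 + b];
          jt[a][sa][b] = val;
          jmax = std::max(jmax, std::fabs(val));
          if (std::fabs(val * 20.0 - std::round(val * 20.0)) > 1e-9)
            gridded = false;
        }
    for (int a = 0; a < 3; ++a)
      for (int sa = 0; sa < 2; ++sa)
        for (int b = 0; b < 3; ++b)
          jdiff[a][sa][b] = jt[a][sa][b] - jt[a][1 - sa][b];
    if (gridded) {
      // |dJ| <= 6 * max over neighbors of (j1 + j2 + 2*j3) <= 24 * jmax
      const double grid = 0.05;
      egrid_inv = 1.0 / grid;
      int n = (int)std::ceil(24.0 * jmax / grid) + 2;
      etab.resize(n);
      for (int i = 0; i < n; ++i) etab[i] = std::exp(-beta * grid * i);
    }
  }
  inline double p_accept(double dJ) const {
    if (gridded) {
      int idx = (int)(dJ * egrid_inv + 0.5);
      if (idx < (int)etab.size()) return etab[idx];
    }
    return std::exp(-beta * dJ);
  }
};

// ------------------------------------------------------------- Engine ----
struct Engine {
  int Rr, Cc, N;
  Tables tb;
  // restrict the Gillespie event set to swaps of unlike species (identity
  // swaps leave the configuration unchanged; excluding them only rescales
  // the event clock)
  bool hetero_only = false;
  std::vector<int32_t> nb;    // N x 6 neighbor sites
  std::vector<int8_t> nbd;    // N x 6 neighbor directions (redundant, = d)
  std::vector<int8_t> sp;     // species per site
  std::vector<int8_t> st;     // ordering state per site (0 ho / 1 lo)

  // Gillespie rate bookkeeping: u_i = exp(beta*w_i), v_i = sum_nb u,
  // q_i = u_i * v_i; q summed per 64-site block, T = grand total.
  std::vector<double> w, u, v, q, bsum;
  double T;
  int nblocks;

  // Lipid identity tracking (for displacement / MSD work).
  std::vector<int32_t> lip;        // site -> lipid id
  std::vector<int32_t> ddu, ddv;   // lipid -> accumulated axial displacement

  double t_sim;
  Xoshiro rng;

  // scratch for localized updates
  std::vector<int32_t> seenS, seenQ;
  int32_t stampS, stampQ;

  Engine(int nr, int nc, uint64_t seed)
      : Rr(nr), Cc(nc), N(nr * nc), rng(seed) {
    nb.resize((size_t)N * 6);
    for (int uu = 0; uu < Rr; ++uu)
      for (int vv = 0; vv < Cc; ++vv) {
        int i = uu * Cc + vv;
        for (int d = 0; d < 6; ++d) {
          int u2 = uu + OFFU[d]; if (u2 < 0) u2 += Rr; else if (u2 >= Rr) u2 -= Rr;
          int v2 = vv + OFFV[d]; if (v2 < 0) v2 += Cc; else if (v2 >= Cc) v2 -= Cc;
          nb[(size_t)i * 6 + d] = u2 * Cc + v2;
        }
      }
    sp.resize(N); st.resize(N);
    w.resize(N); u.resize(N); v.resize(N); q.resize(N);
    nblocks = (N + 63) / 64;
    bsum.resize(nblocks);
    lip.resize(N); ddu.assign(N, 0); ddv.assign(N, 0);
    for (int i = 0; i < N; ++i) lip[i] = i;
    seenS.assign(N, -1); seenQ.assign(N, -1);
    stampS = 0; stampQ = 0;
    t_sim = 0.0;
  }

  void load(const IntegerVector& species, const IntegerVector& spin) {
    for (int i = 0; i < N; ++i) {
      sp[i] = (int8_t)(species[i] - 1);
      st[i] = (int8_t)(spin[i] > 0 ? 1 : 0);
    }
  }

  inline double site_w(int i) const {
    const int32_t* nbi = &nb[(size_t)i * 6];
    const double (*row)[2] = tb.pairE[sp[i]][st[i]];
    double s = 0.0;
    for (int d = 0; d < 6; ++d) {
      int k = nbi[d];
      s += row[sp[k]][st[k]];
    }
    return s;
  }

  void rebuild_rates() {
    for (int i = 0; i < N; ++i) {
      w[i] = site_w(i);
      u[i] = std::exp(tb.beta * w[i]);
    }
    for (int i = 0; i < N; ++i) {
      const int32_t* nbi = &nb[(size_t)i * 6];
      double s = 0.0;
      for (int d = 0; d < 6; ++d) {
        int k = nbi[d];
        if (!hetero_only || sp[k] != sp[i]) s += u[k];
      }
      v[i] = s;
      q[i] = u[i] * s;
    }
    T = 0.0;
    for (int b = 0; b < nblocks; ++b) {
      double s = 0.0;
      int i1 = std::min(N, (b + 1) * 64);
      for (int i = b * 64; i < i1; ++i) s += q[i];
      bsum[b] = s;
      T += s;
    }
  }

  // Execute the swap of sites i and k (k = neighbor d of i); updates the
  // localized rate bookkeeping.
  void exec_swap(int i, int k, int d) {
    int a = lip[i], b = lip[k];
    ddu[a] += OFFU[d]; ddv[a] += OFFV[d];
    ddu[b] -= OFFU[d]; ddv[b] -= OFFV[d];
    lip[i] = b; lip[k] = a;
    int8_t spi = sp[i], spk = sp[k];
    if (spi == spk) return;  // energetically a no-op
    sp[i] = spk; sp[k] = spi;

    const int32_t* nbi = &nb[(size_t)i * 6];
    const int32_t* nbk = &nb[(size_t)k * 6];
    // w deltas on the neighborhoods (pair terms with i or k changed)
    for (int t = 0; t < 6; ++t) {
      int m = nbi[t];
      if (m == k) continue;
      w[m] += tb.pairE[sp[m]][st[m]][spk][st[i]] -
              tb.pairE[sp[m]][st[m]][spi][st[i]];
    }
    for (int t = 0; t < 6; ++t) {
      int m = nbk[t];
      if (m == i) continue;
      w[m] += tb.pairE[sp[m]][st[m]][spi][st[k]] -
              tb.pairE[sp[m]][st[m]][spk][st[k]];
    }
    w[i] = site_w(i);
    w[k] = site_w(k);

    // refresh u on S = {i,k} + neighborhoods, v on n(S), q on S + n(S)
    int slist[14], ns = 0;
    ++stampS;
    {
      auto addS = [&](int s) {
        if (seenS[s] != stampS) { seenS[s] = stampS; slist[ns++] = s; }
      };
      addS(i); addS(k);
      for (int t = 0; t < 6; ++t) { addS(nbi[t]); addS(nbk[t]); }
    }
    int qlist[96], nq = 0;
    ++stampQ;
    auto addQ = [&](int m) {
      if (seenQ[m] != stampQ) { seenQ[m] = stampQ; qlist[nq++] = m; }
    };
    if (hetero_only) {
      for (int t = 0; t < ns; ++t) {
        int s = slist[t];
        u[s] = std::exp(tb.beta * w[s]);
        addQ(s);
        const int32_t* nbs = &nb[(size_t)s * 6];
        for (int dd2 = 0; dd2 < 6; ++dd2) addQ(nbs[dd2]);
      }
      for (int t = 0; t < nq; ++t) {
        int m = qlist[t];
        const int32_t* nbm = &nb[(size_t)m * 6];
        double s2 = 0.0;
        for (int dd2 = 0; dd2 < 6; ++dd2) {
          int k2 = nbm[dd2];
          if (sp[k2] != sp[m]) s2 += u[k2];
        }
        v[m] = s2;
      }
    } else {
      for (int t = 0; t < ns; ++t) {
        int s = slist[t];
        double un = std::exp(tb.beta * w[s]);
        double du = un - u[s];
        addQ(s);
        if (du != 0.0) {
          u[s] = un;
          const int32_t* nbs = &nb[(size_t)s * 6];
          for (int dd2 = 0; dd2 < 6; ++dd2) {
            int m = nbs[dd2];
            v[m] += du;
            addQ(m);
          }
        }
      }
    }
    for (int t = 0; t < nq; ++t) {
      int m = qlist[t];
      double qn = u[m] * v[m];
      double dq = qn - q[m];
      q[m] = qn;
      bsum[m >> 6] += dq;
      T += dq;
    }
  }

  // One Gillespie event: advance the clock, pick a swap ~ its rate, do it.
  // Returns (i, k) through the pointers if requested.
  inline double step(int* oi = nullptr, int* ok = nullptr) {
    double dt = -std::log(rng.unif_pos()) / (0.5 * T);
    t_sim += dt;
    double x = rng.unif() * T;
    int b = 0;
    while (b < nblocks - 1 && x >= bsum[b]) { x -= bsum[b]; ++b; }
    int i = b << 6;
    int i1 = std::min(N, i + 64);
    while (i < i1 - 1 && x >= q[i]) { x -= q[i]; ++i; }
    const int32_t* nbi = &nb[(size_t)i * 6];
    double y = rng.unif() * v[i];
    int d = 0, dlast = 0;
    for (; d < 6; ++d) {
      if (hetero_only && sp[nbi[d]] == sp[i]) continue;
      dlast = d;
      double uk = u[nbi[d]];
      if (y < uk) break;
      y -= uk;
    }
    if (d == 6) d = dlast;  // numerical overshoot: take the last candidate
    int k = nbi[d];
    if (oi) { *oi = i; *ok = k; }
    exec_swap(i, k, d);
    return dt;
  }

  void gillespie(long nswaps) {
    if (T <= 0.0) Rcpp::stop("total swap rate is zero (no eligible events)");
    for (long s = 0; s < nswaps; ++s) step();
  }

  inline double flip_dJ(int i) const {
    int8_t s = st[i];
    int8_t spi = sp[i];
    const int32_t* nbi = &nb[(size_t)i * 6];
    double dJ = 0.0;
    if (tb.spin_product) {
      int sig = 2 * s - 1;
      for (int t = 0; t < 6; ++t) {
        int m = nbi[t];
        int8_t sm = st[m], spm = sp[m];
        double c = tb.jt[spi][s][spm] + tb.jt[spi][1 - s][spm] +
                   2.0 * tb.jt[spm][sm][spi];
        dJ += (double)(sig * (2 * sm - 1)) * c;
      }
    } else {
      // only site i's own directed terms involve its state
      const double* row = tb.jdiff[spi][s];
      for (int t = 0; t < 6; ++t) dJ += row[sp[nbi[t]]];
    }
    return dJ;
  }

  long metropolis(long nprop) {
    long acc = 0;
    for (long p = 0; p < nprop; ++p) {
      int i = rng.below(N);
      double dJ = flip_dJ(i);
      bool take = (dJ <= 0.0) || (rng.unif() < tb.p_accept(dJ));
      if (take) { st[i] = (int8_t)(1 - st[i]); ++acc; }
    }
    return acc;
  }

  double total_W() const {
    double W = 0.0;
    for (int i = 0; i < N; ++i) W += site_w(i);
    return W;
  }
  double total_J() const {
    double J = 0.0;
    for (int i = 0; i < N; ++i) {
      const int32_t* nbi = &nb[(size_t)i * 6];
      int sig = 2 * st[i] - 1;
      for (int d = 0; d < 6; ++d) {
        int k = nbi[d];
        double jv = tb.jt[sp[i]][st[i]][sp[k]];
        J -= tb.spin_product ? jv * sig * (2 * st[k] - 1) : jv;
      }
    }
    return J;
  }
  double lo_fraction() const {
    long n = 0;
    for (int i = 0; i < N; ++i) n += st[i];
    return (double)n / N;
  }
  // undirected species-pair contact counts (6 independent entries)
  void contact_counts(double* c6) const {
    static const int DIRS[3] = {1, 3, 4};  // one direction per undirected edge
    long cnt[3][3] = {{0}};
    for (int i = 0; i < N; ++i) {
      const int32_t* nbi = &nb[(size_t)i * 6];
      for (int t = 0; t < 3; ++t) {
        int k = nbi[DIRS[t]];
        int a = sp[i], b = sp[k];
        if (a > b) std::swap(a, b);
        ++cnt[a][b];
      }
    }
    int idx = 0;
    for (int a = 0; a < 3; ++a)
      for (int b = a; b < 3; ++b) c6[idx++] = (double)cnt[a][b] / (3.0 * N);
  }
};

uint64_t mix_seed(int seed) { return (uint64_t)(uint32_t)seed; }

void fill_tables(Engine& E, const NumericVector& pair36,
                 const NumericVector& j18, double beta,
                 bool spin_product = false) {
  E.tb.build(REAL(pair36), REAL(j18), beta, spin_product);
}

double disp2(int du, int dv) {
  // squared Cartesian distance of axial displacement (du, dv)
  return (double)du * du + (double)dv * dv + (double)du * dv;
}

}  // namespace

// ------------------------------------------------------------ exports ----

// [[Rcpp::export]]
NumericVector cpp_site_energies(IntegerVector species, IntegerVector spin,
                                int nrows, int ncols, NumericVector pair36) {
  Engine E(nrows, ncols, 1);
  NumericVector j18(18);
  fill_tables(E, pair36, j18, 1.0);
  E.load(species, spin);
  NumericVector out(E.N);
  for (int i = 0; i < E.N; ++i) out[i] = E.site_w(i);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_total_energies(IntegerVector species, IntegerVector spin,
                                 int nrows, int ncols, NumericVector pair36,
                                 NumericVector j18,
                                 bool spin_product = false) {
  Engine E(nrows, ncols, 1);
  fill_tables(E, pair36, j18, 1.0, spin_product);
  E.load(species, spin);
  return NumericVector::create(_["W"] = E.total_W(), _["J"] = E.total_J());
}

// [[Rcpp::export]]
double cpp_flip_delta(IntegerVector species, IntegerVector spin, int nrows,
                      int ncols, NumericVector j18, int site0,
                      bool spin_product = false) {
  Engine E(nrows, ncols, 1);
  NumericVector pair36(36);
  fill_tables(E, pair36, j18, 1.0, spin_product);
  E.load(species, spin);
  return E.flip_dJ(site0);
}

// [[Rcpp::export]]
List cpp_metropolis(IntegerVector species, IntegerVector spin, int nrows,
                    int ncols, NumericVector j18, double beta, double nprop,
                    int seed, bool spin_product = false) {
  Engine E(nrows, ncols, mix_seed(seed));
  NumericVector pair36(36);
  fill_tables(E, pair36, j18, beta, spin_product);
  E.load(species, spin);
  long acc = E.metropolis((long)nprop);
  IntegerVector out(E.N);
  for (int i = 0; i < E.N; ++i) out[i] = 2 * E.st[i] - 1;
  return List::create(_["spin"] = out, _["accepted"] = (double)acc);
}

// [[Rcpp::export]]
List cpp_interaction_phase(IntegerVector species, IntegerVector spin,
                           int nrows, int ncols, NumericVector pair36,
                           double beta, double nswaps, int seed,
                           bool record = false, bool hetero_only = false) {
  Engine E(nrows, ncols, mix_seed(seed));
  NumericVector j18(18);
  fill_tables(E, pair36, j18, beta);
  E.hetero_only = hetero_only;
  E.load(species, spin);
  E.rebuild_rates();
  long ns = (long)nswaps;
  NumericMatrix steps(record ? ns : 0, 3);
  for (long s = 0; s < ns; ++s) {
    if (record) {
      int i, k;
      double t0 = E.t_sim;
      double dt = E.step(&i, &k);
      (void)t0;
      steps(s, 0) = i + 1;
      steps(s, 1) = k + 1;
      steps(s, 2) = dt;
    } else {
      E.step();
    }
  }
  IntegerVector spOut(E.N), lipOut(E.N), duOut(E.N), dvOut(E.N);
  for (int i = 0; i < E.N; ++i) {
    spOut[i] = E.sp[i] + 1;
    lipOut[i] = E.lip[i] + 1;
  }
  for (int l = 0; l < E.N; ++l) {
    duOut[l] = E.ddu[l];
    dvOut[l] = E.ddv[l];
  }
  return List::create(_["species"] = spOut, _["t_sim"] = E.t_sim,
                      _["steps"] = steps, _["lipid_at"] = lipOut,
                      _["du"] = duOut, _["dv"] = dvOut,
                      _["r_tot"] = 0.5 * E.T);
}

// [[Rcpp::export]]
NumericVector cpp_edge_rates_total(IntegerVector species, IntegerVector spin,
                                   int nrows, int ncols, NumericVector pair36,
                                   double beta, bool hetero_only = false) {
  Engine E(nrows, ncols, 1);
  NumericVector j18(18);
  fill_tables(E, pair36, j18, beta);
  E.hetero_only = hetero_only;
  E.load(species, spin);
  E.rebuild_rates();
  return NumericVector::create(0.5 * E.T);
}

// Full two-step simulation: initial Metropolis relaxation, then alternating
// swap phases and ordering relaxations until the physical life-time tau is
// reached, stationarity is detected, or max_cycles is hit.
// [[Rcpp::export]]
List cpp_simulate(IntegerVector species, IntegerVector spin, int nrows,
                  int ncols, NumericVector pair36, NumericVector j18,
                  double beta, int n_J, int n_W, double tau_s, double a_nm,
                  double D_ref, int seed, int max_cycles,
                  bool stop_stationary = false, double stat_tol = 0.01,
                  int stat_window = 10, bool initial_relax = true,
                  bool spin_product = false, int log_every = 1,
                  bool hetero_only = false) {
  Engine E(nrows, ncols, mix_seed(seed));
  fill_tables(E, pair36, j18, beta, spin_product);
  E.hetero_only = hetero_only;
  E.load(species, spin);
  const int N = E.N;
  const long nprop = (long)n_J * N;
  const long nswap = (long)std::ceil(0.5 * (double)n_W * N);
  const double a2_um = (a_nm * 1e-3) * (a_nm * 1e-3);

  if (initial_relax) E.metropolis(nprop);

  std::vector<double> log;  // cycle rows
  std::vector<int> du0(N), dv0(N);
  std::vector<int8_t> stlip0(N);
  std::vector<double> statbuf;  // 8 stats per cycle
  double t_real = 0.0;
  int cycle = 0;
  bool stationary = false, capped = false;

  // full statistics are needed every cycle only for stationarity detection;
  // otherwise they are logged every log_every cycles to keep overhead low
  auto push_log = [&](double dt_sim, double dmsd) {
    bool full = stop_stationary || log_every <= 1 ||
                cycle % log_every == 0;
    if (stop_stationary) {
      double c6[6];
      E.contact_counts(c6);
      double Dc = dt_sim > 0 ? dmsd / (4.0 * dt_sim) : 0.0;
      statbuf.push_back(E.lo_fraction());
      for (int t = 0; t < 6; ++t) statbuf.push_back(c6[t]);
      statbuf.push_back(Dc);
    }
    if (!full) return;
    log.push_back(cycle);
    log.push_back(E.t_sim);
    log.push_back(t_real);
    log.push_back(dt_sim);
    log.push_back(dmsd);
    log.push_back(E.lo_fraction());
    log.push_back(E.total_W());
    log.push_back(E.total_J());
  };
  push_log(0.0, 0.0);

  while (true) {
    if (tau_s >= 0 && t_real >= tau_s) break;
    if (cycle >= max_cycles) { capped = true; break; }
    if (stop_stationary && cycle >= 2 * stat_window) {
      bool ok = true;
      for (int sidx = 0; sidx < 8 && ok; ++sidx) {
        double m1 = 0, m2 = 0;
        for (int cc = cycle - 2 * stat_window; cc < cycle - stat_window; ++cc)
          m1 += statbuf[(size_t)(cc + 1) * 8 + sidx];
        for (int cc = cycle - stat_window; cc < cycle; ++cc)
          m2 += statbuf[(size_t)(cc + 1) * 8 + sidx];
        m1 /= stat_window; m2 /= stat_window;
        double den = std::max(std::fabs(m1), std::fabs(m2));
        if (den > 1e-12 && std::fabs(m1 - m2) / den > stat_tol) ok = false;
      }
      if (ok) { stationary = true; break; }
    }

    // swap phase
    for (int i = 0; i < N; ++i) {
      int l = E.lip[i];
      du0[l] = E.ddu[l];
      dv0[l] = E.ddv[l];
      stlip0[l] = E.st[i];
    }
    double t0 = E.t_sim;
    E.rebuild_rates();
    E.gillespie(nswap);
    double dt_sim = E.t_sim - t0;

    // per-cycle MSD of the Ld cohort (lipids on lo sites at both phase ends)
    double sum_lo = 0.0, sum_all = 0.0;
    long n_lo = 0;
    for (int i = 0; i < N; ++i) {
      int l = E.lip[i];
      double d2 = disp2(E.ddu[l] - du0[l], E.ddv[l] - dv0[l]);
      sum_all += d2;
      if (stlip0[l] == 1 && E.st[i] == 1) { sum_lo += d2; ++n_lo; }
    }
    double dmsd = (n_lo >= 30) ? sum_lo / n_lo : sum_all / N;
    t_real += a2_um * dmsd / (4.0 * D_ref);

    // ordering relaxation
    E.metropolis(nprop);
    ++cycle;
    push_log(dt_sim, dmsd);
    if ((cycle & 0x3F) == 0) Rcpp::checkUserInterrupt();
  }

  if (!stop_stationary && log_every > 1 && cycle % log_every != 0) {
    // ensure the final cycle is always present in the log
    log.push_back(cycle);
    log.push_back(E.t_sim);
    log.push_back(t_real);
    log.push_back(NA_REAL);
    log.push_back(NA_REAL);
    log.push_back(E.lo_fraction());
    log.push_back(E.total_W());
    log.push_back(E.total_J());
  }

  IntegerVector spOut(N), spinOut(N), lipOut(N), duOut(N), dvOut(N);
  for (int i = 0; i < N; ++i) {
    spOut[i] = E.sp[i] + 1;
    spinOut[i] = 2 * E.st[i] - 1;
    lipOut[i] = E.lip[i] + 1;
  }
  for (int l = 0; l < N; ++l) { duOut[l] = E.ddu[l]; dvOut[l] = E.ddv[l]; }
  int nrow = (int)(log.size() / 8);
  NumericMatrix logm(nrow, 8);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < 8; ++c) logm(r, c) = log[(size_t)r * 8 + c];
  colnames(logm) = CharacterVector::create("cycle", "t_sim", "t_real",
                                           "dt_sim", "dmsd", "lo_fraction",
                                           "W", "J");
  return List::create(_["species"] = spOut, _["spin"] = spinOut,
                      _["log"] = logm, _["cycles"] = cycle,
                      _["t_sim"] = E.t_sim, _["t_real"] = t_real,
                      _["stationary"] = stationary, _["capped"] = capped,
                      _["lipid_at"] = lipOut, _["du"] = duOut,
                      _["dv"] = dvOut);
}

// Continue an (equilibrated) configuration for n_cycles, tracking tagged
// lipid displacements; a record is invalidated as soon as the state of the
// occupied site differs from the initial one at a checkpoint (checked at
// both phase boundaries of every cycle).
// [[Rcpp::export]]
List cpp_track(IntegerVector species, IntegerVector spin, int nrows,
               int ncols, NumericVector pair36, NumericVector j18,
               double beta, int n_J, int n_W, int seed, int n_cycles,
               bool spin_product = false, bool hetero_only = false) {
  Engine E(nrows, ncols, mix_seed(seed));
  fill_tables(E, pair36, j18, beta, spin_product);
  E.hetero_only = hetero_only;
  E.load(species, spin);
  const int N = E.N;
  const long nprop = (long)n_J * N;
  const long nswap = (long)std::ceil(0.5 * (double)n_W * N);

  std::vector<int8_t> st0(N), valid(N, 1), spl(N);
  for (int i = 0; i < N; ++i) {
    int l = E.lip[i];
    st0[l] = E.st[i];
    spl[l] = E.sp[i];
  }
  NumericMatrix series(n_cycles, 6);
  colnames(series) = CharacterVector::create("cycle", "t_sim", "msd_lo",
                                             "n_lo", "msd_ho", "n_ho");
  auto check_valid = [&]() {
    for (int i = 0; i < N; ++i) {
      int l = E.lip[i];
      if (E.st[i] != st0[l]) valid[l] = 0;
    }
  };
  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    E.rebuild_rates();
    E.gillespie(nswap);
    check_valid();
    E.metropolis(nprop);
    check_valid();
    double s_lo = 0, s_ho = 0;
    long c_lo = 0, c_ho = 0;
    for (int l = 0; l < N; ++l) {
      if (!valid[l]) continue;
      double d2 = disp2(E.ddu[l], E.ddv[l]);
      if (st0[l] == 1) { s_lo += d2; ++c_lo; }
      else { s_ho += d2; ++c_ho; }
    }
    series(cyc, 0) = cyc + 1;
    series(cyc, 1) = E.t_sim;
    series(cyc, 2) = c_lo ? s_lo / c_lo : NA_REAL;
    series(cyc, 3) = (double)c_lo;
    series(cyc, 4) = c_ho ? s_ho / c_ho : NA_REAL;
    series(cyc, 5) = (double)c_ho;
    Rcpp::checkUserInterrupt();
  }
  IntegerVector spOut(N), spinOut(N);
  IntegerVector lsp(N), linit(N), lvalid(N), ldu(N), ldv(N);
  NumericVector ld2(N);
  for (int i = 0; i < N; ++i) {
    spOut[i] = E.sp[i] + 1;
    spinOut[i] = 2 * E.st[i] - 1;
  }
  for (int l = 0; l < N; ++l) {
    lsp[l] = spl[l] + 1;
    linit[l] = 2 * st0[l] - 1;
    lvalid[l] = valid[l];
    ldu[l] = E.ddu[l];
    ldv[l] = E.ddv[l];
    ld2[l] = disp2(E.ddu[l], E.ddv[l]);
  }
  return List::create(_["species"] = spOut, _["spin"] = spinOut,
                      _["t_sim"] = E.t_sim, _["series"] = series,
                      _["lipid_species"] = lsp, _["init_spin"] = linit,
                      _["valid"] = lvalid, _["du"] = ldu, _["dv"] = ldv,
                      _["disp2"] = ld2);
}

// Connected components of constant ordering state (6-neighbor, periodic).
// [[Rcpp::export]]
IntegerVector cpp_label_domains(IntegerVector spin, int nrows, int ncols) {
  Engine E(nrows, ncols, 1);
  const int N = E.N;
  IntegerVector lab(N, 0);
  std::vector<int> queue(N);
  int next = 0;
  for (int s = 0; s < N; ++s) {
    if (lab[s]) continue;
    ++next;
    int head = 0, tail = 0;
    queue[tail++] = s;
    lab[s] = next;
    while (head < tail) {
      int i = queue[head++];
      const int32_t* nbi = &E.nb[(size_t)i * 6];
      for (int d = 0; d < 6; ++d) {
        int k = nbi[d];
        if (!lab[k] && spin[k] == spin[i]) {
          lab[k] = next;
          queue[tail++] = k;
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
NumericMatrix cpp_contact_counts(IntegerVector species, int nrows, int ncols) {
  Engine E(nrows, ncols, 1);
  static const int DIRS[3] = {1, 3, 4};
  NumericMatrix cnt(3, 3);
  for (int i = 0; i < E.N; ++i) {
    const int32_t* nbi = &E.nb[(size_t)i * 6];
    for (int t = 0; t < 3; ++t) {
      int k = nbi[DIRS[t]];
      int a = species[i] - 1, b = species[k] - 1;
      if (a > b) std::swap(a, b);
      cnt(a, b) += 1;
    }
  }
  return cnt;
}

// Scan all centers for hexagonal patches (offsets supplied) lying fully in
// the lo phase; report validity, union coverage and pooled species counts.
// [[Rcpp::export]]
List cpp_patch_scan(IntegerVector species, IntegerVector spin, int nrows,
                    int ncols, IntegerMatrix offsets) {
  const int N = nrows * ncols;
  const int P = offsets.nrow();
  std::vector<int> offsite(P);
  LogicalVector valid(N);
  LogicalVector covered(N);
  NumericVector pooled(3);
  std::vector<int> members(P);
  int nvalid = 0;
  for (int uu = 0; uu < nrows; ++uu) {
    for (int vv = 0; vv < ncols; ++vv) {
      int c = uu * ncols + vv;
      bool ok = true;
      for (int p = 0; p < P; ++p) {
        int u2 = uu + offsets(p, 0);
        int v2 = vv + offsets(p, 1);
        u2 %= nrows; if (u2 < 0) u2 += nrows;
        v2 %= ncols; if (v2 < 0) v2 += ncols;
        int m = u2 * ncols + v2;
        if (spin[m] <= 0) { ok = false; break; }
        members[p] = m;
      }
      if (ok) {
        valid[c] = true;
        ++nvalid;
        for (int p = 0; p < P; ++p) {
          covered[members[p]] = true;
          pooled[species[members[p]] - 1] += 1;
        }
      }
    }
  }
  return List::create(_["valid"] = valid, _["covered"] = covered,
                      _["pooled"] = pooled, _["n_valid"] = nvalid);
}

// Randomized greedy disjoint packing of valid patch placements.
// [[Rcpp::export]]
IntegerVector cpp_greedy_pack(IntegerVector centers0, int nrows, int ncols,
                              IntegerMatrix offsets, int n_orderings,
                              int seed) {
  const int P = offsets.nrow();
  const int nc = centers0.size();
  Xoshiro rng(mix_seed(seed));
  std::vector<int> order(nc);
  std::vector<int> used(nrows * ncols, -1);
  std::vector<int> members(P);
  IntegerVector counts(n_orderings);
  for (int rep = 0; rep < n_orderings; ++rep) {
    for (int t = 0; t < nc; ++t) order[t] = centers0[t];
    for (int t = nc - 1; t > 0; --t)
      std::swap(order[t], order[rng.below(t + 1)]);
    int taken = 0;
    for (int t = 0; t < nc; ++t) {
      int c = order[t];
      int uu = c / ncols, vv = c % ncols;
      bool free_ = true;
      for (int p = 0; p < P; ++p) {
        int u2 = (uu + offsets(p, 0)) % nrows; if (u2 < 0) u2 += nrows;
        int v2 = (vv + offsets(p, 1)) % ncols; if (v2 < 0) v2 += ncols;
        int m = u2 * ncols + v2;
        if (used[m] == rep) { free_ = false; break; }
        members[p] = m;
      }
      if (free_) {
        for (int p = 0; p < P; ++p) used[members[p]] = rep;
        ++taken;
      }
    }
    counts[rep] = taken;
  }
  return counts;
}
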