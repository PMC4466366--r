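// Event-by-event transport of a primary charged particle and its
// secondary-electron cascade in a bounded water cube, driven by
// pre-tabulated per-channel cross-sections and inverse-CDF energy-loss
// tables (built in R).  Free flights are exponential; trajectories are
// straight lines; every ionisation spawns a secondary electron that is
// transported identically.
//
// Randomness comes from a self-contained counter-seeded xoshiro256++
// stream per history, so each history is bit-reproducible independently of
// execution order and of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in the open interval (0, 1)
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

struct SpeciesTable {
  int nE, nC, nQ;
  double loge0, dloge;
  NumericMatrix sigma;     // nE x nC, m^2 per molecule
  IntegerVector proc;      // per channel: 1 = ionisation, 2 = excitation
  NumericVector bind;      // per channel binding energy (eV)
  IntegerMatrix model;     // nE x nC model code
  NumericVector qtab;      // nE*nC*nQ quantile table, probs equispaced 0..1
};

static SpeciesTable parse_table(List t) {
  SpeciesTable st;
  NumericVector loge = t["loge"];
  st.nE = loge.size();
  st.loge0 = loge[0];
  st.dloge = (loge[st.nE - 1] - loge[0]) / (st.nE - 1);
  st.sigma = as<NumericMatrix>(t["sigma"]);
  st.proc = as<IntegerVector>(t["chan_process"]);
  st.bind = as<NumericVector>(t["chan_binding"]);
  st.model = as<IntegerMatrix>(t["model_code"]);
  st.qtab = as<NumericVector>(t["qtab"]);
  st.nC = st.sigma.ncol();
  st.nQ = t["n_quantile"];
  return st;
}

struct Particle {
  int sp;        // index into species tables
  double E;      // kinetic energy (eV)
  double pos[3];
  double dir[3];
  int gen;
};

// distance to the cube boundary along dir from pos (box = [0, L]^3)
static double dist_to_boundary(const double *pos, const double *dir,
                               double L) {
  double dmin = INFINITY;
  for (int a = 0; a < 3; ++a) {
    if (dir[a] > 0) {
      double d = (L - pos[a]) / dir[a];
      if (d < dmin) dmin = d;
    } else if (dir[a] < 0) {
      double d = -pos[a] / dir[a];
      if (d < dmin) dmin = d;
    }
  }
  return dmin;
}

// [[Rcpp::export]]
List cpp_run_history(double E0, int species0, List species_tables,
                     int electron_index, double box_m,
                     NumericVector cutoffs_eV, double number_density_m3,
                     double seed, bool record_events,
                     bool isotropic_secondaries,
                     NumericVector start_pos, NumericVector start_dir) {
  const int nSp = species_tables.size();
  std::vector<SpeciesTable> tabs;
  tabs.reserve(nSp);
  for (int i = 0; i < nSp; ++i) {
    tabs.push_back(parse_table(as<List>(species_tables[i])));
  }
  Xoshiro rng(static_cast<uint64_t>(seed));

  double deposited = 0.0, sub_cutoff = 0.0, exited = 0.0;
  long n_ion = 0, n_exc = 0;
  std::vector<double> ev_x, ev_y, ev_z, ev_W;
  std::vector<int> ev_gen, ev_sp, ev_chan, ev_proc, ev_model;

  std::vector<Particle> stack;
  {
    Particle p;
    p.sp = species0 - 1;
    p.E = E0;
    for (int a = 0; a < 3; ++a) {
      p.pos[a] = start_pos[a];
      p.dir[a] = start_dir[a];
    }
    p.gen = 0;
    stack.push_back(p);
  }

  std::vector<double> sig;
  while (!stack.empty()) {
    Particle p = stack.back();
    stack.pop_back();
    const SpeciesTable &st = tabs[p.sp];
    const double cutoff = cutoffs_eV[p.sp];
    sig.assign(st.nC, 0.0);

    for (;;) {
      if (p.E < cutoff || p.E <= 0) { sub_cutoff += p.E; break; }
      // grid position (uniform in log10 E), clamped
      double fi = (std::log10(p.E) - st.loge0) / st.dloge;
      if (fi < 0) fi = 0;
      if (fi > st.nE - 1) fi = st.nE - 1;
      int i0 = static_cast<int>(fi);
      if (i0 > st.nE - 2) i0 = st.nE - 2;
      double fr = fi - i0;
      double sig_tot = 0.0;
      for (int c = 0; c < st.nC; ++c) {
        double s = st.sigma(i0, c) * (1 - fr) + st.sigma(i0 + 1, c) * fr;
        if (s < 0) s = 0;
        sig[c] = s;
        sig_tot += s;
      }
      if (sig_tot <= 0) { exited += p.E; break; }

      double lambda = 1.0 / (number_density_m3 * sig_tot);
      double step = -lambda * std::log(rng.unif());
      double db = dist_to_boundary(p.pos, p.dir, box_m);
      if (step >= db) { exited += p.E; break; }
      for (int a = 0; a < 3; ++a) p.pos[a] += step * p.dir[a];

      // channel selection proportional to interpolated cross-sections
      double u = rng.unif() * sig_tot;
      int c = 0;
      double acc = sig[0];
      while (u > acc && c < st.nC - 1) { ++c; acc += sig[c]; }

      // energy-loss sampling from the nearest-grid quantile table
      int ie = (fr > 0.5) ? i0 + 1 : i0;
      double uq = rng.unif() * (st.nQ - 1);
      int k0 = static_cast<int>(uq);
      if (k0 > st.nQ - 2) k0 = st.nQ - 2;
      double kf = uq - k0;
      const double *q = &st.qtab[0];
      auto Q = [&](int k) {
        return q[ie + st.nE * (c + st.nC * k)];
      };
      double W = Q(k0) * (1 - kf) + Q(k0 + 1) * kf;
      if (W < 0) W = 0;

      int proc = st.proc[c];
      double B = st.bind[c];
      if (proc == 1) {
        if (p.E <= B) { sub_cutoff += p.E; break; }
        if (W > p.E - B) W = p.E - B;
        p.E -= (W + B);
        deposited += B;
        ++n_ion;
        // secondary electron of energy W
        if (W >= cutoffs_eV[electron_index - 1]) {
          Particle s2;
          s2.sp = electron_index - 1;
          s2.E = W;
          for (int a = 0; a < 3; ++a) s2.pos[a] = p.pos[a];
          if (isotropic_secondaries) {
            double cz = 2.0 * rng.unif() - 1.0;
            double phi = 6.283185307179586 * rng.unif();
            double sz = std::sqrt(1.0 - cz * cz);
            s2.dir[0] = sz * std::cos(phi);
            s2.dir[1] = sz * std::sin(phi);
            s2.dir[2] = cz;
          } else {
            for (int a = 0; a < 3; ++a) s2.dir[a] = p.dir[a];
          }
          s2.gen = p.gen + 1;
          stack.push_back(s2);
        } else {
          sub_cutoff += W;
        }
      } else {
        if (W > p.E) W = p.E;
        p.E -= W;
        deposited += W;
        ++n_exc;
      }
      if (record_events) {
        ev_x.push_back(p.pos[0]); ev_y.push_back(p.pos[1]);
        ev_z.push_back(p.pos[2]); ev_W.push_back(W);
        ev_gen.push_back(p.gen); ev_sp.push_back(p.sp + 1);
        ev_chan.push_back(c + 1); ev_proc.push_back(proc);
        ev_model.push_back(st.model(ie, c));
      }
    }
  }

  List out = List::create(
    _["n_ionisation"] = static_cast<double>(n_ion),
    _["n_excitation"] = static_cast<double>(n_exc),
    _["deposited_eV"] = deposited,
    _["sub_cutoff_eV"] = sub_cutoff,
    _["exited_eV"] = exited);
  if (record_events) {
    out["events"] = DataFrame::create(
      _["species"] = ev_sp, _["generation"] = ev_gen,
      _["process"] = ev_proc, _["channel"] = ev_chan,
      _["model"] = ev_model, _["W_eV"] = ev_W,
      _["x_m"] = ev_x, _["y_m"] = ev_y, _["z_m"] = ev_z);
  }
  return out;
}
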