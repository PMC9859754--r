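// Class-aggregated direct-method Gillespie engine for the growing-lattice
// motor-cargo model. Events with identical rates are pooled into classes;
// per-event work is O(1) (constant-size membership updates around the event
// site), which is what makes the published system size (10^3 sites growing
// over ~10^4-10^5 s) tractable. Per-site state is packed into a single
// 8-byte record and class membership positions are interleaved per site to
// keep each event's working set within a few cache lines.
//
// Nucleotide codes: 0 = GTP, 1 = GDP-Pi, 2 = GDP (hydrolysis only increases
// the code). Sites are 0-based here; the R wrapper presents 1-based sites.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

enum EventClass {
  C_ATT = 0,   // attachment at empty site
  C_DET,       // detachment, unstabilized
  C_DETS,      // detachment, stabilized cluster member (omega_d / s)
  C_HOPF,      // hop with GDP destination (rate p)
  C_HOPS,      // hop with GTP/GDP-Pi destination (rate p_slow)
  C_CBON,      // first-layer cargo binding
  C_CBOFF,     // first-layer cargo unbinding (stack == 1)
  C_MON,       // multi-layer adsorption (stack >= 1)
  C_MOFF,      // multi-layer desorption (stack >= 2)
  C_H1,        // GTP -> GDP-Pi
  C_H2,        // GDP-Pi -> GDP
  C_EXITF,     // walk-off at the plus-most site, GDP tip (rate p)
  C_EXITS,     // walk-off at the plus-most site, GTP/GDP-Pi tip (rate p_slow)
  NCLASS
};

struct SiteRec {
  std::uint8_t motor;
  std::uint8_t nuc;
  std::uint16_t cargo;
  std::uint16_t mask;   // cached class-membership bits
  std::uint16_t pad;
};

// xoshiro256++ (public-domain algorithm); seeded from R's RNG so that
// set.seed() in R fully determines the trajectory
struct Rng {
  std::uint64_t st[4];
  static inline std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  void seed(std::uint64_t x) {  // splitmix64 expansion
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      std::uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      st[i] = z ^ (z >> 31);
    }
  }
  inline std::uint64_t next() {
    std::uint64_t r = rotl(st[0] + st[3], 23) + st[0];
    std::uint64_t t = st[1] << 17;
    st[2] ^= st[0]; st[3] ^= st[1]; st[1] ^= st[2]; st[0] ^= st[3];
    st[2] ^= t; st[3] = rotl(st[3], 45);
    return r;
  }
  inline double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

struct Engine {
  // parameters
  double wa, wd, wds, p, pslow, kcon, kcoff, kmon, kmoff, kh1, kh2, gamma, s;
  bool cap, trains, stab;

  int L;
  std::vector<SiteRec> site;
  std::vector<int> pos;            // pos[i * NCLASS + c]
  std::vector<int> items[NCLASS];  // members per class
  double t;
  double rate[NCLASS];
  Rng rng;

  double n_att, n_det, n_hop, n_train_hop, n_cbind, n_cunbind,
         n_ads, n_des, n_h1, n_h2, n_grow, n_exit;

  inline void add(int i, int c) {
    pos[(size_t)i * NCLASS + c] = (int)items[c].size();
    items[c].push_back(i);
  }
  inline void rem(int i, int c) {
    int pp = pos[(size_t)i * NCLASS + c];
    int last = items[c].back();
    items[c][pp] = last;
    pos[(size_t)last * NCLASS + c] = pp;
    items[c].pop_back();
    pos[(size_t)i * NCLASS + c] = -1;
  }

  void setup(List pars, int L0, double horizon) {
    wa = as<double>(pars["omega_a"]);
    wd = as<double>(pars["omega_d"]);
    s = as<double>(pars["s"]);
    wds = wd / s;
    p = as<double>(pars["p"]);
    pslow = as<double>(pars["p_slow"]);
    kcon = as<double>(pars["k_c_on"]);
    kcoff = as<double>(pars["k_c_off"]);
    kmon = as<double>(pars["k_m_on"]);
    kmoff = as<double>(pars["k_m_off"]);
    kh1 = as<double>(pars["k_h1"]);
    kh2 = as<double>(pars["k_h2"]);
    gamma = as<double>(pars["gamma"]);
    cap = as<bool>(pars["enable_cap"]);
    trains = as<bool>(pars["enable_trains"]);
    stab = as<bool>(pars["enable_stabilization"]);

    rate[C_ATT] = wa; rate[C_DET] = wd; rate[C_DETS] = wds;
    rate[C_HOPF] = p; rate[C_HOPS] = pslow;
    rate[C_CBON] = kcon; rate[C_CBOFF] = kcoff;
    rate[C_MON] = kmon; rate[C_MOFF] = kmoff;
    rate[C_H1] = kh1; rate[C_H2] = kh2;
    rate[C_EXITF] = p; rate[C_EXITS] = pslow;

    L = L0; t = 0.0;
    double mu = gamma * horizon;
    int cap0 = L0 + (int)(mu + 8.0 * std::sqrt(mu + 1.0)) + 64;
    SiteRec empty_gdp = {0, 2, 0, 0, 0};  // empty, fully hydrolysed
    site.assign(cap0, empty_gdp);
    pos.assign((size_t)cap0 * NCLASS, -1);
    for (int c = 0; c < NCLASS; ++c) items[c].clear();
    for (int i = 0; i < L; ++i) sync_site(i);

    n_att = n_det = n_hop = n_train_hop = n_cbind = n_cunbind =
      n_ads = n_des = n_h1 = n_h2 = n_grow = n_exit = 0.0;
  }

  inline bool cargo_motor(int i) const {
    return site[i].motor && site[i].cargo > 0;
  }

  inline std::uint16_t desired_mask(int i) const {
    const SiteRec &r = site[i];
    bool m = r.motor != 0;
    bool stabilized = false;
    if (stab && m && r.cargo > 0) {
      if (i > 0 && cargo_motor(i - 1)) stabilized = true;
      else if (i + 1 < L && cargo_motor(i + 1)) stabilized = true;
    }
    bool can_hop = m && (i + 1 < L) && !site[i + 1].motor;
    bool slow = cap && can_hop && site[i + 1].nuc != 2;
    std::uint16_t d = 0;
    d |= (std::uint16_t)(!m) << C_ATT;
    d |= (std::uint16_t)(m && !stabilized) << C_DET;
    d |= (std::uint16_t)(m && stabilized) << C_DETS;
    d |= (std::uint16_t)(can_hop && !slow) << C_HOPF;
    d |= (std::uint16_t)(can_hop && slow) << C_HOPS;
    d |= (std::uint16_t)(m && r.cargo == 0) << C_CBON;
    d |= (std::uint16_t)(m && r.cargo == 1) << C_CBOFF;
    d |= (std::uint16_t)(m && r.cargo >= 1) << C_MON;
    d |= (std::uint16_t)(m && r.cargo >= 2) << C_MOFF;
    d |= (std::uint16_t)(cap && r.nuc == 0) << C_H1;
    d |= (std::uint16_t)(cap && r.nuc == 1) << C_H2;
    bool at_tip = m && (i == L - 1);  // open plus-boundary: walk off the end
    bool tip_slow = cap && r.nuc != 2;
    d |= (std::uint16_t)(at_tip && !tip_slow) << C_EXITF;
    d |= (std::uint16_t)(at_tip && tip_slow) << C_EXITS;
    return d;
  }

  inline void sync_site(int i) {
    std::uint16_t want = desired_mask(i);
    std::uint16_t diff = want ^ site[i].mask;
    if (!diff) return;
    site[i].mask = want;
    do {
      int b = __builtin_ctz(diff);
      diff &= (std::uint16_t)(diff - 1);
      if (want >> b & 1) add(i, b); else rem(i, b);
    } while (diff);
  }

  inline void sync_range(int lo, int hi) {
    if (lo < 0) lo = 0;
    if (hi > L - 1) hi = L - 1;
    for (int i = lo; i <= hi; ++i) sync_site(i);
  }

  inline double total_rate() const {
    double tot = gamma;
    for (int c = 0; c < NCLASS; ++c) tot += items[c].size() * rate[c];
    return tot;
  }

  void grow_lattice() {
    ++L; ++n_grow;
    if ((int)site.size() < L) {
      size_t ncap = site.size() + site.size() / 4 + 64;
      SiteRec empty_gdp = {0, 2, 0, 0, 0};
      site.resize(ncap, empty_gdp);
      pos.resize(ncap * NCLASS, -1);
    }
    int i = L - 1;
    SiteRec fresh = {0, (std::uint8_t)(cap ? 0 : 2), 0, 0, 0};
    site[i] = fresh;  // fresh tip site: empty, GTP under the cap scenario
    sync_range(i - 1, i);
  }

  void do_hop(int i) {
    if (trains && site[i].cargo > 0) {
      int j = i;
      while (j > 0 && cargo_motor(j - 1)) --j;
      site[i + 1].motor = 1;
      for (int k = i + 1; k > j; --k) site[k].cargo = site[k - 1].cargo;
      site[j].motor = 0; site[j].cargo = 0;
      ++n_train_hop;
      sync_range(j - 1, i + 2);
    } else {
      site[i + 1].motor = 1; site[i + 1].cargo = site[i].cargo;
      site[i].motor = 0; site[i].cargo = 0;
      ++n_hop;
      sync_range(i - 1, i + 2);
    }
  }

  void execute(int c, int i) {
    switch (c) {
    case C_ATT:
      site[i].motor = 1; ++n_att; sync_range(i - 1, i + 1); break;
    case C_DET: case C_DETS:
      site[i].motor = 0; site[i].cargo = 0; ++n_det;
      sync_range(i - 1, i + 1); break;
    case C_HOPF: case C_HOPS:
      do_hop(i); break;
    case C_CBON:
      site[i].cargo = 1; ++n_cbind; sync_range(i - 1, i + 1); break;
    case C_CBOFF:
      site[i].cargo = 0; ++n_cunbind; sync_range(i - 1, i + 1); break;
    case C_MON:
      ++site[i].cargo; ++n_ads; sync_site(i); break;
    case C_MOFF:
      --site[i].cargo; ++n_des; sync_site(i); break;
    case C_H1:
      site[i].nuc = 1; ++n_h1; sync_range(i - 1, i); break;
    case C_H2:
      site[i].nuc = 2; ++n_h2; sync_range(i - 1, i); break;
    case C_EXITF: case C_EXITS:
      site[i].motor = 0; site[i].cargo = 0; ++n_exit;
      sync_range(i - 1, i + 1); break;
    }
  }

  List snapshot(double at_time) const {
    IntegerVector m(L), cg(L), nu(L);
    for (int i = 0; i < L; ++i) {
      m[i] = site[i].motor; cg[i] = site[i].cargo; nu[i] = site[i].nuc;
    }
    return List::create(
      _["time"] = at_time, _["length"] = L,
      _["motor"] = m, _["cargo"] = cg, _["nucleotide"] = nu);
  }
};

}  // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List pars, int L0, double t_equilibrate, int n_samples,
                double sample_interval) {
  if (n_samples < 1) stop("schedule must request at least one sample");
  double horizon = t_equilibrate + (double)(n_samples) * sample_interval;
  Engine eng;
  eng.setup(pars, L0, horizon);
  eng.rng.seed((std::uint64_t)(unif_rand() * 9007199254740992.0) + 1ULL);

  std::vector<List> snaps;
  snaps.reserve(n_samples);
  std::vector<double> times;
  times.reserve(n_samples);

  int k = 0;
  double next_t = t_equilibrate;
  long long n_events = 0;
  while (k < n_samples) {
    double tot = eng.total_rate();
    if (tot <= 0.0)
      stop("absorbing state at t=%g: no reaction has positive rate", eng.t);
    double dt = -std::log(eng.rng.unif()) / tot;
    // states are piecewise constant: the current state is the state at every
    // scheduled time inside (t, t + dt]
    while (k < n_samples && eng.t + dt >= next_t) {
      snaps.push_back(eng.snapshot(next_t));
      times.push_back(next_t);
      ++k;
      next_t = t_equilibrate + (double)k * sample_interval;
    }
    if (k >= n_samples) break;
    double r = eng.rng.unif() * tot;
    bool done = false;
    for (int c = 0; c < NCLASS; ++c) {
      int n = (int)eng.items[c].size();
      if (n == 0) continue;
      double w = n * eng.rate[c];
      if (r < w) {
        int idx = (int)(r / eng.rate[c]);
        if (idx >= n) idx = n - 1;
        eng.execute(c, eng.items[c][idx]);
        done = true;
        break;
      }
      r -= w;
    }
    if (!done) eng.grow_lattice();
    eng.t += dt;
    if ((++n_events & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  int n_motors = 0;
  for (int i = 0; i < eng.L; ++i) n_motors += eng.site[i].motor;

  return List::create(
    _["times"] = NumericVector(times.begin(), times.end()),
    _["states"] = List(snaps.begin(), snaps.end()),
    _["counts"] = NumericVector::create(
      _["attach"] = eng.n_att, _["detach"] = eng.n_det,
      _["hop"] = eng.n_hop, _["train_hop"] = eng.n_train_hop,
      _["cargo_bind"] = eng.n_cbind, _["cargo_unbind"] = eng.n_cunbind,
      _["cargo_adsorb"] = eng.n_ads, _["cargo_desorb"] = eng.n_des,
      _["hydrolysis1"] = eng.n_h1, _["hydrolysis2"] = eng.n_h2,
      _["grow"] = eng.n_grow, _["end_exit"] = eng.n_exit,
      _["events"] = (double)n_events),
    _["final_motor_count"] = n_motors,
    _["final_length"] = eng.L);
}

// Grey-level morphological erosion/dilation with a ball (spherical cap)
// structuring element; used by the rolling-ball background estimator.
// Outside-image offsets are ignored (the centre offset is always valid).
// [[Rcpp::export(name = ".ball_morph")]]
NumericMatrix ball_morph(NumericMatrix img, double radius, bool erode) {
  int nr = img.nrow(), nc = img.ncol();
  int ri = (int)std::floor(radius);
  std::vector<int> offx, offy;
  std::vector<double> height;
  for (int dy = -ri; dy <= ri; ++dy)
    for (int dx = -ri; dx <= ri; ++dx) {
      double d2 = (double)dx * dx + (double)dy * dy;
      if (d2 <= radius * radius) {
        offx.push_back(dx); offy.push_back(dy);
        height.push_back(std::sqrt(radius * radius - d2));
      }
    }
  int K = (int)offx.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = erode ? R_PosInf : R_NegInf;
      for (int k = 0; k < K; ++k) {
        int ii = i + offx[k], jj = j + offy[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double v = erode ? img(ii, jj) - height[k] : img(ii, jj) + height[k];
        if (erode ? (v < best) : (v > best)) best = v;
      }
      out(i, j) = best;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
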